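test_that("simulated gene counts match the requested density", {
  sim <- simulateReference(simParams(scaffold_length = 1e7,
                                     gene_density = 200, seed = 11))
  expect_equal(length(sim$genes), 2000)

  p290 <- simPreset("strongyloides_like", scaffold_length = 1e6, seed = 12)
  sim290 <- simulateReference(p290)
  expect_equal(length(sim290$genes), 290)
})

test_that("genes never overlap and never exceed scaffold bounds", {
  for (seed in c(1, 7, 23)) {
    sim <- simulateReference(simParams(n_scaffolds = 3,
                                       scaffold_length = c(5e5, 1e6, 2e6),
                                       seed = seed))
    tab <- data.frame(sc = as.character(seqnames(sim$genes)),
                      s = start(sim$genes), e = end(sim$genes))
    lens <- scaffoldLengths(sim$genome)
    expect_true(all(tab$s >= 1))
    expect_true(all(tab$e <= lens[tab$sc]))
    for (d in split(tab, tab$sc)) {
      d <- d[order(d$s), ]
      expect_true(all(d$s[-1] > d$e[-nrow(d)]))
    }
  }
})

test_that("a fixed seed reproduces the simulation bit-identically", {
  p <- simParams(scaffold_length = 3e5, seed = 42)
  a <- simulateReference(p)
  b <- simulateReference(p)
  expect_identical(a$genes, b$genes)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  writeAnnotationGff3(a$genes, f1)
  writeAnnotationGff3(b$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("impossible gene densities are rejected with a sizing error", {
  expect_error(
    simulateReference(simParams(scaffold_length = 1e5, gene_density = 400,
                                gene_length_mean = 5000,
                                gene_length_sd = 0, seed = 1)),
    "cannot fit")
})

test_that("zero-event evolution yields identity orthology and one block per scaffold", {
  sim <- simulateReference(simParams(n_scaffolds = 2, scaffold_length = 5e5,
                                     seed = 5))
  ev <- evolveQuery(sim$genome, sim$genes, evoParams(seed = 6))
  expect_equal(length(orthologPairs(ev$truth)$geneA), length(sim$genes))
  tb <- blockTable(ev$truth)
  expect_equal(nrow(tb), 2)
  expect_true(all(tb$orientation == "same"))
  ## query gene order equals reference order
  qo <- order(as.character(seqnames(ev$genes)), start(ev$genes))
  expect_identical(orthologPairs(ev$truth)$geneB,
                   mcols(ev$genes)$gene_id[qo])
})

test_that("an inversion introduces two block boundaries and flips strand", {
  sim <- simulateReference(simParams(scaffold_length = 5e5, seed = 8))
  ev <- evolveQuery(sim$genome, sim$genes,
                    evoParams(n_inversions = 1,
                              rearrangement_span_mean = 10, seed = 3))
  evs <- truthEvents(ev$truth)
  expect_equal(nrow(evs), 1)
  span <- evs$start_index[1]:evs$end_index[1]
  n <- length(sim$genes)
  ## interior span -> three truth blocks, the middle one inverted
  expect_gt(evs$start_index[1], 1)
  expect_lt(evs$end_index[1], n)
  tb <- blockTable(ev$truth)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$orientation, c("same", "inverted", "same"))
  expect_equal(tb$n_anchors[2], length(span))
  ## strands of the inverted genes flipped relative to the reference
  pairs <- orthologPairs(ev$truth)
  ref_strand <- as.character(strand(sim$genes))[
    match(pairs$geneA, mcols(sim$genes)$gene_id)]
  qry_strand <- as.character(strand(ev$genes))[
    match(pairs$geneB, mcols(ev$genes)$gene_id)]
  flipped <- ref_strand != qry_strand
  ref_idx <- match(pairs$geneA, mcols(sim$genes)$gene_id)
  expect_setequal(ref_idx[flipped], span)
})

test_that("truth blocks agree with brute-force maximal co-ordered runs", {
  sim <- simulateReference(simParams(scaffold_length = 3e5, seed = 21))
  for (seed in 1:5) {
    ev <- evolveQuery(sim$genome, sim$genes,
                      evoParams(n_inversions = 2, n_transpositions = 2,
                                rearrangement_span_mean = 4, seed = seed))
    pairs <- orthologPairs(ev$truth)
    ## permutation: query ortholog rank in reference ortholog-rank order
    ra <- match(pairs$geneA, mcols(sim$genes)$gene_id)
    qo <- order(start(ev$genes))
    qrank <- match(pairs$geneB, mcols(ev$genes)$gene_id[qo])
    perm <- qrank[order(ra)]
    runs <- oracleRuns(perm)
    tb <- blockTable(ev$truth)
    expect_equal(nrow(tb), length(runs))
    expect_equal(tb$n_anchors, lengths(runs))
  }
})

test_that("ortholog loss follows the binomial expectation", {
  sim <- simulateReference(simParams(scaffold_length = 1e7, seed = 31))
  ev <- evolveQuery(sim$genome, sim$genes,
                    evoParams(ortholog_loss_fraction = 0.1, seed = 32))
  n_pairs <- nrow(orthologPairs(ev$truth))
  expect_gt(n_pairs, 1760)   # 1800 +- 3 sd
  expect_lt(n_pairs, 1840)
})

test_that("event counts in the truth log equal the request exactly", {
  sim <- simulateReference(simParams(scaffold_length = 1e6, seed = 41))
  ev <- evolveQuery(sim$genome, sim$genes,
                    evoParams(n_inversions = 3, n_transpositions = 2,
                              rearrangement_span_mean = 3, seed = 42))
  evs <- truthEvents(ev$truth)
  expect_equal(sum(evs$type == "inversion"), 3)
  expect_equal(sum(evs$type == "transposition"), 2)
})

test_that("degradeAnnotation removes a random subset and keeps coordinates", {
  sim <- simulateReference(simParams(scaffold_length = 1e7, seed = 51))
  expect_identical(degradeAnnotation(sim$genes, 0), sim$genes)
  deg <- degradeAnnotation(sim$genes, 0.05, seed = 52)
  expect_gt(length(deg), 1870)   # 1900 +- ~3 sd
  expect_lt(length(deg), 1930)
  keep <- match(mcols(deg)$gene_id, mcols(sim$genes)$gene_id)
  expect_identical(start(deg), start(sim$genes)[keep])
  expect_identical(end(deg), end(sim$genes)[keep])
  expect_error(degradeAnnotation(sim$genes, 1), "missing_fraction")
})
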