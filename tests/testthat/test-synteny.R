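## small helper: collinear annotations with given orphan layout
collinearPair <- function(nA, orphanA = integer(0), orphanB = integer(0)) {
  idsA <- sprintf("a%03d", seq_len(nA))
  idsB <- sprintf("b%03d", seq_len(nA))
  startsA <- seq(1, by = 1000, length.out = nA)
  a <- makeGenes("cA", startsA, startsA + 500, idsA)
  b <- makeGenes("cB", startsA, startsA + 500, idsB)
  keep <- setdiff(seq_len(nA), union(orphanA, orphanB))
  orth <- OrthologyMap(idsA[keep], idsB[keep])
  list(a = a, b = b, orth = orth)
}

test_that("anchor ranks count every gene, orphans included", {
  p <- collinearPair(3)
  anc <- buildAnchors(p$orth, p$a, p$b)
  expect_equal(anc$rankA, 1:3)
  expect_equal(anc$rankB, 1:3)

  ## an orphan gene between pairs consumes a rank on its genome
  p2 <- collinearPair(3, orphanA = 2)
  anc2 <- buildAnchors(p2$orth, p2$a, p2$b)
  expect_equal(anc2$rankA, c(1, 3))
  expect_equal(anc2$rankB, c(1, 3))

  empty <- buildAnchors(OrthologyMap(character(0), character(0)), p$a, p$b)
  expect_equal(nrow(empty), 0)
})

test_that("buildAnchors names missing gene ids in its error", {
  p <- collinearPair(3)
  bad <- OrthologyMap(c("a001", "zzz"), c("b001", "b002"))
  expect_error(buildAnchors(bad, p$a, p$b), "zzz")
})

test_that("collinear, reversed and gap-split layouts chain as expected", {
  p <- collinearPair(5)
  cp <- chainParams(min_anchors = 3, max_gap_genes = 10)
  b1 <- blockTable(chainAnchors(buildAnchors(p$orth, p$a, p$b), cp))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$orientation, "same")
  expect_equal(b1$n_anchors, 5)

  ## genome B carries the segment reversed -> one inverted block
  bRev <- makeGenes("cB", seq(1, by = 1000, length.out = 5),
                    seq(1, by = 1000, length.out = 5) + 500,
                    sprintf("b%03d", 5:1))
  b2 <- blockTable(chainAnchors(buildAnchors(p$orth, p$a, bRev), cp))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$orientation, "inverted")

  ## 3 anchors, 12 orphans, 3 anchors with max gap 10 -> two blocks
  n <- 18
  idsA <- sprintf("a%03d", 1:n); idsB <- sprintf("b%03d", 1:n)
  s <- seq(1, by = 1000, length.out = n)
  a <- makeGenes("cA", s, s + 500, idsA)
  b <- makeGenes("cB", s, s + 500, idsB)
  pairs_idx <- c(1:3, 16:18)
  orth <- OrthologyMap(idsA[pairs_idx], idsB[pairs_idx])
  b3 <- blockTable(chainAnchors(buildAnchors(orth, a, b), cp))
  expect_equal(nrow(b3), 2)
  expect_equal(b3$n_anchors, c(3, 3))
})

test_that("blocks span first to last anchor gene on both genomes", {
  p <- collinearPair(6, orphanB = 6)
  cp <- chainParams(min_anchors = 3, max_gap_genes = 10)
  b <- blockTable(chainAnchors(buildAnchors(p$orth, p$a, p$b), cp))
  expect_equal(b$startA, 1)
  expect_equal(b$endA, 4501)   # fifth gene's end; the orphan lies outside
  expect_equal(b$endB, 4501)
})

test_that("chaining equals exhaustive enumeration on random instances", {
  set.seed(202)
  for (i in 1:80) {
    n <- sample(4:9, 1)
    ra <- sort(sample.int(30, n))
    rb <- sample.int(30, n)
    gap <- sample(0:6, 1)
    minA <- sample(2:3, 1)
    anchors <- data.frame(
      geneA = sprintf("a%02d", seq_len(n)), geneB = sprintf("b%02d", seq_len(n)),
      scaffoldA = "cA", scaffoldB = "cB",
      rankA = ra, rankB = rb,
      startA = ra * 100, endA = ra * 100 + 50,
      startB = rb * 100, endB = rb * 100 + 50,
      strandA = "+", strandB = "+", stringsAsFactors = FALSE)
    got <- chainAnchors(anchors, chainParams(minA, gap))
    want <- oracleChainSets(ra, rb, gap, minA)
    expect_equal(length(got), length(want))
    got_sets <- vapply(blockAnchors(got), function(d)
      paste(sort(d$rankA), collapse = ","), character(1))
    want_sets <- vapply(want, function(w)
      paste(sort(ra[w$idx]), collapse = ","), character(1))
    expect_setequal(got_sets, want_sets)
    got_ori <- blockTable(got)$orientation[order(got_sets)]
    want_ori <- vapply(want, function(w) w$orientation, "")[
      order(want_sets)]
    expect_equal(got_ori, want_ori)
  }
})

test_that("coverage merges overlapping block intervals before summing", {
  gen <- Genome(c(s = 200))
  blocks <- data.frame(scaffoldA = "s", startA = c(1, 41), endA = c(60, 100),
                       scaffoldB = "x", startB = c(1, 41), endB = c(60, 100),
                       orientation = "same", n_anchors = 5)
  expect_equal(syntenyCoverage(blocks, gen, "A")$coverage, 50)

  one <- data.frame(scaffoldA = "s", startA = 1, endA = 200,
                    scaffoldB = "x", startB = 1, endB = 200,
                    orientation = "same", n_anchors = 5)
  expect_equal(syntenyCoverage(one, gen, "A")$coverage, 100)

  bad <- transform(one, scaffoldA = "nope")
  expect_error(syntenyCoverage(bad, gen, "A"), "nope")
})

test_that("self-comparison gives one all-gene block per scaffold and symmetric coverage", {
  sim <- simulateReference(simParams(n_scaffolds = 2, scaffold_length = 4e5,
                                     seed = 71))
  orth <- orthologyFromTruth(identityTruth(sim$genes), sim$genes, sim$genes)
  blocks <- chainAnchors(buildAnchors(orth, sim$genes, sim$genes))
  tb <- blockTable(blocks)
  expect_equal(nrow(tb), 2)
  expect_equal(sum(tb$n_anchors), length(sim$genes))
  covA <- syntenyCoverage(blocks, sim$genome, "A")$coverage
  covB <- syntenyCoverage(blocks, sim$genome, "B")$coverage
  expect_equal(covA, covB)
  ## closed form: per-scaffold span from first gene start to last gene end
  tab <- data.frame(sc = as.character(seqnames(sim$genes)),
                    s = start(sim$genes), e = end(sim$genes))
  span <- sum(vapply(split(tab, tab$sc),
                     function(d) max(d$e) - min(d$s) + 1, numeric(1)))
  expect_equal(covA, 100 * span / genomeSize(sim$genome))
})

test_that("reversing genome B maps same blocks to inverted and keeps coverage", {
  sim <- simulateReference(simParams(scaffold_length = 3e5, seed = 81))
  genes <- sim$genes
  L <- genomeSize(sim$genome)
  rev_genes <- makeGenes(as.character(seqnames(genes)),
                         L - end(genes) + 1, L - start(genes) + 1,
                         mcols(genes)$gene_id,
                         seqlen = scaffoldLengths(sim$genome))
  orth <- orthologyFromTruth(identityTruth(genes), genes, genes)
  fwd <- chainAnchors(buildAnchors(orth, genes, genes))
  rev <- chainAnchors(buildAnchors(orth, genes, rev_genes))
  expect_equal(blockTable(fwd)$orientation, "same")
  expect_equal(blockTable(rev)$orientation, "inverted")
  expect_equal(syntenyCoverage(fwd, sim$genome, "A")$coverage,
               syntenyCoverage(rev, sim$genome, "A")$coverage)
})

test_that("coverage is monotone in the chaining parameters", {
  set.seed(303)
  sim <- simulateReference(simParams(scaffold_length = 2e5, seed = 91))
  genes <- sim$genes
  gen <- sim$genome
  for (i in 1:10) {
    ## anchor-loss-only instance: identity order, random orphans
    keep <- runif(length(genes)) > 0.35
    ids <- mcols(genes)$gene_id[keep]
    orth <- OrthologyMap(ids, ids)
    anc <- buildAnchors(orth, genes, genes)
    cov <- function(minA, gap)
      syntenyCoverage(chainAnchors(anc, chainParams(minA, gap)),
                      gen, "A")$coverage
    expect_lte(cov(5, 5), cov(3, 5))   # fewer required anchors: never less
    expect_lte(cov(3, 2), cov(3, 8))   # larger tolerated gaps: never less
    expect_lte(cov(5, 10), cov(2, 10))
  }
})
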