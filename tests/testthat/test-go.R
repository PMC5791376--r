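test_that("break genes are exactly the genes intersecting no block", {
  genes <- makeGenes("s", c(10, 200, 400, 550), c(100, 300, 500, 650),
                     c("g1", "g2", "g3", "g4"))
  all_cov <- data.frame(scaffoldA = "x", startA = 1, endA = 10,
                        scaffoldB = "s", startB = 1, endB = 1000,
                        orientation = "same", n_anchors = 5)
  expect_equal(genesInBreaks(all_cov, genes, side = "B"), character(0))
  none <- all_cov[0, ]
  expect_setequal(genesInBreaks(none, genes, side = "B"),
                  c("g1", "g2", "g3", "g4"))
  ## a gene straddling a block edge intersects it and is not a break gene
  part <- transform(all_cov, startB = 250, endB = 1000)
  expect_setequal(genesInBreaks(part, genes, side = "B"), "g1")
})

test_that("break-gene calls match an interval-intersection oracle", {
  set.seed(404)
  for (i in 1:20) {
    n <- 30
    s <- sort(sample.int(5000, n))
    genes <- makeGenes("s", s, s + sample.int(80, n, replace = TRUE),
                       sprintf("g%02d", 1:n))
    nb <- sample(1:4, 1)
    bs <- sort(sample.int(5000, nb))
    blocks <- data.frame(scaffoldA = "x", startA = 1, endA = 10,
                         scaffoldB = "s", startB = bs,
                         endB = bs + sample.int(800, nb, replace = TRUE),
                         orientation = "same", n_anchors = 5)
    got <- genesInBreaks(blocks, genes, side = "B")
    want <- vapply(seq_len(n), function(k) {
      !any(start(genes)[k] <= blocks$endB & end(genes)[k] >= blocks$startB)
    }, logical(1))
    expect_setequal(got, mcols(genes)$gene_id[want])
  }
})

test_that("Fisher p-values equal the hypergeometric tail enumeration", {
  universe <- sprintf("u%02d", 1:20)
  selected <- universe[1:5]
  ## a term annotating exactly the selected genes
  go <- data.frame(gene = selected, term = "GO:X")
  res <- fisherEnrichment(selected, universe, go, min_annotated = 3)
  expect_equal(res$pvalue, 1 / choose(20, 5))
  expect_equal(res$pvalue, oracleHyperTail(5, 5, 20, 5))

  ## random tables, universe <= 25
  set.seed(505)
  for (i in 1:25) {
    N <- sample(10:25, 1)
    n <- sample(3:(N - 2), 1)
    K <- sample(3:N, 1)
    uni <- sprintf("g%02d", 1:N)
    sel <- sample(uni, n)
    withterm <- sample(uni, K)
    go <- data.frame(gene = withterm, term = "GO:Y")
    res <- fisherEnrichment(sel, uni, go, min_annotated = 3)
    k <- length(intersect(sel, withterm))
    expect_equal(res$pvalue, oracleHyperTail(k, K, N, n), tolerance = 1e-12)
    ## cross-check against stats::fisher.test
    ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - (n - k)), 2),
                      alternative = "greater")
    expect_equal(res$pvalue, unname(ft$p.value), tolerance = 1e-9)
  }
})

test_that("proportionally distributed terms are not called enriched", {
  universe <- sprintf("u%03d", 1:100)
  selected <- universe[1:20]
  ## term annotates 20% of selected and 20% of the rest
  go <- data.frame(gene = c(selected[1:4], universe[21:100][1:16]),
                   term = "GO:FLAT")
  res <- fisherEnrichment(selected, universe, go)
  expect_gte(res$pvalue, 0.5)
})

test_that("terms below min_annotated are excluded and BH never lowers p", {
  universe <- sprintf("u%02d", 1:30)
  go <- rbind(data.frame(gene = universe[1:2], term = "GO:TINY"),
              data.frame(gene = universe[1:10], term = "GO:BIG"),
              data.frame(gene = universe[5:20], term = "GO:MID"))
  res <- fisherEnrichment(universe[1:8], universe, go, min_annotated = 3)
  expect_false("GO:TINY" %in% res$term)
  expect_true(all(res$padj >= res$pvalue))
  ## p-values invariant under gene relabelling
  perm <- setNames(sample(universe), universe)
  go2 <- transform(go, gene = unname(perm[gene]))
  res2 <- fisherEnrichment(unname(perm[universe[1:8]]), universe, go2,
                           min_annotated = 3)
  expect_equal(sort(res$pvalue), sort(res2$pvalue))
  expect_equal(nrow(fisherEnrichment(character(0), universe, go)), 0)
})

test_that("a spiked term in the selected set recovers rank 1", {
  genes <- sprintf("g%04d", 1:1000)
  sel <- genes[101:200]
  go <- simulateGOAnnotation(genes, n_terms = 80, spike_genes = sel,
                             seed = 9)
  res <- fisherEnrichment(sel, genes, go)
  expect_equal(res$term[res$rank == 1], "GO:SPIKE")
})

test_that("identical replicates give a diagonal stability matrix, zero flags", {
  genes <- sprintf("g%04d", 1:500)
  sel <- genes[1:60]
  go <- simulateGOAnnotation(genes, n_terms = 40, spike_genes = sel,
                             seed = 19)
  orig <- fisherEnrichment(sel, genes, go)
  stab <- rankStability(orig, replicate(5, orig, simplify = FALSE))
  cm <- stabilityCounts(stab)
  expect_true(all(cm[cbind(seq_len(nrow(cm)), seq_len(nrow(cm)))] == 5))
  expect_equal(sum(cm) - sum(diag(cm[, seq_len(nrow(cm))])), 0)
  fl <- stabilityFlags(stab)
  expect_equal(nrow(fl$intruders), 0)
  expect_equal(nrow(fl$dropouts), 0)
  expect_equal(nrow(fl$shifts), 0)
  ## every row tallies exactly one bucket per replicate
  expect_true(all(rowSums(cm) == 5))
})

test_that("dropouts and intruders are flagged with their occurrence counts", {
  mk <- function(terms) {
    data.frame(term = terms, n_selected = 5, n_universe = 10,
               size_selected = 50, size_universe = 200,
               pvalue = seq_along(terms) * 1e-4,
               padj = seq_along(terms) * 1e-3,
               rank = seq_along(terms), stringsAsFactors = FALSE)
  }
  orig <- mk(sprintf("GO:%03d", 1:120))
  ## replicate drops the original rank-10 term and promotes term 111
  rep1 <- mk(c(sprintf("GO:%03d", 1:9), "GO:111",
               sprintf("GO:%03d", c(10:110, 112:120))))
  stab <- rankStability(orig, list(rep1, rep1, rep1))
  fl <- stabilityFlags(stab)
  expect_equal(fl$dropouts$term, "GO:010")
  expect_equal(fl$dropouts$count, 3)
  expect_equal(fl$intruders$term, "GO:111")
  expect_equal(fl$intruders$count, 3)
  cm <- stabilityCounts(stab)
  expect_equal(unname(cm["GO:010", "out"]), 3)
})
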