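test_that("scaffolding a self-fragmented genome reconstructs gene order", {
  sim <- simulateReference(simParams(scaffold_length = 1e6, seed = 33))
  fr <- fragmentAssembly(sim$genome, 1e5, seed = 34)
  fGenes <- remapAnnotation(sim$genes, fr$breakMap)
  orth <- orthologyFromTruth(identityTruth(sim$genes), sim$genes, fGenes)
  sc <- scaffoldByReference(fr$genome, fGenes, sim$genes, orth)
  p <- placements(sc$plan)
  expect_true(all(p$orientation == "+"))
  ## reconstructed order of surviving genes equals the original order
  got <- mcols(sc$genes)$gene_id[order(as.character(seqnames(sc$genes)),
                                       start(sc$genes))]
  want <- mcols(sim$genes)$gene_id[mcols(sim$genes)$gene_id %in% got]
  expect_identical(got, want)
  ## round trip is adjacency-faithful and inflates N50 back up
  blocks <- chainAnchors(buildAnchors(
    orthologyFromTruth(identityTruth(sim$genes), sim$genes, sc$genes),
    sim$genes, sc$genes))
  rep <- assessCollinearity(blocks, identityTruth(sim$genes), sc$plan,
                            fr$breakMap, fr$genome, sc$genome, sim$genes)
  expect_equal(rep$false_joins, 0)
  expect_equal(rep$lost_breakpoints, 0)
  expect_gt(rep$n50_after, rep$n50_before)
  expect_equal(rep$pairs$rank_correlation, 1)
})

test_that("placed fragment lengths are conserved inside pseudochromosomes", {
  sim <- simulateReference(simParams(scaffold_length = 5e5, seed = 43))
  fr <- fragmentAssembly(sim$genome, 5e4, seed = 44)
  fGenes <- remapAnnotation(sim$genes, fr$breakMap)
  orth <- orthologyFromTruth(identityTruth(sim$genes), sim$genes, fGenes)
  sc <- scaffoldByReference(fr$genome, fGenes, sim$genes, orth,
                            gap_length = 100)
  p <- placements(sc$plan)
  frag_lens <- scaffoldLengths(fr$genome)
  expect_equal(p$end - p$start + 1, unname(frag_lens[p$fragment]))
  for (ps in unique(p$pseudochrom)) {
    d <- p[p$pseudochrom == ps, ]
    expect_equal(unname(scaffoldLengths(sc$genome)[ps]),
                 sum(d$end - d$start + 1) + 100 * (nrow(d) - 1))
  }
})

test_that("fragments without anchored genes stay unplaced", {
  ref <- makeGenes("chr", c(100, 1100), c(600, 1600), c("r1", "r2"))
  refGen <- Genome(c(chr = 2000))
  fragGen <- Genome(c(f1 = 1000, f2 = 1000, bare = 500))
  fGenes <- makeGenes(c("f1", "f2"), c(100, 100), c(600, 600),
                      c("q1", "q2"))
  orth <- OrthologyMap(c("r1", "r2"), c("q1", "q2"))
  expect_warning(sc0 <- scaffoldByReference(Genome(c(bare = 500)),
                                            fGenes[0], ref,
                                            OrthologyMap(character(0),
                                                         character(0))),
                 "unplaced")
  sc <- scaffoldByReference(fragGen, fGenes, ref, orth)
  expect_equal(unplacedFragments(sc$plan), "bare")
  expect_true("bare" %in% names(scaffoldLengths(sc$genome)))
  expect_equal(nrow(placements(sc$plan)), 2)
})

test_that("whole-fragment inversions are erased by reference scaffolding", {
  sim <- simulateReference(simParams(scaffold_length = 4e6, seed = 53))
  ev <- evolveQuery(sim$genome, sim$genes,
                    evoParams(n_inversions = 2,
                              rearrangement_span_mean = 120,
                              span_min = 80, seed = 54))
  fr <- fragmentAssembly(ev$genome, 1e5, seed = 55)
  fGenes <- remapAnnotation(ev$genes, fr$breakMap)
  orth <- orthologyFromTruth(ev$truth, sim$genes, fGenes)
  sc <- scaffoldByReference(fr$genome, fGenes, sim$genes, orth)
  orth2 <- orthologyFromTruth(ev$truth, sim$genes, sc$genes)
  blocks <- chainAnchors(buildAnchors(orth2, sim$genes, sc$genes))
  rep <- assessCollinearity(blocks, ev$truth, sc$plan, fr$breakMap,
                            fr$genome, sc$genome, sim$genes)
  expect_equal(rep$n_true_inversions, 2)
  expect_equal(rep$orientation_loss, 2)
  expect_gt(rep$false_joins, 0)
  ## before scaffolding the inversions ARE seen as inverted anchors; after,
  ## the relationship is falsely near-collinear (only partially-inverted
  ## boundary fragments may leave a residual inverted block)
  direct <- blockTable(chainAnchors(buildAnchors(orth, sim$genes, fGenes)))
  after <- blockTable(blocks)
  inv_anchors_before <- sum(direct$n_anchors[direct$orientation == "inverted"])
  inv_anchors_after <- sum(after$n_anchors[after$orientation == "inverted"])
  expect_gt(inv_anchors_before, 0)
  expect_lt(inv_anchors_after, 0.2 * inv_anchors_before)
})
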