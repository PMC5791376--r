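#' Simulate a gene-ontology annotation
#'
#' Term sizes follow a Zipf law (term t annotates a fraction of the genome
#' proportional to 1/t^exponent), genes are annotated independently, and one
#' optional "spiked" term is concentrated in a designated gene set — the
#' handle used for parameter-recovery tests, where the spiked term must
#' reach rank 1 when its gene set is selected.
#'
#' @param gene_ids character vector of genes to annotate.
#' @param n_terms number of GO-like terms (ids `GO:0000001`, ...).
#' @param zipf_exponent decay of term sizes across ranks.
#' @param max_term_fraction fraction of genes annotated by the largest term.
#' @param spike_genes optional character vector: genes carrying the spiked
#'   term.
#' @param spike_term id of the spiked term (default `"GO:SPIKE"`).
#' @param spike_prob probability that a spike gene carries the spiked term.
#' @param background_prob probability that any other gene carries it.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `term` (GAF-like two-column
#'   association).
#' @export
simulateGOAnnotation <- function(gene_ids, n_terms = 100L,
                                 zipf_exponent = 1,
                                 max_term_fraction = 0.2,
                                 spike_genes = NULL,
                                 spike_term = "GO:SPIKE",
                                 spike_prob = 0.9,
                                 background_prob = 0.01,
                                 seed = 1L) {
  stopifnot(length(gene_ids) > 0, n_terms >= 1,
            max_term_fraction > 0, max_term_fraction <= 1)
  set.seed(seed)
  n <- length(gene_ids)
  p_term <- max_term_fraction / (seq_len(n_terms)^zipf_exponent)
  rows <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    hit <- runif(n) < p_term[t]
    if (any(hit))
      rows[[t]] <- data.frame(gene = gene_ids[hit],
                              term = sprintf("GO:%07d", t),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(spike_genes)) {
    spiked <- runif(n) < ifelse(gene_ids %in% spike_genes,
                                spike_prob, background_prob)
    if (any(spiked))
      out <- rbind(out, data.frame(gene = gene_ids[spiked],
                                   term = spike_term,
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Genes lying in synteny breaks
#'
#' Returns the genes whose interval does not intersect any merged synteny
#' block interval on the given genome side — the gene set whose functional
#' enrichment the break-analysis experiment interrogates. A gene straddling
#' a block edge intersects the block and is therefore *not* a break gene.
#'
#' @param blocks a [SyntenyBlocks-class] (or block data.frame).
#' @param genes annotation GRanges with `gene_id`, on the same genome side.
#' @param side `"A"` or `"B"`: which block side `genes` lives on.
#' @return character vector of gene ids.
#' @export
genesInBreaks <- function(blocks, genes, side = c("A", "B")) {
  side <- match.arg(side)
  b <- if (is(blocks, "SyntenyBlocks")) blockTable(blocks) else blocks
  ids <- mcols(genes)$gene_id
  if (nrow(b) == 0L) return(ids)
  bl <- GRanges(b[[paste0("scaffold", side)]],
                IRanges(b[[paste0("start", side)]],
                        b[[paste0("end", side)]]))
  gr <- GRanges(as.character(seqnames(genes)),
                IRanges(start(genes), end(genes)))
  hit <- IRanges::overlapsAny(gr, bl)
  ids[!hit]
}

#' Fisher over-representation test per GO term
#'
#' Classic per-term one-sided Fisher exact test (hypergeometric upper tail)
#' for over-representation of each term in the selected set versus the
#' universe, for terms annotating at least `min_annotated` universe genes.
#' P-values are Benjamini-Hochberg adjusted; ranks are 1..n by ascending
#' p-value with lexicographic term-id tie-breaking, so output is
#' deterministic.
#'
#' @param selected character vector of selected genes (subset of universe).
#' @param universe character vector: the background gene set.
#' @param go GO association data.frame with columns `gene`, `term`.
#' @param min_annotated minimum universe genes per tested term (default 3).
#' @return data.frame with one row per tested term: `term`, `n_selected`
#'   (selected genes with the term), `n_universe` (universe genes with the
#'   term), `size_selected`, `size_universe`, `pvalue`, `padj`, `rank`.
#' @export
fisherEnrichment <- function(selected, universe, go, min_annotated = 3L) {
  stopifnot(min_annotated >= 1)
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  empty <- data.frame(term = character(0), n_selected = integer(0),
                      n_universe = integer(0), size_selected = integer(0),
                      size_universe = integer(0), pvalue = numeric(0),
                      padj = numeric(0), rank = integer(0))
  if (length(selected) == 0L) return(empty)
  go <- go[go$gene %in% universe, , drop = FALSE]
  K <- table(go$term)
  terms <- names(K)[K >= min_annotated]
  if (length(terms) == 0L) return(empty)
  go <- go[go$term %in% terms, , drop = FALSE]
  k <- table(factor(go$term[go$gene %in% selected], levels = terms))
  K <- as.integer(K[terms])
  k <- as.integer(k)
  N <- length(universe)
  n <- length(selected)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, n_selected = k, n_universe = K,
                    size_selected = n, size_universe = N,
                    pvalue = p, padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank stability of top GO terms across fragmentation replicates
#'
#' For each term in the original top-k, tallies which rank bucket (1..k, or
#' "out of top k") it occupied in each replicate. Flags three instability
#' modes: *intruders* (terms outside the original top-100 entering a
#' replicate top-k), *dropouts* (original top-k terms absent from a
#' replicate top-k), and *shifts* (original top-k terms retained in the
#' top-k but at a different rank).
#'
#' @param original [fisherEnrichment()] result of the un-fragmented
#'   comparison.
#' @param replicates list of [fisherEnrichment()] results, one per
#'   fragmentation replicate.
#' @param top_k number of top ranks tracked (default 10).
#' @return a [StabilityMatrix-class].
#' @export
rankStability <- function(original, replicates, top_k = 10L) {
  stopifnot(length(replicates) >= 1, top_k >= 1)
  top <- original$term[original$rank <= top_k]
  top100 <- original$term[original$rank <= 100L]
  k_eff <- length(top)
  counts <- matrix(0L, nrow = k_eff, ncol = top_k + 1L,
                   dimnames = list(top, c(as.character(seq_len(top_k)),
                                          "out")))
  intr <- list()
  drop <- stats::setNames(integer(k_eff), top)
  shft <- stats::setNames(integer(k_eff), top)
  for (rep in replicates) {
    rr <- rep$rank[match(top, rep$term)]
    bucket <- ifelse(is.na(rr) | rr > top_k, top_k + 1L, rr)
    for (i in seq_len(k_eff))
      counts[i, bucket[i]] <- counts[i, bucket[i]] + 1L
    out_of_top <- bucket == top_k + 1L
    drop[out_of_top] <- drop[out_of_top] + 1L
    orig_rank <- original$rank[match(top, original$term)]
    moved <- !out_of_top & bucket != orig_rank
    shft[moved] <- shft[moved] + 1L
    rep_top <- rep$term[rep$rank <= top_k]
    new_terms <- setdiff(rep_top, top100)
    for (tm in new_terms) intr[[tm]] <- (intr[[tm]] %||% 0L) + 1L
  }
  flags <- list(
    intruders = data.frame(term = as.character(names(intr)),
                           count = if (length(intr)) as.integer(unlist(intr))
                                   else integer(0),
                           stringsAsFactors = FALSE),
    dropouts = data.frame(term = names(drop[drop > 0L]),
                          count = as.integer(drop[drop > 0L]),
                          stringsAsFactors = FALSE),
    shifts = data.frame(term = names(shft[shft > 0L]),
                        count = as.integer(shft[shft > 0L]),
                        stringsAsFactors = FALSE))
  new("StabilityMatrix", counts = counts, flags = flags,
      topK = as.numeric(top_k), nReplicates = length(replicates))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
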