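#' Restrict truth orthology to surviving genes
#'
#' The default anchor source of the pipeline: the simulation's known
#' one-to-one orthology, restricted to genes present in both provided
#' annotations (i.e. genes surviving fragmentation or annotation
#' degradation). This models the anchor-loss mechanism without
#' orthology-inference noise. Idempotent under repeated restriction.
#'
#' @param truth a [TruthSet-class] (or an [OrthologyMap-class]).
#' @param annotA,annotB annotation GRanges with `gene_id` for the two sides.
#' @return an [OrthologyMap-class].
#' @export
orthologyFromTruth <- function(truth, annotA, annotB) {
  pairs <- if (is(truth, "TruthSet")) orthologPairs(truth)
           else orthologPairs(truth)
  keep <- pairs$geneA %in% mcols(annotA)$gene_id &
          pairs$geneB %in% mcols(annotB)$gene_id
  OrthologyMap(pairs[keep, , drop = FALSE])
}

#' Reciprocal best hits on a similarity matrix
#'
#' A pair (a, b) is reported iff b is a's best hit and a is b's best hit,
#' with ties at the top broken by lexicographic gene id on each side; a pair
#' that survives tie-breaking on both sides is kept. Higher scores mean more
#' similar.
#'
#' @param sim numeric matrix of similarity scores, rownames = genes of
#'   genome A, colnames = genes of genome B; all finite.
#' @return an [OrthologyMap-class].
#' @examples
#' m <- matrix(c(9, 1, 1, 8), 2, 2, byrow = TRUE,
#'             dimnames = list(c("a1", "a2"), c("b1", "b2")))
#' orthologPairs(reciprocalBestHits(m))
#' @export
reciprocalBestHits <- function(sim) {
  if (length(sim) == 0L)
    return(OrthologyMap(character(0), character(0)))
  stopifnot(is.matrix(sim), all(is.finite(sim)),
            !is.null(rownames(sim)), !is.null(colnames(sim)))
  bestIn <- function(scores, ids) {
    top <- ids[scores == max(scores)]
    sort(top)[1L]                      # lexicographic tie-break
  }
  best_col <- vapply(seq_len(nrow(sim)),
                     function(i) bestIn(sim[i, ], colnames(sim)),
                     character(1))
  best_row <- vapply(seq_len(ncol(sim)),
                     function(j) bestIn(sim[, j], rownames(sim)),
                     character(1))
  names(best_col) <- rownames(sim)
  names(best_row) <- colnames(sim)
  a <- rownames(sim)
  b <- best_col[a]
  keep <- best_row[b] == a
  OrthologyMap(a[keep], unname(b[keep]))
}
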