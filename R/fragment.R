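#' Randomly fragment an assembly into fixed-size pieces
#'
#' For each scaffold longer than `fragment_size`, a phase offset is drawn
#' uniformly in `[0, fragment_size)` and the scaffold is cut at
#' `offset, offset + fragment_size, ...`, yielding an optional short leading
#' piece, a run of exact `fragment_size` pieces, and an optional short
#' remainder. Scaffolds no longer than `fragment_size` pass through
#' unchanged (keeping their name). Total length is conserved exactly.
#' Fragments are named `<scaffold>_frag<k>` in source order.
#'
#' @param genome a [Genome-class] (sequences, if present, are sliced too).
#' @param fragment_size target fragment size in bp (>= 1).
#' @param seed integer seed for the per-scaffold offsets.
#' @return list with `genome` (the fragmented [Genome-class]) and
#'   `breakMap` (a [BreakMap-class] tracing fragments to source
#'   coordinates).
#' @examples
#' fr <- fragmentAssembly(Genome(c(chr1 = 10000)), 3000, seed = 1)
#' breakTable(fr$breakMap)
#' @export
fragmentAssembly <- function(genome, fragment_size, seed = 1L) {
  stopifnot(is(genome, "Genome"), fragment_size >= 1)
  fragment_size <- round(fragment_size)
  set.seed(seed)
  lens <- scaffoldLengths(genome)
  rows <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    L <- lens[i]
    sc <- names(lens)[i]
    if (L <= fragment_size) {
      rows[[i]] <- data.frame(fragment = sc, source = sc,
                              start = 1, end = L,
                              stringsAsFactors = FALSE)
      next
    }
    o <- floor(runif(1L, 0, fragment_size))
    n_full <- floor((L - o) / fragment_size)
    edges <- c(if (o > 0) o,
               if (n_full > 0) o + fragment_size * seq_len(n_full))
    edges <- unique(c(0, edges[edges < L], L))
    k <- length(edges) - 1L
    rows[[i]] <- data.frame(
      fragment = sprintf("%s_frag%d", sc, seq_len(k)),
      source = sc,
      start = edges[-length(edges)] + 1,
      end = edges[-1L],
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  new_lens <- map$end - map$start + 1
  names(new_lens) <- map$fragment
  seqs <- NULL
  if (!is.null(genome@sequences)) {
    seqs <- Biostrings::subseq(genome@sequences[map$source],
                               start = map$start, end = map$end)
    names(seqs) <- map$fragment
  }
  list(genome = Genome(new_lens, seqs),
       breakMap = new("BreakMap", map = map,
                      fragmentSize = fragment_size, seed = as.numeric(seed)))
}

#' Remap an annotation onto assembly fragments
#'
#' Genes fully contained in a fragment are shifted to fragment coordinates;
#' genes overlapping any break point are dropped, modelling the loss of
#' anchors when fragmentation breaks within genes. Retained genes keep their
#' length and id exactly.
#'
#' @param genes annotation GRanges with `gene_id`, on the break map's source
#'   scaffolds.
#' @param breakMap a [BreakMap-class] from [fragmentAssembly()].
#' @return the remapped GRanges (gene count less than or equal to the input).
#' @export
remapAnnotation <- function(genes, breakMap) {
  stopifnot(is(breakMap, "BreakMap"))
  map <- breakMap@map
  tab <- .annotTable(genes)
  unknown <- setdiff(unique(tab$scaffold), unique(map$source))
  if (length(unknown))
    stop("annotation references scaffold(s) unknown to the break map: ",
         paste(unknown, collapse = ", "))
  frag_gr <- GRanges(map$source, IRanges(map$start, map$end))
  gene_gr <- GRanges(tab$scaffold, IRanges(tab$start, tab$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, frag_gr, type = "within")
  gi <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  frag_lens <- map$end - map$start + 1
  names(frag_lens) <- map$fragment
  out <- GRanges(map$fragment[fi],
                 IRanges(tab$start[gi] - map$start[fi] + 1,
                         tab$end[gi] - map$start[fi] + 1),
                 strand = tab$strand[gi],
                 seqlengths = frag_lens)
  mcols(out)$gene_id <- tab$gene_id[gi]
  out
}
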