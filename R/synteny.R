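#' Chaining parameters for synteny detection
#'
#' Defaults follow the common anchor-chaining convention: at least five gene
#' anchors per block, up to ten skipped gene ranks between consecutive
#' anchors (gaps measured in genes without orthology assignment, not in
#' unaligned nucleotides).
#'
#' @param min_anchors minimum anchors per reported block (>= 2).
#' @param max_gap_genes maximum number of skipped gene ranks between
#'   consecutive anchors, on both genomes (>= 0).
#' @return a validated `ChainParams` list.
#' @export
chainParams <- function(min_anchors = 5L, max_gap_genes = 10L) {
  stopifnot(min_anchors >= 2, max_gap_genes >= 0)
  structure(list(min_anchors = as.integer(min_anchors),
                 max_gap_genes = as.integer(max_gap_genes)),
            class = "ChainParams")
}

#' Build anchors from an orthology map
#'
#' One anchor per ortholog pair, carrying the gene-rank index of each gene
#' along its scaffold. Ranks are assigned by gene-start order over *all*
#' genes of the scaffold, so genes without orthologs consume a rank and act
#' as gaps during chaining.
#'
#' @param orth an [OrthologyMap-class] (geneA on side A, geneB on side B).
#' @param annotA,annotB annotation GRanges with `gene_id`.
#' @return data.frame of anchors: `geneA`, `geneB`, `scaffoldA`, `scaffoldB`,
#'   `rankA`, `rankB`, `startA`, `endA`, `startB`, `endB`, `strandA`,
#'   `strandB`.
#' @export
buildAnchors <- function(orth, annotA, annotB) {
  pairs <- orthologPairs(orth)
  ta <- .annotTable(annotA)
  tb <- .annotTable(annotB)
  missA <- setdiff(pairs$geneA, ta$gene_id)
  missB <- setdiff(pairs$geneB, tb$gene_id)
  if (length(missA) || length(missB))
    stop("orthology references gene id(s) absent from the annotation: ",
         paste(utils::head(c(missA, missB), 5L), collapse = ", "))
  rankWithin <- function(t) {
    r <- integer(nrow(t))
    for (d in split(seq_len(nrow(t)), t$scaffold))
      r[d] <- rank(t$start[d], ties.method = "first")
    r
  }
  ta$rank <- rankWithin(ta)
  tb$rank <- rankWithin(tb)
  ia <- match(pairs$geneA, ta$gene_id)
  ib <- match(pairs$geneB, tb$gene_id)
  out <- data.frame(geneA = pairs$geneA, geneB = pairs$geneB,
                    scaffoldA = ta$scaffold[ia], scaffoldB = tb$scaffold[ib],
                    rankA = ta$rank[ia], rankB = tb$rank[ib],
                    startA = ta$start[ia], endA = ta$end[ia],
                    startB = tb$start[ib], endB = tb$end[ib],
                    strandA = ta$strand[ia], strandB = tb$strand[ib],
                    stringsAsFactors = FALSE)
  out <- out[order(out$scaffoldA, out$scaffoldB, out$rankA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Longest valid chain among anchors (ra strictly increasing order assumed).
## A chain advances by 1..gap+1 ranks on A and, in one fixed direction, by
## 1..gap+1 ranks on B. Returns the maximum-length chain; ties broken by
## orientation ("same" first) then by lexicographically smallest rankA
## sequence, which makes extraction deterministic.
.bestChain <- function(ra, rb, gap) {
  n <- length(ra)
  G <- gap + 1L
  best <- NULL
  for (dir in c(1L, -1L)) {
    F <- integer(n)                    # longest chain starting at i
    nxt <- vector("list", n)
    for (i in n:1) {
      da <- ra - ra[i]
      db <- dir * (rb - rb[i])
      succ <- which(da >= 1L & da <= G & db >= 1L & db <= G)
      if (length(succ)) {
        m <- max(F[succ])
        F[i] <- m + 1L
        nxt[[i]] <- succ[F[succ] == m]
      } else F[i] <- 1L
    }
    len <- max(F)
    starts <- which(F == len)
    i <- starts[1L]                    # ra sorted: first = smallest rankA
    chain <- i
    while (F[i] > 1L) {
      cand <- nxt[[i]]
      i <- cand[1L]                    # smallest rankA successor
      chain <- c(chain, i)
    }
    if (is.null(best) || len > best$len)
      best <- list(len = len, idx = chain,
                   orientation = if (dir == 1L) "same" else "inverted")
  }
  best
}

#' Chain anchors into synteny blocks
#'
#' Within each scaffold pair, maximal chains of anchors are extracted
#' greedily, longest first: consecutive anchors must advance by at most
#' `max_gap_genes + 1` gene ranks on both genomes, strictly increasing on
#' genome A and uniformly monotone (one direction per block) on genome B.
#' Chains shorter than `min_anchors` are discarded; each anchor belongs to
#' at most one reported block. Mixed orientations never share a block.
#' Block spans run from the start of the first anchor gene to the end of the
#' last anchor gene on each genome. Deterministic: length ties prefer
#' same-orientation chains, then the lexicographically smallest rank
#' sequence.
#'
#' @param anchors anchor data.frame from [buildAnchors()].
#' @param params a [chainParams()] list.
#' @return a [SyntenyBlocks-class].
#' @export
chainAnchors <- function(anchors, params = chainParams()) {
  stopifnot(inherits(params, "ChainParams"))
  cols <- c("scaffoldA", "startA", "endA", "scaffoldB", "startB", "endB",
            "orientation", "n_anchors")
  empty <- data.frame(scaffoldA = character(0), startA = numeric(0),
                      endA = numeric(0), scaffoldB = character(0),
                      startB = numeric(0), endB = numeric(0),
                      orientation = character(0), n_anchors = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(anchors) || nrow(anchors) == 0L)
    return(new("SyntenyBlocks", blocks = empty, anchors = list(),
               params = unclass(params)))
  groups <- split(anchors,
                  paste(anchors$scaffoldA, anchors$scaffoldB, sep = "\r"))
  blk_rows <- list()
  blk_anch <- list()
  for (g in groups) {
    g <- g[order(g$rankA), , drop = FALSE]
    remaining <- seq_len(nrow(g))
    while (length(remaining) >= params$min_anchors) {
      b <- .bestChain(g$rankA[remaining], g$rankB[remaining],
                      params$max_gap_genes)
      if (b$len < params$min_anchors) break
      idx <- remaining[b$idx]
      ga <- g[idx, , drop = FALSE]
      blk_rows[[length(blk_rows) + 1L]] <- data.frame(
        scaffoldA = ga$scaffoldA[1L],
        startA = min(ga$startA), endA = max(ga$endA),
        scaffoldB = ga$scaffoldB[1L],
        startB = min(ga$startB), endB = max(ga$endB),
        orientation = b$orientation, n_anchors = nrow(ga),
        stringsAsFactors = FALSE)
      blk_anch[[length(blk_anch) + 1L]] <- ga
      remaining <- setdiff(remaining, idx)
    }
  }
  if (length(blk_rows) == 0L)
    return(new("SyntenyBlocks", blocks = empty, anchors = list(),
               params = unclass(params)))
  blocks <- do.call(rbind, blk_rows)
  ord <- order(blocks$scaffoldA, blocks$startA, blocks$scaffoldB,
               blocks$startB)
  blocks <- blocks[ord, cols, drop = FALSE]
  rownames(blocks) <- NULL
  new("SyntenyBlocks", blocks = blocks, anchors = blk_anch[ord],
      params = unclass(params))
}

#' Synteny coverage of a genome
#'
#' Block intervals are merged (union) per scaffold before summing, and the
#' merged length is divided by total assembly size. Coverage is asymmetric
#' between the two genomes of a comparison; compute it per side.
#'
#' @param blocks a [SyntenyBlocks-class] (or a block data.frame).
#' @param genome the [Genome-class] of the requested side.
#' @param side `"A"` or `"B"`: which side of the blocks lies on `genome`.
#' @return list with `coverage` (percent), `merged_length` (bp),
#'   `genome_size` (bp) and `side`.
#' @export
syntenyCoverage <- function(blocks, genome, side = c("A", "B")) {
  side <- match.arg(side)
  b <- if (is(blocks, "SyntenyBlocks")) blockTable(blocks) else blocks
  lens <- scaffoldLengths(genome)
  merged <- 0
  if (nrow(b) > 0L) {
    sc <- b[[paste0("scaffold", side)]]
    unknown <- setdiff(unique(sc), names(lens))
    if (length(unknown))
      stop("block(s) on scaffold(s) unknown to the genome: ",
           paste(unknown, collapse = ", "))
    ir <- IRanges(b[[paste0("start", side)]], b[[paste0("end", side)]])
    merged <- sum(vapply(split(ir, sc),
                         function(x) sum(IRanges::width(IRanges::reduce(x))),
                         numeric(1)))
  }
  list(coverage = 100 * merged / sum(lens),
       merged_length = merged,
       genome_size = sum(lens),
       side = side)
}
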