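## Independent brute-force oracles used to pin down expected values.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## GRanges annotation from plain vectors
makeGenes <- function(scaffold, start, end, ids,
                      strand = rep("+", length(start)),
                      seqlen = NULL) {
  gr <- GRanges(scaffold, IRanges(start, end), strand = strand,
                seqlengths = seqlen)
  mcols(gr)$gene_id <- ids
  gr
}

## Definition scan for N50: largest length l such that sequences >= l hold
## at least half the assembly.
bruteN50 <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (l in cand) if (sum(lengths[lengths >= l]) >= half) return(l)
  min(lengths)
}

## All valid chains among anchors (ra strictly increasing order), by
## exhaustive subset enumeration. Returns list of index vectors + direction.
enumerateChains <- function(ra, rb, gap) {
  n <- length(ra)
  G <- gap + 1
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    idx <- idx[order(ra[idx])]
    if (length(idx) == 1L) {
      out[[length(out) + 1L]] <- list(idx = idx, dir = 1L)
      next
    }
    da <- diff(ra[idx])
    db <- diff(rb[idx])
    if (any(da < 1 | da > G)) next
    s <- sign(db[1])
    if (any(sign(db) != s) || any(abs(db) < 1 | abs(db) > G)) next
    out[[length(out) + 1L]] <- list(idx = idx, dir = s)
  }
  out
}

## Greedy longest-first chain extraction by exhaustive enumeration,
## mirroring the documented tie-breaks: length desc, then same-orientation
## first, then lexicographically smallest rankA sequence.
oracleChainSets <- function(ra, rb, gap, min_anchors) {
  remaining <- seq_along(ra)
  res <- list()
  repeat {
    if (length(remaining) < min_anchors) break
    chains <- enumerateChains(ra[remaining], rb[remaining], gap)
    lens <- vapply(chains, function(c) length(c$idx), integer(1))
    if (max(lens) < min_anchors) break
    best <- chains[lens == max(lens)]
    dirs <- vapply(best, function(c) c$dir, numeric(1))
    if (any(dirs == 1)) best <- best[dirs == 1]
    keys <- vapply(best, function(c)
      paste(sprintf("%09d", ra[remaining][c$idx]), collapse = ","),
      character(1))
    pick <- best[[order(keys)[1]]]
    res[[length(res) + 1L]] <- list(
      idx = remaining[pick$idx],
      orientation = if (pick$dir >= 0) "same" else "inverted")
    remaining <- setdiff(remaining, remaining[pick$idx])
  }
  res
}

## Maximal co-ordered runs of a permutation (query ortholog rank as a
## function of reference ortholog rank): independent check of truth blocks.
oracleRuns <- function(perm) {
  n <- length(perm)
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    dir <- 0L
    while (j < n) {
      step <- perm[j + 1L] - perm[j]
      if (abs(step) != 1L || (dir != 0L && step != dir)) break
      if (dir == 0L) dir <- step
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

## Upper hypergeometric tail by direct enumeration of the support.
oracleHyperTail <- function(k, K, N, n) {
  js <- max(0, k):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
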