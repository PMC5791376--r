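#' @describeIn scaffoldLengths method for Genome
#' @export
setMethod("scaffoldLengths", "Genome", function(x) x@lengths)

#' @describeIn genomeSize method for Genome
#' @export
setMethod("genomeSize", "Genome", function(x) sum(x@lengths))

#' @describeIn n50 method for numeric length vectors
#' @export
setMethod("n50", "numeric", function(x) {
  if (length(x) == 0L) stop("n50: empty length vector")
  if (any(!is.finite(x)) || any(x <= 0)) stop("n50: lengths must be positive")
  s <- sort(x, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
})

#' @describeIn n50 method for Genome
#' @export
setMethod("n50", "Genome", function(x) n50(unname(x@lengths)))

setMethod("names", "Genome", function(x) names(x@lengths))
setMethod("length", "Genome", function(x) length(x@lengths))

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome: %d scaffold(s), %s bp total, N50 %s bp, %s\n",
              length(object@lengths),
              format(sum(object@lengths), big.mark = ","),
              format(n50(object), big.mark = ","),
              if (is.null(object@sequences)) "coordinates only"
              else "with sequence"))
  k <- min(5L, length(object@lengths))
  for (i in seq_len(k))
    cat(sprintf("  %s: %s bp\n", names(object@lengths)[i],
                format(object@lengths[i], big.mark = ",")))
  if (length(object@lengths) > k) cat("  ...\n")
})

#' @describeIn orthologPairs method for OrthologyMap
#' @export
setMethod("orthologPairs", "OrthologyMap", function(x) x@pairs)

#' @describeIn orthologPairs truth orthology of a TruthSet
#' @export
setMethod("orthologPairs", "TruthSet",
          function(x) orthologPairs(x@orthology))

setMethod("length", "OrthologyMap", function(x) nrow(x@pairs))

setMethod("show", "OrthologyMap", function(object) {
  cat(sprintf("OrthologyMap: %d one-to-one pair(s)\n", nrow(object@pairs)))
})

#' @describeIn blockTable true blocks of a TruthSet
#' @export
setMethod("blockTable", "TruthSet", function(x) x@trueBlocks)

#' @describeIn truthEvents method for TruthSet
#' @export
setMethod("truthEvents", "TruthSet", function(x) x@events)

setMethod("show", "TruthSet", function(object) {
  cat(sprintf(
    "TruthSet: %d ortholog pair(s), %d true block(s), %d applied event(s)\n",
    nrow(object@orthology@pairs), nrow(object@trueBlocks),
    nrow(object@events)))
})

#' @describeIn breakTable method for BreakMap
#' @export
setMethod("breakTable", "BreakMap", function(x) x@map)

#' Target fragment size of a BreakMap
#' @param x a [BreakMap-class].
#' @return fragment size in bp.
#' @export
fragmentSize <- function(x) {
  stopifnot(is(x, "BreakMap"))
  x@fragmentSize
}

setMethod("show", "BreakMap", function(object) {
  cat(sprintf(
    "BreakMap: %d fragment(s) of %d scaffold(s), target size %s bp, seed %d\n",
    nrow(object@map), length(unique(object@map$source)),
    format(object@fragmentSize, big.mark = ","), as.integer(object@seed)))
})

#' @describeIn blockTable method for SyntenyBlocks
#' @export
setMethod("blockTable", "SyntenyBlocks", function(x) x@blocks)

#' @describeIn blockAnchors method for SyntenyBlocks
#' @export
setMethod("blockAnchors", "SyntenyBlocks", function(x) x@anchors)

setMethod("length", "SyntenyBlocks", function(x) nrow(x@blocks))

setMethod("show", "SyntenyBlocks", function(object) {
  b <- object@blocks
  cat(sprintf(
    "SyntenyBlocks: %d block(s) (%d same, %d inverted), %d anchor(s) total\n",
    nrow(b), sum(b$orientation == "same"), sum(b$orientation == "inverted"),
    sum(b$n_anchors)))
})

#' @describeIn sweepReplicates method for SweepReport
#' @export
setMethod("sweepReplicates", "SweepReport", function(x) x@replicates)

#' @describeIn sweepSummary method for SweepReport
#' @export
setMethod("sweepSummary", "SweepReport", function(x) x@summary)

#' @describeIn sweepBaseline method for SweepReport
#' @export
setMethod("sweepBaseline", "SweepReport", function(x) x@baseline)

setMethod("show", "SweepReport", function(object) {
  cat(sprintf(
    "SweepReport: baseline coverage %.2f%%, %d size(s) x %d replicate(s)\n",
    object@baseline, nrow(object@summary),
    max(object@replicates$replicate)))
  print(object@summary, row.names = FALSE)
})

#' @describeIn placements method for ScaffoldingPlan
#' @export
setMethod("placements", "ScaffoldingPlan", function(x) x@placements)

#' @describeIn unplacedFragments method for ScaffoldingPlan
#' @export
setMethod("unplacedFragments", "ScaffoldingPlan", function(x) x@unplaced)

setMethod("show", "ScaffoldingPlan", function(object) {
  cat(sprintf(
    "ScaffoldingPlan: %d fragment(s) placed on %d pseudochromosome(s), %d unplaced, gap %d N\n",
    nrow(object@placements),
    length(unique(object@placements$pseudochrom)),
    length(object@unplaced), as.integer(object@gapLength)))
})

#' @describeIn stabilityCounts method for StabilityMatrix
#' @export
setMethod("stabilityCounts", "StabilityMatrix", function(x) x@counts)

#' @describeIn stabilityFlags method for StabilityMatrix
#' @export
setMethod("stabilityFlags", "StabilityMatrix", function(x) x@flags)

setMethod("show", "StabilityMatrix", function(object) {
  cat(sprintf(
    "StabilityMatrix: top %d term(s) over %d replicate(s); %d intruder, %d dropout, %d shift flag(s)\n",
    as.integer(object@topK), as.integer(object@nReplicates),
    nrow(object@flags$intruders), nrow(object@flags$dropouts),
    nrow(object@flags$shifts)))
})
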