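#' Scaffold lengths of a Genome
#'
#' @param x a [Genome-class].
#' @return named numeric vector of scaffold lengths in bp.
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))

#' Total assembly size
#'
#' @param x a [Genome-class].
#' @return total length in bp.
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' N50 contiguity statistic
#'
#' The largest length L such that sequences of length >= L together contain at
#' least half of the assembly.
#'
#' @param x a numeric vector of sequence lengths, or a [Genome-class].
#' @return the N50 in bp.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
setGeneric("n50", function(x) standardGeneric("n50"))

#' Block table of a SyntenyBlocks object
#'
#' @param x a [SyntenyBlocks-class] (or [TruthSet-class], whose true blocks
#'   are returned).
#' @return data.frame of block coordinates.
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))

#' Anchors supporting each detected block
#'
#' @param x a [SyntenyBlocks-class].
#' @return list of data.frames, one per block, anchors in chain order.
#' @export
setGeneric("blockAnchors", function(x) standardGeneric("blockAnchors"))

#' Ortholog pairs as a data.frame
#'
#' @param x an [OrthologyMap-class] or [TruthSet-class].
#' @return data.frame with columns `geneA`, `geneB`.
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))

#' Event log of a simulated evolution
#'
#' @param x a [TruthSet-class].
#' @return data.frame of applied events.
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' Fragment table of a BreakMap
#'
#' @param x a [BreakMap-class].
#' @return data.frame with columns `fragment`, `source`, `start`, `end`
#'   (1-based closed source coordinates).
#' @export
setGeneric("breakTable", function(x) standardGeneric("breakTable"))

#' Per-replicate rows of a sweep
#'
#' @param x a [SweepReport-class].
#' @return data.frame with one row per (size, replicate).
#' @export
setGeneric("sweepReplicates", function(x) standardGeneric("sweepReplicates"))

#' Per-size summary of a sweep
#'
#' @param x a [SweepReport-class].
#' @return data.frame with median/quartile error rates per fragment size.
#' @export
setGeneric("sweepSummary", function(x) standardGeneric("sweepSummary"))

#' Baseline (un-fragmented) coverage of a sweep
#'
#' @param x a [SweepReport-class].
#' @return baseline reference-side coverage in percent.
#' @export
setGeneric("sweepBaseline", function(x) standardGeneric("sweepBaseline"))

#' Placement table of a scaffolding plan
#'
#' @param x a [ScaffoldingPlan-class].
#' @return data.frame of placed fragments.
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))

#' Fragments a scaffolding plan could not place
#'
#' @param x a [ScaffoldingPlan-class].
#' @return character vector of fragment names.
#' @export
setGeneric("unplacedFragments",
           function(x) standardGeneric("unplacedFragments"))

#' Rank-occurrence counts of a stability analysis
#'
#' @param x a [StabilityMatrix-class].
#' @return integer matrix (original top-k terms x replicate rank buckets).
#' @export
setGeneric("stabilityCounts", function(x) standardGeneric("stabilityCounts"))

#' Instability flags of a stability analysis
#'
#' @param x a [StabilityMatrix-class].
#' @return list with data.frames `intruders`, `dropouts`, `shifts`.
#' @export
setGeneric("stabilityFlags", function(x) standardGeneric("stabilityFlags"))
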