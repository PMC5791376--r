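#' @import methods
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' Genome: an ordered collection of named scaffolds
#'
#' Lightweight container for an assembly: scaffold names, scaffold lengths and
#' (optionally) nucleotide sequences. Anchor-based synteny detection only uses
#' coordinates, so sequences are optional and can be attached or generated on
#' demand (see [writeGenomeFasta()]).
#'
#' @slot lengths named numeric vector of scaffold lengths (bp), in assembly
#'   order.
#' @slot sequences a [Biostrings::DNAStringSet] matching `lengths`, or `NULL`.
#'
#' @seealso [Genome()], [scaffoldLengths()], [genomeSize()], [n50()]
#' @export
setClass("Genome", representation(lengths = "numeric",
                                  sequences = "DNAStringSetOrNULL"))

setValidity("Genome", function(object) {
  len <- object@lengths
  if (is.null(names(len)) || anyNA(names(len)) || any(names(len) == ""))
    return("all scaffolds must be named")
  if (anyDuplicated(names(len)))
    return("scaffold names must be unique")
  if (length(len) == 0L)
    return("a Genome needs at least one scaffold")
  if (any(!is.finite(len)) || any(len < 1) || any(len != round(len)))
    return("scaffold lengths must be positive whole numbers of bp")
  if (!is.null(object@sequences)) {
    if (!identical(names(object@sequences), names(len)))
      return("sequence names must match scaffold names (same order)")
    if (!identical(as.numeric(Biostrings::width(object@sequences)),
                   as.numeric(len)))
      return("sequence widths must match scaffold lengths")
  }
  TRUE
})

#' Construct a Genome
#'
#' @param lengths named numeric vector of scaffold lengths in bp.
#' @param sequences optional [Biostrings::DNAStringSet] with matching names
#'   and widths.
#' @return a [Genome-class] object.
#' @examples
#' gen <- Genome(c(chr1 = 1e6, chr2 = 5e5))
#' genomeSize(gen)
#' @export
Genome <- function(lengths, sequences = NULL) {
  new("Genome", lengths = round(lengths), sequences = sequences)
}

#' One-to-one orthology between two gene sets
#'
#' Each gene appears in at most one pair; pairs are the source of synteny
#' anchors.
#'
#' @slot pairs data.frame with character columns `geneA`, `geneB`.
#' @seealso [OrthologyMap()], [orthologyFromTruth()], [reciprocalBestHits()]
#' @export
setClass("OrthologyMap", representation(pairs = "data.frame"))

setValidity("OrthologyMap", function(object) {
  p <- object@pairs
  if (!all(c("geneA", "geneB") %in% names(p)))
    return("pairs must have columns geneA and geneB")
  if (nrow(p) > 0L) {
    if (anyDuplicated(p$geneA) || anyDuplicated(p$geneB))
      return("orthology must be one-to-one: a gene may appear in one pair only")
    if (anyNA(p$geneA) || anyNA(p$geneB))
      return("gene ids must not be NA")
  }
  TRUE
})

#' Construct an OrthologyMap
#'
#' @param geneA,geneB character vectors of equal length, or `geneA` may be a
#'   two-column data.frame with columns `geneA`, `geneB`.
#' @return an [OrthologyMap-class] object.
#' @export
OrthologyMap <- function(geneA, geneB = NULL) {
  if (is.data.frame(geneA)) {
    pairs <- data.frame(geneA = as.character(geneA$geneA),
                        geneB = as.character(geneA$geneB),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(geneA = as.character(geneA),
                        geneB = as.character(geneB),
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  new("OrthologyMap", pairs = pairs)
}

#' Ground truth of a simulated genome pair
#'
#' Records, for an evolved query genome, the surviving one-to-one orthology,
#' the true synteny blocks implied by the applied rearrangements, and the
#' event log itself.
#'
#' @slot orthology an [OrthologyMap-class] (reference gene -> query gene).
#' @slot trueBlocks data.frame of blocks (scaffoldA, startA, endA, scaffoldB,
#'   startB, endB, orientation, n_anchors) tiling the orthologous gene
#'   complement.
#' @slot events data.frame logging every applied event (type, scaffold,
#'   start_index, end_index, insert_after).
#' @seealso [evolveQuery()]
#' @export
setClass("TruthSet", representation(orthology = "OrthologyMap",
                                    trueBlocks = "data.frame",
                                    events = "data.frame"))

#' Record of how scaffolds were fragmented
#'
#' Per input scaffold, the ordered list of fragments (with 1-based closed
#' source coordinates) that tile it exactly.
#'
#' @slot map data.frame with columns `fragment`, `source`, `start`, `end`.
#' @slot fragmentSize target fragment size in bp.
#' @slot seed integer seed used to draw the per-scaffold phase offsets.
#' @seealso [fragmentAssembly()], [remapAnnotation()]
#' @export
setClass("BreakMap", representation(map = "data.frame",
                                    fragmentSize = "numeric",
                                    seed = "numeric"))

setValidity("BreakMap", function(object) {
  m <- object@map
  need <- c("fragment", "source", "start", "end")
  if (!all(need %in% names(m)))
    return("map must have columns fragment, source, start, end")
  if (any(m$end < m$start)) return("fragment end before start")
  bad <- vapply(split(m, m$source), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    any(d$start[-1] != d$end[-nrow(d)] + 1) || d$start[1] != 1
  }, logical(1))
  if (any(bad))
    return(paste("fragments do not tile scaffold(s):",
                 paste(names(bad)[bad], collapse = ", ")))
  TRUE
})

#' Detected synteny blocks
#'
#' A set of chained anchor runs between two genomes. `blockTable()` gives the
#' per-block coordinates (1-based closed, as in GFF3) and `blockAnchors()` the
#' anchors supporting each block.
#'
#' @slot blocks data.frame: scaffoldA, startA, endA, scaffoldB, startB, endB,
#'   orientation ("same"/"inverted"), n_anchors.
#' @slot anchors list of data.frames, one per block row, each holding that
#'   block's anchors in chain order.
#' @slot params the [chainParams()] used for detection.
#' @seealso [chainAnchors()], [syntenyCoverage()]
#' @export
setClass("SyntenyBlocks", representation(blocks = "data.frame",
                                         anchors = "list",
                                         params = "list"))

setValidity("SyntenyBlocks", function(object) {
  b <- object@blocks
  need <- c("scaffoldA", "startA", "endA", "scaffoldB", "startB", "endB",
            "orientation", "n_anchors")
  if (!all(need %in% names(b)))
    return("blocks must have the standard block columns")
  if (nrow(b) != length(object@anchors))
    return("one anchor table per block row required")
  if (nrow(b) > 0L && !all(b$orientation %in% c("same", "inverted")))
    return("orientation must be 'same' or 'inverted'")
  TRUE
})

#' Replicate-resolved fragmentation sweep results
#'
#' @slot replicates data.frame with one row per (fragment size, replicate):
#'   `size`, `replicate`, `seed`, `coverage`, `error_rate`, `n50`.
#' @slot summary data.frame with one row per size: `size`, `median_error`,
#'   `q25`, `q75`, `median_coverage`.
#' @slot baseline baseline (un-fragmented) reference-side coverage in percent.
#' @slot config the [sweepConfig()] that produced the report.
#' @seealso [runSweep()], [requiredN50()]
#' @export
setClass("SweepReport", representation(replicates = "data.frame",
                                       summary = "data.frame",
                                       baseline = "numeric",
                                       config = "list"))

#' Reference-guided scaffolding plan
#'
#' @slot placements data.frame, one row per placed fragment: `pseudochrom`,
#'   `fragment`, `ref_scaffold`, `position` (median anchor reference
#'   coordinate), `orientation`, `start`, `end` (1-based closed coordinates on
#'   the pseudochromosome), `n_anchors`.
#' @slot unplaced character vector of fragments left out (no anchors or
#'   ambiguous scaffold assignment).
#' @slot gapLength length of the N-gap inserted between joined fragments.
#' @seealso [scaffoldByReference()], [assessCollinearity()]
#' @export
setClass("ScaffoldingPlan", representation(placements = "data.frame",
                                           unplaced = "character",
                                           gapLength = "numeric"))

#' GO-enrichment rank stability across fragmentation replicates
#'
#' @slot counts integer matrix: rows are the original top-k terms (in original
#'   rank order), columns are replicate rank buckets 1..k plus "out";
#'   each row sums to the number of replicates.
#' @slot flags list with data.frames `intruders` (terms outside the original
#'   top-100 entering a replicate top-k), `dropouts` (original top-k terms
#'   absent from a replicate top-k) and `shifts` (retained terms whose rank
#'   moved), each with a per-term occurrence count.
#' @slot topK number of top ranks tracked.
#' @slot nReplicates number of replicates tallied.
#' @seealso [rankStability()]
#' @export
setClass("StabilityMatrix", representation(counts = "matrix",
                                           flags = "list",
                                           topK = "numeric",
                                           nReplicates = "numeric"))
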