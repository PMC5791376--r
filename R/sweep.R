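#' Synteny-identification error rate
#'
#' The difference between the baseline synteny coverage measured with the
#' original (un-fragmented) genome pair and the coverage measured after
#' fragmentation, with the intact assembly used as the reference side in
#' both cases. The baseline is always the *measured* original coverage,
#' not an assumed 100%.
#'
#' @param cov_baseline,cov_fragmented coverages in percent, in `[0, 100]`.
#' @return the error rate in percent.
#' @examples
#' errorRate(100, 84)  # 16
#' @export
errorRate <- function(cov_baseline, cov_fragmented) {
  stopifnot(all(cov_baseline >= 0 & cov_baseline <= 100),
            all(cov_fragmented >= 0 & cov_fragmented <= 100))
  cov_baseline - cov_fragmented
}

#' Configuration of a fragmentation sweep
#'
#' @param fragment_sizes fragment sizes in bp, sorted ascending. Default
#'   `c(100e3, 200e3, 500e3, 1e6)`.
#' @param n_replicates fragmentation replicates per size (default 100; reduce
#'   for desk-scale runs).
#' @param base_seed integer; replicate r uses seed `base_seed + r`, so the
#'   same replicate seeds are reused across sizes and across sweeps sharing a
#'   base seed.
#' @param chain a [chainParams()] list for the detector.
#' @param mode `"self"` (query is a copy of the reference) or
#'   `"interspecies"` (an evolved query); informational, recorded in the
#'   report.
#' @return a validated `SweepConfig` list.
#' @export
sweepConfig <- function(fragment_sizes = c(100e3, 200e3, 500e3, 1e6),
                        n_replicates = 100L, base_seed = 1L,
                        chain = chainParams(),
                        mode = c("self", "interspecies")) {
  mode <- match.arg(mode)
  stopifnot(length(fragment_sizes) >= 1, all(fragment_sizes > 0),
            !is.unsorted(fragment_sizes), n_replicates >= 1,
            inherits(chain, "ChainParams"))
  structure(list(fragment_sizes = round(fragment_sizes),
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 chain = chain, mode = mode),
            class = "SweepConfig")
}

#' Run a fragmentation sweep
#'
#' For every fragment size and replicate: fragment the *query* genome (the
#' reference stays intact), remap its annotation, restrict the truth
#' orthology to surviving genes, detect synteny blocks, and record the
#' reference-side coverage, the error rate against the un-fragmented
#' baseline, and the realized N50. Replicate r uses seed
#' `base_seed + r`, so reruns with the same config are identical.
#'
#' @param refGenome,refGenes the intact reference genome and annotation.
#' @param queryGenome,queryGenes the query to be fragmented (for a
#'   self-comparison, pass the reference pair again with
#'   `truth = identityTruth(refGenes)`).
#' @param truth a [TruthSet-class] providing the anchor orthology.
#' @param config a [sweepConfig()] list.
#' @return a [SweepReport-class].
#' @seealso [requiredN50()], [plotSweep()]
#' @export
runSweep <- function(refGenome, refGenes, queryGenome, queryGenes, truth,
                     config = sweepConfig()) {
  stopifnot(inherits(config, "SweepConfig"))
  orth0 <- orthologyFromTruth(truth, refGenes, queryGenes)
  blocks0 <- chainAnchors(buildAnchors(orth0, refGenes, queryGenes),
                          config$chain)
  baseline <- syntenyCoverage(blocks0, refGenome, "A")$coverage
  rows <- vector("list", length(config$fragment_sizes) * config$n_replicates)
  k <- 0L
  for (size in config$fragment_sizes) {
    for (r in seq_len(config$n_replicates)) {
      seed_r <- config$base_seed + r
      fr <- fragmentAssembly(queryGenome, size, seed = seed_r)
      qGenes <- remapAnnotation(queryGenes, fr$breakMap)
      orth <- orthologyFromTruth(truth, refGenes, qGenes)
      blocks <- chainAnchors(buildAnchors(orth, refGenes, qGenes),
                             config$chain)
      cov <- syntenyCoverage(blocks, refGenome, "A")$coverage
      k <- k + 1L
      rows[[k]] <- data.frame(size = size, replicate = r, seed = seed_r,
                              coverage = cov,
                              error_rate = errorRate(baseline, cov),
                              n50 = n50(unname(scaffoldLengths(fr$genome))))
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, reps$size), function(d) {
    data.frame(size = d$size[1L],
               median_error = median(d$error_rate),
               q25 = unname(quantile(d$error_rate, 0.25)),
               q75 = unname(quantile(d$error_rate, 0.75)),
               median_coverage = median(d$coverage))
  }))
  agg <- agg[order(agg$size), , drop = FALSE]
  rownames(agg) <- NULL
  new("SweepReport", replicates = reps, summary = agg,
      baseline = baseline, config = unclass(config))
}

#' Minimum fragment size (N50) meeting an error threshold
#'
#' The smallest tested fragment size whose median error rate is at or below
#' `threshold`. Because fixed-size fragmentation realizes an N50 equal to
#' the fragment size, this is the sweep's N50 recommendation.
#'
#' @param report a [SweepReport-class] covering at least two sizes.
#' @param threshold error-rate threshold in percent (default 5).
#' @return the qualifying fragment size in bp, or `NA` with attribute
#'   `reason = "threshold unreachable"` if no tested size qualifies.
#' @export
requiredN50 <- function(report, threshold = 5) {
  stopifnot(is(report, "SweepReport"))
  s <- sweepSummary(report)
  if (nrow(s) < 2L)
    stop("requiredN50 needs a sweep over at least two fragment sizes")
  ok <- s$size[s$median_error <= threshold]
  if (length(ok) == 0L)
    return(structure(NA_real_, reason = "threshold unreachable"))
  min(ok)
}

#' Boxplot of error rate versus fragment size
#'
#' @param report a [SweepReport-class].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plotSweep <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSweep requires ggplot2")
  d <- sweepReplicates(report)
  d$size_label <- factor(sprintf("%g kb", d$size / 1e3),
                         levels = sprintf("%g kb", sort(unique(d$size)) / 1e3))
  ggplot2::ggplot(d, ggplot2::aes(x = size_label, y = error_rate)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = c(2, 5), linetype = c("dashed", "solid"),
                        colour = "grey50") +
    ggplot2::labs(x = "Fragment size (realized N50)",
                  y = "Error rate (%)") +
    ggplot2::theme_bw()
}
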