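## stable stage-seed derivation: global seed + fixed per-stage offset
.stageOffsets <- c(simulate = 101L, evolve = 202L, go = 303L,
                   sweep = 404L, fragment = 505L, sequence = 606L)

.stageSeed <- function(seed, stage) {
  seed + .stageOffsets[[stage]]
}

#' Assemble and validate an experiment configuration
#'
#' Ties the simulation, evolution, detection and evaluation stages into one
#' of the three packaged experiments: the fragmentation `sweep`, the
#' `go_stability` analysis, or the `scaffold_pitfall` scaffolding artifact
#' demonstration. Every stochastic stage receives a seed derived stably
#' from the global seed plus a fixed per-stage offset, so reruns are
#' byte-identical.
#'
#' @param experiment one of `"sweep"`, `"go_stability"`,
#'   `"scaffold_pitfall"`.
#' @param sim a [simParams()] list (e.g. from [simPreset()]); its seed is
#'   overridden by the derived stage seed.
#' @param evo an [evoParams()] list (ignored by the self-comparison sweep).
#' @param sweep a [sweepConfig()] list; its base seed is overridden by the
#'   derived stage seed.
#' @param go list of GO-stage settings: `n_terms`, `fragment_size`,
#'   `n_replicates`, `top_k`, `min_annotated`, `spike_prob`.
#' @param scaffold list of scaffolding-stage settings: `fragment_size`,
#'   `gap_length`.
#' @param outdir output directory (created if missing).
#' @param seed global integer seed.
#' @return a validated `ExperimentConfig` list.
#' @seealso [runExperiment()], [readExperimentConfig()]
#' @export
experimentConfig <- function(experiment = c("sweep", "go_stability",
                                            "scaffold_pitfall"),
                             sim = simParams(),
                             evo = evoParams(),
                             sweep = sweepConfig(),
                             go = list(),
                             scaffold = list(),
                             outdir = tempfile("fragsynt_"),
                             seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(sim, "SimParams"), inherits(evo, "EvoParams"),
            inherits(sweep, "SweepConfig"), length(seed) == 1L)
  go <- utils::modifyList(list(n_terms = 150L, fragment_size = 100e3,
                               n_replicates = 20L, top_k = 10L,
                               min_annotated = 3L, spike_prob = 0.9), go)
  scaffold <- utils::modifyList(list(fragment_size = 100e3,
                                     gap_length = 100), scaffold)
  sim$seed <- .stageSeed(seed, "simulate")
  evo$seed <- .stageSeed(seed, "evolve")
  sweep$base_seed <- .stageSeed(seed, "sweep")
  structure(list(experiment = experiment, sim = sim, evo = evo,
                 sweep = sweep, go = go, scaffold = scaffold,
                 outdir = outdir, seed = as.integer(seed)),
            class = "ExperimentConfig")
}

#' Read an experiment configuration from YAML
#'
#' Recognized top-level keys: `experiment`, `seed`, `outdir`, `preset`
#' (`caenorhabditis_like` or `strongyloides_like`), and the nested blocks
#' `sim`, `evo`, `sweep`, `go`, `scaffold`, whose entries are passed to
#' [simParams()], [evoParams()], [sweepConfig()] and [experimentConfig()].
#'
#' @param path YAML file.
#' @return an `ExperimentConfig` list.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ## tolerate numeric scalars YAML leaves as strings (e.g. "1.0e6")
  numify <- function(args) lapply(args, function(x) {
    if (is.character(x) && length(x) == 1L &&
        !is.na(suppressWarnings(as.numeric(x)))) as.numeric(x) else x
  })
  for (blk in c("sim", "evo", "sweep", "go", "scaffold", "chain"))
    y[[blk]] <- numify(y[[blk]] %||% list())
  sim_args <- y$sim %||% list()
  sim <- if (!is.null(y$preset)) do.call(simPreset, c(list(y$preset), sim_args))
         else do.call(simParams, sim_args)
  chain <- do.call(chainParams, y$chain %||% list())
  sweep_args <- y$sweep %||% list()
  sweep_args$chain <- chain
  if (!is.null(sweep_args$fragment_sizes))
    sweep_args$fragment_sizes <- as.numeric(unlist(sweep_args$fragment_sizes))
  experimentConfig(experiment = y$experiment %||% "sweep",
                   sim = sim,
                   evo = do.call(evoParams, y$evo %||% list()),
                   sweep = do.call(sweepConfig, sweep_args),
                   go = y$go %||% list(),
                   scaffold = y$scaffold %||% list(),
                   outdir = y$outdir %||% tempfile("fragsynt_"),
                   seed = y$seed %||% 1L)
}

#' Run a configured experiment end to end
#'
#' Executes simulate -> evolve -> (fragment -> restrict -> detect ->
#' evaluate) for the configured experiment, writing all summary TSVs plus a
#' `manifest.yaml` recording the derived stage seeds and run counts to the
#' output directory. Reruns with the same configuration produce identical
#' files.
#'
#' @param cfg an [experimentConfig()] list.
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
runExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(experiment = cfg$experiment, seed = cfg$seed,
                   derived_seeds = list(
                     simulate = .stageSeed(cfg$seed, "simulate"),
                     evolve = .stageSeed(cfg$seed, "evolve"),
                     go = .stageSeed(cfg$seed, "go"),
                     sweep = .stageSeed(cfg$seed, "sweep"),
                     fragment = .stageSeed(cfg$seed, "fragment")))
  ref <- simulateReference(cfg$sim)
  res <- switch(cfg$experiment,
    sweep = {
      if (cfg$sweep$mode == "self") {
        qry <- ref
        truth <- identityTruth(ref$genes)
      } else {
        e <- evolveQuery(ref$genome, ref$genes, cfg$evo)
        qry <- list(genome = e$genome, genes = e$genes)
        truth <- e$truth
      }
      report <- runSweep(ref$genome, ref$genes, qry$genome, qry$genes,
                         truth, cfg$sweep)
      .writeTsv(sweepReplicates(report),
                file.path(cfg$outdir, "sweep_replicates.tsv"))
      .writeTsv(sweepSummary(report),
                file.path(cfg$outdir, "sweep_summary.tsv"))
      manifest$n_detection_runs <-
        length(cfg$sweep$fragment_sizes) * cfg$sweep$n_replicates
      manifest$baseline_coverage <- sweepBaseline(report)
      list(report = report)
    },
    go_stability = {
      e <- evolveQuery(ref$genome, ref$genes, cfg$evo)
      truth <- e$truth
      orth0 <- orthologyFromTruth(truth, ref$genes, e$genes)
      blocks0 <- chainAnchors(buildAnchors(orth0, ref$genes, e$genes),
                              cfg$sweep$chain)
      break0 <- genesInBreaks(blocks0, e$genes, side = "B")
      universe <- mcols(e$genes)$gene_id
      go <- simulateGOAnnotation(universe, n_terms = cfg$go$n_terms,
                                 spike_genes = break0,
                                 spike_prob = cfg$go$spike_prob,
                                 seed = .stageSeed(cfg$seed, "go"))
      original <- fisherEnrichment(break0, universe, go,
                                   min_annotated = cfg$go$min_annotated)
      reps <- lapply(seq_len(cfg$go$n_replicates), function(r) {
        fr <- fragmentAssembly(e$genome, cfg$go$fragment_size,
                               seed = .stageSeed(cfg$seed, "fragment") + r)
        qg <- remapAnnotation(e$genes, fr$breakMap)
        orth <- orthologyFromTruth(truth, ref$genes, qg)
        blocks <- chainAnchors(buildAnchors(orth, ref$genes, qg),
                               cfg$sweep$chain)
        sel <- genesInBreaks(blocks, qg, side = "B")
        fisherEnrichment(sel, universe, go,
                         min_annotated = cfg$go$min_annotated)
      })
      stab <- rankStability(original, reps, top_k = cfg$go$top_k)
      .writeTsv(original, file.path(cfg$outdir, "original_enrichment.tsv"))
      .writeTsv(as.data.frame(stabilityCounts(stab)),
                file.path(cfg$outdir, "stability_matrix.tsv"))
      for (f in names(stabilityFlags(stab)))
        .writeTsv(stabilityFlags(stab)[[f]],
                  file.path(cfg$outdir, paste0("flags_", f, ".tsv")))
      manifest$n_detection_runs <- cfg$go$n_replicates + 1L
      list(original = original, replicates = reps, stability = stab)
    },
    scaffold_pitfall = {
      e <- evolveQuery(ref$genome, ref$genes, cfg$evo)
      truth <- e$truth
      fr <- fragmentAssembly(e$genome, cfg$scaffold$fragment_size,
                             seed = .stageSeed(cfg$seed, "fragment"))
      fGenes <- remapAnnotation(e$genes, fr$breakMap)
      orth <- orthologyFromTruth(truth, ref$genes, fGenes)
      sc <- scaffoldByReference(fr$genome, fGenes, ref$genes, orth,
                                gap_length = cfg$scaffold$gap_length)
      orth2 <- orthologyFromTruth(truth, ref$genes, sc$genes)
      blocks <- chainAnchors(buildAnchors(orth2, ref$genes, sc$genes),
                             cfg$sweep$chain)
      report <- assessCollinearity(blocks, truth, sc$plan, fr$breakMap,
                                   fr$genome, sc$genome, ref$genes)
      .writeTsv(placements(sc$plan), file.path(cfg$outdir, "plan.tsv"))
      .writeTsv(blockTable(blocks), file.path(cfg$outdir, "blocks.tsv"))
      .writeTsv(report$pairs, file.path(cfg$outdir, "pair_summary.tsv"))
      yaml::write_yaml(report[setdiff(names(report), "pairs")],
                       file.path(cfg$outdir, "collinearity.yaml"))
      manifest$n_detection_runs <- 1L
      list(scaffolded = sc, blocks = blocks, report = report)
    })
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  invisible(c(res, list(manifest = manifest, outdir = cfg$outdir)))
}
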