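#' @importFrom GenomicRanges GRanges start end strand seqnames findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom stats rlnorm rgeom rbinom median quantile runif cor setNames
NULL

## Integer draws from a log-normal parameterized by its arithmetic mean/sd,
## truncated below at 1 bp. Long right tail matches empirical intergenic
## length distributions.
.rlnormInt <- function(n, mean, sd) {
  if (n == 0L) return(integer(0))
  if (sd <= 0) return(pmax(1, round(rep(mean, n))))
  s2 <- log1p((sd / mean)^2)
  x <- rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  pmax(1, round(x))
}

#' Parameters for reference genome simulation
#'
#' Gene and intergenic lengths are drawn from log-normal distributions with
#' the stated arithmetic mean/sd, truncated at 1 bp. The realized gene count
#' per scaffold is `round(gene_density * scaffold_length / 1e6)` exactly.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length scaffold length(s) in bp (scalar, or one per
#'   scaffold).
#' @param gene_density genes per Mb.
#' @param gene_length_mean,gene_length_sd gene length distribution (bp).
#' @param intergenic_length_mean,intergenic_length_sd intergenic gap
#'   distribution (bp).
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @param scaffold_prefix prefix for scaffold names.
#' @return a validated `SimParams` list.
#' @seealso [simPreset()] for the nematode-like presets, [simulateReference()]
#' @export
simParams <- function(n_scaffolds = 1L, scaffold_length = 1e7,
                      gene_density = 200,
                      gene_length_mean = 3000, gene_length_sd = 2000,
                      intergenic_length_mean = 2000,
                      intergenic_length_sd = 2000,
                      seed = 1L, scaffold_prefix = "chr") {
  stopifnot(n_scaffolds >= 1, all(scaffold_length > 0), gene_density > 0,
            gene_length_mean > 0, gene_length_sd >= 0,
            intergenic_length_mean > 0, intergenic_length_sd >= 0,
            length(seed) == 1L, is.finite(seed))
  scaffold_length <- rep_len(round(scaffold_length), n_scaffolds)
  n_genes <- round(gene_density * scaffold_length / 1e6)
  if (any(n_genes < 1))
    stop("gene_density * scaffold_length must round to >= 1 gene per scaffold")
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = scaffold_length,
                 gene_density = gene_density,
                 gene_length_mean = gene_length_mean,
                 gene_length_sd = gene_length_sd,
                 intergenic_length_mean = intergenic_length_mean,
                 intergenic_length_sd = intergenic_length_sd,
                 seed = as.integer(seed),
                 scaffold_prefix = scaffold_prefix),
            class = "SimParams")
}

#' Nematode-like simulation presets
#'
#' Two presets named after the gene densities of the chromosome-scale genome
#' pairs the simulator emulates: `caenorhabditis_like` (200 genes/Mb, longer
#' genes and intergenic gaps) and `strongyloides_like` (290 genes/Mb, a more
#' compact genome).
#'
#' @param name preset name.
#' @param ... overrides passed on to [simParams()] (e.g. `scaffold_length`,
#'   `seed`).
#' @return a `SimParams` list.
#' @examples
#' p <- simPreset("caenorhabditis_like", scaffold_length = 1e6, seed = 7)
#' p$gene_density
#' @export
simPreset <- function(name = c("caenorhabditis_like", "strongyloides_like"),
                      ...) {
  name <- match.arg(name)
  base <- switch(name,
    caenorhabditis_like = list(gene_density = 200,
                               gene_length_mean = 3000, gene_length_sd = 2000,
                               intergenic_length_mean = 2000,
                               intergenic_length_sd = 2000),
    strongyloides_like = list(gene_density = 290,
                              gene_length_mean = 1300, gene_length_sd = 900,
                              intergenic_length_mean = 2100,
                              intergenic_length_sd = 2000))
  do.call(simParams, utils::modifyList(base, list(...)))
}

## Lay n genes on one scaffold: leading gap, gene, gap, gene, ... If the drawn
## gaps overshoot the scaffold they are scaled down (floored at 1 bp) so that
## exactly n genes always fit; an undershoot leaves a bare tail.
.layoutScaffold <- function(L, n, p) {
  glen <- .rlnormInt(n, p$gene_length_mean, p$gene_length_sd)
  avail <- L - sum(glen)
  if (avail < n)
    stop(sprintf(paste0("gene density too high: %d genes of mean %g bp ",
                        "cannot fit in a %g bp scaffold"),
                 n, p$gene_length_mean, L))
  gaps <- .rlnormInt(n, p$intergenic_length_mean, p$intergenic_length_sd)
  if (sum(gaps) > avail) {
    gaps <- pmax(1, floor(gaps * avail / sum(gaps)))
    excess <- sum(gaps) - avail
    if (excess > 0) {
      ord <- order(gaps, decreasing = TRUE)
      i <- 1L
      while (excess > 0) {
        j <- ord[(i - 1L) %% n + 1L]
        if (gaps[j] > 1) {
          gaps[j] <- gaps[j] - 1
          excess <- excess - 1
        }
        i <- i + 1L
      }
    }
  }
  starts <- cumsum(gaps) + c(0, cumsum(glen))[seq_len(n)] + 1
  list(start = starts, end = starts + glen - 1)
}

#' Simulate a reference genome and gene annotation
#'
#' Genes are laid down left-to-right with log-normal intergenic gaps; genes
#' never overlap and never exceed scaffold bounds. The realized gene count
#' equals `round(gene_density * length / 1e6)` per scaffold.
#'
#' @param params a [simParams()] list.
#' @return list with `genome` (a [Genome-class]) and `genes` (a
#'   [GenomicRanges::GRanges] with a `gene_id` metadata column, one
#'   representative model per locus).
#' @examples
#' sim <- simulateReference(simParams(scaffold_length = 1e6, seed = 1))
#' length(sim$genes)
#' @export
simulateReference <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed)
  scafs <- sprintf("%s%d", params$scaffold_prefix,
                   seq_len(params$n_scaffolds))
  lens <- params$scaffold_length
  names(lens) <- scafs
  n_genes <- round(params$gene_density * lens / 1e6)
  parts <- vector("list", length(scafs))
  for (i in seq_along(scafs)) {
    lay <- .layoutScaffold(lens[i], n_genes[i], params)
    parts[[i]] <- data.frame(
      scaffold = scafs[i],
      start = lay$start, end = lay$end,
      strand = sample(c("+", "-"), n_genes[i], replace = TRUE),
      gene_id = sprintf("%s.g%05d", scafs[i], seq_len(n_genes[i])),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, parts)
  genes <- GRanges(tab$scaffold, IRanges(tab$start, tab$end),
                   strand = tab$strand,
                   seqlengths = lens)
  mcols(genes)$gene_id <- tab$gene_id
  list(genome = Genome(lens), genes = genes)
}

#' Parameters for query genome evolution
#'
#' @param n_inversions,n_transpositions number of intra-scaffold
#'   rearrangement events.
#' @param ortholog_loss_fraction probability that a reference gene's ortholog
#'   becomes unrecognizable in the query (the query gene survives as an
#'   orphan).
#' @param gene_gain_fraction fraction of novel orphan genes inserted into the
#'   query, relative to the reference gene count.
#' @param rearrangement_span_mean mean rearranged span in genes (geometric,
#'   minimum `span_min`).
#' @param span_min minimum span of a rearrangement in genes (>= 2 so that
#'   inversions are detectable as order breaks).
#' @param gene_gain_cluster_mean mean size (genes) of inserted orphan
#'   clusters; 1 inserts orphans singly, larger values emulate tandem
#'   gene-family expansions, whose orphan runs can exceed the chaining gap
#'   tolerance and produce synteny breaks even without fragmentation.
#' @param seed integer seed.
#' @return a validated `EvoParams` list.
#' @seealso [evolveQuery()]
#' @export
evoParams <- function(n_inversions = 0L, n_transpositions = 0L,
                      ortholog_loss_fraction = 0, gene_gain_fraction = 0,
                      rearrangement_span_mean = 5, span_min = 2L,
                      gene_gain_cluster_mean = 1,
                      seed = 1L) {
  stopifnot(n_inversions >= 0, n_transpositions >= 0,
            ortholog_loss_fraction >= 0, ortholog_loss_fraction <= 1,
            gene_gain_fraction >= 0, gene_gain_fraction <= 1,
            span_min >= 2, rearrangement_span_mean >= span_min,
            gene_gain_cluster_mean >= 1)
  structure(list(n_inversions = as.integer(n_inversions),
                 n_transpositions = as.integer(n_transpositions),
                 ortholog_loss_fraction = ortholog_loss_fraction,
                 gene_gain_fraction = gene_gain_fraction,
                 rearrangement_span_mean = rearrangement_span_mean,
                 span_min = as.integer(span_min),
                 gene_gain_cluster_mean = gene_gain_cluster_mean,
                 seed = as.integer(seed)),
            class = "EvoParams")
}

## Sample non-overlapping gene-index spans across scaffolds, probability
## proportional to gene count. Errors if a drawn span cannot fit anywhere.
.sampleSpans <- function(counts, n_events, evo) {
  spans <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0))
  if (n_events == 0L) return(spans)
  p_extra <- 1 / (1 + evo$rearrangement_span_mean - evo$span_min)
  taken <- lapply(counts, function(x) logical(x))
  for (e in seq_len(n_events)) {
    placed <- FALSE
    for (try in seq_len(10000L)) {
      sc <- sample(names(counts), 1L, prob = counts)
      len <- evo$span_min + rgeom(1L, p_extra)
      if (len > counts[[sc]]) {
        if (len > max(counts))
          stop(sprintf(paste0("rearrangement span of %d genes exceeds the ",
                              "gene count of scaffold %s (and of every ",
                              "other scaffold)"), len, sc))
        next
      }
      s <- sample.int(counts[[sc]] - len + 1L, 1L)
      idx <- s:(s + len - 1L)
      if (!any(taken[[sc]][idx])) {
        taken[[sc]][idx] <- TRUE
        spans <- rbind(spans, data.frame(scaffold = sc, start = s,
                                         end = s + len - 1L))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place all rearrangement events without overlap")
  }
  spans
}

## Maximal runs of orthologs contiguous in both genomes' ortholog-rank order:
## the ground-truth synteny blocks implied by the applied events.
.truthBlocks <- function(refGenes, qGenes, pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(scaffoldA = character(0), startA = numeric(0),
                      endA = numeric(0), scaffoldB = character(0),
                      startB = numeric(0), endB = numeric(0),
                      orientation = character(0), n_anchors = integer(0)))
  ga <- .annotTable(refGenes)
  gb <- .annotTable(qGenes)
  a <- ga[match(pairs$geneA, ga$gene_id), ]
  b <- gb[match(pairs$geneB, gb$gene_id), ]
  ## ortholog-only ranks along each genome
  okey_a <- order(a$scaffold, a$start)
  rank_a <- integer(nrow(a)); rank_a[okey_a] <- seq_len(nrow(a))
  okey_b <- order(b$scaffold, b$start)
  rank_b <- integer(nrow(b)); rank_b[okey_b] <- seq_len(nrow(b))
  ord <- okey_a
  blocks <- list()
  cur <- ord[1L]; dir <- 0L
  flush <- function(idx) {
    data.frame(scaffoldA = a$scaffold[idx[1L]],
               startA = min(a$start[idx]), endA = max(a$end[idx]),
               scaffoldB = b$scaffold[idx[1L]],
               startB = min(b$start[idx]), endB = max(b$end[idx]),
               orientation = if (dir < 0L) "inverted" else "same",
               n_anchors = length(idx), stringsAsFactors = FALSE)
  }
  for (i in ord[-1L]) {
    prev <- cur[length(cur)]
    step <- rank_b[i] - rank_b[prev]
    contiguous <- a$scaffold[i] == a$scaffold[prev] &&
      b$scaffold[i] == b$scaffold[prev] &&
      abs(step) == 1L && (dir == 0L || step == dir)
    if (contiguous) {
      if (dir == 0L) dir <- step
      cur <- c(cur, i)
    } else {
      blocks[[length(blocks) + 1L]] <- flush(cur)
      cur <- i; dir <- 0L
    }
  }
  blocks[[length(blocks) + 1L]] <- flush(cur)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

## GRanges with gene_id -> plain table used throughout
.annotTable <- function(genes) {
  stopifnot(!is.null(mcols(genes)$gene_id))
  data.frame(gene_id = mcols(genes)$gene_id,
             scaffold = as.character(seqnames(genes)),
             start = start(genes), end = end(genes),
             strand = as.character(strand(genes)),
             stringsAsFactors = FALSE)
}

#' Evolve a query genome from a reference
#'
#' Applies intra-scaffold inversions and transpositions (non-overlapping
#' gene-index spans), ortholog loss (surviving query genes become orphans),
#' and gene gain (novel orphans inserted at random positions), then rebuilds
#' the query genome left-to-right with fresh intergenic gaps resampled from
#' the reference's realized gaps. Gene lengths are preserved for genes
#' carried over. Inverted genes carry flipped strand.
#'
#' With all-zero `EvoParams` the query gene order equals the reference and
#' the truth contains one block per scaffold.
#'
#' @param genome reference [Genome-class].
#' @param genes reference annotation (GRanges with `gene_id`).
#' @param evo an [evoParams()] list.
#' @return list with `genome`, `genes` (query side) and `truth`
#'   (a [TruthSet-class]: orthology, true blocks, event log).
#' @export
evolveQuery <- function(genome, genes, evo) {
  stopifnot(inherits(evo, "EvoParams"))
  set.seed(evo$seed)
  tab <- .annotTable(genes)
  tab <- tab[order(tab$scaffold, tab$start), ]
  scafs <- names(scaffoldLengths(genome))
  per <- split(tab, factor(tab$scaffold, levels = scafs))
  counts <- vapply(per, nrow, integer(1))

  n_ev <- evo$n_inversions + evo$n_transpositions
  spans <- .sampleSpans(counts, n_ev, evo)
  types <- c(rep("inversion", evo$n_inversions),
             rep("transposition", evo$n_transpositions))
  events <- if (n_ev > 0L)
    data.frame(type = types, scaffold = spans$scaffold,
               start_index = spans$start, end_index = spans$end,
               insert_after = NA_integer_, stringsAsFactors = FALSE)
  else
    data.frame(type = character(0), scaffold = character(0),
               start_index = integer(0), end_index = integer(0),
               insert_after = integer(0))

  ## current order per scaffold as vectors of original gene indices
  ordIdx <- lapply(counts, seq_len)
  flip <- lapply(counts, function(x) logical(x))  # by original index

  inv <- which(events$type == "inversion")
  for (e in inv) {
    sc <- events$scaffold[e]
    idx <- events$start_index[e]:events$end_index[e]
    pos <- match(idx, ordIdx[[sc]])        # contiguous: spans do not overlap
    ordIdx[[sc]][pos] <- rev(ordIdx[[sc]][pos])
    flip[[sc]][idx] <- !flip[[sc]][idx]
  }
  trn <- which(events$type == "transposition")
  for (e in trn) {
    sc <- events$scaffold[e]
    idx <- events$start_index[e]:events$end_index[e]
    pos <- sort(match(idx, ordIdx[[sc]]))
    seg <- ordIdx[[sc]][pos]
    rest <- ordIdx[[sc]][-pos]
    ## insert after a position of `rest` outside any event span
    in_span <- rest %in% unlist(lapply(which(events$scaffold == sc),
      function(k) events$start_index[k]:events$end_index[k]))
    cand <- c(0L, which(!in_span))
    at <- cand[sample.int(length(cand), 1L)]
    ordIdx[[sc]] <- append(rest, seg, after = at)
    events$insert_after[e] <- if (at == 0L) 0L else rest[at]
  }

  total <- sum(counts)
  lost <- lapply(counts, function(x) rbinom(x, 1L, evo$ortholog_loss_fraction) == 1L)
  n_gain <- round(evo$gene_gain_fraction * total)
  gains <- data.frame(scaffold = character(0), after_pos = integer(0),
                      length = integer(0))
  if (n_gain > 0L) {
    ## orphans arrive in clusters (tandem-expansion-like); cluster size is
    ## geometric with the configured mean, 1 = independent single inserts
    placed_gain <- 0L
    while (placed_gain < n_gain) {
      k <- 1L + if (evo$gene_gain_cluster_mean > 1)
        rgeom(1L, 1 / evo$gene_gain_cluster_mean) else 0L
      k <- min(k, n_gain - placed_gain)
      sc <- sample(scafs, 1L, prob = counts)
      at <- sample(0:length(ordIdx[[sc]]), 1L)
      gains <- rbind(gains, data.frame(
        scaffold = sc, after_pos = rep(at, k),
        length = sample(tab$end - tab$start + 1L, k, replace = TRUE)))
      placed_gain <- placed_gain + k
    }
  }

  ## realized reference intergenic gaps, resampled for the query layout
  ref_gaps <- unlist(lapply(per, function(d) {
    c(d$start[1L] - 1L, d$start[-1L] - d$end[-nrow(d)] - 1L)
  }), use.names = FALSE)
  ref_gaps <- pmax(1L, ref_gaps)

  q_parts <- vector("list", length(scafs))
  orth_parts <- vector("list", length(scafs))
  q_lens <- numeric(length(scafs))
  for (si in seq_along(scafs)) {
    sc <- scafs[si]
    d <- per[[sc]]
    ord <- ordIdx[[sc]]
    glen <- (d$end - d$start + 1L)[ord]
    gstr <- d$strand[ord]
    gstr[flip[[sc]][ord]] <- ifelse(gstr[flip[[sc]][ord]] == "+", "-", "+")
    src_id <- d$gene_id[ord]
    is_orphan <- lost[[sc]][ord]
    g_here <- gains[gains$scaffold == sc, , drop = FALSE]
    if (nrow(g_here) > 0L) {
      ## insert gains back-to-front so positions stay valid
      g_here <- g_here[order(g_here$after_pos, decreasing = TRUE), ,
                       drop = FALSE]
      for (gi in seq_len(nrow(g_here))) {
        at <- g_here$after_pos[gi]
        glen <- append(glen, g_here$length[gi], after = at)
        gstr <- append(gstr, sample(c("+", "-"), 1L), after = at)
        src_id <- append(src_id, NA_character_, after = at)
        is_orphan <- append(is_orphan, TRUE, after = at)
      }
    }
    n <- length(glen)
    qsc <- paste0("q_", sc)
    gaps <- sample(ref_gaps, n + 1L, replace = TRUE)
    starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(glen))[seq_len(n)] + 1
    ends <- starts + glen - 1
    qid <- sprintf("%s.g%05d", qsc, seq_len(n))
    q_lens[si] <- ends[n] + gaps[n + 1L]
    q_parts[[si]] <- data.frame(scaffold = qsc, start = starts, end = ends,
                                strand = gstr, gene_id = qid,
                                stringsAsFactors = FALSE)
    keep <- !is_orphan & !is.na(src_id)
    orth_parts[[si]] <- data.frame(geneA = src_id[keep], geneB = qid[keep],
                                   stringsAsFactors = FALSE)
  }
  names(q_lens) <- paste0("q_", scafs)
  qtab <- do.call(rbind, q_parts)
  qGenes <- GRanges(qtab$scaffold, IRanges(qtab$start, qtab$end),
                    strand = qtab$strand, seqlengths = q_lens)
  mcols(qGenes)$gene_id <- qtab$gene_id
  qGenome <- Genome(q_lens)
  pairs <- do.call(rbind, orth_parts)
  rownames(pairs) <- NULL
  truth <- new("TruthSet", orthology = OrthologyMap(pairs),
               trueBlocks = .truthBlocks(genes, qGenes, pairs),
               events = events)
  list(genome = qGenome, genes = qGenes, truth = truth)
}

#' Degrade an annotation by random gene loss
#'
#' Models incomplete annotation: a uniformly random subset of genes is
#' removed; the coordinates of the remaining genes are untouched.
#'
#' @param genes annotation GRanges with `gene_id`.
#' @param missing_fraction fraction of genes to drop, in `[0, 1)`.
#' @param seed integer seed.
#' @return the thinned GRanges.
#' @export
degradeAnnotation <- function(genes, missing_fraction, seed = 1L) {
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")
  if (missing_fraction == 0) return(genes)
  set.seed(seed)
  drop <- rbinom(length(genes), 1L, missing_fraction) == 1L
  genes[!drop]
}

#' Identity truth for a self-comparison
#'
#' Pairs every gene with itself and declares one true block per scaffold,
#' which is the baseline configuration of the fragmentation experiments
#' (a genome compared against its own fragmented copy).
#'
#' @param genes annotation GRanges with `gene_id`.
#' @return a [TruthSet-class].
#' @export
identityTruth <- function(genes) {
  ids <- mcols(genes)$gene_id
  pairs <- data.frame(geneA = ids, geneB = ids, stringsAsFactors = FALSE)
  new("TruthSet", orthology = OrthologyMap(pairs),
      trueBlocks = .truthBlocks(genes, genes, pairs),
      events = data.frame(type = character(0), scaffold = character(0),
                          start_index = integer(0), end_index = integer(0),
                          insert_after = integer(0)))
}
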