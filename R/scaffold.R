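#' Reference-guided scaffolding of a fragmented assembly
#'
#' Emulates ordering and orienting assembly fragments along a closely
#' related reference: each fragment with at least one anchored gene is
#' assigned to the reference scaffold holding the majority of its anchors
#' (requiring at least `min_agreement` of them to agree, which prevents
#' chimeric inter-chromosome joins), positioned by the median reference
#' coordinate of its anchors, and oriented by the majority direction of its
#' anchor order (ties keep the original orientation). Assigned fragments
#' are tiled into one pseudochromosome per reference scaffold, joined by
#' `gap_length` N-gaps; unanchored or ambiguous fragments are carried over
#' unplaced. This reproduces the failure mode in which true rearrangements
#' between the species are silently re-ordered to match the reference.
#'
#' @param fragGenome fragmented query [Genome-class].
#' @param fragGenes query annotation on the fragments (GRanges, `gene_id`).
#' @param refGenes reference annotation (GRanges, `gene_id`).
#' @param orth an [OrthologyMap-class]; `geneA` on the reference side,
#'   `geneB` on the fragment side.
#' @param gap_length bp of N inserted between joined fragments (default 100).
#' @param min_agreement minimum fraction of a fragment's anchors that must
#'   agree on one reference scaffold (default 0.5).
#' @return list with `genome` (pseudochromosomes plus unplaced fragments),
#'   `genes` (remapped annotation) and `plan` (a [ScaffoldingPlan-class]).
#' @export
scaffoldByReference <- function(fragGenome, fragGenes, refGenes, orth,
                                gap_length = 100, min_agreement = 0.5) {
  stopifnot(is(fragGenome, "Genome"), gap_length >= 0)
  pairs <- orthologPairs(orth)
  ft <- .annotTable(fragGenes)
  rt <- .annotTable(refGenes)
  anchors <- data.frame(
    frag = ft$scaffold[match(pairs$geneB, ft$gene_id)],
    frag_start = ft$start[match(pairs$geneB, ft$gene_id)],
    ref_scaffold = rt$scaffold[match(pairs$geneA, rt$gene_id)],
    ref_mid = (rt$start + rt$end)[match(pairs$geneA, rt$gene_id)] / 2,
    stringsAsFactors = FALSE)
  anchors <- anchors[!is.na(anchors$frag) & !is.na(anchors$ref_scaffold), ,
                     drop = FALSE]
  frag_lens <- scaffoldLengths(fragGenome)
  if (nrow(anchors) == 0L)
    warning("no anchors: every fragment is left unplaced")

  place <- list()
  for (f in unique(anchors$frag)) {
    a <- anchors[anchors$frag == f, , drop = FALSE]
    tab <- table(a$ref_scaffold)
    best <- names(tab)[which.max(tab)]
    if (max(tab) / nrow(a) < min_agreement) next
    a <- a[a$ref_scaffold == best, , drop = FALSE]
    a <- a[order(a$frag_start), , drop = FALSE]
    ori <- "+"
    if (nrow(a) >= 2L) {
      d <- diff(a$ref_mid)
      if (sum(d < 0) > sum(d > 0)) ori <- "-"
    }
    place[[f]] <- data.frame(fragment = f, ref_scaffold = best,
                             position = median(a$ref_mid),
                             orientation = ori, n_anchors = nrow(a),
                             stringsAsFactors = FALSE)
  }
  placed <- if (length(place)) do.call(rbind, place) else
    data.frame(fragment = character(0), ref_scaffold = character(0),
               position = numeric(0), orientation = character(0),
               n_anchors = integer(0))
  unplaced <- setdiff(names(frag_lens), placed$fragment)

  out_lens <- numeric(0)
  rows <- list()
  gtab <- ft
  new_genes <- list()
  for (rc in sort(unique(placed$ref_scaffold))) {
    p <- placed[placed$ref_scaffold == rc, , drop = FALSE]
    p <- p[order(p$position, p$fragment), , drop = FALSE]
    ps <- paste0("ps_", rc)
    cur <- 0
    for (i in seq_len(nrow(p))) {
      f <- p$fragment[i]
      len <- frag_lens[[f]]
      rows[[length(rows) + 1L]] <- data.frame(
        pseudochrom = ps, fragment = f, ref_scaffold = rc,
        position = p$position[i], orientation = p$orientation[i],
        start = cur + 1, end = cur + len, n_anchors = p$n_anchors[i],
        stringsAsFactors = FALSE)
      g <- gtab[gtab$scaffold == f, , drop = FALSE]
      if (nrow(g) > 0L) {
        if (p$orientation[i] == "+") {
          g2 <- data.frame(scaffold = ps, start = cur + g$start,
                           end = cur + g$end, strand = g$strand,
                           gene_id = g$gene_id, stringsAsFactors = FALSE)
        } else {
          g2 <- data.frame(scaffold = ps,
                           start = cur + len - g$end + 1,
                           end = cur + len - g$start + 1,
                           strand = ifelse(g$strand == "+", "-", "+"),
                           gene_id = g$gene_id, stringsAsFactors = FALSE)
        }
        new_genes[[length(new_genes) + 1L]] <- g2
      }
      cur <- cur + len + if (i < nrow(p)) gap_length else 0
    }
    out_lens[ps] <- cur
  }
  ## carry unplaced fragments (and their genes) through unchanged
  for (f in unplaced) {
    out_lens[f] <- frag_lens[[f]]
    g <- gtab[gtab$scaffold == f, , drop = FALSE]
    if (nrow(g) > 0L) new_genes[[length(new_genes) + 1L]] <- g
  }
  plan_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pseudochrom = character(0), fragment = character(0),
               ref_scaffold = character(0), position = numeric(0),
               orientation = character(0), start = numeric(0),
               end = numeric(0), n_anchors = integer(0))
  rownames(plan_tab) <- NULL

  seqs <- NULL
  if (!is.null(fragGenome@sequences)) {
    seqs <- Biostrings::DNAStringSet(vapply(names(out_lens), function(ps) {
      if (ps %in% unplaced)
        return(as.character(fragGenome@sequences[[ps]]))
      p <- plan_tab[plan_tab$pseudochrom == ps, , drop = FALSE]
      pieces <- vapply(seq_len(nrow(p)), function(i) {
        s <- fragGenome@sequences[[p$fragment[i]]]
        if (p$orientation[i] == "-")
          s <- Biostrings::reverseComplement(s)
        as.character(s)
      }, character(1))
      paste(pieces, collapse = strrep("N", gap_length))
    }, character(1)))
    names(seqs) <- names(out_lens)
  }

  gdf <- do.call(rbind, new_genes)
  genes <- GRanges(gdf$scaffold, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand, seqlengths = out_lens)
  mcols(genes)$gene_id <- gdf$gene_id
  list(genome = Genome(out_lens, seqs),
       genes = genes,
       plan = new("ScaffoldingPlan", placements = plan_tab,
                  unplaced = unplaced, gapLength = gap_length))
}

#' Assess collinearity artifacts of a scaffolded assembly
#'
#' Compares synteny blocks detected between the reference and a
#' reference-scaffolded assembly against the simulation truth: counts truth
#' inversions that were erased (their reference span is now covered by
#' majority same-orientation blocks), truth rearrangement breakpoints still
#' detectable as block boundaries, fragment adjacencies in the plan that
#' contradict true adjacency in the query genome, and the N50 inflation the
#' scaffolding produced.
#'
#' @param blocks [SyntenyBlocks-class] detected between the reference (side
#'   A) and the scaffolded assembly (side B).
#' @param truth the query's [TruthSet-class] (for the inversion event log).
#' @param plan the [ScaffoldingPlan-class] used.
#' @param breakMap the [BreakMap-class] tracing fragments to query
#'   scaffolds (for true-adjacency checks).
#' @param fragGenome the fragmented genome (N50 before).
#' @param scafGenome the scaffolded genome (N50 after).
#' @param refGenes reference annotation (to map truth gene-index spans to
#'   reference coordinates).
#' @param breakpoint_tol bp tolerance when matching truth breakpoints to
#'   block boundaries (default 10000).
#' @return list with `pairs` (per chromosome-pair block counts and
#'   anchor-rank correlation), `n50_before`, `n50_after`,
#'   `n_true_inversions`, `orientation_loss` (inversions erased),
#'   `breakpoints_total`, `breakpoints_detected`, `lost_breakpoints`,
#'   `false_joins`, `n_adjacencies`.
#' @export
assessCollinearity <- function(blocks, truth, plan, breakMap,
                               fragGenome, scafGenome, refGenes,
                               breakpoint_tol = 10000) {
  b <- blockTable(blocks)
  anch <- blockAnchors(blocks)
  ## per chromosome-pair summary
  key <- paste(b$scaffoldA, b$scaffoldB, sep = "\r")
  pair_rows <- lapply(split(seq_len(nrow(b)), key), function(ix) {
    aa <- do.call(rbind, anch[ix])
    data.frame(scaffoldA = b$scaffoldA[ix[1L]],
               scaffoldB = b$scaffoldB[ix[1L]],
               n_blocks = length(ix),
               n_inverted = sum(b$orientation[ix] == "inverted"),
               rank_correlation =
                 if (nrow(aa) >= 2L)
                   suppressWarnings(cor(aa$rankA, aa$rankB,
                                        method = "spearman"))
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  pair_tab <- do.call(rbind, pair_rows)
  if (!is.null(pair_tab)) rownames(pair_tab) <- NULL

  ## truth inversions -> reference coordinate spans
  ev <- truthEvents(truth)
  inv <- ev[ev$type == "inversion", , drop = FALSE]
  rt <- .annotTable(refGenes)
  rt <- rt[order(rt$scaffold, rt$start), ]
  per <- split(rt, rt$scaffold)
  erased <- 0L
  bp_total <- 0L
  bp_detected <- 0L
  edges <- c(b$startA, b$endA)
  edge_sc <- c(b$scaffoldA, b$scaffoldA)
  for (e in seq_len(nrow(inv))) {
    sc <- inv$scaffold[e]
    d <- per[[sc]]
    span_start <- d$start[inv$start_index[e]]
    span_end <- d$end[inv$end_index[e]]
    ## orientation content of detected blocks over the span (reference side)
    ov <- b$scaffoldA == sc & b$endA >= span_start & b$startA <= span_end
    same_bp <- sum(pmin(b$endA[ov & b$orientation == "same"], span_end) -
                   pmax(b$startA[ov & b$orientation == "same"], span_start) + 1)
    inv_bp <- sum(pmin(b$endA[ov & b$orientation == "inverted"], span_end) -
                  pmax(b$startA[ov & b$orientation == "inverted"], span_start) + 1)
    if (same_bp > inv_bp) erased <- erased + 1L
    for (x in c(span_start, span_end)) {
      bp_total <- bp_total + 1L
      near <- edge_sc == sc & abs(edges - x) <= breakpoint_tol
      if (any(near)) bp_detected <- bp_detected + 1L
    }
  }

  ## plan adjacencies versus true adjacency in the (pre-fragmentation) query
  fmap <- breakTable(breakMap)
  p <- placements(plan)
  false_joins <- 0L
  n_adj <- 0L
  for (ps in unique(p$pseudochrom)) {
    d <- p[p$pseudochrom == ps, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2L) next
    for (i in seq_len(nrow(d) - 1L)) {
      n_adj <- n_adj + 1L
      f1 <- fmap[fmap$fragment == d$fragment[i], , drop = FALSE]
      f2 <- fmap[fmap$fragment == d$fragment[i + 1L], , drop = FALSE]
      ok <- nrow(f1) == 1L && nrow(f2) == 1L &&
        f1$source == f2$source &&
        ((d$orientation[i] == "+" && d$orientation[i + 1L] == "+" &&
            f2$start == f1$end + 1) ||
         (d$orientation[i] == "-" && d$orientation[i + 1L] == "-" &&
            f2$end == f1$start - 1))
      if (!ok) false_joins <- false_joins + 1L
    }
  }

  list(pairs = pair_tab,
       n50_before = n50(unname(scaffoldLengths(fragGenome))),
       n50_after = n50(unname(scaffoldLengths(scafGenome))),
       n_true_inversions = nrow(inv),
       orientation_loss = erased,
       breakpoints_total = bp_total,
       breakpoints_detected = bp_detected,
       lost_breakpoints = bp_total - bp_detected,
       false_joins = false_joins,
       n_adjacencies = n_adj)
}
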