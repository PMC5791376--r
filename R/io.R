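#' @importFrom Biostrings writeXStringSet readDNAStringSet width
#' @importFrom GenomeInfoDb seqlengths seqlevels
NULL

#' Attach random nucleotide sequence to a Genome
#'
#' Anchor-based synteny detection ignores nucleotide content, so simulated
#' genomes carry coordinates only; this fills in uniform random ACGT when a
#' FASTA representation is needed. Deterministic for a fixed seed.
#'
#' @param genome a [Genome-class].
#' @param seed integer seed.
#' @return the Genome with sequences attached (existing sequences are kept).
#' @export
randomizeSequences <- function(genome, seed = 1L) {
  if (!is.null(genome@sequences)) return(genome)
  set.seed(seed)
  lens <- scaffoldLengths(genome)
  seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- names(lens)
  Genome(lens, seqs)
}

#' Write a Genome as FASTA
#'
#' @param genome a [Genome-class]; if it has no sequences, random ACGT is
#'   generated with `seed` (see [randomizeSequences()]).
#' @param path output file.
#' @param seed seed for sequence generation when needed.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path, seed = 1L) {
  genome <- randomizeSequences(genome, seed)
  writeXStringSet(genome@sequences, path)
  invisible(path)
}

#' Read a Genome from FASTA
#'
#' @param path FASTA file.
#' @return a [Genome-class] with sequences attached.
#' @export
readGenomeFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lens <- width(seqs)
  names(lens) <- names(seqs)
  Genome(lens, seqs)
}

#' Write a gene annotation as GFF3
#'
#' Emits one `gene` feature per locus (one representative model per locus),
#' 1-based closed coordinates as GFF3 requires.
#'
#' @param genes annotation GRanges with `gene_id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationGff3 <- function(genes, path) {
  gr <- genes
  mcols(gr) <- NULL
  mcols(gr)$source <- "fragsynt"
  mcols(gr)$type <- "gene"
  mcols(gr)$ID <- mcols(genes)$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Keeps `gene` features only; the gene id is taken from the `ID` attribute
#' (falling back to `gene_id` or `Name`).
#'
#' @param path GFF3 file.
#' @return annotation GRanges with a `gene_id` metadata column.
#' @export
readAnnotationGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[mcols(gr)$type == "gene"]
  id <- mcols(gr)$ID
  if (is.null(id)) id <- mcols(gr)$gene_id
  if (is.null(id)) id <- mcols(gr)$Name
  if (is.null(id)) stop("no gene identifier attribute found in ", path)
  mcols(gr) <- NULL
  mcols(gr)$gene_id <- as.character(id)
  gr
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write / read a two-column orthology TSV
#'
#' @param orth an [OrthologyMap-class].
#' @param path TSV file (`geneA<TAB>geneB`, with header).
#' @return `path` (write) or an [OrthologyMap-class] (read).
#' @export
writeOrthologyTsv <- function(orth, path) {
  .writeTsv(orthologPairs(orth), path)
}

#' @rdname writeOrthologyTsv
#' @export
readOrthologyTsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  OrthologyMap(d[[1L]], d[[2L]])
}

#' Write synteny blocks as TSV
#'
#' Columns: scaffoldA, startA, endA, scaffoldB, startB, endB, orientation,
#' n_anchors; 1-based closed coordinates (GFF3 convention).
#'
#' @param blocks a [SyntenyBlocks-class] or block data.frame (also accepts
#'   [TruthSet-class] true blocks via [blockTable()]).
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
writeBlocksTsv <- function(blocks, path) {
  b <- if (is.data.frame(blocks)) blocks else blockTable(blocks)
  .writeTsv(b, path)
}

#' Write / read a break map as AGP-like TSV
#'
#' Columns: fragment, source, start, end (1-based closed source
#' coordinates).
#'
#' @param breakMap a [BreakMap-class].
#' @param path TSV file.
#' @param fragment_size,seed metadata restored on read.
#' @return `path` (write) or a [BreakMap-class] (read).
#' @export
writeBreakMapTsv <- function(breakMap, path) {
  .writeTsv(breakTable(breakMap), path)
}

#' @rdname writeBreakMapTsv
#' @export
readBreakMapTsv <- function(path, fragment_size = NA_real_, seed = NA_real_) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$start <- as.numeric(d$start)
  d$end <- as.numeric(d$end)
  new("BreakMap", map = d, fragmentSize = as.numeric(fragment_size),
      seed = as.numeric(seed))
}

#' Write / read a GAF-like two-column GO association TSV
#'
#' @param go data.frame with columns `gene`, `term`.
#' @param path TSV file.
#' @return `path` (write) or the association data.frame (read).
#' @export
writeGoTsv <- function(go, path) .writeTsv(go[, c("gene", "term")], path)

#' @rdname writeGoTsv
#' @export
readGoTsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("gene", "term")
  d
}
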