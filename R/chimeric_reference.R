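# Construction of a chimeric reference: human transgene sequences appended
# to a mouse genome as separate chromosomes, with matching gene/exon
# annotation rows so transgene expression can be quantified alongside the
# endogenous genes.

#' Build a chimeric (transgene-augmented) reference
#'
#' Appends each transgene sequence to the genome as a new record named by its
#' assigned chromosome label (e.g. human APP as chromosome "21" and human
#' PSEN1 as chromosome "22"), and emits one gene plus one exon annotation row
#' per transgene spanning its full length (1-based inclusive coordinates).
#'
#' @param genome a `Biostrings::DNAStringSet` (or named character vector) of
#'   reference sequences.
#' @param transgenes data.frame with columns `name` (gene id, e.g. `"hAPP"`),
#'   `sequence` (A/C/G/T/N string) and `chromosome` (new record label).
#' @return A list: `sequences` (`DNAStringSet` with the transgenes appended)
#'   and `annotation` (a `GRanges` of gene and exon features).
#' @export
build_chimeric_reference <- function(genome, transgenes) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(all(c("name", "sequence", "chromosome") %in% names(transgenes)))
  labels <- as.character(transgenes$chromosome)
  if (anyDuplicated(labels) || any(labels %in% names(genome)))
    stop_invalid("transgene chromosome labels must be unique and not ",
                 "collide with existing records")
  bad <- grepl("[^ACGTN]", toupper(transgenes$sequence))
  if (any(bad))
    stop_invalid("transgene sequences must be over {A,C,G,T,N}: ",
                 paste(transgenes$name[bad], collapse = ", "))
  tg <- Biostrings::DNAStringSet(toupper(transgenes$sequence))
  names(tg) <- labels
  sequences <- c(genome, tg)
  lens <- Biostrings::width(tg)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(labels, each = 2),
    ranges = IRanges::IRanges(start = 1, end = rep(lens, each = 2)),
    strand = "+",
    type = rep(c("gene", "exon"), times = length(labels)),
    gene_id = rep(transgenes$name, each = 2),
    transcript_id = rep(paste0(transgenes$name, ".1"), each = 2),
    source = "transgene"
  )
  list(sequences = sequences, annotation = gr)
}

#' Write a chimeric reference to FASTA and GTF
#'
#' @param ref result of \code{\link{build_chimeric_reference}}.
#' @param fasta_path,gtf_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_chimeric_reference <- function(ref, fasta_path, gtf_path) {
  Biostrings::writeXStringSet(ref$sequences, fasta_path)
  rtracklayer::export(ref$annotation, gtf_path, format = "gtf")
  invisible(c(fasta = fasta_path, gtf = gtf_path))
}

#' Read a chimeric reference back from disk
#'
#' @param fasta_path,gtf_path paths written by
#'   \code{\link{write_chimeric_reference}}.
#' @return A list with `sequences` and `annotation` as in
#'   \code{\link{build_chimeric_reference}}.
#' @export
read_chimeric_reference <- function(fasta_path, gtf_path) {
  list(sequences = Biostrings::readDNAStringSet(fasta_path),
       annotation = rtracklayer::import(gtf_path, format = "gtf"))
}
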