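#' Read and write the pipeline's on-disk formats
#'
#' Thin wrappers over rtracklayer/Biostrings: exon tables go to GTF (1-based,
#' inclusive), interval tables to BED (0-based, half-open; conversion handled
#' by rtracklayer), genomes to FASTA.
#'
#' @param exons exon table (`transcript_id`, optional `gene_id`, `chrom`,
#'   `strand`, `start`, `end`).
#' @param path file path.
#' @name isodyn-io
NULL

#' @rdname isodyn-io
#' @export
write_gtf <- function(exons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand,
    type = "exon",
    transcript_id = exons$transcript_id,
    gene_id = if ("gene_id" %in% names(exons)) exons$gene_id
              else exons$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname isodyn-io
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tibble(gene_id = as.character(gr$gene_id),
         transcript_id = as.character(gr$transcript_id),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         strand = as.character(GenomicRanges::strand(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr)) |>
    arrange(.data$transcript_id, .data$start)
}

#' @rdname isodyn-io
#' @param intervals tibble `chrom`, `start`, `end`, optional `strand`.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(intervals$start, intervals$end),
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*")
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname isodyn-io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname isodyn-io
#' @param genome named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname isodyn-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
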