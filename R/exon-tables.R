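#' Exon tables: the package's transcript representation
#'
#' Throughout isodyn a transcript model is a set of rows in an *exon table*: a
#' tibble with one row per exon and columns `chrom`, `strand` (`"+"`/`"-"`),
#' `start`, `end` (1-based, closed, as in GTF) plus an identifier column
#' (`transcript_id` for annotations and catalogs, `read_id` for long reads).
#' Annotation tables additionally carry `gene_id`. Exons of one transcript must
#' be non-overlapping and are kept sorted by genomic start; the splice-junction
#' chain is derived as the ordered introns between consecutive exons.
#'
#' A genome is a named character vector of chromosome sequences (A/C/G/T).
#'
#' @param exons an exon table.
#' @param id_col name of the identifier column.
#' @name exon-tables
NULL

#' Validate an exon table
#'
#' Checks column presence, coordinate sanity and per-transcript exon
#' disjointness. Called by the generators and entry points; returns its input
#' invisibly so it can sit in a pipe.
#'
#' @inheritParams exon-tables
#' @return `exons`, invisibly.
#' @export
validate_exons <- function(exons, id_col = "transcript_id") {
  need <- c(id_col, "chrom", "strand", "start", "end")
  missing_cols <- setdiff(need, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(exons) == 0) abort("exon table is empty")
  if (any(exons$end < exons$start)) abort("exon with end < start")
  if (!all(exons$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  bad <- exons |>
    arrange(.data[[id_col]], .data$start) |>
    group_by(.data[[id_col]]) |>
    summarise(ok = all(diff(.data$start) > 0) && all(head(.data$end, -1) < tail(.data$start, -1)),
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("overlapping or unsorted exons within transcript(s): ",
                 paste(head(bad[[id_col]], 3), collapse = ", ")))
  }
  invisible(exons)
}

# split an exon table into a named list of per-transcript matrices
# (rows sorted by start, columns start/end); the workhorse layout for
# chain comparisons
chain_list <- function(exons, id_col = "transcript_id") {
  exons <- arrange(exons, .data[[id_col]], .data$start)
  split(as.matrix(exons[, c("start", "end")]), exons[[id_col]])[unique(exons[[id_col]])] |>
    lapply(function(v) matrix(v, ncol = 2, dimnames = list(NULL, c("start", "end"))))
}

# introns of a sorted start/end matrix: k-1 x 2 matrix of (first, last) intron
# bases in genomic coordinates; NULL for mono-exon models
introns_of <- function(mat) {
  k <- nrow(mat)
  if (k < 2) return(NULL)
  cbind(start = mat[-k, "end"] + 1L, end = mat[-1, "start"] - 1L)
}

# junction chain as a character vector "start-end" per intron (genomic order)
junction_keys <- function(mat) {
  intr <- introns_of(mat)
  if (is.null(intr)) return(character(0))
  paste0(intr[, "start"], "-", intr[, "end"])
}

# per-transcript junction table for a whole exon table
junction_table <- function(exons, id_col = "transcript_id") {
  exons |>
    arrange(.data[[id_col]], .data$start) |>
    group_by(.data[[id_col]], .data$chrom, .data$strand) |>
    reframe(jstart = head(.data$end, -1) + 1L, jend = tail(.data$start, -1) - 1L)
}

# reverse complement of a plain character vector of sequences (IUPAC-aware)
revcomp <- function(x) {
  comp <- chartr("ACGTUacgtuRYSWKMBDHVryswkmbdhv",
                 "TGCAAtgcaaYRSWMKVHDByrswmkvhdb", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# genomic subsequence, clipped to the chromosome; empty string if out of range
genome_slice <- function(genome, chrom, start, end) {
  n <- nchar(genome[[chrom]])
  start <- max(1L, start)
  end <- min(n, end)
  if (end < start) return("")
  substr(genome[[chrom]], start, end)
}

#' Spliced transcript sequence from a genome
#'
#' Concatenates the exon sequences of one transcript in transcript (5'->3')
#' orientation; minus-strand models are reverse-complemented.
#'
#' @param exons exon table rows of a single transcript.
#' @param genome named character vector of chromosome sequences.
#' @return a single character string.
#' @export
transcript_seq <- function(exons, genome) {
  exons <- arrange(exons, .data$start)
  chrom <- exons$chrom[1]
  pieces <- mapply(function(s, e) genome_slice(genome, chrom, s, e),
                   exons$start, exons$end)
  s <- paste(pieces, collapse = "")
  if (exons$strand[1] == "-") revcomp(s) else s
}

# transcript-orientation 5' and 3' genomic end coordinates
tx_ends <- function(mat, strand) {
  if (strand == "+") {
    c(five = unname(mat[1, "start"]), three = unname(mat[nrow(mat), "end"]))
  } else {
    c(five = unname(mat[nrow(mat), "end"]), three = unname(mat[1, "start"]))
  }
}

# merge possibly-overlapping closed intervals; returns sorted matrix
merge_intervals <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      if (starts[i] <= me + 1L) {
        me <- max(me, ends[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# fraction of a given base in a string; 0-length string -> NA
base_fraction <- function(s, base) {
  n <- nchar(s)
  if (n == 0) return(NA_real_)
  str_count(s, fixed(base)) / n
}
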