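#' Flag potential oligo-dT mispriming at a transcript 3' end
#'
#' A transcript is a potential reverse-transcription mispriming product when
#' the genomic sequence immediately 3' of its end (on the transcript strand)
#' is at least 60% adenine over `window` nt. Near a chromosome edge the
#' available bases are used; an empty window is never flagged.
#'
#' @param model exon table rows of one transcript.
#' @param genome named character vector.
#' @param window nt examined downstream of the 3' end.
#' @param min_a_frac adenine fraction threshold.
#' @return logical scalar.
#' @export
detect_mispriming <- function(model, genome, window = 20L, min_a_frac = 0.6) {
  model <- arrange(model, .data$start)
  chrom <- model$chrom[1]
  if (model$strand[1] == "+") {
    e <- max(model$end)
    s <- genome_slice(genome, chrom, e + 1L, e + window)
  } else {
    b <- min(model$start)
    s <- revcomp(genome_slice(genome, chrom, b - window, b - 1L))
    if (nchar(s) == 0) s <- ""
  }
  f <- base_fraction(s, "A")
  !is.na(f) && f >= min_a_frac
}

#' Per-junction canonicality of a transcript model
#'
#' A junction is canonical when the transcript-strand intron starts and ends
#' with one of GT..AG, GC..AG or AT..AC.
#'
#' @param model exon table rows of one transcript (>= 2 exons for any output).
#' @param genome named character vector.
#' @return tibble: one row per junction in transcript order, with genomic
#'   intron coordinates (`intron_start`, `intron_end`), the transcript-strand
#'   dinucleotides and `canonical`.
#' @export
junction_canonicality <- function(model, genome) {
  model <- arrange(model, .data$start)
  mat <- as.matrix(model[, c("start", "end")])
  intr <- introns_of(mat)
  if (is.null(intr)) {
    return(tibble(intron_start = integer(), intron_end = integer(),
                  donor_dinuc = character(), acceptor_dinuc = character(),
                  canonical = logical()))
  }
  chrom <- model$chrom[1]; strand <- model$strand[1]
  left <- vapply(seq_len(nrow(intr)), function(i)
    genome_slice(genome, chrom, intr[i, "start"], intr[i, "start"] + 1L),
    character(1))
  right <- vapply(seq_len(nrow(intr)), function(i)
    genome_slice(genome, chrom, intr[i, "end"] - 1L, intr[i, "end"]),
    character(1))
  if (strand == "+") {
    donor <- left; acceptor <- right
  } else {
    donor <- rev(revcomp(right)); acceptor <- rev(revcomp(left))
    intr <- intr[rev(seq_len(nrow(intr))), , drop = FALSE]
  }
  canonical_pairs <- c("GT.AG", "GC.AG", "AT.AC")
  tibble(intron_start = intr[, "start"], intron_end = intr[, "end"],
         donor_dinuc = donor, acceptor_dinuc = acceptor,
         canonical = paste(donor, acceptor, sep = ".") %in% canonical_pairs)
}

#' End support from CAGE peaks, polyA-site clusters and polyA motifs
#'
#' @param model exon table rows of one transcript.
#' @param cage_peaks,polya_sites interval tibbles (`chrom`, `start`, `end`,
#'   optional `strand`); `NULL` or empty means unsupported.
#' @param genome named character vector (for the motif search).
#' @param polya_motifs character vector of motifs accepted near the 3' end.
#' @param tss_window,tts_window maximal distance (nt) between a transcript end
#'   and a peak/cluster interval.
#' @param motif_window nt upstream of the 3' end (transcript strand) searched
#'   for a polyA motif.
#' @return one-row tibble: `tss_supported`, `tts_supported`,
#'   `polya_motif_found`.
#' @export
end_support <- function(model, cage_peaks, polya_sites, genome,
                        polya_motifs = c("AATAAA", "ATTAAA"),
                        tss_window = 50L, tts_window = 50L, motif_window = 50L) {
  model <- arrange(model, .data$start)
  chrom <- model$chrom[1]; strand <- model$strand[1]
  ends <- tx_ends(as.matrix(model[, c("start", "end")]), strand)

  near_interval <- function(pos, ivl, win) {
    if (is.null(ivl) || nrow(ivl) == 0) return(FALSE)
    ivl <- filter(ivl, .data$chrom == !!chrom)
    if ("strand" %in% names(ivl)) ivl <- filter(ivl, .data$strand == !!strand)
    if (nrow(ivl) == 0) return(FALSE)
    any(pos >= ivl$start - win & pos <= ivl$end + win)
  }

  tts <- ends[["three"]]
  if (strand == "+") {
    up <- genome_slice(genome, chrom, tts - motif_window + 1L, tts)
  } else {
    up <- revcomp(genome_slice(genome, chrom, tts, tts + motif_window - 1L))
  }
  motif_found <- any(vapply(polya_motifs, function(m)
    str_detect(up, fixed(m)), logical(1)))

  tibble(tss_supported = near_interval(ends[["five"]], cage_peaks, tss_window),
         tts_supported = near_interval(tts, polya_sites, tts_window),
         polya_motif_found = motif_found)
}

#' Compute artifact and end-support flags for a whole catalog
#'
#' Convenience wrapper running [detect_mispriming()],
#' [junction_canonicality()] and [end_support()] per catalog isoform.
#'
#' @param catalog an `isodyn_catalog`.
#' @param genome,cage_peaks,polya_sites,polya_motifs see the per-isoform
#'   functions.
#' @return the catalog with `mispriming`, `template_switch` (any
#'   non-canonical junction), `junctions` (list-column from
#'   [junction_canonicality()]), `tss_supported`, `tts_supported`,
#'   `polya_motif_found` columns added.
#' @export
flag_artifacts <- function(catalog, genome, cage_peaks = NULL,
                           polya_sites = NULL,
                           polya_motifs = c("AATAAA", "ATTAAA")) {
  per <- pmap(list(catalog$exons, catalog$chrom, catalog$strand),
    function(ex, ch, st) {
      model <- mutate(ex, chrom = ch, strand = st)
      jc <- junction_canonicality(model, genome)
      bind_cols(
        tibble(mispriming = detect_mispriming(model, genome),
               template_switch = nrow(jc) > 0 && !all(jc$canonical),
               junctions = list(jc)),
        end_support(model, cage_peaks, polya_sites, genome, polya_motifs))
    }) |> list_rbind()
  out <- bind_cols(catalog, per)
  class(out) <- unique(c("isodyn_catalog", class(out)))
  out
}
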