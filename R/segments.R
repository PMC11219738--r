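segment_names <- c("upExon3p", "upIntron5p", "upIntron3p", "target5p",
                   "target3p", "dnIntron5p", "dnIntron3p", "dnExon5p")

# genomic coordinates of the eight rMAPS-style segments for one event row;
# events carry transcript-orientation upstream/target/downstream exon coords
segment_coords_one <- function(ev, exon_offset, intron_offset) {
  eo <- exon_offset; io <- intron_offset
  if (ev$strand == "+") {
    i1 <- c(ev$up_end + 1L, ev$target_start - 1L)
    i2 <- c(ev$target_end + 1L, ev$dn_start - 1L)
    segs <- list(
      upExon3p   = c(max(ev$up_start, ev$up_end - eo + 1L), ev$up_end),
      upIntron5p = c(i1[1], min(i1[2], i1[1] + io - 1L)),
      upIntron3p = c(max(i1[1], i1[2] - io + 1L), i1[2]),
      target5p   = c(ev$target_start, min(ev$target_end, ev$target_start + eo - 1L)),
      target3p   = c(max(ev$target_start, ev$target_end - eo + 1L), ev$target_end),
      dnIntron5p = c(i2[1], min(i2[2], i2[1] + io - 1L)),
      dnIntron3p = c(max(i2[1], i2[2] - io + 1L), i2[2]),
      dnExon5p   = c(ev$dn_start, min(ev$dn_end, ev$dn_start + eo - 1L)))
  } else {
    i1 <- c(ev$target_end + 1L, ev$up_start - 1L)
    i2 <- c(ev$dn_end + 1L, ev$target_start - 1L)
    segs <- list(
      upExon3p   = c(ev$up_start, min(ev$up_end, ev$up_start + eo - 1L)),
      upIntron5p = c(max(i1[1], i1[2] - io + 1L), i1[2]),
      upIntron3p = c(i1[1], min(i1[2], i1[1] + io - 1L)),
      target5p   = c(max(ev$target_start, ev$target_end - eo + 1L), ev$target_end),
      target3p   = c(ev$target_start, min(ev$target_end, ev$target_start + eo - 1L)),
      dnIntron5p = c(max(i2[1], i2[2] - io + 1L), i2[2]),
      dnIntron3p = c(i2[1], min(i2[2], i2[1] + io - 1L)),
      dnExon5p   = c(max(ev$dn_start, ev$dn_end - eo + 1L), ev$dn_end))
  }
  tibble(event_id = ev$event_id, segment = segment_names,
         chrom = ev$chrom, strand = ev$strand,
         seg_start = as.integer(vapply(segs, `[`, numeric(1), 1)[segment_names]),
         seg_end = as.integer(vapply(segs, `[`, numeric(1), 2)[segment_names]))
}

#' Extract the eight positional segments around cassette-exon events
#'
#' For every event, returns the eight sequence segments scanned by positional
#' RBP analyses: the terminal `exon_offset` nt of the upstream exon, the first
#' and last `intron_offset` nt of the upstream intron, the first and last
#' `exon_offset` nt of the target exon, the first and last `intron_offset` nt
#' of the downstream intron, and the first `exon_offset` nt of the downstream
#' exon. Segments are clipped to the underlying feature; a short intron yields
#' two overlapping segments. Sequences are reported in transcript orientation,
#' so position 1 is always the 5'-most base of the segment.
#'
#' @param events tibble with `event_id`, `chrom`, `strand` and
#'   transcript-orientation exon coordinates `up_start`, `up_end`,
#'   `target_start`, `target_end`, `dn_start`, `dn_end`.
#' @param genome named character vector; `NULL` skips sequence extraction.
#' @param exon_offset,intron_offset segment extents (nt).
#' @return tibble: event_id, segment, chrom, strand, seg_start, seg_end,
#'   length, and `seq` when a genome is given.
#' @export
extract_segments <- function(events, genome = NULL, exon_offset = 50L,
                             intron_offset = 250L) {
  need <- c("event_id", "chrom", "strand", "up_start", "up_end",
            "target_start", "target_end", "dn_start", "dn_end")
  if (!all(need %in% names(events))) {
    abort(paste0("events table needs columns: ", paste(need, collapse = ", ")))
  }
  bad <- events |>
    filter((.data$strand == "+" &
              !(.data$up_end < .data$target_start & .data$target_end < .data$dn_start)) |
           (.data$strand == "-" &
              !(.data$dn_end < .data$target_start & .data$target_end < .data$up_start)))
  if (nrow(bad) > 0) abort("event with unresolvable exon order")
  out <- events |>
    mutate(.row = row_number()) |>
    group_by(.data$.row) |>
    group_map(~ segment_coords_one(.x, exon_offset, intron_offset)) |>
    list_rbind() |>
    mutate(length = .data$seg_end - .data$seg_start + 1L)
  if (!is.null(genome)) {
    out <- out |>
      mutate(seq = pmap(list(.data$chrom, .data$seg_start, .data$seg_end,
                             .data$strand),
                        function(ch, s, e, st) {
                          x <- genome_slice(genome, ch, s, e)
                          if (st == "-") revcomp(x) else x
                        }) |> unlist())
  }
  out
}

# genomic coordinate of transcript-orientation position p within a segment row
segment_genomic_pos <- function(seg_start, seg_end, strand, p) {
  ifelse(strand == "+", seg_start + p - 1L, seg_end - p + 1L)
}
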