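#' Plant motif occurrences in a chosen segment of included events
#'
#' Writes concrete instances of an IUPAC motif at random positions inside the
#' named segment of a random fraction of the events labelled `included`;
#' excluded and background events are untouched. Instances are written on the
#' transcript strand (reverse-complemented into the genome for minus-strand
#' events) and positions avoid the two terminal intron bases so planted motifs
#' never destroy splice-site dinucleotides.
#'
#' @param genome named character vector of chromosome sequences.
#' @param events event table (see [extract_segments()]) with a `group` column
#'   (`included` / `excluded` / `background`).
#' @param motif IUPAC consensus string.
#' @param segment one of the eight segment names.
#' @param fraction fraction of included events that receive plants.
#' @param seed integer seed.
#' @param n_per_event motif instances planted per chosen event.
#' @param exon_offset,intron_offset segment geometry (must match the later
#'   scan).
#' @return list with `genome` (modified) and `log` (tibble: event_id, segment,
#'   chrom, strand, start, end, instance).
#' @export
plant_motifs <- function(genome, events, motif, segment = "dnIntron5p",
                         fraction = 1, seed = 1L, n_per_event = 3L,
                         exon_offset = 50L, intron_offset = 250L) {
  if (!segment %in% segment_names) abort("unknown segment name")
  if (!"group" %in% names(events)) abort("events need a 'group' column")
  with_seed(seed + 3L, {
    inc <- filter(events, .data$group == "included")
    if (nrow(inc) == 0 || fraction == 0) {
      return(list(genome = genome,
                  log = tibble(event_id = character(), segment = character(),
                               chrom = character(), strand = character(),
                               start = integer(), end = integer(),
                               instance = character())))
    }
    chosen <- inc$event_id[seq_len(nrow(inc)) %in%
                             sample(nrow(inc), round(fraction * nrow(inc)))]
    segs <- extract_segments(inc |> filter(.data$event_id %in% chosen),
                             genome = NULL, exon_offset, intron_offset) |>
      filter(.data$segment == !!segment)
    w <- nchar(motif)
    glog <- vector("list", nrow(segs))
    chars <- strsplit(genome, "")
    for (i in seq_len(nrow(segs))) {
      sg <- segs[i, ]
      lo <- 3L; hi <- sg$length - w - 1L   # keep off the splice dinucleotides
      if (hi < lo) next
      # greedily keep non-overlapping positions so instances never collide
      cand <- sample(seq(lo, hi))
      pos <- integer(0)
      for (p in cand) {
        if (length(pos) >= n_per_event) break
        if (all(abs(pos - p) >= w)) pos <- c(pos, p)
      }
      rows <- vector("list", length(pos))
      for (j in seq_along(pos)) {
        inst <- instantiate_motif(motif)
        gpos <- segment_genomic_pos(sg$seg_start, sg$seg_end, sg$strand, pos[j])
        if (sg$strand == "+") {
          gs <- gpos; ge <- gpos + w - 1L
          chars[[sg$chrom]][gs:ge] <- strsplit(inst, "")[[1]]
        } else {
          gs <- gpos - w + 1L; ge <- gpos
          chars[[sg$chrom]][gs:ge] <- strsplit(revcomp(inst), "")[[1]]
        }
        rows[[j]] <- tibble(event_id = sg$event_id, segment = segment,
                            chrom = sg$chrom, strand = sg$strand,
                            start = gs, end = ge, instance = inst)
      }
      glog[[i]] <- list_rbind(rows)
    }
    genome2 <- vapply(chars, paste, character(1), collapse = "")
    list(genome = genome2, log = list_rbind(glog))
  })
}

#' Simulate CLIP peak intervals from planted motif sites
#'
#' Emits one peak interval per planted motif instance (extended by
#' `flank` nt on both sides) for a random fraction of the planted events, plus
#' optional uniform decoy peaks across the genome.
#'
#' @param plant_log the `log` tibble from [plant_motifs()].
#' @param fraction fraction of planted events that get peaks.
#' @param flank peak half-width extension (nt).
#' @param n_decoys uniform random decoy peaks to add.
#' @param genome genome (only needed when `n_decoys > 0`).
#' @param seed integer seed.
#' @return BED-like tibble: chrom, start, end, strand.
#' @export
simulate_clip_peaks <- function(plant_log, fraction = 1, flank = 10L,
                                n_decoys = 0L, genome = NULL, seed = 1L) {
  with_seed(seed + 4L, {
    ids <- unique(plant_log$event_id)
    keep <- if (length(ids)) sample(ids, round(fraction * length(ids))) else character(0)
    peaks <- plant_log |>
      filter(.data$event_id %in% keep) |>
      transmute(chrom = .data$chrom, start = .data$start - flank,
                end = .data$end + flank, strand = .data$strand)
    if (n_decoys > 0) {
      stopifnot(!is.null(genome))
      ch <- sample(names(genome), n_decoys, replace = TRUE)
      s <- vapply(ch, function(x) sample(nchar(genome[[x]]) - 50L, 1), numeric(1))
      peaks <- bind_rows(peaks, tibble(chrom = ch, start = as.integer(s),
                                       end = as.integer(s) + 20L + 2L * flank,
                                       strand = sample(c("+", "-"), n_decoys,
                                                       replace = TRUE)))
    }
    arrange(peaks, .data$chrom, .data$start)
  })
}
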