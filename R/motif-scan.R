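IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

# normalise an IUPAC motif: uppercase, U -> T, validate alphabet
normalize_motif <- function(motif) {
  m <- chartr("u", "U", toupper(motif))
  m <- chartr("U", "T", m)
  if (!all(strsplit(m, "")[[1]] %in% names(IUPAC_MAP))) {
    abort(paste0("motif contains non-IUPAC characters: ", motif))
  }
  m
}

# one concrete instantiation of a degenerate motif (used by the planter)
instantiate_motif <- function(motif) {
  paste(vapply(strsplit(normalize_motif(motif), "")[[1]],
               function(ch) sample(IUPAC_MAP[[ch]], 1), character(1)),
        collapse = "")
}

#' Motif coverage mask of a sequence
#'
#' Marks every position lying inside at least one (possibly overlapping) match
#' of an IUPAC consensus motif. Degeneracy is honoured (R = A/G, U equals T,
#' ...); matching is done with [Biostrings::matchPattern()] over degenerate
#' alphabets.
#'
#' @param sequence a character string (DNA/RNA; U is treated as T).
#' @param motif IUPAC consensus string.
#' @return integer vector of 0/1, one per position of `sequence`.
#' @export
scan_motif <- function(sequence, motif) {
  m <- normalize_motif(motif)
  s <- chartr("Uu", "Tt", toupper(sequence))
  n <- nchar(s)
  w <- nchar(m)
  mask <- integer(n)
  if (n < w) return(mask)
  # overlap-aware search: zero-width lookahead records every match start
  rx <- paste(vapply(strsplit(m, "")[[1]], function(ch) {
    alt <- IUPAC_MAP[[ch]]
    if (length(alt) == 1) alt else paste0("[", paste(alt, collapse = ""), "]")
  }, character(1)), collapse = "")
  hit <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
  if (hit[1] != -1) {
    for (st in as.integer(hit)) mask[st:(st + w - 1L)] <- 1L
  }
  mask
}

# sliding-window motif score per position: 100 * covered / available window
# bases, window centred on the position and clipped at segment bounds
window_score <- function(mask, window = 50L) {
  n <- length(mask)
  half <- window %/% 2L
  cs <- c(0L, cumsum(mask))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (window - half) - 1L, n)
  100 * (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Positional motif-score profile over a set of events
#'
#' For every event segment, computes the percentage of nucleotides covered by
#' the motif within a `window`-bp sliding window centred at each position
#' (clipped at segment boundaries, with the number of available bases as
#' denominator), then averages over events. Positions beyond a clipped
#' segment's length simply drop that event from the mean.
#'
#' @param segments output of [extract_segments()] (with sequences).
#' @param motif IUPAC consensus string.
#' @param window sliding-window size (nt).
#' @return tibble: segment, position, score (mean over events), n_events.
#' @export
motif_score_profile <- function(segments, motif, window = 50L) {
  if (nrow(segments) == 0) abort("empty event set")
  per_event <- motif_scores_by_event(segments, motif, window)
  per_event |>
    group_by(.data$segment, .data$position) |>
    summarise(score = mean(.data$score), n_events = n(), .groups = "drop") |>
    mutate(segment = factor(.data$segment, levels = segment_names)) |>
    arrange(.data$segment, .data$position)
}

# long per-event scores: event_id, segment, position, score
motif_scores_by_event <- function(segments, motif, window = 50L) {
  stopifnot("seq" %in% names(segments))
  segments |>
    mutate(score = map(.data$seq, ~ window_score(scan_motif(.x, motif), window))) |>
    select("event_id", "segment", "score") |>
    mutate(position = map(.data$score, seq_along)) |>
    unnest(c("score", "position"))
}
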