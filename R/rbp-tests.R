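#' Two-sample rank-sum test
#'
#' Wilcoxon rank-sum with the switch used throughout the positional analyses:
#' exact permutation enumeration when both groups have at most `exact_max`
#' observations (ties handled naturally by the permutation distribution),
#' tie-corrected normal approximation otherwise. Two-sided.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest per-group size for the exact path.
#' @return two-sided p-value.
#' @export
ranksum_test <- function(x, y, exact_max = 4L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) return(NA_real_)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (max(n1, n2) <= exact_max) {
    sets <- combn(n, n1)
    Wp <- colSums(matrix(r[sets], nrow = n1))
    return(mean(abs(Wp - mu) >= abs(W - mu) - 1e-9))
  }
  ties <- tabulate(match(r, unique(r)))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(1)
  2 * pnorm(-abs(W - mu) / sqrt(sig2))
}

#' Positional motif enrichment test around regulated exons
#'
#' Computes per-event sliding-window motif scores over the eight segments,
#' compares regulated (included or excluded) against background events at
#' every position with the two-sided rank-sum test, and summarises each
#' region by its smallest p-value. A region is called enriched when its
#' minimum p-value falls below `alpha` (default 0.001).
#'
#' @param segments [extract_segments()] output with sequences for all events.
#' @param motif IUPAC consensus string.
#' @param groups tibble `event_id`, `group` with values `included`,
#'   `excluded`, `background`.
#' @param window sliding window (nt).
#' @param alpha region-level motif enrichment threshold.
#' @param rbp,comparison labels carried into the summary.
#' @return object of class `motif_profile`: list with `profile` (group mean
#'   score per segment position), `tests` (per-position p-values per
#'   comparison) and `summary` (per-region min-p and enrichment call).
#' @export
positional_motif_test <- function(segments, motif, groups, window = 50L,
                                  alpha = 0.001, rbp = motif,
                                  comparison = NA_character_) {
  if (nrow(segments) == 0) abort("empty event set")
  groups <- distinct(groups, .data$event_id, .data$group)
  scores <- motif_scores_by_event(segments, motif, window) |>
    inner_join(groups, by = "event_id")
  if (!"background" %in% scores$group) abort("no background events")

  profile <- scores |>
    group_by(.data$group, .data$segment, .data$position) |>
    summarise(score = mean(.data$score), n_events = n(), .groups = "drop")

  run_side <- function(side) {
    reg <- filter(scores, .data$group == side)
    if (nrow(reg) == 0) return(NULL)
    bg <- filter(scores, .data$group == "background")
    map(segment_names, function(sg) {
      R <- filter(reg, .data$segment == sg)
      B <- filter(bg, .data$segment == sg)
      if (nrow(R) == 0 || nrow(B) == 0) return(NULL)
      rs <- split(R$score, R$position)
      bs <- split(B$score, B$position)
      positions <- sort(as.integer(unique(R$position)))
      p <- vapply(as.character(positions), function(cp) {
        if (is.null(bs[[cp]])) return(NA_real_)
        ranksum_test(rs[[cp]], bs[[cp]])
      }, numeric(1), USE.NAMES = FALSE)
      tibble(comparison = comparison, rbp = rbp,
             side = side, segment = sg, position = positions, p = p)
    }) |> list_rbind()
  }
  tests <- map(c("included", "excluded"), run_side) |> list_rbind()
  summary <- tests |>
    group_by(.data$comparison, .data$rbp, .data$side, .data$segment) |>
    summarise(min_p = suppressWarnings(min(.data$p, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(min_p = ifelse(is.finite(.data$min_p), .data$min_p, NA_real_),
           enriched = !is.na(.data$min_p) & .data$min_p < alpha)
  structure(list(profile = profile, tests = tests, summary = summary,
                 motif = motif, window = window, alpha = alpha),
            class = "motif_profile")
}

#' Positional CLIP-peak density test around regulated exons
#'
#' Per position, the binding-site density is the fraction of events whose
#' segment base at that position lies inside a peak; regulated and background
#' event sets are compared per position with Fisher's exact test. A region is
#' called when its minimum Fisher p-value falls below `alpha` (default 0.05).
#'
#' @param segments [extract_segments()] output (sequences not needed).
#' @param peaks interval tibble (`chrom`, `start`, `end`, optional `strand`).
#' @param groups tibble `event_id`, `group`.
#' @param alpha region-level threshold.
#' @param rbp,comparison labels carried into the summary.
#' @return object of class `peak_profile`: list with `profile` (per-group
#'   density), `tests` (per-position Fisher p), `summary` (region min-p and
#'   call).
#' @export
peak_density_test <- function(segments, peaks, groups, alpha = 0.05,
                              rbp = NA_character_, comparison = NA_character_) {
  groups <- distinct(groups, .data$event_id, .data$group)
  occ <- segments |>
    inner_join(groups, by = "event_id") |>
    mutate(hit = pmap(list(.data$chrom, .data$strand, .data$seg_start,
                           .data$seg_end, .data$length),
      function(ch, st, s, e, len) {
        pk <- peaks
        if (!is.null(pk) && nrow(pk) > 0) pk <- filter(pk, .data$chrom == ch)
        if (!is.null(pk) && "strand" %in% names(pk) && nrow(pk) > 0) {
          pk <- filter(pk, .data$strand == st)
        }
        pos <- seq_len(len)
        g <- segment_genomic_pos(s, e, st, pos)
        if (is.null(pk) || nrow(pk) == 0) return(rep(FALSE, len))
        vapply(g, function(x) any(pk$start <= x & x <= pk$end), logical(1))
      })) |>
    select("event_id", "segment", "group", "hit") |>
    mutate(position = map(.data$hit, seq_along)) |>
    unnest(c("hit", "position"))

  profile <- occ |>
    group_by(.data$group, .data$segment, .data$position) |>
    summarise(density = mean(.data$hit), n_events = n(), .groups = "drop")

  run_side <- function(side) {
    reg <- filter(occ, .data$group == side)
    bg <- filter(occ, .data$group == "background")
    if (nrow(reg) == 0 || nrow(bg) == 0) return(NULL)
    both <- bind_rows(reg, bg) |>
      group_by(.data$segment, .data$position) |>
      summarise(a = sum(.data$hit[.data$group == side]),
                b = sum(!.data$hit[.data$group == side]),
                c = sum(.data$hit[.data$group == "background"]),
                d = sum(!.data$hit[.data$group == "background"]),
                .groups = "drop")
    both |>
      mutate(p = pmap_dbl(list(.data$a, .data$b, .data$c, .data$d),
                          function(a, b, c, d) {
                            if (a + c == 0) return(1)
                            fisher.test(matrix(c(a, b, c, d), 2,
                                               byrow = TRUE))$p.value
                          }),
             comparison = comparison, rbp = rbp, side = side)
  }
  tests <- map(c("included", "excluded"), run_side) |> list_rbind()
  summary <- tests |>
    group_by(.data$comparison, .data$rbp, .data$side, .data$segment) |>
    summarise(min_p = suppressWarnings(min(.data$p, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(min_p = ifelse(is.finite(.data$min_p), .data$min_p, NA_real_),
           enriched = !is.na(.data$min_p) & .data$min_p < alpha)
  structure(list(profile = profile, tests = tests, summary = summary,
                 alpha = alpha),
            class = "peak_profile")
}

#' Summarise motif and peak enrichment per RBP, comparison and region
#'
#' Joins the region-level summaries of any number of [positional_motif_test()]
#' and [peak_density_test()] results and flags co-occurrence: a motif
#' enrichment (min-p < the motif alpha) and a peak enrichment (min-p < the
#' Fisher alpha) in the same region, side and comparison.
#'
#' @param motif_profiles list of `motif_profile` objects.
#' @param peak_profiles list of `peak_profile` objects (optional).
#' @return tibble: comparison, rbp, side, segment, min_p_motif, min_p_peaks,
#'   motif_enriched, peaks_enriched, co_occurrence.
#' @export
rbp_summary <- function(motif_profiles, peak_profiles = list()) {
  ms <- map(motif_profiles, "summary") |> list_rbind() |>
    rename(min_p_motif = "min_p", motif_enriched = "enriched")
  ps <- if (length(peak_profiles) > 0) {
    map(peak_profiles, "summary") |> list_rbind() |>
      rename(min_p_peaks = "min_p", peaks_enriched = "enriched")
  } else {
    tibble(comparison = character(), rbp = character(), side = character(),
           segment = character(), min_p_peaks = numeric(),
           peaks_enriched = logical())
  }
  full_join(ms, ps, by = c("comparison", "rbp", "side", "segment")) |>
    mutate(motif_enriched = replace_na(.data$motif_enriched, FALSE),
           peaks_enriched = replace_na(.data$peaks_enriched, FALSE),
           co_occurrence = .data$motif_enriched & .data$peaks_enriched)
}
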