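#' Simulate a time-course isoform count matrix with planted usage switches
#'
#' Counts are negative binomial with variance `mu + alpha * mu^2`. Per-gene
#' baseline expression is log-normal; isoform fractions are drawn from a
#' symmetric Dirichlet. For genes named in `switch_plan`, the fraction of the
#' `iso_up` isoform rises by `dif` (and `iso_down` falls by `dif`) linearly
#' between `day_from` and `day_to`. Library sizes vary by a uniform factor.
#'
#' @param annotation reference exon table (defines isoforms and genes).
#' @param design design tibble from [design_table()].
#' @param switch_plan optional tibble (`gene_id`, `iso_up`, `iso_down`, `dif`,
#'   `day_from`, `day_to`); `NULL` derives one from `config`.
#' @param seed integer seed.
#' @param config an [simulation_config()]; supplies dispersion, switch
#'   fraction/size and library-size range.
#' @param base_mu median per-gene expected count.
#' @return list with `counts` (tibble: transcript_id, gene_id, one column per
#'   sample), `tpm` (same shape, length-normalised), `switch_plan`,
#'   `lib_factors`.
#' @export
simulate_counts <- function(annotation, design, switch_plan = NULL, seed = 1L,
                            config = simulation_config(), base_mu = 300) {
  iso <- annotation |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(length = sum(.data$end - .data$start + 1), .groups = "drop")
  days <- sort(unique(design$day))
  with_seed(seed + 1L, {
    genes <- unique(iso$gene_id)
    gene_mu <- setNames(rlnorm(length(genes), log(base_mu), 0.7), genes)
    base_frac <- iso |>
      group_by(.data$gene_id) |>
      mutate(frac = {
        g <- rgamma(n(), shape = 3)
        g / sum(g)
      }) |>
      ungroup()

    if (is.null(switch_plan)) {
      multi <- base_frac |> count(.data$gene_id) |> filter(.data$n >= 2)
      n_sw <- round(config$switch_fraction * nrow(multi))
      sw_genes <- if (n_sw > 0) sample(multi$gene_id, n_sw) else character(0)
      switch_plan <- map(sw_genes, function(g) {
        tx <- base_frac$transcript_id[base_frac$gene_id == g]
        pick <- sample(tx, 2)
        tibble(gene_id = g, iso_up = pick[1], iso_down = pick[2],
               dif = config$switch_dif,
               day_from = days[1], day_to = days[length(days)])
      }) |> list_rbind()
      if (is.null(switch_plan) || ncol(switch_plan) == 0) {
        switch_plan <- tibble(gene_id = character(), iso_up = character(),
                              iso_down = character(), dif = numeric(),
                              day_from = numeric(), day_to = numeric())
      }
    }

    # rebalance switch-pair baseline fractions so the planted shift fits
    # inside [0, 1]: the pair's combined share S is split S(1 -/+ dif)/2
    if (nrow(switch_plan) > 0) {
      base_frac <- base_frac |>
        left_join(switch_plan, by = "gene_id") |>
        group_by(.data$gene_id) |>
        mutate(pair_share = sum(.data$frac[.data$transcript_id %in%
                                             c(.data$iso_up[1], .data$iso_down[1])]),
               frac = case_when(
                 !is.na(.data$iso_up) & .data$transcript_id == .data$iso_up ~
                   .data$pair_share * (1 - .data$dif) / 2,
                 !is.na(.data$iso_down) & .data$transcript_id == .data$iso_down ~
                   .data$pair_share * (1 + .data$dif) / 2,
                 TRUE ~ .data$frac)) |>
        ungroup() |>
        select(-"iso_up", -"iso_down", -"dif", -"day_from", -"day_to", -"pair_share")
    }

    lib <- setNames(runif(nrow(design), config$lib_size_range[1],
                          config$lib_size_range[2]), design$sample)

    # per-day isoform fractions after applying switches
    frac_day <- crossing(base_frac, day = days) |>
      left_join(switch_plan, by = "gene_id") |>
      mutate(
        prog = case_when(
          is.na(.data$dif) ~ 0,
          .data$day <= .data$day_from ~ 0,
          .data$day >= .data$day_to ~ 1,
          TRUE ~ (.data$day - .data$day_from) / (.data$day_to - .data$day_from)),
        delta = case_when(
          !is.na(.data$iso_up) & .data$transcript_id == .data$iso_up ~
            .data$dif * .data$prog,
          !is.na(.data$iso_down) & .data$transcript_id == .data$iso_down ~
            -.data$dif * .data$prog,
          TRUE ~ 0),
        frac = pmin(pmax(.data$frac + replace_na(.data$delta, 0), 0.001), 0.999))

    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    long <- crossing(design, iso |> select("transcript_id", "gene_id")) |>
      left_join(frac_day |> select("transcript_id", "day", "frac"),
                by = c("transcript_id", "day")) |>
      mutate(mu = lib[.data$sample] * gene_mu[.data$gene_id] * .data$frac,
             count = if (is.finite(size)) rnbinom(n(), mu = .data$mu, size = size)
                     else round(.data$mu))

    counts <- long |>
      select("transcript_id", "gene_id", "sample", "count") |>
      pivot_wider(names_from = "sample", values_from = "count") |>
      arrange(.data$transcript_id)
    tpm <- tpm_from_counts(counts, iso |> select("transcript_id", "length"))
    list(counts = counts, tpm = tpm, switch_plan = switch_plan,
         lib_factors = enframe_lib(lib))
  })
}

enframe_lib <- function(lib) tibble(sample = names(lib), factor = unname(lib))

#' Length-normalised TPM from a count matrix
#'
#' `TPM_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6`, per sample.
#'
#' @param counts tibble with `transcript_id` and sample columns (a `gene_id`
#'   column is carried through if present).
#' @param lengths tibble with `transcript_id`, `length` (nt).
#' @return tibble of the same shape as `counts`.
#' @export
tpm_from_counts <- function(counts, lengths) {
  id_cols <- intersect(c("transcript_id", "gene_id"), names(counts))
  samp <- setdiff(names(counts), id_cols)
  len <- lengths$length[match(counts$transcript_id, lengths$transcript_id)]
  if (anyNA(len)) abort("missing length for some transcripts")
  out <- counts
  for (s in samp) {
    rate <- counts[[s]] / len
    tot <- sum(rate)
    out[[s]] <- if (tot > 0) rate / tot * 1e6 else 0
  }
  out
}

#' Simulate junction read counts for cassette-exon events
#'
#' For each event, day and replicate the two inclusion-junction counts and the
#' skipping-junction count are drawn binomially around the planted inclusion
#' level: `I1, I2 ~ Bin(depth, psi)`, `S ~ Bin(depth, 1 - psi)`.
#'
#' @param events event table (needs `event_id`).
#' @param psi_plan tibble `event_id`, `day`, `psi` (one row per event and day).
#' @param depth per-junction binomial size.
#' @param seed integer seed.
#' @param design design tibble ([design_table()]).
#' @return tibble: event_id, sample, day, replicate, I1, I2, S.
#' @export
simulate_junction_counts <- function(events, psi_plan, depth = 100L, seed = 1L,
                                     design = design_table()) {
  stopifnot(all(events$event_id %in% psi_plan$event_id))
  with_seed(seed + 2L, {
    crossing(design, event_id = events$event_id) |>
      left_join(psi_plan, by = c("event_id", "day")) |>
      mutate(I1 = rbinom(n(), depth, .data$psi),
             I2 = rbinom(n(), depth, .data$psi),
             S = rbinom(n(), depth, 1 - .data$psi)) |>
      select("event_id", "sample", "day", "replicate", "I1", "I2", "S")
  })
}

#' Build a per-day inclusion-level plan for simulated events
#'
#' Assigns each event a baseline psi and, for events listed in `dpsi`, a linear
#' change of that size between `day_from` and `day_to`.
#'
#' @param events event table (needs `event_id`).
#' @param days day labels.
#' @param dpsi named numeric: planted psi change per event id (others stay
#'   flat).
#' @param base_psi baseline inclusion level.
#' @param day_from,day_to change window (defaults: whole course).
#' @return tibble `event_id`, `day`, `psi`.
#' @export
make_psi_plan <- function(events, days = 0:5, dpsi = NULL, base_psi = 0.5,
                          day_from = min(days), day_to = max(days)) {
  crossing(event_id = events$event_id, day = days) |>
    mutate(change = if (is.null(dpsi)) 0 else
             ifelse(.data$event_id %in% names(dpsi), dpsi[.data$event_id], 0),
           prog = ifelse(.data$day <= day_from, 0,
                         pmin(1, (.data$day - day_from) / max(day_to - day_from, 1))),
           psi = pmin(pmax(base_psi + .data$change * .data$prog, 0.01), 0.99)) |>
    select("event_id", "day", "psi")
}
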