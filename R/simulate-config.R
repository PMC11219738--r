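# seeded evaluation that never leaks into the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study design the package targets: a 6-day
#' differentiation time course with 3 replicates per day, multi-isoform gene
#' models carrying planted alternative transcription/splicing events, long
#' reads with planted artifact classes, usage switches in a subset of genes,
#' motif plants around included cassette exons, and isoform-resolved peptides
#' with missing-not-at-random dropout.
#'
#' @param seed integer; fully determines all generator output.
#' @param n_genes number of gene models.
#' @param isoforms_per_gene length-2 integer range (inclusive).
#' @param n_days,replicates_per_day time-course design (days are labelled
#'   `0 .. n_days-1`).
#' @param artifact_rates named fractions for `mispriming`, `template_switch`,
#'   `truncation`, `fusion`; the remainder of reads is clean. Must sum to <= 1.
#' @param switch_fraction fraction of genes with a planted usage switch.
#' @param switch_dif planted change in isoform fraction for switch genes.
#' @param motif_plant list with `motif` (IUPAC string), `segment` (one of the
#'   eight segment names, see [extract_segments()]) and `fraction` of included
#'   events that receive plants.
#' @param peptide_missingness MNAR fraction for simulated peptide intensities.
#' @param exons_per_gene,exon_length,intron_length length-2 ranges for gene
#'   geometry (nt).
#' @param a_rich_fraction fraction of genes given an A-rich mispriming trap
#'   downstream of an internal exon.
#' @param jitter_sd,end_sd read-level boundary noise (nt, gaussian).
#' @param dispersion negative-binomial dispersion alpha (variance mu+alpha*mu^2).
#' @param lib_size_range multiplicative library-size factor range.
#'
#' @return a validated list of class `isodyn_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 50L,
                              isoforms_per_gene = c(2L, 4L),
                              n_days = 6L,
                              replicates_per_day = 3L,
                              artifact_rates = c(mispriming = 0.05,
                                                 template_switch = 0.05,
                                                 truncation = 0.10,
                                                 fusion = 0.02),
                              switch_fraction = 0.3,
                              switch_dif = 0.4,
                              motif_plant = list(motif = "TTTTAA",
                                                 segment = "dnIntron5p",
                                                 fraction = 0.8),
                              peptide_missingness = 0.2,
                              exons_per_gene = c(5L, 8L),
                              exon_length = c(90L, 250L),
                              intron_length = c(350L, 900L),
                              a_rich_fraction = 0.3,
                              jitter_sd = 1,
                              end_sd = 10,
                              dispersion = 0.05,
                              lib_size_range = c(0.8, 1.25)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              n_days = as.integer(n_days),
              replicates_per_day = as.integer(replicates_per_day),
              artifact_rates = artifact_rates,
              switch_fraction = switch_fraction, switch_dif = switch_dif,
              motif_plant = motif_plant,
              peptide_missingness = peptide_missingness,
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              a_rich_fraction = a_rich_fraction,
              jitter_sd = jitter_sd, end_sd = end_sd,
              dispersion = dispersion, lib_size_range = lib_size_range)
  rates <- c(cfg$artifact_rates, cfg$switch_fraction, cfg$motif_plant$fraction,
             cfg$peptide_missingness, cfg$a_rich_fraction)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (sum(cfg$artifact_rates) > 1) abort("artifact rates must sum to <= 1")
  if (cfg$n_days < 2) abort("need at least 2 days")
  if (cfg$replicates_per_day < 2) abort("need at least 2 replicates per day")
  if (cfg$isoforms_per_gene[1] < 1 ||
      cfg$isoforms_per_gene[2] < cfg$isoforms_per_gene[1]) {
    abort("isoforms_per_gene must be an increasing range starting at >= 1")
  }
  seg_names <- c("upExon3p", "upIntron5p", "upIntron3p", "target5p",
                 "target3p", "dnIntron5p", "dnIntron3p", "dnExon5p")
  if (!cfg$motif_plant$segment %in% seg_names) {
    abort(paste0("motif_plant$segment must be one of: ",
                 paste(seg_names, collapse = ", ")))
  }
  structure(cfg, class = "isodyn_config")
}

#' Time-course design table
#'
#' @param n_days number of days (labelled from 0).
#' @param replicates_per_day replicates per day.
#' @return tibble with `sample`, `day`, `replicate`.
#' @export
design_table <- function(n_days = 6, replicates_per_day = 3) {
  crossing(day = seq_len(n_days) - 1L, replicate = seq_len(replicates_per_day)) |>
    mutate(sample = paste0("d", .data$day, "_r", .data$replicate), .before = 1)
}
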