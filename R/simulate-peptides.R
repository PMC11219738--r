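#' Tryptic-like in-silico digestion
#'
#' Cleaves after K or R except when the next residue is P; peptides outside
#' the retained length range are discarded.
#'
#' @param aa amino-acid sequence (single string).
#' @param min_len,max_len retained peptide length range.
#' @return character vector of peptides (may contain duplicates if the
#'   protein repeats a peptide).
#' @export
tryptic_peptides <- function(aa, min_len = 7L, max_len = 30L) {
  ch <- strsplit(aa, "")[[1]]
  n <- length(ch)
  if (n == 0) return(character(0))
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & ch[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- head(bounds, -1) + 1L
  ends <- tail(bounds, -1)
  peps <- substring(aa, starts, ends)
  peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
}

#' Predicted protein sequences for annotated isoforms
#'
#' Extracts each transcript's spliced sequence, finds the longest
#' ATG-initiated open reading frame and translates it. Transcripts without an
#' ORF (no in-frame stop) are dropped.
#'
#' @param annotation exon table.
#' @param genome named character vector.
#' @return tibble: transcript_id, gene_id, aa.
#' @export
isoform_proteins <- function(annotation, genome) {
  annotation |>
    group_by(.data$gene_id, .data$transcript_id) |>
    group_map(function(ex, key) {
      s <- transcript_seq(mutate(ex, strand = ex$strand[1]), genome)
      orf <- longest_orf(s)
      if (is.null(orf)) return(NULL)
      tibble(transcript_id = key$transcript_id, gene_id = key$gene_id,
             aa = orf$aa)
    }) |>
    list_rbind()
}

#' Construct a pair of protein isoforms with shared and unique segments
#'
#' Two amino-acid sequences sharing N- and C-terminal segments and differing
#' in one internal segment — the canonical situation in which only the
#' peptides overlapping the distinct segment are isoform-specific. Cleavage
#' residues (K/R) are sprinkled so tryptic digestion yields peptides in the
#' retained length range.
#'
#' @param seed integer seed.
#' @param shared_len length of each shared terminal segment (aa).
#' @param unique_len length of the isoform-specific internal segment (aa).
#' @param gene_id,ids identifiers for the emitted tibble.
#' @return tibble: transcript_id, gene_id, aa (2 rows).
#' @export
synthetic_protein_pair <- function(seed = 1L, shared_len = 120L,
                                   unique_len = 40L, gene_id = "G1",
                                   ids = c("G1.A", "G1.B")) {
  aa_pool <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  with_seed(seed + 8L, {
    seg <- function(n) {
      x <- sample(aa_pool, n, replace = TRUE)
      x[seq(10, n, by = 12)] <- sample(c("K", "R"), length(seq(10, n, by = 12)),
                                       replace = TRUE)
      paste(x, collapse = "")
    }
    nter <- seg(shared_len); cter <- seg(shared_len)
    tibble(transcript_id = ids, gene_id = gene_id,
           aa = c(paste0(nter, seg(unique_len), cter),
                  paste0(nter, seg(unique_len), cter)))
  })
}

#' Simulate an isoform-resolved peptide intensity table
#'
#' Digests each protein isoform, marks peptides shared between isoforms,
#' assigns each peptide a base detectability (log-normal), splits intensity
#' across chromatographic fractions with a fixed per-peptide profile, scales
#' by the isoform abundance trajectory per day, adds log-normal noise, and
#' censors values missing-not-at-random: the dropout probability is a
#' decreasing logistic function of log-intensity centred at the lower
#' `missingness` quantile, so dropout concentrates in low-abundance values.
#'
#' @param proteins tibble: `transcript_id` (or `isoform_id`), `gene_id`, `aa`.
#' @param abundance_plan tibble `transcript_id`, `day`, `log2_abundance`
#'   (relative to baseline); `NULL` means flat trajectories.
#' @param missingness overall MNAR fraction in (0, 1); 0 disables dropout.
#' @param seed integer seed.
#' @param design design tibble.
#' @param n_fractions SCX-like fractions per sample.
#' @param noise_sd log2-scale measurement noise.
#' @return list with `peptides` (tibble: peptide, matched_isoforms
#'   (;-separated), fraction, sample, intensity with NA = missing) and
#'   `truth` (the abundance plan used).
#' @export
simulate_peptides <- function(proteins, abundance_plan = NULL, missingness = 0.2,
                              seed = 1L, design = design_table(),
                              n_fractions = 4L, noise_sd = 0.25) {
  if ("isoform_id" %in% names(proteins) && !"transcript_id" %in% names(proteins)) {
    proteins <- rename(proteins, transcript_id = "isoform_id")
  }
  with_seed(seed + 5L, {
    pep_map <- proteins |>
      mutate(peptide = map(.data$aa, tryptic_peptides)) |>
      select("transcript_id", "peptide") |>
      unnest("peptide") |>
      distinct() |>
      group_by(.data$peptide) |>
      summarise(matched_isoforms = paste(sort(.data$transcript_id), collapse = ";"),
                isoforms = list(sort(.data$transcript_id)), .groups = "drop")
    if (nrow(pep_map) == 0) abort("no peptides survive digestion")
    days <- sort(unique(design$day))
    if (is.null(abundance_plan)) {
      abundance_plan <- crossing(transcript_id = proteins$transcript_id,
                                 day = days) |>
        mutate(log2_abundance = 0)
    }
    ab <- abundance_plan |>
      pivot_wider(names_from = "day", values_from = "log2_abundance")

    base <- setNames(rlnorm(nrow(pep_map), log(1e6), 1), pep_map$peptide)
    fw <- lapply(setNames(pep_map$peptide, pep_map$peptide), function(p) {
      w <- rgamma(n_fractions, 1.5); w / sum(w)
    })

    long <- crossing(pep_map |> select("peptide", "matched_isoforms", "isoforms"),
                     design, fraction = seq_len(n_fractions)) |>
      mutate(
        day_abund = map2_dbl(.data$isoforms, .data$day, function(iso, d) {
          rows <- match(iso, ab$transcript_id)
          sum(2^(as.numeric(ab[[as.character(d)]][rows])), na.rm = TRUE)
        }),
        w = map2_dbl(.data$peptide, .data$fraction, ~ fw[[.x]][.y]),
        intensity = base[.data$peptide] * .data$w * .data$day_abund *
          2^rnorm(n(), 0, noise_sd))

    if (missingness > 0) {
      x <- log2(long$intensity)
      thr <- quantile(x, missingness)
      p_miss <- stats::plogis((thr - x) / 0.5)
      long$intensity[runif(nrow(long)) < p_miss] <- NA_real_
    }
    list(peptides = long |>
           select("peptide", "matched_isoforms", "fraction", "sample",
                  "day", "replicate", "intensity"),
         truth = abundance_plan)
  })
}
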