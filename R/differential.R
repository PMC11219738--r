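#' Relative-log-expression (median-of-ratios) normalization
#'
#' Size factor per sample = median over features of count / geometric mean
#' across samples; features containing any zero are excluded from the median.
#' Normalized counts are counts divided by the sample's size factor.
#'
#' @param counts tibble with feature id column(s) (`transcript_id` and/or
#'   `gene_id`) and one numeric column per sample.
#' @return list with `normalized` (same shape) and `size_factors` (tibble:
#'   sample, size_factor).
#' @export
rle_normalize <- function(counts) {
  id_cols <- intersect(c("transcript_id", "gene_id", "feature_id"), names(counts))
  samp <- setdiff(names(counts), id_cols)
  m <- as.matrix(counts[, samp])
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) abort("no feature free of zeros; cannot compute size factors")
  geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  # median of ratios, computed in log space so even-count medians average
  # geometrically (the convention of the reference implementation)
  sf <- exp(apply(log(m[pos, , drop = FALSE] / geo), 2, median))
  norm <- counts
  for (s in samp) norm[[s]] <- counts[[s]] / sf[[s]]
  list(normalized = norm,
       size_factors = tibble(sample = samp, size_factor = unname(sf)))
}

# Welch test on two numeric vectors, safe for degenerate inputs
welch_p <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' Differential gene expression between two days
#'
#' On RLE-normalized counts: `log2FC = log2((mean_B + 1) / (mean_A + 1))`, a
#' two-sample unequal-variance t-test on `log2(normalized + 1)`, BH adjustment
#' across genes, and the printed significance rule `padj < 0.05` and
#' `|log2FC| > 0.59` (a change of at least 50%).
#'
#' @param normalized normalized count tibble (gene rows; id column `gene_id`
#'   or `transcript_id` for transcript-level calls).
#' @param design design tibble mapping samples to days.
#' @param day_a,day_b the two days compared (B vs A).
#' @param lfc_cutoff,alpha significance rule.
#' @return `isodyn_dge` tibble: feature_id, comparison, mean_a, mean_b,
#'   log2FC, p, padj, significant.
#' @export
dge <- function(normalized, design, day_a, day_b,
                lfc_cutoff = 0.59, alpha = 0.05) {
  id_col <- intersect(c("gene_id", "transcript_id", "feature_id"),
                      names(normalized))[1]
  if (is.na(id_col)) abort("no feature id column found")
  sa <- design$sample[design$day == day_a]
  sb <- design$sample[design$day == day_b]
  stopifnot(length(sa) >= 2, length(sb) >= 2)
  A <- as.matrix(normalized[, sa]); B <- as.matrix(normalized[, sb])
  res <- tibble(
    feature_id = normalized[[id_col]],
    comparison = paste0("d", day_a, "_d", day_b),
    mean_a = rowMeans(A), mean_b = rowMeans(B),
    log2FC = log2((rowMeans(B) + 1) / (rowMeans(A) + 1)),
    p = vapply(seq_len(nrow(A)), function(i)
      welch_p(log2(A[i, ] + 1), log2(B[i, ] + 1)), numeric(1))) |>
    mutate(padj = p.adjust(.data$p, "BH"),
           significant = !is.na(.data$padj) & .data$padj < alpha &
             abs(.data$log2FC) > lfc_cutoff)
  class(res) <- c("isodyn_dge", class(res))
  res
}

#' Per-sample isoform fractions with expression filters
#'
#' Keeps genes whose mean TPM exceeds `min_gene_tpm` at every day and that
#' have at least `min_isoforms` detected isoforms, then computes
#' `IF = isoform TPM / gene TPM` per sample.
#'
#' @param tpm isoform TPM tibble (`transcript_id`, `gene_id`, sample columns).
#' @param design design tibble.
#' @param min_gene_tpm gene-level mean-TPM floor applied at each day.
#' @param min_isoforms minimum detected (nonzero somewhere) isoforms per gene.
#' @return tibble: transcript_id, gene_id, sample, day, IF.
#' @export
compute_usage <- function(tpm, design, min_gene_tpm = 1, min_isoforms = 2) {
  samp <- design$sample
  long <- tpm |>
    pivot_longer(all_of(samp), names_to = "sample", values_to = "tpm") |>
    left_join(design, by = "sample")
  gene_day <- long |>
    group_by(.data$gene_id, .data$day, .data$sample) |>
    summarise(gene_tpm = sum(.data$tpm), .groups = "drop_last") |>
    summarise(mean_tpm = mean(.data$gene_tpm), .groups = "drop")
  ok_expr <- gene_day |>
    group_by(.data$gene_id) |>
    summarise(ok = all(.data$mean_tpm > min_gene_tpm), .groups = "drop") |>
    filter(.data$ok)
  ok_iso <- long |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(detected = any(.data$tpm > 0), .groups = "drop_last") |>
    summarise(n_detected = sum(.data$detected), .groups = "drop") |>
    filter(.data$n_detected >= min_isoforms)
  long |>
    filter(.data$gene_id %in% ok_expr$gene_id,
           .data$gene_id %in% ok_iso$gene_id) |>
    group_by(.data$gene_id, .data$sample) |>
    mutate(IF = if (sum(.data$tpm) > 0) .data$tpm / sum(.data$tpm)
                else rep(NA_real_, n())) |>
    ungroup() |>
    select("transcript_id", "gene_id", "sample", "day", "IF")
}

#' Differential transcript usage between two days
#'
#' `dIF = mean IF(day B) - mean IF(day A)`; p-values from an
#' unequal-variance t-test on logit-transformed isoform fractions (clamped to
#' \[0.01, 0.99\]), BH-adjusted across isoforms. An isoform is significant
#' when `padj < alpha` and `|dIF| >= dif_cutoff`.
#'
#' @param usage output of [compute_usage()].
#' @param day_a,day_b days compared (B vs A).
#' @param dif_cutoff minimum absolute usage change (default 0.1).
#' @param alpha FDR level.
#' @return `isodyn_dtu` tibble: isoform_id, gene_id, comparison, IF_a, IF_b,
#'   dIF, p, padj, significant.
#' @export
dtu_test <- function(usage, day_a, day_b, dif_cutoff = 0.1, alpha = 0.05) {
  logit <- function(x) {
    x <- pmin(pmax(x, 0.01), 0.99)
    log(x / (1 - x))
  }
  res <- usage |>
    filter(.data$day %in% c(day_a, day_b), !is.na(.data$IF)) |>
    group_by(isoform_id = .data$transcript_id, gene_id = .data$gene_id) |>
    summarise(
      IF_a = mean(.data$IF[.data$day == day_a]),
      IF_b = mean(.data$IF[.data$day == day_b]),
      p = welch_p(logit(.data$IF[.data$day == day_a]),
                  logit(.data$IF[.data$day == day_b])),
      .groups = "drop") |>
    mutate(comparison = paste0("d", day_a, "_d", day_b),
           dIF = .data$IF_b - .data$IF_a,
           padj = p.adjust(.data$p, "BH"),
           significant = !is.na(.data$padj) & .data$padj < alpha &
             abs(.data$dIF) >= dif_cutoff) |>
    select("isoform_id", "gene_id", "comparison", "IF_a", "IF_b", "dIF",
           "p", "padj", "significant")
  class(res) <- c("isodyn_dtu", class(res))
  res
}

#' Junction-count inclusion levels and regulated-event classification
#'
#' Per replicate, `Psi = ((I1 + I2) / 2) / (((I1 + I2) / 2) + S)` (two
#' inclusion junctions count half each against one skipping junction).
#' `dPsi = mean Psi(day B) - mean Psi(day A)`; p-values from a two-sample
#' rank-sum test on replicate Psi (exact permutation for groups of up to 4,
#' tie-corrected normal approximation otherwise), BH-adjusted to an FDR.
#' Events are partitioned into `included` (`dPsi > 0.05`, `FDR < 0.05`),
#' `excluded` (`dPsi < -0.05`, `FDR < 0.05`), `background` (`FDR > 0.5`) and
#' `unassigned` otherwise. Replicates with `I1 + I2 + S = 0` are dropped;
#' events need two informative replicates per group.
#'
#' @param junctions tibble: event_id, day, replicate, I1, I2, S.
#' @param day_a,day_b days compared (B vs A).
#' @param dpsi_cutoff,alpha,background_fdr partition thresholds.
#' @return `isodyn_psi` tibble: event_id, comparison, psi_a, psi_b, dPsi, p,
#'   FDR, regulation.
#' @export
psi_and_classify <- function(junctions, day_a, day_b, dpsi_cutoff = 0.05,
                             alpha = 0.05, background_fdr = 0.5) {
  dat <- junctions |>
    filter(.data$day %in% c(day_a, day_b)) |>
    mutate(inc = (.data$I1 + .data$I2) / 2,
           informative = .data$inc + .data$S > 0,
           psi = ifelse(.data$informative, .data$inc / (.data$inc + .data$S),
                        NA_real_)) |>
    filter(.data$informative)
  res <- dat |>
    group_by(.data$event_id) |>
    summarise(
      n_a = sum(.data$day == day_a), n_b = sum(.data$day == day_b),
      psi_a = mean(.data$psi[.data$day == day_a]),
      psi_b = mean(.data$psi[.data$day == day_b]),
      p = if (sum(.data$day == day_a) >= 2 && sum(.data$day == day_b) >= 2) {
        ranksum_test(.data$psi[.data$day == day_a],
                     .data$psi[.data$day == day_b])
      } else NA_real_,
      .groups = "drop") |>
    filter(.data$n_a >= 2, .data$n_b >= 2) |>
    mutate(comparison = paste0("d", day_a, "_d", day_b),
           dPsi = .data$psi_b - .data$psi_a,
           FDR = p.adjust(.data$p, "BH"),
           regulation = case_when(
             .data$dPsi > dpsi_cutoff & .data$FDR < alpha ~ "included",
             .data$dPsi < -dpsi_cutoff & .data$FDR < alpha ~ "excluded",
             .data$FDR > background_fdr ~ "background",
             TRUE ~ "unassigned")) |>
    select("event_id", "comparison", "psi_a", "psi_b", "dPsi", "p", "FDR",
           "regulation")
  class(res) <- c("isodyn_psi", class(res))
  res
}
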