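#' Presence filter for protein intensity matrices
#'
#' Keeps proteins observed in at least `min_present` replicates within at
#' least one condition (day).
#'
#' @param mat tibble: protein id column (first non-sample column) + one
#'   numeric column per sample; NA = missing.
#' @param design design tibble.
#' @param min_present minimum observed replicates in some condition.
#' @return the filtered tibble.
#' @export
presence_filter <- function(mat, design, min_present = 2L) {
  samp <- intersect(design$sample, names(mat))
  keep <- vapply(seq_len(nrow(mat)), function(i) {
    x <- as.numeric(mat[i, samp])
    any(vapply(split(samp, design$day[match(samp, design$sample)]),
               function(s) sum(!is.na(x[match(s, samp)])) >= min_present,
               logical(1)))
  }, logical(1))
  mat[keep, , drop = FALSE]
}

#' Left-censored (MNAR) imputation
#'
#' Missing cells are drawn per sample from a left-shifted gaussian:
#' `Normal(mean - shift * sd, (scale * sd)^2)` where mean and sd are the
#' sample's observed log2 intensities. Observed values are never touched.
#'
#' @param mat filtered log2 intensity tibble (see [presence_filter()]).
#' @param design design tibble (identifies sample columns).
#' @param shift,scale imputation distribution parameters (defaults 1.8, 0.3).
#' @param seed integer seed.
#' @return the completed tibble.
#' @export
impute_mnar <- function(mat, design, shift = 1.8, scale = 0.3, seed = 1L) {
  samp <- intersect(design$sample, names(mat))
  with_seed(seed + 6L, {
    for (s in samp) {
      x <- mat[[s]]
      miss <- is.na(x)
      if (!any(miss)) next
      m <- mean(x[!miss]); sdev <- sd(x[!miss])
      if (!is.finite(sdev) || sdev == 0) sdev <- 0.3
      mat[[s]][miss] <- rnorm(sum(miss), m - shift * sdev, scale * sdev)
    }
    mat
  })
}

#' Differential protein abundance between two days
#'
#' `log2FC = mean(B) - mean(A)` on log2 intensities, unequal-variance t-test,
#' BH adjustment; significant when `padj < 0.1` and `|log2FC| > 0.32` (at
#' least a 25% change).
#'
#' @param mat imputed log2 intensity tibble; first column is the protein id.
#' @param design design tibble.
#' @param day_a,day_b days compared (B vs A).
#' @param lfc_cutoff,alpha significance rule.
#' @return `isodyn_dge`-style tibble: feature_id, comparison, log2FC, p,
#'   padj, significant.
#' @export
differential_protein <- function(mat, design, day_a, day_b,
                                 lfc_cutoff = 0.32, alpha = 0.1) {
  id_col <- setdiff(names(mat), design$sample)[1]
  sa <- design$sample[design$day == day_a]
  sb <- design$sample[design$day == day_b]
  A <- as.matrix(mat[, sa]); B <- as.matrix(mat[, sb])
  res <- tibble(
    feature_id = mat[[id_col]],
    comparison = paste0("d", day_a, "_d", day_b),
    log2FC = rowMeans(B, na.rm = TRUE) - rowMeans(A, na.rm = TRUE),
    p = vapply(seq_len(nrow(A)), function(i) welch_p(A[i, ], B[i, ]),
               numeric(1))) |>
    mutate(padj = p.adjust(.data$p, "BH"),
           significant = !is.na(.data$padj) & .data$padj < alpha &
             abs(.data$log2FC) > lfc_cutoff)
  class(res) <- c("isodyn_dge", class(res))
  res
}

#' Isoform-level LFQ from unique peptides
#'
#' Discards peptides matching more than one isoform, sums each remaining
#' peptide's per-fraction intensities, and totals unique-peptide intensity
#' per isoform and sample. Isoforms without any unique peptide are reported
#' as unquantifiable.
#'
#' @param peptides long tibble: peptide, matched_isoforms (;-separated),
#'   fraction, sample, intensity (NA = missing).
#' @param isoform_ids optional universe of isoforms (to report unquantifiable
#'   ones not present in the table).
#' @return list with `lfq` (tibble: isoform_id, sample, lfq) and
#'   `unquantifiable` (character vector).
#' @export
assign_peptides <- function(peptides, isoform_ids = NULL) {
  pep <- peptides |>
    mutate(n_match = str_count(.data$matched_isoforms, ";") + 1L)
  uni <- filter(pep, .data$n_match == 1L)
  lfq <- uni |>
    group_by(isoform_id = .data$matched_isoforms, .data$sample) |>
    summarise(lfq = sum(.data$intensity, na.rm = TRUE), .groups = "drop")
  universe <- unique(c(isoform_ids,
                       unlist(str_split(pep$matched_isoforms, ";"))))
  unq <- setdiff(universe, unique(uni$matched_isoforms))
  list(lfq = lfq, unquantifiable = sort(unq))
}

#' Protein isoform trend differences
#'
#' For each gene and pair of quantified isoforms, computes per-comparison
#' log2 fold changes of the isoform LFQ (mean over replicates,
#' observed-values-only) and the absolute difference of the two isoforms'
#' fold changes; a pair is a trend change when any comparison's difference
#' reaches `delta_cutoff` (default 1). Fold changes are invariant to the
#' per-isoform max-normalisation used for plotting.
#'
#' @param lfq tibble isoform_id, sample, lfq (from [assign_peptides()]).
#' @param design design tibble.
#' @param gene_of named character vector isoform -> gene.
#' @param comparisons list of `c(day_a, day_b)` pairs; default consecutive
#'   days.
#' @param delta_cutoff trend-change threshold on |log2FC_A - log2FC_B|.
#' @return `isodyn_trend` tibble: gene_id, isoform_a, isoform_b, comparison,
#'   lfc_a, lfc_b, delta, trend_change (pair-level flag repeated per row).
#' @export
trend_differences <- function(lfq, design, gene_of, comparisons = NULL,
                              delta_cutoff = 1) {
  days <- sort(unique(design$day))
  if (is.null(comparisons)) {
    comparisons <- map(seq_len(length(days) - 1), ~ c(days[.x], days[.x + 1]))
  }
  lfc <- lfq |>
    left_join(design, by = "sample") |>
    group_by(.data$isoform_id, .data$day) |>
    summarise(mean_lfq = mean(.data$lfq[.data$lfq > 0]), .groups = "drop")
  lfc_pair <- map(comparisons, function(cmp) {
    a <- filter(lfc, .data$day == cmp[1]); b <- filter(lfc, .data$day == cmp[2])
    inner_join(a, b, by = "isoform_id", suffix = c("_a", "_b")) |>
      transmute(isoform_id = .data$isoform_id,
                comparison = paste0("d", cmp[1], "_d", cmp[2]),
                lfc = log2(.data$mean_lfq_b / .data$mean_lfq_a))
  }) |> list_rbind()

  iso <- unique(lfc_pair$isoform_id)
  res <- tibble(gene_id = unname(gene_of[iso]), isoform_id = iso) |>
    filter(!is.na(.data$gene_id)) |>
    group_by(.data$gene_id) |>
    filter(n() >= 2) |>
    group_map(function(g, key) {
      prs <- combn(sort(g$isoform_id), 2)
      map(seq_len(ncol(prs)), function(i) {
        a <- prs[1, i]; b <- prs[2, i]
        inner_join(filter(lfc_pair, .data$isoform_id == a),
                   filter(lfc_pair, .data$isoform_id == b),
                   by = "comparison", suffix = c("_a", "_b")) |>
          transmute(gene_id = key$gene_id, isoform_a = a, isoform_b = b,
                    comparison = .data$comparison,
                    lfc_a = .data$lfc_a, lfc_b = .data$lfc_b,
                    delta = abs(.data$lfc_a - .data$lfc_b))
      }) |> list_rbind()
    }) |> list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    res <- tibble(gene_id = character(), isoform_a = character(),
                  isoform_b = character(), comparison = character(),
                  lfc_a = numeric(), lfc_b = numeric(), delta = numeric())
  }
  res <- res |>
    group_by(.data$gene_id, .data$isoform_a, .data$isoform_b) |>
    mutate(trend_change = any(.data$delta >= delta_cutoff, na.rm = TRUE)) |>
    ungroup()
  class(res) <- c("isodyn_trend", class(res))
  res
}

#' Lagged RNA-protein fold-change correlation
#'
#' Joins RNA and protein log2 fold-change tables on feature id and computes
#' Spearman's rho for every pair of (RNA comparison, protein comparison),
#' optionally restricted to features significant in at least one comparison
#' of either table.
#'
#' @param rna,protein `isodyn_dge`-style tibbles (feature_id, comparison,
#'   log2FC, significant).
#' @param restrict limit to features significant somewhere (default TRUE).
#' @return tibble: rna_comparison, protein_comparison, rho, n.
#' @export
rna_protein_correlation <- function(rna, protein, restrict = TRUE) {
  if (restrict) {
    keep <- union(rna$feature_id[rna$significant],
                  protein$feature_id[protein$significant])
    rna <- filter(rna, .data$feature_id %in% keep)
    protein <- filter(protein, .data$feature_id %in% keep)
  }
  crossing(rna_comparison = unique(rna$comparison),
           protein_comparison = unique(protein$comparison)) |>
    mutate(res = map2(.data$rna_comparison, .data$protein_comparison,
      function(rc, pc) {
        j <- inner_join(filter(rna, .data$comparison == rc),
                        filter(protein, .data$comparison == pc),
                        by = "feature_id", suffix = c("_rna", "_prot"))
        tibble(rho = if (nrow(j) >= 3)
                 suppressWarnings(cor(j$log2FC_rna, j$log2FC_prot,
                                      method = "spearman",
                                      use = "complete.obs")) else NA_real_,
               n = nrow(j))
      })) |>
    unnest("res")
}
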