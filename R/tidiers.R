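#' @method tidy isodyn_catalog
#' @export
tidy.isodyn_catalog <- function(x, ...) {
  as_tibble(x) |> select(-any_of(c("exons", "read_ids", "junctions", "matched")))
}

#' @method glance isodyn_catalog
#' @export
glance.isodyn_catalog <- function(x, ...) {
  tibble(n_isoforms = nrow(x),
         n_retained = if ("retained" %in% names(x)) sum(x$retained) else NA_integer_,
         classes = if ("class" %in% names(x))
           paste(names(table(x$class)), table(x$class), sep = ":", collapse = ", ")
         else NA_character_)
}

#' @method glance isodyn_dge
#' @export
glance.isodyn_dge <- function(x, ...) {
  x |> group_by(.data$comparison) |>
    summarise(n = n(), n_significant = sum(.data$significant, na.rm = TRUE),
              .groups = "drop")
}

#' @method glance isodyn_dtu
#' @export
glance.isodyn_dtu <- function(x, ...) {
  x |> group_by(.data$comparison) |>
    summarise(n_isoforms = n(), n_significant = sum(.data$significant, na.rm = TRUE),
              n_genes_switching = n_distinct(.data$gene_id[.data$significant]),
              .groups = "drop")
}

#' @method glance isodyn_psi
#' @export
glance.isodyn_psi <- function(x, ...) {
  x |> count(.data$comparison, .data$regulation) |>
    pivot_wider(names_from = "regulation", values_from = "n", values_fill = 0L)
}

#' @method tidy motif_profile
#' @export
tidy.motif_profile <- function(x, ...) x$tests

#' @method glance motif_profile
#' @export
glance.motif_profile <- function(x, ...) x$summary

#' @method tidy peak_profile
#' @export
tidy.peak_profile <- function(x, ...) x$tests

#' @method glance peak_profile
#' @export
glance.peak_profile <- function(x, ...) x$summary

#' @method glance isodyn_trend
#' @export
glance.isodyn_trend <- function(x, ...) {
  pairs <- x |> distinct(.data$gene_id, .data$isoform_a, .data$isoform_b,
                         .data$trend_change)
  tibble(n_pairs = nrow(pairs),
         n_trend_changes = sum(pairs$trend_change),
         n_genes = n_distinct(pairs$gene_id[pairs$trend_change]))
}
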