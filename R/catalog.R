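#' Collapse long-read exon chains into isoform models
#'
#' Reads on the same chromosome and strand with the same exon count are merged
#' when every internal boundary agrees within `internal_tol` nt and both
#' transcript ends agree within `end_tol` nt (single-linkage over pairwise
#' compatibility). The cluster representative takes the per-boundary median;
#' clusters with fewer than `min_cluster` reads are discarded.
#'
#' @param reads exon table keyed by `read_id`.
#' @param internal_tol internal boundary tolerance (nt).
#' @param end_tol end tolerance (nt).
#' @param min_cluster minimum reads per emitted isoform.
#' @return a catalog tibble of class `isodyn_catalog`: one row per isoform
#'   with `isoform_id`, `chrom`, `strand`, `read_support`, `read_ids`
#'   (list-column) and `exons` (list-column of start/end tibbles).
#' @export
collapse_reads <- function(reads, internal_tol = 5L, end_tol = 50L,
                           min_cluster = 3L) {
  validate_exons(reads, id_col = "read_id")
  reads <- arrange(reads, .data$read_id, .data$start)
  info <- reads |>
    group_by(.data$read_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              n_exons = n(),
              bounds = list(c(rbind(.data$start, .data$end))), .groups = "drop")

  clusters <- info |>
    group_by(.data$chrom, .data$strand, .data$n_exons) |>
    group_map(function(g, key) {
      B <- do.call(rbind, g$bounds)   # reads x (2*n_exons), interleaved s,e
      n <- nrow(B)
      nb <- ncol(B)
      is_end <- rep(FALSE, nb)
      is_end[c(1, nb)] <- TRUE        # outer start of first, outer end of last
      tol <- ifelse(is_end, end_tol, internal_tol)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      if (n > 1) {
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
          if (all(abs(B[i, ] - B[j, ]) <= tol)) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
      comp <- vapply(seq_len(n), find, integer(1))
      lapply(split(seq_len(n), comp), function(idx) {
        rep_bounds <- round(apply(B[idx, , drop = FALSE], 2, median))
        k <- nb / 2
        tibble(chrom = key$chrom, strand = key$strand,
               read_support = length(idx),
               read_ids = list(g$read_id[idx]),
               exons = list(tibble(start = rep_bounds[2 * seq_len(k) - 1],
                                   end = rep_bounds[2 * seq_len(k)])))
      }) |> list_rbind()
    }) |>
    list_rbind() |>
    filter(.data$read_support >= min_cluster)

  if (nrow(clusters) == 0) {
    out <- tibble(isoform_id = character(), chrom = character(),
                  strand = character(), read_support = integer(),
                  read_ids = list(), exons = list())
  } else {
    out <- clusters |>
      arrange(.data$chrom, map_dbl(.data$exons, ~ .x$start[1]), .data$strand) |>
      mutate(isoform_id = sprintf("ISO%04d", row_number()), .before = 1)
  }
  class(out) <- c("isodyn_catalog", class(out))
  out
}

#' Snap catalog boundaries to nearby annotated splice sites
#'
#' Collapse representatives are medians of jittered read boundaries and can
#' sit a nucleotide or two off the true splice site. As in reference-guided
#' long-read pipelines, each internal boundary is corrected to the nearest
#' annotated donor/acceptor on the same chromosome and strand when within
#' `site_tol` nt; boundaries further away (genuinely novel sites) are kept.
#'
#' @param catalog an `isodyn_catalog`.
#' @param annotation reference exon table.
#' @param site_tol snap tolerance (nt); use the collapse `internal_tol`.
#' @return the catalog with corrected `exons`.
#' @export
correct_to_reference <- function(catalog, annotation, site_tol = 5L) {
  idx <- reference_index(annotation)
  catalog$exons <- pmap(list(catalog$exons, catalog$chrom, catalog$strand),
    function(ex, ch, st) {
      k <- nrow(ex)
      if (k < 2) return(ex)
      key <- paste(ch, st)
      donors <- idx$sites[[key]]$donor_pos
      acceptors <- idx$sites[[key]]$acceptor_pos
      # genomic-left intron edge comes from an exon end; genomic-right from a start
      left_sites <- if (st == "+") donors - 1L else acceptors - 1L
      right_sites <- if (st == "+") acceptors + 1L else donors + 1L
      snap <- function(x, sites) {
        if (length(sites) == 0) return(x)
        d <- abs(sites - x)
        if (min(d) <= site_tol) sites[which.min(d)] else x
      }
      ex$end[-k] <- vapply(ex$end[-k], snap, numeric(1), sites = left_sites)
      ex$start[-1] <- vapply(ex$start[-1], snap, numeric(1), sites = right_sites)
      ex
    })
  catalog
}
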