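#' Apply class-specific curation rules to a classified catalog
#'
#' FSM and ISM isoforms are retained when they are (1) not potential
#' mispriming products, (2) free of template-switch junctions, (3) TSS- and
#' (4) TTS-supported, and (5) carry a polyA motif near the 3' end. NIC, NNC
#' and fusion isoforms are retained when they are not mispriming products and
#' every splice junction is either canonical or supported by at least
#' `min_junction_reads` short reads (the operative reading of the
#' template-switch criterion for novel classes).
#'
#' @param catalog catalog with classification and flags (see
#'   [classify_isoforms()], [flag_artifacts()]).
#' @param junction_support tibble (`chrom`, `strand`, `intron_start`,
#'   `intron_end`, `reads`) of short-read junction coverage; `NULL` means no
#'   support anywhere.
#' @param min_junction_reads support threshold for non-canonical junctions.
#' @return the catalog with a logical `retained` column.
#' @export
curate <- function(catalog, junction_support = NULL, min_junction_reads = 10L) {
  need <- c("class", "mispriming", "template_switch", "tss_supported",
            "tts_supported", "polya_motif_found", "junctions")
  if (!all(need %in% names(catalog))) {
    abort("catalog lacks computed classification/flags; run classify_isoforms() and flag_artifacts() first")
  }
  sup_key <- if (!is.null(junction_support) && nrow(junction_support) > 0) {
    setNames(junction_support$reads,
             paste(junction_support$chrom, junction_support$strand,
                   junction_support$intron_start, junction_support$intron_end))
  } else c()

  catalog$retained <- pmap_lgl_safe(catalog, function(row) {
    if (row$class %in% c("FSM", "ISM")) {
      !row$mispriming && !row$template_switch && row$tss_supported &&
        row$tts_supported && row$polya_motif_found
    } else {
      jc <- row$junctions
      ok_junc <- if (nrow(jc) == 0) TRUE else {
        keys <- paste(row$chrom, row$strand, jc$intron_start, jc$intron_end)
        sup <- if (length(sup_key)) unname(sup_key[keys])
               else rep(NA_real_, length(keys))
        sup[is.na(sup)] <- 0
        all(jc$canonical | sup >= min_junction_reads)
      }
      !row$mispriming && ok_junc
    }
  })
  catalog
}

# rowwise pmap over a tibble with list-columns, returning logical
pmap_lgl_safe <- function(df, f) {
  vapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df, function(col) if (is.list(col)) col[[i]] else col[i])
    f(row)
  }, logical(1))
}

#' Assign reads to catalog isoforms and quantify
#'
#' Each read goes to the single best-matching retained isoform on its
#' chromosome and strand: most shared junctions (within `internal_tol` per
#' boundary), ties broken by the longest compatible isoform, remaining ties by
#' the lexicographically smallest id. Mono-exon reads are scored by exonic
#' overlap. `TPM_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6`
#' with effective length = summed exon length.
#'
#' @param reads exon table keyed by `read_id` (an optional `sample` column
#'   yields per-sample counts).
#' @param catalog curated catalog (rows with `retained == FALSE` are ignored
#'   when the column exists).
#' @param internal_tol junction matching tolerance (nt).
#' @return tibble: isoform_id (+ sample), count, tpm.
#' @export
quantify_isoforms <- function(reads, catalog, internal_tol = 5L) {
  if ("retained" %in% names(catalog)) catalog <- filter(catalog, .data$retained)
  if (nrow(catalog) == 0) abort("no retained isoforms to quantify against")
  iso_j <- lapply(catalog$exons, function(ex) {
    introns_of(as.matrix(ex[, c("start", "end")]))
  })
  iso_len <- map_dbl(catalog$exons, ~ sum(.x$end - .x$start + 1))
  iso_span <- map(catalog$exons, ~ c(min(.x$start), max(.x$end)))

  has_sample <- "sample" %in% names(reads)
  rinfo <- reads |> arrange(.data$read_id, .data$start) |>
    group_by(.data$read_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              sample = if (has_sample) .data$sample[1] else "all",
              mat = list(cbind(start = .data$start, end = .data$end)),
              .groups = "drop")

  assign_one <- function(chrom, strand, mat) {
    cand <- which(catalog$chrom == chrom & catalog$strand == strand)
    if (length(cand) == 0) return(NA_character_)
    rj <- introns_of(mat)
    score <- vapply(cand, function(ci) {
      cj <- iso_j[[ci]]
      if (is.null(rj) || is.null(cj)) {
        # mono-exon on either side: fall back to overlap fraction below
        return(0)
      }
      sum(vapply(seq_len(nrow(rj)), function(r) {
        any(abs(cj[, "start"] - rj[r, "start"]) <= internal_tol &
              abs(cj[, "end"] - rj[r, "end"]) <= internal_tol)
      }, logical(1)))
    }, numeric(1))
    if (all(score == 0)) {
      ov <- vapply(cand, function(ci) {
        sp <- iso_span[[ci]]
        max(0, min(sp[2], max(mat[, "end"])) - max(sp[1], min(mat[, "start"])) + 1)
      }, numeric(1))
      if (max(ov) <= 0) return(NA_character_)
      score <- ov
    }
    best <- cand[score == max(score)]
    if (length(best) > 1) {
      lens <- iso_len[best]
      best <- best[lens == max(lens)]
      if (length(best) > 1) best <- best[order(catalog$isoform_id[best])][1]
    }
    catalog$isoform_id[best[1]]
  }

  rinfo$isoform_id <- pmap(list(rinfo$chrom, rinfo$strand, rinfo$mat),
                           assign_one) |> unlist()
  counts <- rinfo |>
    filter(!is.na(.data$isoform_id)) |>
    count(.data$sample, .data$isoform_id, name = "count") |>
    tidyr::complete(sample = unique(rinfo$sample),
                    isoform_id = catalog$isoform_id,
                    fill = list(count = 0L))
  counts |>
    mutate(length = iso_len[match(.data$isoform_id, catalog$isoform_id)]) |>
    group_by(.data$sample) |>
    mutate(rate = .data$count / .data$length,
           tpm = if (sum(.data$rate) > 0) .data$rate / sum(.data$rate) * 1e6 else 0) |>
    ungroup() |>
    select("sample", "isoform_id", "count", "tpm") |>
    (\(x) if (has_sample) x else select(x, -"sample"))()
}
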