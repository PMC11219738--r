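# reference index for classification: per (chrom, strand) donor/acceptor
# position sets, per-transcript junction chains, junction -> gene map and
# non-overlapping gene loci
reference_index <- function(annotation) {
  chains <- chain_list(annotation)
  meta <- annotation |> distinct(.data$transcript_id, .data$gene_id,
                                 .data$chrom, .data$strand)
  tx_chain <- lapply(chains, junction_keys)
  # chain string with sentinels for contiguous-subchain search
  chain_str <- vapply(tx_chain, function(x) paste0(",", paste(x, collapse = ","), ","),
                      character(1))

  gene_span <- annotation |> group_by(.data$chrom, .data$gene_id) |>
    summarise(strand = .data$strand[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  # loci: overlapping gene spans on a chromosome merged into one locus
  gene_span <- gene_span |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(locus = cumsum(.data$start >
                            lag(cummax(as.numeric(.data$end)), default = -Inf))) |>
    ungroup() |>
    mutate(locus = paste0(.data$chrom, "_L", .data$locus))
  locus_of_gene <- setNames(gene_span$locus, gene_span$gene_id)

  sites <- list(); junc_locus <- list()
  for (key in unique(paste(meta$chrom, meta$strand))) {
    tids <- meta$transcript_id[paste(meta$chrom, meta$strand) == key]
    donor <- integer(0); acceptor <- integer(0)
    jl <- list()
    for (tid in tids) {
      mat <- chains[[tid]]
      intr <- introns_of(mat)
      if (is.null(intr)) next
      st <- meta$strand[meta$transcript_id == tid][1]
      if (st == "+") {
        donor <- c(donor, intr[, "start"]); acceptor <- c(acceptor, intr[, "end"])
      } else {
        donor <- c(donor, intr[, "end"]); acceptor <- c(acceptor, intr[, "start"])
      }
      g <- meta$gene_id[meta$transcript_id == tid][1]
      for (jk in junction_keys(mat)) {
        jl[[jk]] <- union(jl[[jk]], locus_of_gene[[g]])
      }
    }
    sites[[key]] <- list(donor_pos = sort(unique(donor)),
                         acceptor_pos = sort(unique(acceptor)))
    junc_locus[[key]] <- jl
  }

  mono <- meta |>
    filter(!vapply(meta$transcript_id, function(t) nrow(chains[[t]]) > 1, logical(1)))
  mono_ref <- lapply(split(mono$transcript_id, paste(mono$chrom, mono$strand)),
                     function(tids) {
                       do.call(rbind, lapply(tids, function(t) {
                         c(start = chains[[t]][1, "start"], end = chains[[t]][1, "end"])
                       })) -> m
                       tibble(transcript_id = tids, start = m[, 1], end = m[, 2])
                     })

  list(chains = chains, meta = meta, tx_chain = tx_chain, chain_str = chain_str,
       sites = sites, junc_locus = junc_locus, locus_of_gene = locus_of_gene,
       mono_ref = mono_ref)
}

near_any <- function(x, sites, tol) {
  length(sites) > 0 && min(abs(sites - x)) <= tol
}

classify_one <- function(mat, chrom, strand, idx, site_tol = 0L, end_tol = 50L) {
  if (nrow(mat) == 0) abort("transcript model with zero exons")
  key <- paste(chrom, strand)
  same <- idx$meta$transcript_id[idx$meta$chrom == chrom & idx$meta$strand == strand]

  if (nrow(mat) == 1) {
    # mono-exon: FSM when contained in a mono-exon reference within end_tol
    mr <- idx$mono_ref[[key]]
    if (!is.null(mr) && nrow(mr) > 0) {
      hit <- mr |> filter(mat[1, "start"] >= .data$start - end_tol,
                          mat[1, "end"] <= .data$end + end_tol)
      if (nrow(hit) > 0) {
        return(list(class = "FSM", matched = hit$transcript_id))
      }
    }
    return(list(class = "NNC", matched = character(0)))
  }

  jk <- junction_keys(mat)
  q <- paste0(",", paste(jk, collapse = ","), ",")
  ref_str <- idx$chain_str[same]

  fsm <- names(ref_str)[ref_str == q]
  if (length(fsm) > 0) return(list(class = "FSM", matched = fsm))

  ism <- names(ref_str)[str_detect(ref_str, fixed(q))]
  if (length(ism) > 0) return(list(class = "ISM", matched = ism))

  # fusion: annotated junctions from >= 2 distinct loci
  jl <- idx$junc_locus[[key]]
  loci <- unique(unlist(jl[intersect(jk, names(jl))]))
  if (length(loci) >= 2) return(list(class = "fusion", matched = loci))

  intr <- introns_of(mat)
  if (strand == "+") {
    donors <- intr[, "start"]; acceptors <- intr[, "end"]
  } else {
    donors <- intr[, "end"]; acceptors <- intr[, "start"]
  }
  s <- idx$sites[[key]]
  known <- all(vapply(donors, near_any, logical(1), sites = s$donor_pos, tol = site_tol)) &&
    all(vapply(acceptors, near_any, logical(1), sites = s$acceptor_pos, tol = site_tol))
  if (known) list(class = "NIC", matched = character(0))
  else list(class = "NNC", matched = character(0))
}

#' Classify a transcript model against a reference annotation
#'
#' Assigns exactly one of the five classes:
#' * **FSM** — the junction chain equals a reference transcript's chain;
#' * **ISM** — a contiguous proper sub-chain of a reference chain;
#' * **fusion** — annotated junctions from two or more distinct,
#'   non-overlapping gene loci;
#' * **NIC** — every donor and acceptor is annotated but the combination is
#'   new;
#' * **NNC** — at least one donor or acceptor is unannotated.
#'
#' Mono-exon models are FSM when contained in a mono-exon reference within
#' `end_tol`, otherwise NNC.
#'
#' @param model exon table rows of one transcript.
#' @param reference reference exon table.
#' @param site_tol junction-matching tolerance in nt (0 = exact); pipelines
#'   whose representatives are medians of jittered boundaries should pass the
#'   collapse `internal_tol` or run [correct_to_reference()] first.
#' @param end_tol mono-exon containment tolerance (nt).
#' @return one-row tibble: `class`, `matched` (list of reference transcript
#'   ids, or locus ids for fusions).
#' @export
classify_isoform <- function(model, reference, site_tol = 0L, end_tol = 50L) {
  if (!"transcript_id" %in% names(model)) model$transcript_id <- "query"
  validate_exons(model)
  idx <- reference_index(reference)
  mat <- as.matrix(arrange(model, .data$start)[, c("start", "end")])
  res <- classify_with_tol(mat, model$chrom[1], model$strand[1], idx,
                           site_tol, end_tol)
  tibble(class = res$class, matched = list(res$matched))
}

# tolerance-aware wrapper: with site_tol > 0, FSM/ISM string matching runs on
# boundaries snapped to the nearest annotated site
classify_with_tol <- function(mat, chrom, strand, idx, site_tol, end_tol) {
  if (site_tol > 0 && nrow(mat) > 1) {
    key <- paste(chrom, strand)
    s <- idx$sites[[key]]
    if (strand == "+") { left <- s$donor_pos - 1L; right <- s$acceptor_pos + 1L }
    else { left <- s$acceptor_pos - 1L; right <- s$donor_pos + 1L }
    snap <- function(x, sites) {
      if (length(sites) == 0) return(x)
      d <- abs(sites - x)
      if (min(d) <= site_tol) sites[which.min(d)] else x
    }
    k <- nrow(mat)
    mat[-k, "end"] <- vapply(mat[-k, "end"], snap, numeric(1), sites = left)
    mat[-1, "start"] <- vapply(mat[-1, "start"], snap, numeric(1), sites = right)
  }
  classify_one(mat, chrom, strand, idx, site_tol = 0L, end_tol = end_tol)
}

#' Classify every isoform of a catalog
#'
#' @param catalog an `isodyn_catalog` (see [collapse_reads()]).
#' @param reference reference exon table.
#' @inheritParams classify_isoform
#' @return the catalog with `class` and `matched` columns added.
#' @export
classify_isoforms <- function(catalog, reference, site_tol = 0L, end_tol = 50L) {
  idx <- reference_index(reference)
  res <- pmap(list(catalog$exons, catalog$chrom, catalog$strand),
              function(ex, ch, st) {
                classify_with_tol(as.matrix(ex), ch, st, idx, site_tol, end_tol)
              })
  catalog$class <- map_chr(res, "class")
  catalog$matched <- map(res, "matched")
  catalog
}
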