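#' Hypothetical pre-mRNA of a gene
#'
#' The union of all exon intervals across the gene's isoforms, merged where
#' overlapping. This is the scaffold against which per-isoform alternative
#' transcription and splicing events are annotated.
#'
#' @param gene_exons exon table rows of one gene (any number of isoforms).
#' @return tibble: chrom, strand, start, end, ordered by genomic start.
#' @export
build_premrna <- function(gene_exons) {
  m <- merge_intervals(gene_exons$start, gene_exons$end)
  tibble(chrom = gene_exons$chrom[1], strand = gene_exons$strand[1],
         start = m[, "start"], end = m[, "end"])
}

overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# does isoform (matrix) contain an exon overlapping [s, e]?
contains_exon <- function(mat, s, e) any(overlaps(mat[, "start"], mat[, "end"], s, e))

annotate_events_one <- function(tid, mats, strand, tol = 50L) {
  me <- mats[[tid]]
  others <- mats[names(mats) != tid]
  ev <- list()
  add <- function(type, s, e, partner = NA_character_) {
    ev[[length(ev) + 1]] <<- tibble(event_type = type, start = unname(s),
                                    end = unname(e), partner = partner)
  }
  k <- nrow(me)
  union_mat <- merge_intervals(
    unlist(lapply(mats, function(m) m[, "start"])),
    unlist(lapply(mats, function(m) m[, "end"])))

  # ---- MEE: pairwise witness with shared flanking exons ----------------------
  mee_exons <- list()
  internal_rows <- function(m) if (nrow(m) >= 3) seq(2, nrow(m) - 1) else integer(0)
  for (pid in names(others)) {
    pm <- others[[pid]]
    for (i in internal_rows(me)) {
      if (contains_exon(pm, me[i, "start"], me[i, "end"])) next
      for (j in internal_rows(pm)) {
        if (contains_exon(me, pm[j, "start"], pm[j, "end"])) next
        if (overlaps(me[i, "start"], me[i, "end"], pm[j, "start"], pm[j, "end"])) next
        flank_ok <-
          overlaps(me[i - 1, "start"], me[i - 1, "end"],
                   pm[j - 1, "start"], pm[j - 1, "end"]) &&
          overlaps(me[i + 1, "start"], me[i + 1, "end"],
                   pm[j + 1, "start"], pm[j + 1, "end"])
        if (!flank_ok) next
        both <- any(vapply(mats, function(m)
          contains_exon(m, me[i, "start"], me[i, "end"]) &&
            contains_exon(m, pm[j, "start"], pm[j, "end"]), logical(1)))
        if (both) next
        add("MEE", me[i, "start"], me[i, "end"], partner = pid)
        mee_exons[[length(mee_exons) + 1]] <- c(me[i, "start"], me[i, "end"])
        mee_exons[[length(mee_exons) + 1]] <- c(pm[j, "start"], pm[j, "end"])
      }
    }
  }

  # ---- SES / MES: runs of absent pre-mRNA internal exons --------------------
  span <- c(min(me[, "start"]), max(me[, "end"]))
  n_u <- nrow(union_mat)
  missing_internal <- vapply(seq_len(n_u), function(u) {
    us <- union_mat[u, "start"]; ue <- union_mat[u, "end"]
    if (us <= span[1] || ue >= span[2]) return(FALSE)     # must lie between retained exons
    if (contains_exon(me, us, ue)) return(FALSE)
    if (length(mee_exons) > 0 &&
        any(vapply(mee_exons, function(x) overlaps(x[1], x[2], us, ue),
                   logical(1)))) return(FALSE)            # handled as MEE
    TRUE
  }, logical(1))
  if (any(missing_internal)) {
    r <- rle(missing_internal)
    pos <- cumsum(c(1, head(r$lengths, -1)))
    for (ri in which(r$values)) {
      u_first <- pos[ri]; u_last <- pos[ri] + r$lengths[ri] - 1L
      add(if (r$lengths[ri] == 1) "SES" else "MES",
          union_mat[u_first, "start"], union_mat[u_last, "end"])
    }
  }

  # ---- IR: an exon fully spanning another isoform's intron ------------------
  for (pid in names(others)) {
    intr <- introns_of(others[[pid]])
    if (is.null(intr)) next
    for (r in seq_len(nrow(intr))) {
      hit <- me[, "start"] < intr[r, "start"] & me[, "end"] > intr[r, "end"]
      if (any(hit)) {
        i <- which(hit)[1]
        add("IR", intr[r, "start"], intr[r, "end"], partner = pid)
      }
    }
  }

  # ---- A5 / A3: alternative donor/acceptor with matching opposite site ------
  my_intr <- introns_of(me)
  if (!is.null(my_intr)) {
    for (pid in names(others)) {
      ointr <- introns_of(others[[pid]])
      if (is.null(ointr)) next
      pm <- others[[pid]]
      for (r in seq_len(nrow(my_intr))) {
        ms <- my_intr[r, "start"]; mend <- my_intr[r, "end"]
        # genomic-left side differs, right side matches
        shared_right <- ointr[, "end"] == mend & ointr[, "start"] != ms
        for (q in which(shared_right)) {
          # boundary exons (left flank) must overlap: alternative boundary of
          # the *same* exon, not a different (skipped) exon
          my_ex <- me[me[, "end"] == ms - 1L, , drop = FALSE]
          o_ex <- pm[pm[, "end"] == ointr[q, "start"] - 1L, , drop = FALSE]
          if (nrow(my_ex) && nrow(o_ex) &&
              overlaps(my_ex[1, "start"], my_ex[1, "end"],
                       o_ex[1, "start"], o_ex[1, "end"])) {
            add(if (strand == "+") "A5" else "A3",
                min(ms, ointr[q, "start"]), max(ms, ointr[q, "start"]) - 1L,
                partner = pid)
          }
        }
        shared_left <- ointr[, "start"] == ms & ointr[, "end"] != mend
        for (q in which(shared_left)) {
          my_ex <- me[me[, "start"] == mend + 1L, , drop = FALSE]
          o_ex <- pm[pm[, "start"] == ointr[q, "end"] + 1L, , drop = FALSE]
          if (nrow(my_ex) && nrow(o_ex) &&
              overlaps(my_ex[1, "start"], my_ex[1, "end"],
                       o_ex[1, "start"], o_ex[1, "end"])) {
            add(if (strand == "+") "A3" else "A5",
                min(mend, ointr[q, "end"]) + 1L, max(mend, ointr[q, "end"]),
                partner = pid)
          }
        }
      }
    }
  }

  # ---- ATSS / ATTS: outer boundary far from every other isoform's ----------
  outer5 <- if (strand == "+") me[1, "start"] else me[k, "end"]
  outer3 <- if (strand == "+") me[k, "end"] else me[1, "start"]
  o5 <- vapply(others, function(m)
    if (strand == "+") m[1, "start"] else m[nrow(m), "end"], numeric(1))
  o3 <- vapply(others, function(m)
    if (strand == "+") m[nrow(m), "end"] else m[1, "start"], numeric(1))
  if (length(o5) > 0 && all(abs(o5 - outer5) > tol)) add("ATSS", outer5, outer5)
  if (length(o3) > 0 && all(abs(o3 - outer3) > tol)) add("ATTS", outer3, outer3)

  if (length(ev) == 0) return(NULL)
  list_rbind(ev) |>
    distinct(.data$event_type, .data$start, .data$end, .keep_all = TRUE) |>
    mutate(transcript_id = tid, .before = 1)
}

#' Annotate alternative transcription and splicing events
#'
#' Compares every isoform to its gene's other isoforms and hypothetical
#' pre-mRNA and labels the eight event types: alternative transcription start
#' and termination sites (ATSS, ATTS), alternative 5' and 3' splice sites
#' (A5, A3; named in transcript orientation, so A5 is an alternative donor),
#' single and multiple exon skipping (SES, MES), mutually exclusive exons
#' (MEE) and intron retention (IR). An isoform may carry several labels;
#' single-isoform genes yield no events.
#'
#' @param annotation exon table (multiple genes allowed).
#' @param tolerance ATSS/ATTS outer-boundary tolerance (nt).
#' @return tibble: gene_id, transcript_id, event_type, chrom, strand, start,
#'   end, partner.
#' @export
annotate_events <- function(annotation, tolerance = 50L) {
  validate_exons(annotation)
  annotation |>
    group_by(.data$gene_id) |>
    group_map(function(g, key) {
      g$gene_id <- key$gene_id
      tids <- unique(g$transcript_id)
      if (length(tids) < 2) return(NULL)
      mats <- chain_list(g)
      strand <- g$strand[1]
      res <- map(tids, annotate_events_one, mats = mats, strand = strand,
                 tol = tolerance) |> list_rbind()
      if (is.null(res) || nrow(res) == 0) return(NULL)
      res |> mutate(gene_id = key$gene_id, chrom = g$chrom[1],
                    strand = strand, .before = 1)
    }) |>
    list_rbind() %||% tibble()
}

#' Event gains and losses between switching isoform pairs
#'
#' For every gene with at least one significant differential-usage isoform in
#' a comparison, pairs the most-upregulated (max dIF) with the
#' most-downregulated (min dIF) isoform and reports, per event type, how often
#' the type is present in the up-isoform but not the down-isoform (gain) or
#' vice versa (loss). Fractions are relative to all gains or all losses in
#' that comparison.
#'
#' @param dtu a [dtu_test()] result (needs gene_id, isoform_id, dIF,
#'   significant, comparison).
#' @param events an [annotate_events()] table.
#' @return tibble: comparison, event_type, direction (gain/loss), n, fraction.
#' @export
gain_loss_summary <- function(dtu, events) {
  # events are compared as instances (type at coordinates): two isoforms can
  # both carry, say, an ATSS label at different positions, and the switch then
  # both gains and loses an alternative start
  if (!all(c("start", "end") %in% names(events))) {
    events$start <- 0L; events$end <- 0L
  }
  ev_sets <- events |>
    mutate(key = paste(.data$event_type, .data$start, .data$end)) |>
    group_by(.data$transcript_id) |>
    summarise(keys = list(unique(.data$key)), .groups = "drop")
  set_of <- setNames(ev_sets$keys, ev_sets$transcript_id)
  keys_of <- function(id) set_of[[id]] %||% character(0)
  type_of_key <- function(keys) vapply(strsplit(keys, " "), `[`, character(1), 1)

  pairs <- dtu |>
    group_by(.data$comparison, .data$gene_id) |>
    filter(any(.data$significant)) |>
    summarise(up = .data$isoform_id[which.max(.data$dIF)][1],
              down = .data$isoform_id[which.min(.data$dIF)][1],
              .groups = "drop")
  if (nrow(pairs) == 0) {
    return(tibble(comparison = character(), event_type = character(),
                  direction = character(), n = integer(), fraction = numeric()))
  }
  long <- pairs |>
    mutate(gain = map2(.data$up, .data$down,
                       ~ unique(type_of_key(setdiff(keys_of(.x), keys_of(.y))))),
           loss = map2(.data$up, .data$down,
                       ~ unique(type_of_key(setdiff(keys_of(.y), keys_of(.x)))))) |>
    select("comparison", "gain", "loss") |>
    pivot_longer(c("gain", "loss"), names_to = "direction",
                 values_to = "event_type") |>
    unnest("event_type")
  long |>
    count(.data$comparison, .data$direction, .data$event_type) |>
    group_by(.data$comparison, .data$direction) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("comparison", "event_type", "direction", "n", "fraction")
}
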