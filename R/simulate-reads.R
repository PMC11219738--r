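#' Simulate long reads with planted artifact classes
#'
#' Draws reads from the annotated isoforms in proportion to `abundances` and
#' plants reverse-transcription/library artifacts at the requested rates. Each
#' read carries exactly one ground-truth label:
#'
#' * `clean` — the source exon chain with gaussian jitter (sd `jitter_sd`) on
#'   internal boundaries and sd `end_sd` on the two transcript ends;
#' * `truncation` — 5' exons dropped (a partial, ISM-like chain);
#' * `mispriming` — the read 3' end relocated immediately upstream of the
#'   gene's planted A-rich intronic tract, emulating oligo-dT annealing to
#'   genomic adenines;
#' * `template_switch` — one acceptor shifted into the intron so the junction
#'   becomes non-canonical; the aberrant junction is fixed per isoform so that
#'   template-switch products form reproducible clusters;
#' * `fusion` — the chain concatenated with the exon chain of the nearest
#'   same-strand neighbouring gene.
#'
#' @param annotation reference exon table.
#' @param genome named character vector of chromosome sequences.
#' @param abundances tibble with `transcript_id` and `abundance` (>= 0).
#' @param artifact_rates named vector (`mispriming`, `template_switch`,
#'   `truncation`, `fusion`); missing names default to 0, sum must be <= 1.
#' @param seed integer seed.
#' @param n_reads number of reads to draw.
#' @param jitter_sd,end_sd boundary noise (nt).
#' @param traps A-rich trap table (`truth$a_rich` from [generate_reference()]);
#'   required when the mispriming rate is positive.
#' @return list with `reads` (exon table keyed by `read_id`) and `truth`
#'   (tibble: read_id, transcript_id, gene_id, label).
#' @export
simulate_long_reads <- function(annotation, genome, abundances, artifact_rates,
                                seed = 1L, n_reads = 2000L,
                                jitter_sd = 1, end_sd = 10, traps = NULL) {
  rates <- c(mispriming = 0, template_switch = 0, truncation = 0, fusion = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (sum(rates) > 1) abort("artifact rates must sum to <= 1")
  if (rates[["mispriming"]] > 0 && (is.null(traps) || nrow(traps) == 0)) {
    abort("mispriming rate > 0 requires a trap table (truth$a_rich)")
  }
  with_seed(seed, {
    chains <- chain_list(annotation)
    meta <- annotation |> distinct(.data$transcript_id, .data$gene_id,
                                   .data$chrom, .data$strand)
    gene_of <- setNames(meta$gene_id, meta$transcript_id)
    strand_of <- setNames(meta$strand, meta$transcript_id)
    chrom_of <- setNames(meta$chrom, meta$transcript_id)
    gene_span <- annotation |> group_by(.data$gene_id) |>
      summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                start = min(.data$start), end = max(.data$end), .groups = "drop")

    ab <- abundances |> filter(.data$abundance > 0)
    stopifnot(nrow(ab) > 0, all(ab$transcript_id %in% names(chains)))

    # per-isoform fixed template-switch variant: junction index + acceptor
    # shift chosen so the new intron end dinucleotide is not AG and the new
    # site is well away (> 5 nt) from any annotated acceptor
    ts_variants <- lapply(setNames(ab$transcript_id, ab$transcript_id), function(tid) {
      mat <- chains[[tid]]
      intr <- introns_of(mat)
      if (is.null(intr)) return(NULL)
      jidx <- sample(nrow(intr), 1)
      for (delta in sample(8:20, 13)) {
        # transcript-strand acceptor dinucleotide after the shift must not be AG
        acc <- if (strand_of[[tid]] == "+") {
          new_end <- intr[jidx, "end"] - delta
          genome_slice(genome, chrom_of[[tid]], new_end - 1L, new_end)
        } else {
          revcomp(genome_slice(genome, chrom_of[[tid]],
                               intr[jidx, "start"] + delta,
                               intr[jidx, "start"] + delta + 1L))
        }
        if (acc != "AG") return(list(jidx = jidx, delta = delta))
      }
      list(jidx = jidx, delta = 8L)
    })

    # fusion partner: nearest same-strand gene
    genes <- gene_span$gene_id
    partner_of <- vapply(seq_len(nrow(gene_span)), function(i) {
      same <- which(gene_span$strand == gene_span$strand[i] &
                    gene_span$chrom == gene_span$chrom[i])
      same <- setdiff(same, i)
      if (length(same) == 0) return(NA_character_)
      genes[same[which.min(abs(gene_span$start[same] - gene_span$start[i]))]]
    }, character(1))
    names(partner_of) <- genes
    trap_of <- if (!is.null(traps)) split(traps, traps$gene_id) else list()

    labels <- sample(c("clean", names(rates)), n_reads, replace = TRUE,
                     prob = c(1 - sum(rates), rates))
    src <- sample(ab$transcript_id, n_reads, replace = TRUE,
                  prob = ab$abundance / sum(ab$abundance))

    out <- vector("list", n_reads)
    truth <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      tid <- src[r]
      lab <- labels[r]
      strand <- strand_of[[tid]]
      mat <- chains[[tid]]
      k <- nrow(mat)
      jitter_ends <- TRUE

      if (lab == "truncation" && k >= 3) {
        drop <- sample(seq_len(k - 2), 1)
        mat <- if (strand == "+") mat[-seq_len(drop), , drop = FALSE]
               else mat[seq_len(k - drop), , drop = FALSE]
      } else if (lab == "mispriming") {
        gid <- gene_of[[tid]]
        if (!gid %in% names(trap_of)) {
          # reassign to an isoform of a trap gene
          cand <- ab$transcript_id[gene_of[ab$transcript_id] %in% names(trap_of)]
          tid <- sample(cand, 1)
          gid <- gene_of[[tid]]; strand <- strand_of[[tid]]
          mat <- chains[[tid]]; k <- nrow(mat)
        }
        tr <- trap_of[[gid]][1, ]
        if (strand == "+") {
          keep <- mat[, "start"] < tr$read_end
          mat <- mat[keep, , drop = FALSE]
          mat[nrow(mat), "end"] <- tr$read_end
        } else {
          keep <- mat[, "end"] > tr$read_end
          mat <- mat[keep, , drop = FALSE]
          mat[1, "start"] <- tr$read_end
        }
        jitter_ends <- FALSE
      } else if (lab == "template_switch" && !is.null(ts_variants[[src[r]]])) {
        v <- ts_variants[[tid]]
        if (strand == "+") {
          mat[v$jidx + 1, "start"] <- mat[v$jidx + 1, "start"] - v$delta
        } else {
          # on the minus strand the acceptor is the genomic-left intron side:
          # extend the genomic-left flanking exon rightwards into the intron
          mat[v$jidx, "end"] <- mat[v$jidx, "end"] + v$delta
        }
      } else if (lab == "fusion" && !is.na(partner_of[gene_of[[tid]]])) {
        pgene <- partner_of[gene_of[[tid]]]
        ptid <- paste0(pgene, ".1")
        if (!ptid %in% names(chains)) ptid <- names(chains)[gene_of[names(chains)] == pgene][1]
        mat <- rbind(mat, chains[[ptid]])
        mat <- mat[order(mat[, "start"]), , drop = FALSE]
        truth[[r]] <- tibble(read_id = sprintf("read%05d", r), transcript_id = tid,
                             gene_id = gene_of[[src[r]]], label = "fusion")
      } else if (lab != "clean") {
        lab <- "clean"   # inapplicable artifact (e.g. mono-exon) falls back
      }

      # noise: always jitter internal boundaries; artifact-defined 3' ends are
      # kept exact so the planted signal survives collapsing
      kk <- nrow(mat)
      if (jitter_sd > 0 && kk > 1) {
        mat[-kk, "end"] <- mat[-kk, "end"] + round(rnorm(kk - 1, 0, jitter_sd))
        mat[-1, "start"] <- mat[-1, "start"] + round(rnorm(kk - 1, 0, jitter_sd))
      }
      if (end_sd > 0 && jitter_ends) {
        if (strand == "+") {
          mat[1, "start"] <- mat[1, "start"] + round(rnorm(1, 0, end_sd))
          mat[kk, "end"] <- mat[kk, "end"] + round(rnorm(1, 0, end_sd))
        } else {
          mat[kk, "end"] <- mat[kk, "end"] + round(rnorm(1, 0, end_sd))
          mat[1, "start"] <- mat[1, "start"] + round(rnorm(1, 0, end_sd))
        }
      } else if (end_sd > 0 && lab == "mispriming") {
        # 5' end still jitters
        if (strand == "+") mat[1, "start"] <- mat[1, "start"] + round(rnorm(1, 0, end_sd))
        else mat[kk, "end"] <- mat[kk, "end"] + round(rnorm(1, 0, end_sd))
      }

      rid <- sprintf("read%05d", r)
      out[[r]] <- tibble(read_id = rid, chrom = chrom_of[[tid]], strand = strand,
                         start = mat[, "start"], end = mat[, "end"])
      if (is.null(truth[[r]])) {
        truth[[r]] <- tibble(read_id = rid, transcript_id = tid,
                             gene_id = gene_of[[tid]], label = lab)
      }
    }
    list(reads = list_rbind(out), truth = list_rbind(truth))
  })
}
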