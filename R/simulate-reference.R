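# ---- isoform derivation in transcript-local (plus-orientation) coordinates ----
#
# A gene is built from a skeleton of k non-overlapping exons; alternative
# isoforms are derived by applying exactly one event to the skeleton. All
# builders work on a k x 2 start/end matrix and return list(mat, type, target)
# where target holds the skeleton indices of the affected exon(s).

skeleton_exons <- function(k, exon_length, intron_length, pad = 400L) {
  lens <- sample(seq(exon_length[1], exon_length[2]), k, replace = TRUE)
  gaps <- sample(seq(intron_length[1], intron_length[2]), k - 1, replace = TRUE)
  starts <- pad + 1L + c(0L, cumsum(lens[-k] + gaps))
  cbind(start = starts, end = starts + lens - 1L)
}

derive_isoform <- function(skel, type, shift = 30L, end_shift = 300L) {
  k <- nrow(skel)
  switch(type,
    SES = {
      i <- sample(2:(k - 1), 1)
      list(mat = skel[-i, , drop = FALSE], type = "SES", target = i)
    },
    MES = {
      i <- sample(2:(k - 2), 1)
      list(mat = skel[-c(i, i + 1), , drop = FALSE], type = "MES", target = c(i, i + 1))
    },
    IR = {
      i <- sample(seq_len(k - 1), 1)
      mat <- skel
      mat[i, "end"] <- mat[i + 1, "end"]
      list(mat = mat[-(i + 1), , drop = FALSE], type = "IR", target = i)
    },
    A5 = {
      i <- sample(seq_len(k - 1), 1)
      mat <- skel
      mat[i, "end"] <- mat[i, "end"] - shift
      list(mat = mat, type = "A5", target = i)
    },
    A3 = {
      i <- sample(2:k, 1)
      mat <- skel
      mat[i, "start"] <- mat[i, "start"] + shift
      list(mat = mat, type = "A3", target = i)
    },
    ATSS = {
      mat <- skel
      mat[1, "start"] <- mat[1, "start"] - end_shift
      list(mat = mat, type = "ATSS", target = 1L)
    },
    ATTS = {
      mat <- skel
      mat[k, "end"] <- mat[k, "end"] + end_shift
      list(mat = mat, type = "ATTS", target = k)
    },
    abort(paste0("unknown event type: ", type))
  )
}

#' Construct a two-isoform gene exhibiting exactly one event type
#'
#' Builds a gene model (local coordinates on its own chromosome) whose two
#' isoforms differ by a single alternative transcription/splicing event of the
#' requested type. Used by the generator and handy for targeted tests.
#'
#' @param type one of `"ATSS"`, `"ATTS"`, `"A5"`, `"A3"`, `"SES"`, `"MES"`,
#'   `"MEE"`, `"IR"`.
#' @param n_exons skeleton size (>= 5).
#' @param strand `"+"` or `"-"`.
#' @param chrom chromosome name for the emitted rows.
#' @param gene_id gene identifier.
#' @return list with `exons` (annotation-style exon table of two isoforms) and
#'   `truth` (one-row tibble: gene, isoform carrying the event, type, skeleton
#'   indices of the affected exons).
#' @export
plant_event_gene <- function(type, n_exons = 6, strand = "+", chrom = "chrE",
                             gene_id = "G1") {
  stopifnot(n_exons >= 5)
  skel <- skeleton_exons(n_exons, c(120L, 200L), c(400L, 700L))
  if (type == "MEE") {
    i <- sample(2:(n_exons - 2), 1)
    iso <- list(
      list(mat = skel[-(i + 1), , drop = FALSE], type = "MEE", target = i),
      list(mat = skel[-i, , drop = FALSE], type = "MEE", target = i + 1L)
    )
  } else {
    iso <- list(list(mat = skel, type = "full", target = NA_integer_),
                derive_isoform(skel, type))
  }
  L <- max(skel[, "end"]) + 400L
  rows <- imap(iso, function(x, j) {
    mat <- x$mat
    if (strand == "-") {
      mat <- cbind(start = L - mat[, "end"] + 1L, end = L - mat[, "start"] + 1L)
      mat <- mat[order(mat[, "start"]), , drop = FALSE]
    }
    tibble(gene_id = gene_id,
           transcript_id = paste0(gene_id, ".", j),
           chrom = chrom, strand = strand,
           start = mat[, "start"], end = mat[, "end"])
  }) |> list_rbind()
  truth <- tibble(gene_id = gene_id,
                  transcript_id = paste0(gene_id, ".", if (type == "MEE") "1" else "2"),
                  event_type = type,
                  target = list(iso[[2]]$target))
  list(exons = validate_exons(rows), truth = truth)
}

# ---- full reference generation ----------------------------------------------

#' Generate a synthetic reference annotation and genome
#'
#' Builds `n_genes` multi-isoform gene models on one chromosome with planted
#' alternative transcription/splicing events, writes a random A/C/G/T genome
#' with canonical GT..AG splice sites at every annotated junction, plants a
#' polyA motif (AATAAA) a short distance upstream of every transcript end,
#' forces a non-A-rich tract immediately downstream of every transcript end,
#' and gives a configurable fraction of genes an A-rich (70% A) mispriming trap
#' inside an intron downstream of an internal exon. CAGE-peak and
#' polyA-site tracks are emitted at the true TSS/TTS +/- 10 nt.
#'
#' @param config an [simulation_config()] object.
#' @return list of class `isodyn_reference` with elements `annotation` (exon
#'   table), `genome` (named character vector), `cage`, `polya` (interval
#'   tibbles: chrom, start, end, strand), `truth` (list: `isoforms`,
#'   `a_rich`, `skipping_events`) and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "isodyn_config"))
  with_seed(config$seed, generate_reference_impl(config))
}

generate_reference_impl <- function(config) {
  spacer <- 1200L
  pad <- 400L
  event_pool <- c("SES", "MES", "IR", "A5", "A3", "ATSS", "ATTS")
  event_w <- c(3, 1, 1, 1, 1, 1, 1)  # cassette exons feed downstream stages

  offset <- 0L
  all_exons <- list(); iso_truth <- list(); a_rich <- list(); skip_ev <- list()
  writes <- list()   # genomic overwrites: tibble(start, end, content)
  cage <- list(); polya <- list()
  n_mee <- if (config$n_genes >= 8) max(1L, round(config$n_genes * 0.06)) else 0L
  mee_genes <- if (n_mee > 0) sample(config$n_genes, n_mee) else integer(0)
  trap_genes <- sample(config$n_genes,
                       round(config$a_rich_fraction * config$n_genes))

  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    strand <- sample(c("+", "-"), 1)
    k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
    skel <- skeleton_exons(k, config$exon_length, config$intron_length, pad)
    m <- sample(seq(config$isoforms_per_gene[1], config$isoforms_per_gene[2]), 1)

    if (g %in% mee_genes && m >= 2) {
      i <- sample(2:(k - 2), 1)
      isos <- list(
        list(mat = skel[-(i + 1), , drop = FALSE], type = "MEE", target = i),
        list(mat = skel[-i, , drop = FALSE], type = "MEE", target = i + 1L))
    } else {
      isos <- list(list(mat = skel, type = "full", target = NA_integer_))
      if (m >= 2) {
        types <- sample(event_pool, m - 1L, replace = FALSE,
                        prob = event_w / sum(event_w))
        for (tp in types) isos <- c(isos, list(derive_isoform(skel, tp)))
      }
    }

    L <- max(skel[, "end"]) + pad
    to_genomic <- function(mat) {
      if (strand == "-") {
        mat <- cbind(start = L - mat[, "end"] + 1L, end = L - mat[, "start"] + 1L)
        mat <- mat[order(mat[, "start"]), , drop = FALSE]
      }
      mat + offset
    }

    gmats <- lapply(isos, function(x) to_genomic(x$mat))
    for (j in seq_along(isos)) {
      tid <- paste0(gid, ".", j)
      mat <- gmats[[j]]
      all_exons[[tid]] <- tibble(gene_id = gid, transcript_id = tid,
                                 chrom = "chr1", strand = strand,
                                 start = mat[, "start"], end = mat[, "end"])
      iso_truth[[tid]] <- tibble(gene_id = gid, transcript_id = tid,
                                 event_type = isos[[j]]$type,
                                 target = list(isos[[j]]$target))
      # splice sites: transcript-strand GT..AG
      intr <- introns_of(mat)
      if (!is.null(intr)) {
        for (r in seq_len(nrow(intr))) {
          if (strand == "+") {
            writes[[length(writes) + 1]] <- tibble(start = intr[r, "start"], content = "GT")
            writes[[length(writes) + 1]] <- tibble(start = intr[r, "end"] - 1L, content = "AG")
          } else {
            writes[[length(writes) + 1]] <- tibble(start = intr[r, "start"], content = "CT")
            writes[[length(writes) + 1]] <- tibble(start = intr[r, "end"] - 1L, content = "AC")
          }
        }
      }
      ends <- tx_ends(mat, strand)
      cage[[tid]] <- tibble(chrom = "chr1", start = unname(ends[["five"]]) - 10L,
                            end = unname(ends[["five"]]) + 10L, strand = strand)
      polya[[tid]] <- tibble(chrom = "chr1", start = unname(ends[["three"]]) - 10L,
                             end = unname(ends[["three"]]) + 10L, strand = strand)
      # polyA motif ~20 nt upstream of the TTS, and a balanced (non A-rich)
      # 20-mer immediately downstream so clean 3' ends never look misprimed
      balanced <- "CGTCGTACGGCTTGCCGGAT"
      if (strand == "+") {
        writes[[length(writes) + 1]] <- tibble(start = ends["three"] - 25L, content = "AATAAA")
        writes[[length(writes) + 1]] <- tibble(start = ends["three"] + 1L, content = balanced)
      } else {
        writes[[length(writes) + 1]] <- tibble(start = ends["three"] + 20L, content = "TTTATT")
        writes[[length(writes) + 1]] <- tibble(start = ends["three"] - 20L, content = revcomp(balanced))
      }
    }

    # A-rich mispriming trap downstream (transcript orientation) of an
    # internal skeleton exon
    if (g %in% trap_genes && k >= 3) {
      t_idx <- sample(2:(k - 1), 1)
      delta <- sample(3:45, 1)
      tract_tx <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE,
                               prob = c(0, 1, 1, 1) / 3), collapse = "")
      apos <- sort(sample(20, 14))
      tract_tx <- strsplit(tract_tx, "")[[1]]; tract_tx[apos] <- "A"
      tract_tx <- paste(tract_tx, collapse = "")  # exactly 70% A
      ex <- skel[t_idx, ] # local coords, + orientation
      if (strand == "+") {
        e_gen <- ex["end"] + offset
        tract_start <- e_gen + delta
        writes[[length(writes) + 1]] <- tibble(start = tract_start, content = tract_tx)
        read_end <- e_gen + delta - 1L
      } else {
        s_gen <- (L - ex["end"] + 1L) + offset
        tract_start <- s_gen - delta - 19L
        writes[[length(writes) + 1]] <- tibble(start = tract_start, content = revcomp(tract_tx))
        read_end <- s_gen - delta + 1L
      }
      a_rich[[gid]] <- tibble(gene_id = gid, exon_index = t_idx,
                              strand = strand,
                              tract_start = unname(tract_start),
                              tract_end = unname(tract_start) + 19L,
                              read_end = unname(read_end))
    }

    # cassette-exon events for the junction-count / RBP stages
    for (j in seq_along(isos)) {
      if (isos[[j]]$type != "SES") next
      i <- isos[[j]]$target
      coords <- lapply(list(up = skel[i - 1, ], tg = skel[i, ], dn = skel[i + 1, ]),
                       function(ex) {
                         if (strand == "-") {
                           c(start = L - ex[["end"]] + 1L, end = L - ex[["start"]] + 1L) + offset
                         } else ex + offset
                       })
      skip_ev[[paste0(gid, "_", j)]] <- tibble(
        event_id = paste0(gid, ".SE", j), gene_id = gid,
        chrom = "chr1", strand = strand,
        up_start = coords$up[["start"]], up_end = coords$up[["end"]],
        target_start = coords$tg[["start"]], target_end = coords$tg[["end"]],
        dn_start = coords$dn[["start"]], dn_end = coords$dn[["end"]],
        iso_in = paste0(gid, ".1"), iso_out = paste0(gid, ".", j))
    }

    offset <- offset + L + spacer
  }

  genome_len <- offset
  bases <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  for (w in writes) {
    idx <- seq(w$start, w$start + nchar(w$content) - 1L)
    bases[idx] <- strsplit(w$content, "")[[1]]
  }
  genome <- c(chr1 = paste(bases, collapse = ""))

  annotation <- list_rbind(all_exons)
  validate_exons(annotation)
  structure(list(
    annotation = annotation,
    genome = genome,
    cage = distinct(list_rbind(cage)),
    polya = distinct(list_rbind(polya)),
    truth = list(isoforms = list_rbind(iso_truth),
                 a_rich = if (length(a_rich)) list_rbind(a_rich) else
                   tibble(gene_id = character(), exon_index = integer(),
                          strand = character(), tract_start = integer(),
                          tract_end = integer(), read_end = integer()),
                 skipping_events = if (length(skip_ev)) list_rbind(skip_ev) else
                   tibble(event_id = character())),
    config = config), class = "isodyn_reference")
}
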