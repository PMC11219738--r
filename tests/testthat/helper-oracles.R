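# Independent reference implementations used to cross-check the package.
# Everything here is deliberately naive: explicit enumeration, position sets,
# all-offsets scans.

# ---- classification oracle ---------------------------------------------------

# junction chain of a sorted exon matrix as a character vector "start-end"
oracle_junctions <- function(mat) {
  k <- nrow(mat)
  if (k < 2) return(character(0))
  paste0(mat[-k, 2] + 1, "-", mat[-1, 1] - 1)
}

# enumerate every contiguous sub-chain (incl. full) of a junction vector
oracle_subchains <- function(j) {
  out <- list()
  n <- length(j)
  for (a in seq_len(n)) for (b in a:n) out[[length(out) + 1]] <- j[a:b]
  out
}

# brute-force five-class classification; reference given as an exon table
oracle_classify <- function(model, reference, end_tol = 50) {
  model <- model[order(model$start), ]
  mat <- cbind(model$start, model$end)
  ref_tx <- split(reference, reference$transcript_id)
  same <- Filter(function(tx) tx$chrom[1] == model$chrom[1] &&
                   tx$strand[1] == model$strand[1], ref_tx)

  if (nrow(mat) == 1) {
    for (tx in same) {
      if (nrow(tx) == 1 &&
          mat[1, 1] >= tx$start - end_tol && mat[1, 2] <= tx$end + end_tol) {
        return("FSM")
      }
    }
    return("NNC")
  }

  mj <- oracle_junctions(mat)
  ref_chains <- lapply(same, function(tx) {
    tx <- tx[order(tx$start), ]
    oracle_junctions(cbind(tx$start, tx$end))
  })
  for (ch in ref_chains) if (identical(ch, mj)) return("FSM")
  for (ch in ref_chains) {
    for (sub in oracle_subchains(ch)) {
      if (length(sub) < length(ch) && identical(sub, mj)) return("ISM")
    }
  }
  # loci by merged gene spans
  spans <- do.call(rbind, lapply(split(reference, reference$gene_id), function(g)
    data.frame(gene = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end))))
  spans <- spans[order(spans$chrom, spans$start), ]
  locus <- integer(nrow(spans)); cur <- 0; hi <- -Inf; last_chrom <- ""
  for (i in seq_len(nrow(spans))) {
    if (spans$chrom[i] != last_chrom || spans$start[i] > hi) cur <- cur + 1
    locus[i] <- cur
    hi <- if (spans$chrom[i] != last_chrom) spans$end[i] else max(hi, spans$end[i])
    last_chrom <- spans$chrom[i]
  }
  spans$locus <- locus
  junc_gene <- list()
  for (gi in seq_along(same)) {
    tx <- same[[gi]][order(same[[gi]]$start), ]
    for (j in oracle_junctions(cbind(tx$start, tx$end))) {
      junc_gene[[j]] <- union(junc_gene[[j]], tx$gene_id[1])
    }
  }
  hit_loci <- unique(unlist(lapply(mj, function(j) {
    g <- junc_gene[[j]]
    if (is.null(g)) NULL else spans$locus[match(g, spans$gene)]
  })))
  if (length(hit_loci) >= 2) return("fusion")

  donors <- c(); acceptors <- c()
  for (tx in same) {
    tx <- tx[order(tx$start), ]
    k <- nrow(tx)
    if (k < 2) next
    if (tx$strand[1] == "+") {
      donors <- c(donors, tx$end[-k] + 1); acceptors <- c(acceptors, tx$start[-1] - 1)
    } else {
      donors <- c(donors, tx$start[-1] - 1); acceptors <- c(acceptors, tx$end[-k] + 1)
    }
  }
  k <- nrow(mat)
  if (model$strand[1] == "+") {
    md <- mat[-k, 2] + 1; ma <- mat[-1, 1] - 1
  } else {
    md <- mat[-1, 1] - 1; ma <- mat[-k, 2] + 1
  }
  if (all(md %in% donors) && all(ma %in% acceptors)) "NIC" else "NNC"
}

# ---- BH step-up oracle -------------------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# ---- naive all-offsets IUPAC matcher ----------------------------------------

oracle_iupac <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_scan <- function(sequence, motif) {
  s <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1]]
  m <- strsplit(chartr("U", "T", toupper(motif)), "")[[1]]
  n <- length(s); w <- length(m)
  mask <- integer(n)
  if (n >= w) {
    for (off in 0:(n - w)) {
      ok <- TRUE
      for (i in seq_len(w)) {
        if (!s[off + i] %in% oracle_iupac[[m[i]]]) { ok <- FALSE; break }
      }
      if (ok) mask[(off + 1):(off + w)] <- 1L
    }
  }
  mask
}

# ---- interval merge by position sets ----------------------------------------

oracle_merge <- function(starts, ends) {
  pos <- sort(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
  brk <- c(0, which(diff(pos) > 1), length(pos))
  t(vapply(seq_len(length(brk) - 1), function(i) {
    c(pos[brk[i] + 1], pos[brk[i + 1]])
  }, numeric(2)))
}

# ---- NMD coordinate oracle ---------------------------------------------------

# maps genomic bases to transcript coordinates explicitly and applies the
# 50-nt rule by counting; independent of the package's width arithmetic
oracle_nmd <- function(model, tx_seq, min_distance = 50) {
  model <- model[order(model$start), ]
  gpos <- unlist(mapply(seq, model$start, model$end, SIMPLIFY = FALSE))
  if (model$strand[1] == "-") gpos <- rev(gpos)
  k <- nrow(model)
  if (k < 2) return("insensitive")
  # last junction: transcript index of the final base of the penultimate exon
  # in transcript order
  exon_of <- unlist(mapply(function(i, s, e) rep(i, e - s + 1),
                           seq_len(k), model$start, model$end, SIMPLIFY = FALSE))
  if (model$strand[1] == "-") exon_of <- rev(exon_of)
  tx_order_exons <- unique(exon_of)
  penult <- tx_order_exons[length(tx_order_exons) - 1]
  last_junction <- max(which(exon_of == penult))
  # longest ATG ORF by explicit codon walk
  s <- strsplit(toupper(tx_seq), "")[[1]]
  best_len <- -1; best_stop <- NA
  for (a in seq_len(max(length(s) - 5, 0))) {
    if (paste(s[a:(a + 2)], collapse = "") != "ATG") next
    p <- a
    while (p + 2 <= length(s)) {
      cod <- paste(s[p:(p + 2)], collapse = "")
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- p + 2 - a + 1
        if (len > best_len) { best_len <- len; best_stop <- p }
        break
      }
      p <- p + 3
    }
  }
  if (is.na(best_stop)) return("insensitive")
  if (last_junction - best_stop >= min_distance) "sensitive" else "insensitive"
}

# ---- random structures for property tests -----------------------------------

random_reference <- function(n_genes = 2, max_exons = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offset <- 0
  out <- list()
  for (g in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    k <- sample(3:max_exons, 1)
    lens <- sample(80:200, k, replace = TRUE)
    gaps <- sample(150:500, k - 1, replace = TRUE)
    starts <- offset + 200 + c(0, cumsum(lens[-k] + gaps))
    full <- data.frame(start = starts, end = starts + lens - 1)
    n_iso <- sample(1:3, 1)
    for (j in seq_len(n_iso)) {
      keep <- sort(sample(seq_len(k), max(2, k - sample(0:2, 1))))
      out[[length(out) + 1]] <- data.frame(
        gene_id = sprintf("RG%02d", g),
        transcript_id = sprintf("RG%02d.%d", g, j),
        chrom = "chrR", strand = strand,
        start = full$start[keep], end = full$end[keep])
    }
    offset <- max(full$end) + 1500
  }
  dplyr::bind_rows(out)
}

# a random query chain derived from a reference: FSM copy, truncation,
# site shifts, exon drops or cross-gene mixes
random_query <- function(reference) {
  tx <- split(reference, reference$transcript_id)
  pick <- tx[[sample(length(tx), 1)]]
  pick <- pick[order(pick$start), ]
  op <- sample(c("copy", "truncate", "shift", "drop", "mix"), 1)
  q <- pick
  if (op == "truncate" && nrow(q) > 2) {
    q <- q[sample(c(TRUE, FALSE), 1) + seq_len(nrow(q) - 1), ]
  } else if (op == "shift" && nrow(q) > 1) {
    i <- sample(nrow(q) - 1, 1)
    q$end[i] <- q$end[i] - sample(c(3:20), 1)
  } else if (op == "drop" && nrow(q) > 2) {
    q <- q[-sample(2:(nrow(q) - 1), 1), ]
  } else if (op == "mix") {
    other <- tx[[sample(length(tx), 1)]]
    if (other$strand[1] == q$strand[1] && other$gene_id[1] != q$gene_id[1]) {
      q <- rbind(q, other[order(other$start), ])
      q <- q[order(q$start), ]
      if (any(q$start[-1] <= q$end[-nrow(q)])) q <- pick
    }
  }
  q$transcript_id <- "query"
  q[order(q$start), ]
}
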