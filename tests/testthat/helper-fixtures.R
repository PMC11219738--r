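# small shared fixture builders (everything generated in code)

# exon table from a compact list: list(tx1 = list(c(s, e), c(s, e), ...), ...)
exons_from_list <- function(spec, chrom = "chrT", strand = "+",
                            gene_id = "GT") {
  purrr::imap(spec, function(ex, id) {
    m <- do.call(rbind, ex)
    tibble::tibble(gene_id = gene_id, transcript_id = id, chrom = chrom,
                   strand = strand, start = m[, 1], end = m[, 2])
  }) |> purrr::list_rbind()
}

# a genome string with given total length and planted substrings
genome_with <- function(len, plants = list(), seed = 42, chrom = "chrT") {
  set.seed(seed)
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (p in plants) {
    idx <- seq(p$at, p$at + nchar(p$seq) - 1)
    x[idx] <- strsplit(p$seq, "")[[1]]
  }
  stats::setNames(paste(x, collapse = ""), chrom)
}

# plant canonical GT..AG sites for every junction of an exon table
plant_splice_sites <- function(genome, exons) {
  ch <- strsplit(genome[[1]], "")[[1]]
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid, ]
    e <- e[order(e$start), ]
    k <- nrow(e)
    if (k < 2) next
    for (i in seq_len(k - 1)) {
      is_ <- e$end[i] + 1; ie <- e$start[i + 1] - 1
      if (e$strand[1] == "+") {
        ch[is_:(is_ + 1)] <- c("G", "T"); ch[(ie - 1):ie] <- c("A", "G")
      } else {
        ch[is_:(is_ + 1)] <- c("C", "T"); ch[(ie - 1):ie] <- c("A", "C")
      }
    }
  }
  stats::setNames(paste(ch, collapse = ""), names(genome))
}

# tiny two-gene reference with planted genome, cage/polya tracks
tiny_reference <- function(seed = 1) {
  cfg <- simulation_config(seed = seed, n_genes = 6,
                           isoforms_per_gene = c(2L, 3L))
  generate_reference(cfg)
}

expect_single_event <- function(exons, type) {
  ev <- annotate_events(exons)
  testthat::expect_setequal(unique(ev$event_type), type)
}
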