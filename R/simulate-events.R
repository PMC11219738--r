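#' Simulate a standalone cassette-exon event set
#'
#' Builds independent three-exon loci (upstream exon, target cassette exon,
#' downstream exon) on a fresh random genome and labels them included,
#' excluded or background — the input shape of the positional RBP analyses,
#' available without running the whole pipeline. Strands alternate so the
#' orientation handling is always exercised.
#'
#' @param n_included,n_excluded,n_background group sizes.
#' @param seed integer seed.
#' @param exon_len,intron_len feature lengths (nt).
#' @return list with `events` (event table with `group` column) and `genome`.
#' @export
simulate_event_set <- function(n_included = 30L, n_excluded = 30L,
                               n_background = 50L, seed = 1L,
                               exon_len = 150L, intron_len = 600L) {
  n <- n_included + n_excluded + n_background
  with_seed(seed + 7L, {
    locus_len <- 3L * exon_len + 2L * intron_len + 200L
    genome <- c(chrE = paste(sample(c("A", "C", "G", "T"), n * locus_len,
                                    replace = TRUE), collapse = ""))
    groups <- sample(rep(c("included", "excluded", "background"),
                         c(n_included, n_excluded, n_background)))
    events <- map(seq_len(n), function(i) {
      off <- (i - 1L) * locus_len + 100L
      st <- if (i %% 2 == 0) "+" else "-"
      e1 <- c(off, off + exon_len - 1L)
      e2 <- e1 + exon_len + intron_len
      e3 <- e2 + exon_len + intron_len
      # transcript-orientation up/target/dn: mirror roles on the minus strand
      if (st == "+") {
        tibble(event_id = sprintf("EV%04d", i), chrom = "chrE", strand = st,
               up_start = e1[1], up_end = e1[2],
               target_start = e2[1], target_end = e2[2],
               dn_start = e3[1], dn_end = e3[2])
      } else {
        tibble(event_id = sprintf("EV%04d", i), chrom = "chrE", strand = st,
               up_start = e3[1], up_end = e3[2],
               target_start = e2[1], target_end = e2[2],
               dn_start = e1[1], dn_end = e1[2])
      }
    }) |> list_rbind() |>
      mutate(group = groups)
    list(events = events, genome = genome)
  })
}
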