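test_that("configuration invariants are enforced", {
  expect_error(simulation_config(artifact_rates = c(mispriming = 1.2)), "rates")
  expect_error(simulation_config(artifact_rates = c(mispriming = 0.6,
                                                    fusion = 0.6)), "sum")
  expect_error(simulation_config(n_days = 1), "days")
  expect_error(simulation_config(replicates_per_day = 1), "replicates")
})

test_that("a fixed seed reproduces every generator output bit-identically", {
  cfg <- simulation_config(seed = 4, n_genes = 8)
  a <- simulate_dataset(cfg, n_reads = 150)
  b <- simulate_dataset(simulation_config(seed = 4, n_genes = 8), n_reads = 150)
  expect_identical(a$reference$annotation, b$reference$annotation)
  expect_identical(a$reference$genome, b$reference$genome)
  expect_identical(a$reads, b$reads)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$peptides$peptides, b$peptides$peptides)
})

test_that("single-isoform genes yield no alternative events downstream", {
  cfg <- simulation_config(seed = 2, n_genes = 6, isoforms_per_gene = c(1L, 1L))
  ref <- generate_reference(cfg)
  expect_equal(nrow(annotate_events(ref$annotation)), 0)
})

test_that("a gene planted with one skipped exon annotates exactly SES", {
  pg <- plant_event_gene("SES", strand = "+")
  expect_single_event(pg$exons, "SES")
})

test_that("reference geometry is sound: canonical sites, polyA motifs, clean 3' ends", {
  ref <- tiny_reference(seed = 8)
  for (tid in unique(ref$annotation$transcript_id)) {
    m <- ref$annotation[ref$annotation$transcript_id == tid, ]
    jc <- junction_canonicality(m, ref$genome)
    expect_true(all(jc$canonical))
    es <- end_support(m, ref$cage, ref$polya, ref$genome)
    expect_true(es$tss_supported && es$tts_supported && es$polya_motif_found)
    expect_false(detect_mispriming(m, ref$genome))
  }
  # the A-rich traps really are >= 60% adenine on the transcript strand
  tr <- ref$truth$a_rich
  for (i in seq_len(nrow(tr))) {
    s <- substr(ref$genome[["chr1"]], tr$tract_start[i], tr$tract_end[i])
    if (tr$strand[i] == "-") s <- chartr("ACGT", "TGCA", s)
    expect_gte(stringr::str_count(s, "A") / nchar(s), 0.6)
  }
})

test_that("zero artifact rates and zero jitter reproduce source chains exactly", {
  cfg <- simulation_config(seed = 6, n_genes = 6, jitter_sd = 0, end_sd = 0)
  ref <- generate_reference(cfg)
  ab <- tibble::tibble(transcript_id = unique(ref$annotation$transcript_id),
                       abundance = 1)
  rd <- simulate_long_reads(ref$annotation, ref$genome, ab, c(), seed = 6,
                            n_reads = 200, jitter_sd = 0, end_sd = 0)
  expect_true(all(rd$truth$label == "clean"))
  chains <- split(rd$reads[, c("start", "end")], rd$reads$read_id)
  src <- split(ref$annotation[, c("start", "end")], ref$annotation$transcript_id)
  for (i in seq_len(nrow(rd$truth))) {
    got <- chains[[rd$truth$read_id[i]]]
    want <- src[[rd$truth$transcript_id[i]]]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("ground-truth labels partition reads and rates are respected", {
  cfg <- simulation_config(seed = 9, n_genes = 15)
  ref <- generate_reference(cfg)
  ab <- tibble::tibble(transcript_id = unique(ref$annotation$transcript_id),
                       abundance = 1)
  rd <- simulate_long_reads(ref$annotation, ref$genome, ab,
                            c(fusion = 0.1), seed = 101, n_reads = 1000,
                            traps = ref$truth$a_rich)
  expect_equal(nrow(rd$truth), 1000)
  expect_equal(dplyr::n_distinct(rd$truth$read_id), 1000)
  expect_true(all(rd$truth$label %in% c("clean", "truncation", "mispriming",
                                        "template_switch", "fusion")))
  # fusion count within the binomial 99% interval around 100
  n_fus <- sum(rd$truth$label == "fusion")
  expect_gte(n_fus, qbinom(0.005, 1000, 0.1))
  expect_lte(n_fus, qbinom(0.995, 1000, 0.1))
  # rates summing above one error out
  expect_error(simulate_long_reads(ref$annotation, ref$genome, ab,
                                   c(mispriming = 0.7, fusion = 0.6),
                                   seed = 1, traps = ref$truth$a_rich), "sum")
})

test_that("mispriming rate 1 means every read is flagged downstream", {
  cfg <- simulation_config(seed = 13, n_genes = 8, a_rich_fraction = 1)
  ref <- generate_reference(cfg)
  ab <- tibble::tibble(transcript_id = unique(ref$annotation$transcript_id),
                       abundance = 1)
  rd <- simulate_long_reads(ref$annotation, ref$genome, ab,
                            c(mispriming = 1), seed = 13, n_reads = 100,
                            jitter_sd = 0, end_sd = 0, traps = ref$truth$a_rich)
  flagged <- rd$reads |>
    dplyr::group_by(read_id) |>
    dplyr::group_map(~ detect_mispriming(dplyr::mutate(.x, chrom = .x$chrom[1]),
                                         ref$genome)) |>
    unlist()
  expect_true(all(flagged))
})

test_that("count simulation hits its noise-free limit and recovers planted dIF", {
  cfg <- simulation_config(seed = 3, n_genes = 8, dispersion = 0,
                           lib_size_range = c(1, 1), switch_fraction = 0)
  ref <- generate_reference(cfg)
  design <- design_table(3, 2)
  sim <- simulate_counts(ref$annotation, design, seed = 3, config = cfg)
  m <- as.matrix(sim$counts[, design$sample])
  # all replicates of a day equal the rounded expected mean
  expect_true(all(m[, 1] == m[, 2]))

  # planted dIF 0.6 recovered within 0.1 at 3 replicates
  cfg2 <- simulation_config(seed = 12, n_genes = 10,
                            isoforms_per_gene = c(2L, 2L), switch_dif = 0.6,
                            switch_fraction = 1)
  ref2 <- generate_reference(cfg2)
  design6 <- design_table(6, 3)
  sim2 <- simulate_counts(ref2$annotation, design6, seed = 12, config = cfg2)
  usage <- compute_usage(sim2$tpm, design6)
  dtu <- dtu_test(usage, 0, 5)
  rec <- dplyr::inner_join(dtu, sim2$switch_plan,
                           by = c("isoform_id" = "iso_up"))
  expect_gt(nrow(rec), 3)
  expect_lt(mean(abs(rec$dIF - 0.6)), 0.1)
})

test_that("junction counts follow the planted inclusion levels", {
  ev <- tibble::tibble(event_id = c("e1", "e2"))
  design <- design_table(2, 3)
  plan1 <- tidyr::crossing(event_id = ev$event_id, day = 0:1) |>
    dplyr::mutate(psi = 0.99)   # the generator clamp for psi = 1
  jc <- simulate_junction_counts(ev, plan1, depth = 50, seed = 5,
                                 design = design)
  expect_lt(mean(jc$S), 2)

  plan2 <- tidyr::crossing(event_id = ev$event_id, day = 0:1) |>
    dplyr::mutate(psi = 0.5)
  jc2 <- simulate_junction_counts(ev, plan2, depth = 20000, seed = 5,
                                  design = design)
  psi_hat <- (jc2$I1 + jc2$I2) / 2 / ((jc2$I1 + jc2$I2) / 2 + jc2$S)
  expect_true(all(abs(psi_hat - 0.5) < 0.02))
})

test_that("motif planting touches only the requested events and is findable", {
  es <- simulate_event_set(n_included = 10, n_excluded = 5, n_background = 10,
                           seed = 3)
  pl <- plant_motifs(es$genome, es$events, motif = "AATAAA",
                     segment = "upIntron3p", fraction = 1, seed = 3)
  expect_true(all(pl$log$event_id %in%
                    es$events$event_id[es$events$group == "included"]))
  # planted instances are present in the modified genome (transcript strand)
  for (i in seq_len(nrow(pl$log))) {
    s <- substr(pl$genome[["chrE"]], pl$log$start[i], pl$log$end[i])
    if (pl$log$strand[i] == "-") {
      s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    }
    expect_equal(s, "AATAAA")
  }
  # scanner finds at least the planted count in each planted segment
  segs <- extract_segments(es$events, pl$genome) |>
    dplyr::filter(segment == "upIntron3p",
                  event_id %in% unique(pl$log$event_id))
  hits <- vapply(segs$seq, function(x) sum(scan_motif(x, "AATAAA")) >= 6,
                 logical(1))
  expect_true(all(hits))
  # fraction 0 plants nothing
  pl0 <- plant_motifs(es$genome, es$events, motif = "AATAAA",
                      segment = "upIntron3p", fraction = 0, seed = 3)
  expect_identical(pl0$genome, es$genome)
  expect_equal(nrow(pl0$log), 0)
})

test_that("peptide simulation marks shared peptides and respects missingness", {
  prot <- synthetic_protein_pair(seed = 4)
  # unique peptides are exactly those overlapping the distinct segment
  p1 <- tryptic_peptides(prot$aa[1]); p2 <- tryptic_peptides(prot$aa[2])
  shared <- intersect(p1, p2)
  expect_gt(length(shared), 0)
  expect_gt(length(setdiff(p1, p2)), 0)
  sim <- simulate_peptides(prot, missingness = 0, seed = 4,
                           design = design_table(2, 2))
  expect_false(anyNA(sim$peptides$intensity))
  both <- sim$peptides |>
    dplyr::filter(stringr::str_detect(matched_isoforms, ";")) |>
    dplyr::pull(peptide) |> unique()
  expect_setequal(both, shared)

  sim2 <- simulate_peptides(prot, missingness = 0.3, seed = 4,
                            design = design_table(2, 2))
  miss_frac <- mean(is.na(sim2$peptides$intensity))
  expect_gt(miss_frac, 0.15)
  expect_lt(miss_frac, 0.45)
  # dropout concentrates in low-abundance cells (MNAR)
  obs <- sim2$peptides$intensity
  base <- sim$peptides$intensity
  expect_lt(mean(log2(base[is.na(obs)])), mean(log2(base[!is.na(obs)])))
})
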