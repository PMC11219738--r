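mk_mat <- function(m, design, ids = sprintf("P%02d", seq_len(nrow(m)))) {
  colnames(m) <- design$sample
  dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(m))
}

test_that("presence filter keeps proteins observed twice in some condition", {
  design <- design_table(2, 3)
  m <- rbind(
    c(20, 21, NA, NA, NA, NA),   # 2/3 on day 0 only -> kept
    c(20, NA, NA, 21, NA, NA),   # 1/3 everywhere -> dropped
    c(20, 21, 22, 23, 24, 25))   # fully observed -> kept
  f <- presence_filter(mk_mat(m, design), design)
  expect_equal(f$protein_id, c("P01", "P03"))
})

test_that("MNAR imputation draws from the left-shifted gaussian and is seeded", {
  design <- design_table(2, 3)
  set.seed(4)
  full <- matrix(rnorm(12000, 25, 2), ncol = 6)
  m <- full
  m[sample(length(m), 2500)] <- NA
  dat <- mk_mat(m, design)
  # observed cells never change
  imp <- impute_mnar(dat, design, seed = 9)
  obs <- !is.na(m)
  expect_equal(as.matrix(imp[, design$sample])[obs], m[obs])
  expect_false(anyNA(imp[, design$sample]))
  # identical when repeated with the same seed; different otherwise
  expect_identical(impute_mnar(dat, design, seed = 9), imp)
  expect_false(identical(impute_mnar(dat, design, seed = 10), imp))
  # no missing cells: untouched
  dat_full <- mk_mat(full, design)
  expect_identical(impute_mnar(dat_full, design, seed = 1), dat_full)
  # distribution: mean within 3 SE of mean - 1.8 sd; sd within 5% of 0.3 sd
  s <- design$sample[1]
  x_obs <- m[, 1][!is.na(m[, 1])]
  drawn <- imp[[s]][is.na(m[, 1])]
  n_draw <- length(drawn)
  target_mean <- mean(x_obs) - 1.8 * sd(x_obs)
  target_sd <- 0.3 * sd(x_obs)
  expect_lt(abs(mean(drawn) - target_mean), 3 * target_sd / sqrt(n_draw))
  expect_lt(abs(sd(drawn) / target_sd - 1), 0.15)
})

test_that("differential protein calls need both padj < 0.1 and |log2FC| > 0.32", {
  design <- design_table(2, 3)
  set.seed(11)
  base <- matrix(rnorm(180, 25, 0.01), ncol = 6)
  m <- base
  m[1:10, 4:6] <- m[1:10, 4:6] + 0.25     # strong evidence, small effect
  m[11:20, 4:6] <- m[11:20, 4:6] + 1.0    # clear hits
  r <- differential_protein(mk_mat(m, design), design, 0, 1)
  expect_true(all(!r$significant[1:10]))
  expect_true(all(r$padj[1:10] < 0.1))    # filtered purely by the effect size
  expect_true(all(r$significant[11:20]))
  ident <- differential_protein(mk_mat(base, design), design, 0, 1)
  expect_true(all(!ident$significant))
})

test_that("peptide assignment uses unique peptides and sums fractions", {
  peps <- tibble::tibble(
    peptide = c("AAAAAAAK", "AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
    matched_isoforms = c("I1", "I1", "I1;I2", "I2"),
    fraction = c(1, 2, 1, 1),
    sample = "s1",
    intensity = c(100, 50, 999, 70))
  r <- assign_peptides(peps, isoform_ids = c("I1", "I2", "I3"))
  expect_equal(r$lfq$lfq[r$lfq$isoform_id == "I1"], 150)  # fractions summed
  expect_equal(r$lfq$lfq[r$lfq$isoform_id == "I2"], 70)   # shared one excluded
  expect_equal(r$unquantifiable, "I3")
  # identical twin sequences share every peptide: both unquantifiable
  twins <- tibble::tibble(peptide = "EEEEEEEK", matched_isoforms = "T1;T2",
                          fraction = 1, sample = "s1", intensity = 5)
  r2 <- assign_peptides(twins, isoform_ids = c("T1", "T2"))
  expect_setequal(r2$unquantifiable, c("T1", "T2"))
  expect_equal(nrow(r2$lfq), 0)
})

test_that("moving a peptide from unique to shared never raises any LFQ", {
  set.seed(14)
  peps <- tibble::tibble(
    peptide = rep(sprintf("PEP%02dAAK", 1:10), each = 2),
    matched_isoforms = rep(sample(c("I1", "I2"), 10, TRUE), each = 2),
    fraction = rep(1:2, 10), sample = "s1",
    intensity = runif(20, 10, 100))
  base <- assign_peptides(peps)$lfq
  for (i in 1:5) {
    shared <- peps
    k <- sample(unique(peps$peptide), 1)
    shared$matched_isoforms[shared$peptide == k] <- "I1;I2"
    after <- assign_peptides(shared)$lfq
    j <- dplyr::left_join(base, after, by = c("isoform_id", "sample"),
                          suffix = c("_b", "_a")) |>
      dplyr::mutate(lfq_a = dplyr::coalesce(lfq_a, 0))
    expect_true(all(j$lfq_a <= j$lfq_b + 1e-9))
  }
})

test_that("trend differences flag |dlog2FC| >= 1 and recover a planted switch", {
  design <- design_table(2, 3)
  lfq <- tidyr::crossing(isoform_id = c("A", "B"), design) |>
    dplyr::mutate(lfq = dplyr::case_when(
      isoform_id == "A" & day == 0 ~ 1000, isoform_id == "A" & day == 1 ~ 2297,
      isoform_id == "B" & day == 0 ~ 500, isoform_id == "B" & day == 1 ~ 406)) |>
    dplyr::select(isoform_id, sample, lfq)
  gene_of <- c(A = "G", B = "G")
  r <- trend_differences(lfq, design, gene_of, comparisons = list(c(0, 1)))
  expect_equal(r$lfc_a, 1.2, tolerance = 5e-3)
  expect_equal(r$lfc_b, -0.3, tolerance = 5e-3)
  expect_equal(r$delta, 1.5, tolerance = 5e-3)
  expect_true(all(r$trend_change))
  # equal trajectories: no call
  flat <- lfq |> dplyr::mutate(lfq = 1000)
  r0 <- trend_differences(flat, design, gene_of, comparisons = list(c(0, 1)))
  expect_true(all(r0$delta == 0))
  expect_false(any(r0$trend_change))

  # end-to-end: planted +1.5 / -0.2 trajectories through peptide simulation
  prot <- synthetic_protein_pair(seed = 2)
  plan <- tidyr::crossing(transcript_id = prot$transcript_id, day = 0:5) |>
    dplyr::mutate(log2_abundance = dplyr::if_else(
      transcript_id == prot$transcript_id[1], 1.5 * day / 5, -0.2 * day / 5))
  sim <- simulate_peptides(prot, plan, missingness = 0.1, seed = 2,
                           design = design_table(6, 3))
  ap <- assign_peptides(sim$peptides, isoform_ids = prot$transcript_id)
  tr <- trend_differences(ap$lfq, design_table(6, 3),
                          setNames(prot$gene_id, prot$transcript_id),
                          comparisons = list(c(0, 5)))
  expect_true(all(tr$trend_change))
  expect_gt(max(tr$delta), 1)
})

test_that("the 50-nt NMD rule and its boundary behave as defined", {
  # three exons; transcript length 300, last junction at position 200
  mk_model <- function(strand = "+") {
    ex <- tibble::tibble(transcript_id = "t", chrom = "c", strand = strand,
                         start = c(1, 201, 401), end = c(100, 300, 500))
    ex
  }
  seq_with_stop_at <- function(stop_start, n = 300) {
    s <- rep("C", n)
    a <- ((stop_start - 1) %% 3) + 1     # ATG in frame with the stop
    s[a:(a + 2)] <- c("A", "T", "G")
    s[stop_start:(stop_start + 2)] <- c("T", "A", "A")
    paste(s, collapse = "")
  }
  # stop 60 nt upstream of the junction (position 140): sensitive
  r <- predict_nmd(mk_model(), tx_seq = seq_with_stop_at(140))
  expect_equal(r$nmd, "sensitive")
  # stop in the final exon: insensitive
  r2 <- predict_nmd(mk_model(), tx_seq = seq_with_stop_at(250))
  expect_equal(r2$nmd, "insensitive")
  # boundary: junction - stop = exactly 50 -> sensitive
  r3 <- predict_nmd(mk_model(), tx_seq = seq_with_stop_at(150))
  expect_equal(r3$nmd, "sensitive")
  r4 <- predict_nmd(mk_model(), tx_seq = seq_with_stop_at(151))
  expect_equal(r4$nmd, "insensitive")
  # mono-exon: insensitive
  mono <- tibble::tibble(transcript_id = "t", chrom = "c", strand = "+",
                         start = 1, end = 300)
  expect_equal(predict_nmd(mono, tx_seq = seq_with_stop_at(100))$nmd,
               "insensitive")
})

test_that("NMD agrees with the coordinate oracle on random structures", {
  set.seed(3)
  n_match <- 0
  for (i in 1:200) {
    k <- sample(1:5, 1)
    lens <- sample(60:300, k, replace = TRUE)
    gaps <- sample(50:200, max(k - 1, 0), replace = TRUE)
    starts <- 1 + c(0, cumsum(lens[-k] + gaps))
    model <- tibble::tibble(transcript_id = "t", chrom = "cO",
                            strand = sample(c("+", "-"), 1),
                            start = starts, end = starts + lens - 1)
    genome <- genome_with(max(model$end) + 10, seed = i, chrom = "cO")
    got <- predict_nmd(model, genome)$nmd
    want <- oracle_nmd(model, transcript_seq(model, genome))
    expect_equal(got, want)
    n_match <- n_match + (got == want)
  }
  expect_equal(n_match, 200)
})

test_that("RNA-protein correlation is 1 on identical fold changes and finds a planted lag", {
  mk_lfc <- function(vals, comps, sig = TRUE) {
    tidyr::crossing(feature_id = names(vals), comparison = comps) |>
      dplyr::mutate(log2FC = vals[feature_id] +
                      as.integer(factor(comparison)) * 0,
                    significant = sig)
  }
  set.seed(5)
  vals <- setNames(rnorm(100), paste0("g", 1:100))
  rna <- mk_lfc(vals, "d0_d1")
  prot <- mk_lfc(vals, "d0_d1")
  r <- rna_protein_correlation(rna, prot)
  expect_equal(r$rho, 1)

  # independent vectors: |rho| small for n = 200
  v2 <- setNames(rnorm(200), paste0("h", 1:200))
  v3 <- setNames(rnorm(200), paste0("h", 1:200))
  r2 <- rna_protein_correlation(mk_lfc(v2, "c"), mk_lfc(v3, "c"))
  expect_lt(abs(r2$rho), 0.2)

  # protein = RNA shifted by one day: argmax correlation at lag 1
  days <- paste0("d", 0:3, "_d", 1:4)
  base <- lapply(1:5, function(i) setNames(rnorm(150), paste0("k", 1:150)))
  rna3 <- purrr::map2(base[1:4], days, ~ mk_lfc(.x, .y)) |> purrr::list_rbind()
  prot3 <- purrr::map2(base[c(5, 1, 2, 3)], days, ~ mk_lfc(.x, .y)) |>
    purrr::list_rbind()
  r3 <- rna_protein_correlation(rna3, prot3)
  best <- r3 |> dplyr::filter(rna_comparison == "d0_d1") |>
    dplyr::slice_max(rho, n = 1)
  expect_equal(best$protein_comparison, "d1_d2")
})
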