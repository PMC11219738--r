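test_that("collapse merges within tolerance and enforces the minimum cluster size", {
  base <- list(c(101, 200), c(401, 500), c(801, 900))
  mk <- function(id, shift_internal = 0, shift_end = 0) {
    ex <- base
    ex[[2]][1] <- ex[[2]][1] + shift_internal
    ex[[3]][2] <- ex[[3]][2] + shift_end
    exons_from_list(setNames(list(ex), id)) |>
      dplyr::rename(read_id = transcript_id) |> dplyr::select(-gene_id)
  }
  three <- dplyr::bind_rows(mk("r1"), mk("r2"), mk("r3"))
  out <- collapse_reads(three)
  expect_equal(nrow(out), 1)
  expect_equal(out$read_support, 3)
  expect_equal(out$exons[[1]]$start, c(101, 401, 801))

  two <- dplyr::bind_rows(mk("r1"), mk("r2"))
  expect_equal(nrow(collapse_reads(two)), 0)

  # 6 nt at an internal boundary exceeds the 5 nt tolerance; 4 nt does not
  far <- dplyr::bind_rows(mk("a1"), mk("a2"), mk("a3"),
                          mk("b1", 6), mk("b2", 6), mk("b3", 6))
  expect_equal(nrow(collapse_reads(far)), 2)
  near <- dplyr::bind_rows(mk("a1"), mk("a2"), mk("a3"),
                           mk("b1", 4), mk("b2", 4), mk("b3", 4))
  expect_equal(nrow(collapse_reads(near)), 1)

  # end jitter up to 50 nt merges; beyond does not
  ends <- dplyr::bind_rows(mk("a1"), mk("a2"), mk("a3"),
                           mk("b1", 0, 49), mk("b2", 0, 49), mk("b3", 0, 49))
  expect_equal(nrow(collapse_reads(ends)), 1)
  ends2 <- dplyr::bind_rows(mk("a1"), mk("a2"), mk("a3"),
                            mk("b1", 0, 60), mk("b2", 0, 60), mk("b3", 0, 60))
  expect_equal(nrow(collapse_reads(ends2)), 2)
})

test_that("collapse matches a brute-force single-linkage oracle on random read sets", {
  set.seed(31)
  for (rep in 1:5) {
    base <- list(c(101, 220), c(501, 640), c(901, 1040), c(1301, 1400))
    n <- 15
    reads <- purrr::map(seq_len(n), function(i) {
      ex <- base
      for (j in 1:3) {
        d <- sample(c(0, 0, 0, 3, 8), 1)
        ex[[j]][2] <- ex[[j]][2] + d
        ex[[j + 1]][1] <- ex[[j + 1]][1] + sample(c(0, 0, 4, 9), 1)
      }
      exons_from_list(setNames(list(ex), sprintf("r%02d", i))) |>
        dplyr::rename(read_id = transcript_id) |> dplyr::select(-gene_id)
    }) |> purrr::list_rbind()

    out <- collapse_reads(reads, min_cluster = 1)
    # oracle: transitive closure of pairwise compatibility
    info <- split(reads, reads$read_id)
    bounds <- lapply(info, function(r) {
      r <- r[order(r$start), ]; c(rbind(r$start, r$end))
    })
    ids <- names(bounds)
    compat <- function(a, b) {
      d <- abs(bounds[[a]] - bounds[[b]])
      tol <- rep(5, length(d)); tol[c(1, length(d))] <- 50
      all(d <= tol)
    }
    groups <- as.list(ids)
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (j <= i) next
          if (any(outer(groups[[i]], groups[[j]], Vectorize(compat)))) {
            groups[[i]] <- c(groups[[i]], groups[[j]])
            groups[[j]] <- character(0)
            merged <- TRUE
          }
        }
      }
      groups <- Filter(length, groups)
      if (!merged) break
    }
    oracle_sets <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                               character(1)))
    got_sets <- sort(vapply(out$read_ids, function(g) paste(sort(g), collapse = ","),
                            character(1)))
    expect_equal(got_sets, oracle_sets)
  }
})

ref_fix <- exons_from_list(list(
  T1 = list(c(101, 200), c(301, 400), c(501, 600), c(701, 800),
            c(901, 1000), c(1101, 1200), c(1301, 1400)),
  T2 = list(c(101, 200), c(301, 400), c(501, 600), c(901, 1000),
            c(1101, 1200), c(1301, 1400))))

test_that("classification assigns the five classes as defined", {
  q <- function(ex) exons_from_list(list(Q = ex))[, -1]
  # FSM: all junctions of T1
  expect_equal(classify_isoform(q(list(c(101, 200), c(301, 400), c(501, 600),
                                       c(701, 800), c(901, 1000),
                                       c(1101, 1200), c(1301, 1400))),
                                ref_fix)$class, "FSM")
  # ISM: junctions 2..4 of the 6-junction reference T1
  ism <- classify_isoform(q(list(c(321, 400), c(501, 600), c(701, 800),
                                 c(901, 980))), ref_fix)
  expect_equal(ism$class, "ISM")
  expect_true("T1" %in% ism$matched[[1]])
  # NIC: annotated donor of exon 1 joined to annotated acceptor of exon 3
  expect_equal(classify_isoform(q(list(c(101, 200), c(501, 600))),
                                ref_fix)$class, "NIC")
  # NNC: donor shifted 8 nt off any annotated donor
  expect_equal(classify_isoform(q(list(c(101, 192), c(501, 600))),
                                ref_fix)$class, "NNC")
  # fusion: junctions of two distinct loci
  ref2 <- dplyr::bind_rows(
    ref_fix,
    exons_from_list(list(U1 = list(c(5001, 5100), c(5301, 5400))),
                    gene_id = "GU"))
  fus <- classify_isoform(
    q(list(c(101, 200), c(301, 400), c(5001, 5100), c(5301, 5400))), ref2)
  expect_equal(fus$class, "fusion")
  # zero exons errors
  expect_error(classify_isoform(ref_fix[0, ], ref_fix))
})

test_that("classification equals the brute-force oracle on random genes", {
  set.seed(17)
  n_ok <- 0
  for (i in 1:120) {
    ref <- random_reference(n_genes = sample(1:3, 1), seed = NULL)
    qq <- random_query(ref)
    got <- classify_isoform(qq, ref)$class
    want <- oracle_classify(qq, ref)
    expect_equal(got, want)
    n_ok <- n_ok + (got == want)
  }
  expect_equal(n_ok, 120)
})

test_that("mispriming detection applies the 60% adenine rule on either strand", {
  # 13 A of 20 downstream -> flagged; 11 of 20 -> not
  mk_g <- function(n_a) {
    tail20 <- paste(c(rep("A", n_a), rep("C", 20 - n_a)), collapse = "")
    genome_with(400, plants = list(list(at = 201, seq = tail20)))
  }
  model <- tibble::tibble(transcript_id = "m", chrom = "chrT", strand = "+",
                          start = 101, end = 200)
  expect_true(detect_mispriming(model, mk_g(13)))
  expect_false(detect_mispriming(model, mk_g(11)))

  # minus strand: window upstream in genomic coordinates, reverse-complemented
  g <- genome_with(400, plants = list(
    list(at = 81, seq = paste(rep("T", 20), collapse = ""))))
  minus <- tibble::tibble(transcript_id = "m", chrom = "chrT", strand = "-",
                          start = 101, end = 200)
  expect_true(detect_mispriming(minus, g))
})

test_that("junction canonicality covers both strands and flags GG..AG", {
  ex <- exons_from_list(list(J = list(c(101, 200), c(401, 500))))
  g_can <- genome_with(700, plants = list(list(at = 201, seq = "GT"),
                                          list(at = 399, seq = "AG")))
  expect_true(junction_canonicality(ex, g_can)$canonical)
  # CT..AC genomic on the minus strand is GT..AG on the transcript strand
  exm <- exons_from_list(list(J = list(c(101, 200), c(401, 500))), strand = "-")
  g_m <- genome_with(700, plants = list(list(at = 201, seq = "CT"),
                                        list(at = 399, seq = "AC")))
  expect_true(junction_canonicality(exm, g_m)$canonical)
  g_bad <- genome_with(700, plants = list(list(at = 201, seq = "GG"),
                                          list(at = 399, seq = "AG")))
  expect_false(junction_canonicality(ex, g_bad)$canonical)
})

test_that("end support windows and polyA motif search behave as specified", {
  g <- genome_with(800, plants = list(list(at = 671, seq = "AATAAA")))
  model <- tibble::tibble(transcript_id = "m", chrom = "chrT", strand = "+",
                          start = c(101, 401), end = c(200, 700))
  cage <- tibble::tibble(chrom = "chrT", start = 101, end = 101, strand = "+")
  polya <- tibble::tibble(chrom = "chrT", start = 695, end = 705, strand = "+")
  r <- end_support(model, cage, polya, g)
  expect_true(r$tss_supported)
  expect_true(r$tts_supported)
  expect_true(r$polya_motif_found)   # AATAAA 24 nt upstream of the 3' end
  # nothing loaded -> unsupported
  r0 <- end_support(model, NULL, NULL, genome_with(800))
  expect_false(r0$tss_supported || r0$tts_supported)
})

test_that("curation applies the class-specific rules and support threshold", {
  g <- genome_with(1200)
  reads <- dplyr::bind_rows(lapply(1:3, function(i)
    tibble::tibble(read_id = paste0("r", i), chrom = "chrT", strand = "+",
                   start = c(101, 481), end = c(200, 640))))
  cat0 <- collapse_reads(reads)
  # a reference elsewhere so the single junction stays unannotated (NNC)
  ref <- exons_from_list(list(Z = list(c(2001, 2100), c(2301, 2400))),
                         gene_id = "GZ", chrom = "chrT")
  g2 <- plant_splice_sites(genome_with(3000, seed = 9), ref)
  cat1 <- classify_isoforms(cat0, ref) |>
    flag_artifacts(g2)
  expect_equal(cat1$class, "NNC")
  sup <- function(n) tibble::tibble(chrom = "chrT", strand = "+",
                                    intron_start = 201, intron_end = 480,
                                    reads = n)
  expect_true(curate(cat1, sup(12))$retained)    # >= 10 supporting reads
  expect_false(curate(cat1, sup(9))$retained)    # below threshold
  # curation is monotone in junction support
  for (n in c(0, 5, 9, 10, 11, 50)) {
    r_lo <- curate(cat1, sup(n))$retained
    r_hi <- curate(cat1, sup(n + 1))$retained
    expect_true(r_hi >= r_lo)
  }
})

test_that("an FSM isoform flagged as mispriming is removed despite canonical junctions", {
  cfg <- simulation_config(seed = 21, n_genes = 8, a_rich_fraction = 1)
  ref <- generate_reference(cfg)
  ab <- tibble::tibble(transcript_id = unique(ref$annotation$transcript_id),
                       abundance = 1)
  rd <- simulate_long_reads(ref$annotation, ref$genome, ab,
                            c(mispriming = 0.5), seed = 21, n_reads = 400,
                            jitter_sd = 0, end_sd = 0, traps = ref$truth$a_rich)
  cat <- build_catalog(rd$reads, ref)
  lab <- setNames(rd$truth$label, rd$truth$read_id)
  maj <- vapply(cat$read_ids, function(ids)
    names(sort(table(lab[ids]), decreasing = TRUE))[1], character(1))
  expect_true(all(!cat$retained[maj == "mispriming"]))
  expect_true(all(cat$mispriming[maj == "mispriming"]))
  # clean full-length isoforms classify FSM and stay in
  expect_true(all(cat$class[maj == "clean"] == "FSM"))
  expect_true(all(cat$retained[maj == "clean"]))
})

test_that("quantification normalises to TPM and applies the tie-break rules", {
  mk_cat <- function() {
    reads <- dplyr::bind_rows(
      lapply(1:3, function(i) tibble::tibble(
        read_id = paste0("a", i), chrom = "chrT", strand = "+",
        start = c(101, 401, 801), end = c(200, 500, 900))),
      lapply(1:3, function(i) tibble::tibble(
        read_id = paste0("b", i), chrom = "chrT", strand = "+",
        start = c(401, 801), end = c(500, 900))))
    collapse_reads(reads)
  }
  cat <- mk_cat()
  one_iso <- cat[1, ]
  reads10 <- purrr::map(1:10, ~ tibble::tibble(
    read_id = paste0("r", .x), chrom = "chrT", strand = "+",
    start = c(101, 401, 801), end = c(200, 500, 900))) |> purrr::list_rbind()
  q1 <- quantify_isoforms(reads10, one_iso)
  expect_equal(q1$tpm, 1e6)

  # equal length, counts 30/70 -> TPM 3e5/7e5
  readsAB <- dplyr::bind_rows(
    purrr::map(1:30, ~ tibble::tibble(read_id = paste0("x", .x), chrom = "chrT",
                                      strand = "+", start = c(101, 401),
                                      end = c(200, 500))),
    purrr::map(1:70, ~ tibble::tibble(read_id = paste0("y", .x), chrom = "chrT",
                                      strand = "+", start = c(1101, 1401),
                                      end = c(1200, 1500))))
  catAB <- collapse_reads(readsAB)
  qAB <- quantify_isoforms(readsAB, catAB) |> dplyr::arrange(count)
  expect_equal(qAB$tpm, c(3e5, 7e5))

  # read compatible with an FSM and its truncation goes to the longer model
  cat2 <- mk_cat()
  truncated_read <- tibble::tibble(read_id = "t1", chrom = "chrT", strand = "+",
                                   start = c(401, 801), end = c(500, 900))
  q2 <- quantify_isoforms(truncated_read, cat2)
  long_id <- cat2$isoform_id[vapply(cat2$exons, nrow, 1L) == 3]
  expect_equal(q2$count[q2$isoform_id == long_id], 1)
})

test_that("classification is total and classes are mutually exclusive over random chains", {
  set.seed(91)
  ref <- random_reference(n_genes = 3, seed = 7)
  classes <- character(0)
  for (i in 1:60) {
    qq <- random_query(ref)
    cl <- classify_isoform(qq, ref)$class
    expect_length(cl, 1)
    expect_true(cl %in% c("FSM", "ISM", "NIC", "NNC", "fusion"))
    classes <- c(classes, cl)
  }
  expect_gt(dplyr::n_distinct(classes), 1)
})
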