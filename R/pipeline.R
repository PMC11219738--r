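#' Simulate a complete synthetic study
#'
#' Orchestrates the generator: reference + genome, long reads with artifacts,
#' time-course isoform counts with usage switches, junction counts for
#' cassette-exon events (a third of events planted with a positive dPsi, a
#' third negative, a third flat — the included/excluded/background split),
#' motif plants in the configured segment of included events, CLIP peaks over
#' the planted sites, and isoform-resolved peptides.
#'
#' @param config a [simulation_config()].
#' @param n_reads long reads to draw.
#' @return list: `reference`, `reads`, `counts`, `junctions`, `event_groups`,
#'   `plant`, `clip_peaks`, `peptides`, `design`, `junction_support`.
#' @export
simulate_dataset <- function(config = simulation_config(), n_reads = 2000L) {
  ref <- generate_reference(config)
  design <- design_table(config$n_days, config$replicates_per_day)
  iso_ids <- unique(ref$annotation$transcript_id)
  abund <- with_seed(config$seed + 10L,
                     tibble(transcript_id = iso_ids,
                            abundance = rlnorm(length(iso_ids), 0, 0.5)))
  reads <- simulate_long_reads(ref$annotation, ref$genome, abund,
                               config$artifact_rates, seed = config$seed,
                               n_reads = n_reads, jitter_sd = config$jitter_sd,
                               end_sd = config$end_sd,
                               traps = ref$truth$a_rich)
  counts <- simulate_counts(ref$annotation, design, seed = config$seed,
                            config = config)

  ev <- ref$truth$skipping_events
  groups <- NULL; junc <- NULL; plant <- NULL; clip <- NULL; genome2 <- ref$genome
  if (nrow(ev) > 0) {
    grp <- with_seed(config$seed + 11L, {
      lab <- rep(c("included", "excluded", "background"), length.out = nrow(ev))
      sample(lab)
    })
    groups <- tibble(event_id = ev$event_id, group = grp)
    days <- sort(unique(design$day))
    dpsi <- setNames(ifelse(grp == "included", 0.3,
                            ifelse(grp == "excluded", -0.3, 0)), ev$event_id)
    plan <- make_psi_plan(ev, days = days, dpsi = dpsi, base_psi = 0.5)
    junc <- simulate_junction_counts(ev, plan, depth = 100L,
                                     seed = config$seed, design = design)
    pl <- plant_motifs(ref$genome, left_join(ev, groups, by = "event_id"),
                       motif = config$motif_plant$motif,
                       segment = config$motif_plant$segment,
                       fraction = config$motif_plant$fraction,
                       seed = config$seed)
    genome2 <- pl$genome; plant <- pl$log
    clip <- simulate_clip_peaks(pl$log, fraction = 1, seed = config$seed)
  }

  proteins <- isoform_proteins(ref$annotation, genome2)
  peps <- simulate_peptides(proteins, abundance_plan = NULL,
                            missingness = config$peptide_missingness,
                            seed = config$seed, design = design)

  # short-read junction support over annotated junctions (uniform, deep)
  jt <- junction_table(ref$annotation) |>
    distinct(.data$chrom, .data$strand, .data$jstart, .data$jend) |>
    transmute(chrom = .data$chrom, strand = .data$strand,
              intron_start = .data$jstart, intron_end = .data$jend,
              reads = 50L)

  list(reference = ref |> modifyList(list(genome = genome2)),
       reads = reads, counts = counts, junctions = junc,
       event_groups = groups, plant = plant, clip_peaks = clip,
       peptides = peps, design = design, junction_support = jt)
}

#' Run the catalog stage end to end
#'
#' Collapse, reference-correct, classify, flag and curate in one call, with
#' the tolerances used throughout: collapse `-d 5 -e 50 -c 3`, junction
#' snapping at the collapse tolerance.
#'
#' @param reads read exon table.
#' @param reference an `isodyn_reference` (or a list with `annotation`,
#'   `genome`, `cage`, `polya`).
#' @param junction_support short-read junction support tibble.
#' @param internal_tol,end_tol,min_cluster,min_junction_reads stage
#'   parameters.
#' @return curated `isodyn_catalog`.
#' @export
build_catalog <- function(reads, reference, junction_support = NULL,
                          internal_tol = 5L, end_tol = 50L, min_cluster = 3L,
                          min_junction_reads = 10L) {
  collapse_reads(reads, internal_tol, end_tol, min_cluster) |>
    correct_to_reference(reference$annotation, site_tol = internal_tol) |>
    classify_isoforms(reference$annotation, site_tol = 0L, end_tol = end_tol) |>
    flag_artifacts(reference$genome, cage_peaks = reference$cage,
                   polya_sites = reference$polya) |>
    curate(junction_support, min_junction_reads)
}

#' Catalog exon table (GTF-shaped) from a catalog
#'
#' @param catalog an `isodyn_catalog`; only retained isoforms are emitted
#'   when curation has run.
#' @param gene_from_matched use the matched reference transcript's gene id
#'   where available.
#' @param annotation reference exon table (for gene lookup).
#' @return exon table with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
catalog_exons <- function(catalog, annotation = NULL, gene_from_matched = TRUE) {
  if ("retained" %in% names(catalog)) catalog <- filter(catalog, .data$retained)
  gene_lookup <- if (!is.null(annotation)) {
    distinct(annotation, .data$transcript_id, .data$gene_id)
  } else NULL
  pmap(list(catalog$isoform_id, catalog$chrom, catalog$strand,
            catalog$exons,
            if ("matched" %in% names(catalog)) catalog$matched
            else vector("list", nrow(catalog))),
    function(id, ch, st, ex, matched) {
      gid <- NA_character_
      if (gene_from_matched && !is.null(gene_lookup) && length(matched) > 0) {
        hit <- gene_lookup$gene_id[gene_lookup$transcript_id %in% matched]
        if (length(hit) > 0) gid <- hit[1]
      }
      tibble(transcript_id = id, gene_id = gid, chrom = ch, strand = st,
             start = ex$start, end = ex$end)
    }) |> list_rbind()
}
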