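# isodyn

Transcript isoforms — not just genes — change across neuronal
differentiation and similar time courses: transcripts start, end and splice
differently day by day, RNA-binding proteins (RBPs) steer which cassette
exons are included, and some of those switches surface as distinct protein
isoforms. isodyn is a desk-scale R pipeline for exactly this kind of study:
it takes long-read exon chains, time-course count matrices, junction counts,
CAGE/polyA tracks, RBP motifs and CLIP peaks, and peptide intensity tables,
and carries them through isoform cataloging, event annotation, differential
usage, positional RBP maps and protein-isoform trend detection. A fully
seeded synthetic-data generator emulates every input with planted ground
truth, so the entire analysis is testable end to end without downloading
anything.

It is written tidyverse-style: every stage takes a data frame and returns a
tibble, results have `tidy()`/`glance()` methods and `autoplot()` figures.

## What it computes

* **Isoform catalog** — collapse reads whose chains agree within 5 nt
  (internal) / 50 nt (ends), keep clusters of ≥ 3 reads; classify each
  isoform against the reference as FSM, ISM, NIC, NNC or fusion by
  junction-chain comparison; flag mispriming (≥ 60% A in the 20 nt past the
  3' end), template switching (non-canonical junctions) and end support
  (CAGE, polyA sites, polyA motif); retain FSM/ISM only if all five checks
  pass, novel classes if every junction is canonical or backed by ≥ 10 short
  reads.
* **Events** — annotate ATSS, ATTS, A5, A3, SES, MES, MEE and IR against the
  gene's hypothetical pre-mRNA (the exon union), and summarise event gains
  and losses between the most up- and down-regulated isoform of each
  switching gene.
* **Differential analyses** — RLE (median-of-ratios) normalization; gene- or
  transcript-level differential expression (significant at padj < 0.05 and
  |log2FC| > 0.59); isoform fraction IF = isoform TPM / gene TPM, with
  differential transcript usage significant at padj < 0.05 and |dIF| ≥ 0.1;
  junction-count inclusion levels Ψ = ((I1+I2)/2)/(((I1+I2)/2)+S) with
  events partitioned into included (ΔΨ > 0.05, FDR < 0.05), excluded
  (ΔΨ < −0.05, FDR < 0.05), background (FDR > 0.5) and unassigned.
* **RBP maps** — the eight positional segments around a cassette exon
  (50-nt exon flanks, 250-nt intron flanks), sliding-window motif scores
  (% of a 50-bp window covered by an IUPAC motif), per-position rank-sum
  tests of included/excluded vs background with per-region minimum p
  (enriched at p < 0.001), CLIP-peak density with per-position Fisher tests
  (p < 0.05), and motif–peak co-occurrence calls.
* **Protein isoforms** — presence filtering (≥ 2/3 replicates in some
  condition), left-censored MNAR imputation (shift 1.8, scale 0.3),
  differential abundance (padj < 0.1, |log2FC| > 0.32), unique-peptide
  isoform LFQ, trend changes (|log2FC_A − log2FC_B| ≥ 1 between isoform
  pairs), the 50-nt NMD rule, and lagged RNA–protein Spearman correlations.

## A worked example

```r
library(isodyn)
library(dplyr)

cfg <- simulation_config(seed = 42, n_genes = 25)
ds  <- simulate_dataset(cfg, n_reads = 1200)

cat <- build_catalog(ds$reads$reads, ds$reference,
                     junction_support = ds$junction_support)
glance(cat)
#> # A tibble: 1 × 3
#>   n_isoforms n_retained classes
#>        <int>      <int> <chr>
#> 1         87         66 FSM:65, fusion:2, ISM:16, NNC:4

usage <- compute_usage(ds$counts$tpm, ds$design)
dtu   <- dtu_test(usage, day_a = 0, day_b = 5)
glance(dtu)
#> # A tibble: 1 × 4
#>   comparison n_isoforms n_significant n_genes_switching
#>   <chr>           <int>         <int>             <int>
#> 1 d0_d5              65            12                 7
```

The catalog row says: 1,200 reads collapsed into 87 isoform models, of
which 66 survive curation — the 65 full splice matches plus novel models
whose junctions are canonical or short-read-supported; the removed rows are
mispriming/template-switch products and truncations with unsupported ends.
The usage table says: of 65 isoforms in genes passing the
expression filters, 12 shift their within-gene fraction significantly
between day 0 and day 5 (|dIF| ≥ 0.1, FDR < 0.05), in 7 distinct genes —
at these defaults the generator plants switches of dIF 0.4 in 30% of genes,
and most are recovered.

Positional RBP maps read the same way as the classic cassette-exon RNA
maps:

```r
es <- simulate_event_set(n_included = 30, n_excluded = 30,
                         n_background = 50, seed = 42)
pl <- plant_motifs(es$genome, es$events, motif = "TTTTAA",
                   segment = "dnIntron5p", fraction = 0.8, seed = 42)
segs <- extract_segments(es$events, pl$genome)
mt <- positional_motif_test(segs, "TTTTAA",
                            es$events[, c("event_id", "group")],
                            rbp = "demoRBP", comparison = "d3_d2")
glance(mt) |> filter(enriched)
#> # A tibble: 1 × 6
#>   comparison rbp     side     segment           min_p enriched
#>   <chr>      <chr>   <chr>    <chr>             <dbl> <lgl>
#> 1 d3_d2      demoRBP included dnIntron5p 0.0000000122 TRUE
autoplot(mt)
```

The motif was planted in the first 250 nt of the downstream intron of 80% of
included events only, and that is the single region-side the test flags.

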