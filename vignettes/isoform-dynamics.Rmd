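---
title: "Isoform dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodyn)
library(dplyr)
```

isodyn is a desk-scale pipeline for transcript-isoform dynamics across a
differentiation-style time course: long-read isoform cataloging and curation,
alternative transcription/splicing event annotation, differential expression
and usage, positional RNA-binding-protein (RBP) maps around cassette exons,
and protein-isoform trend detection from unique peptides. Every stage is
exercised against a seeded synthetic-data generator with planted ground
truth, so the whole analysis is testable without any external download. This
vignette explains the models behind each stage, the parameters that matter,
and the choices made where the design was genuinely open.

## Coordinates and data shapes

All tables are tibbles. A transcript model is an *exon table*: one row per
exon with `transcript_id`, `chrom`, `strand`, `start`, `end`. Coordinates are
1-based and closed, the GTF/GenomicRanges convention, because that is what R's
`substring()` and the Bioconductor stack use natively; BED import/export
converts to 0-based half-open at the file boundary (`write_bed()`,
`read_bed()`). A genome is a named character vector of chromosome sequences
over A/C/G/T (no N handling).

## The isoform catalog

`collapse_reads()` merges reads whose exon chains agree within 5 nt at every
internal boundary and 50 nt at the two transcript ends (single linkage), keeps
clusters of at least 3 reads, and takes per-boundary medians as the
representative — the parameterisation of standard long-read collapse tools
(`-c 3 -d 5 -e 50`).

Because a median of jittered boundaries can sit a base or two off the true
splice site, the pipeline wrapper `build_catalog()` runs
`correct_to_reference()` between collapsing and classification: each internal
boundary is snapped to the nearest annotated donor/acceptor when within the
collapse tolerance (5 nt), mirroring reference-guided correction in long-read
pipelines. Boundaries further away are genuinely novel and kept. The snap
tolerance deliberately equals the collapse boundary tolerance; it was fixed
before any end-to-end evaluation and is not tuned.

`classify_isoforms()` assigns one of five classes by junction-chain
comparison: **FSM** (chain equals a reference transcript), **ISM** (contiguous
proper sub-chain), **fusion** (annotated junctions from two or more
non-overlapping gene loci), **NIC** (all sites annotated, new combination),
**NNC** (at least one novel site). The precedence FSM > ISM > fusion >
NIC > NNC makes the function total: a chain that joins two loci necessarily
contains a novel connecting junction and would otherwise be NNC. Mono-exon
reads are FSM when contained in a mono-exon reference within the end
tolerance, otherwise NNC; annotation formats rarely pin this case down, so the
conservative choice is to treat unplaceable mono-exon models as novel.

Artifact flags follow the field's screening rules:

* **Mispriming** — at least 60% adenine in the 20 nt immediately 3' of the
  transcript end, on the transcript strand. The window length is a choice (the
  rule is usually quoted without one); 20 nt is the smallest window in which a
  60% threshold is meaningful at single-base resolution.
* **Template switching** — any junction whose transcript-strand intron
  boundaries are not GT..AG, GC..AG or AT..AC.
* **End support** — TSS within 50 nt of a CAGE peak, TTS within 50 nt of a
  polyA-site cluster, and a polyA motif (default AATAAA/ATTAAA) within 50 nt
  upstream of the TTS. The windows are choices; "within" and "close to" are
  the usual, unnumbered phrasings.

`curate()` then retains FSM/ISM isoforms only when none of the five checks
fails, and retains NIC/NNC/fusion isoforms when they are not mispriming
products and every junction is canonical or supported by at least 10 short
reads. The template-switch criterion for novel classes overlaps the
canonical-or-supported rule; we apply canonical-or-supported as the operative
test, which is strictly the stronger reading.

`quantify_isoforms()` replaces EM-based assignment with a deterministic
best-match rule (most shared junctions, then longest compatible isoform, then
smallest id) — synthetic reads are unambiguous by construction, and the
substitution keeps quantification reproducible read-by-read. TPM is
`(count/length) / sum(count/length) * 1e6`.

## Event annotation

`build_premrna()` forms the gene's hypothetical pre-mRNA (the union of all
exons). `annotate_events()` labels eight event types: ATSS, ATTS, A5, A3, SES,
MES, MEE, IR, with A5/A3 named in transcript orientation (A5 = alternative
donor). Three refinements prevent spurious labels on perfectly ordinary
structures:

* A5/A3 calls require the two alternative boundary exons to overlap;
  otherwise every exon-skipping junction (shared donor, different acceptor
  exon) would also be reported as A3.
* Exons participating in a detected MEE pair are excluded from SES/MES runs;
  otherwise each isoform of an MEE pair would also be "skipping" its
  partner's exon.
* MEE requires a pairwise witness with overlapping flanking exons on both
  sides plus the absence of any isoform containing both exons — the pairwise
  reading of mutual exclusivity, with the global "no isoform carries both"
  guard.

ATSS/ATTS use a 50-nt outer-boundary tolerance (matching the collapse end
tolerance) so closely spaced alternative ends are not called. Labels are
symmetric where the definition is symmetric: two isoforms with 5' ends 300 nt
apart each carry ATSS, at their own coordinates. `gain_loss_summary()`
therefore compares event *instances* (type at coordinates) between the
most-up- and most-down-regulated isoform of each switching gene; a switch
between two alternative starts registers as both a gain and a loss of ATSS.
Fractions are each type's share of all gains (or all losses) in a comparison.

## Differential analyses

`rle_normalize()` is median-of-ratios scaling (median computed in log space,
so even-length medians average geometrically, as in the reference
implementation). `dge()` uses `log2FC = log2((mean_B+1)/(mean_A+1))` and a
Welch t-test on `log2(normalized+1)` with BH correction; significance is
`padj < 0.05` and `|log2FC| > 0.59` (a 50% change). The negative-binomial
Wald machinery and shrinkage of full-scale tools are deliberately not
reimplemented: the decision thresholds are the point here, and acceptance is
calibration- and recovery-based. One consequence worth knowing: at three
replicates the Welch test detects roughly half of 4-fold changes at typical
dispersion, where a moderated NB test would do better. Transcript-level
differential expression is the same function applied to an isoform-level
matrix.

`compute_usage()` keeps genes with mean TPM > 1 at every day and at least two
detected isoforms, then `IF = isoform TPM / gene TPM` per sample. Within a
gene and sample, IF sums to one; `dIF = mean IF(B) - mean IF(A)` sums to zero
over a gene. `dtu_test()` tests logit-transformed IF (clamped to
[0.01, 0.99]) with a Welch t-test, BH across isoforms; significance needs
`padj < 0.05` *and* `|dIF| >= 0.1`.

`psi_and_classify()` estimates inclusion from junction counts with the 2:1
correction — two inclusion junctions, one skipping junction:
`Psi = ((I1+I2)/2) / (((I1+I2)/2) + S)` — and tests replicate Psi with a
rank-sum test: exact permutation enumeration when both groups have at most 4
replicates, tie-corrected normal approximation otherwise. Events are
partitioned with the printed thresholds: included (`dPsi > 0.05`,
`FDR < 0.05`), excluded (`dPsi < -0.05`, `FDR < 0.05`), background
(`FDR > 0.5`), else unassigned. A structural limitation follows from the
exact test: with 3 replicates per group the smallest attainable two-sided
p-value is 2/choose(6,3) = 0.1, so no event can reach FDR < 0.05 at
triplicates — regulated classes require more replicates (the exact test
first reaches p < 0.05 at 4 per group) or an externally supplied event
classification. The RBP-map stage accepts either.

## Positional RBP maps

`extract_segments()` cuts the eight standard segments around a cassette exon:
the terminal 50 nt of the upstream exon, first/last 250 nt of the upstream
intron, first/last 50 nt of the target exon, first/last 250 nt of the
downstream intron, and the first 50 nt of the downstream exon. Segments are
clipped to the underlying feature (a 300-nt intron yields two 250-nt segments
overlapping by 200), and sequences are transcript-oriented so position 1 is
always the 5'-most base.

`scan_motif()` marks every base inside at least one overlapping match of an
IUPAC consensus (U = T, degeneracy honoured). The motif score at a position is
the percentage of covered bases in a 50-bp window centred there; at segment
edges the window is clipped and the number of *available* bases is the
denominator — the cited tools do not document their edge convention, and the
available-bases choice avoids deflating scores near boundaries.
`positional_motif_test()` compares regulated (included or excluded) versus
background events per position with the two-sided rank-sum test and summarises
each region by its minimum p-value; a region is enriched at min-p < 0.001.
Two-sided is the conservative choice since the direction of a positional
effect is not specified a priori; the alternative is configurable in the
underlying test. `peak_density_test()` does the same with CLIP peak
occupancy per position and Fisher's exact test at 0.05. `rbp_summary()` flags
co-occurrence when both calls land in the same region.

Minimum p-values over ~1,100 correlated positions are a multiplicity-naive
summary; the null-calibration acceptance check (no planting, 100 seeds)
verifies empirically that the min-p < 0.001 rule stays quiet on null data at
the event-set sizes used here (12 regulated vs 20 background and up).

## Protein isoforms

`presence_filter()` keeps proteins observed in at least 2 replicates of some
condition. `impute_mnar()` draws missing cells per sample from
`Normal(mean - 1.8*sd, (0.3*sd)^2)` of that sample's observed log2
intensities — the standard left-censored MNAR model; draws are seeded and
observed values are never touched. `differential_protein()` is a Welch test
with BH, significant at `padj < 0.1` and `|log2FC| > 0.32` (a 25% change);
the moderated empirical-Bayes variance of proteomics suites is intentionally
not re-derived, mirroring the DGE substitution.

`assign_peptides()` discards peptides matching more than one isoform, sums
fractionated intensities, and totals per isoform and sample; isoforms with no
unique peptide are reported unquantifiable rather than imputed.
`trend_differences()` compares isoforms only through the *difference of their
log2 fold changes* across day pairs (direct intensity comparisons between
different peptides are invalid); a pair is a trend change when any
comparison's |difference| reaches 1. Fold changes are computed on
observed-values-only means — whether the upstream study used imputed or
observed data for this step is not stated, and observed-only is the choice
that cannot manufacture a trend from imputation; the LFQ input is accepted
either way. The per-isoform max-normalisation used for plotting does not
affect fold-change differences.

`predict_nmd()` applies the 50-nt rule with the longest ATG-initiated ORF as
the coding-region stand-in: sensitive when the stop codon's first base lies at
least 50 nt upstream (in transcript coordinates) of the final base of the
penultimate exon; exactly 50 nt is sensitive; mono-exon transcripts are
insensitive. Ties between equal-length ORFs go to the 5'-most start.
`rna_protein_correlation()` computes Spearman's rho between RNA and protein
log2 fold changes for every pair of day comparisons (lagged pairs included),
restricted by default to features differentially expressed somewhere.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
dials. The emulated design is a 6-day course with 3 replicates per day.
Gene models (default 50 genes, 5–8 exons of 90–250 nt, introns 350–900 nt)
carry planted events drawn from all eight types, with cassette exons
over-represented because they feed the junction-count and RBP stages. Every
junction gets canonical GT..AG sites written into the genome; every transcript
end gets an AATAAA ~20 nt upstream and a deliberately non-A-rich 20-mer
downstream, so clean reads are never mistaken for mispriming; 30% of genes
carry a 20-nt, 70%-adenine intronic tract 3–48 nt downstream of an internal
exon as a mispriming trap. CAGE and polyA tracks sit at the true ends
± 10 nt.

Reads jitter internal boundaries with sd 1 nt and ends with sd 10 nt.
Artifact classes: truncations drop 5' exons; mispriming reads end immediately
upstream of the trap; template-switch reads shift one acceptor 8–20 nt into
the intron at a per-isoform fixed position (so artifact products form
clusters, as real RT hotspots do) with the shifted dinucleotide checked to be
non-AG; fusions concatenate the chains of nearest same-strand gene
neighbours. Counts are negative binomial with variance `mu + 0.05 mu^2`
(no noise model is given for the real data; 0.05 is a typical bulk RNA-seq
dispersion), usage switches move a planted isoform pair's fractions by 0.4
linearly across the course, and library sizes vary uniformly by ±25%.
Junction counts are binomial at depth 100 around planted inclusion levels.
Peptides are tryptic (cleave after K/R, not before P, 7–30 aa retained),
log-normally detectable with fixed per-peptide fraction profiles, and
missingness is left-censored (logistic dropout centred at the lower
`missingness` quantile of log-intensity).

What the generator does *not* emulate: base-level sequencing errors and
quality scores, positional coverage bias, ambiguous multi-mapping reads,
correlated replicate structure, real codon usage and ORF architecture
(random-genome ORFs are short, so genome-derived proteins are toy-sized;
`synthetic_protein_pair()` provides realistic shared/unique-segment pairs for
the peptide stage), and real RBP motif composition. Passing tests therefore
demonstrate correctness of the decision rules and estimators under the stated
noise models, not performance on real sequencing data.

## Problem sizes and tests

The test-suite and acceptance scales are: 500 random genes for the
classification oracle, 2,000 reads for curation, 50 instances per event type,
500 null genes and 100 seeds for DTU calibration/power, 110-event sets for
the RBP maps with 100 null seeds at 32 events, 10,000 imputation draws, 1,000
random structures for the NMD oracle, and a 200-gene end-to-end run. These
sizes give stable pass/fail behaviour for the calibration bounds while
keeping the default test run comfortably fast on one CPU.

## Known limitations

* The substituted location tests (Welch, rank-sum) trade power for
  transparency; effect-size thresholds are unchanged, so calls are
  conservative relative to moderated estimators at small n.
* The exact rank-sum ceiling makes Psi regulation classes unreachable at
  triplicates (see above).
* Longest-ORF is a stand-in for a trained coding-potential model; NMD calls
  on transcripts with unusual 5' leaders may differ.
* Mono-exon classification and the 20-nt mispriming window are conventions,
  stated above, not field standards with citable numbers.
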