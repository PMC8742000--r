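---
title: "MeD-seq differential methylation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MeD-seq differential methylation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medseqr)
```

## The assay and what the pipeline computes

MeD-seq profiles DNA methylation by digesting genomic DNA with LpnPI, a
methylation-dependent restriction enzyme: only methylated recognition
sites are cut, and each cut releases a 32-bp fragment with the
recognition site a fixed distance from the fragment ends. Sequencing
those fragments therefore samples the methylome in proportion to
per-site methylation — the more often a site is methylated across the
cells in a sample, the more fragments it emits. After adapter trimming
and a geometric sanity filter (the recognition site must sit 13–17 bp
from one read end), each read is assigned to the recognition site(s) it
covers, giving a site × sample count matrix. Everything downstream is
count statistics:

1. **Per-site testing.** For a two-group contrast, counts are pooled
   within each group and each site is tested with a Pearson chi-squared
   on the 2×2 table (reads at the site vs all other reads, per group),
   1 df, no continuity correction; when any marginal is zero the test
   returns statistic 0 and p 1. Bonferroni correction is applied across
   all sites with nonzero pooled count. A site is *significant* when
   its adjusted p is below `alpha` and its RPM fold change (below) is
   beyond the threshold in either direction.
2. **Sliding-window DMR detection.** Each significant site seeds a
   window that collects same-direction significant sites among at most
   50 neighbouring catalogue sites per side, within 1000 bp of the seed
   position. A candidate survives if it has at least 10 significant
   sites spanning at least 100 bp. Candidates sharing any site are
   merged, and counts, fold change and p are recomputed over *all*
   catalogue sites in the merged span. Every emitted DMR satisfies all
   thresholds.
3. **Fold change.** `FC = (RPM_A + pc) / (RPM_B + pc)` with
   `RPM = 1e6 · count / total` and a pseudocount `pc = 0.5` RPM that
   keeps the ratio finite at empty sites; two-fold is the general
   threshold, five-fold the threshold used when selecting rows for
   clustering. RPM makes fold changes library-size invariant.
4. **Group-unique DMRs.** With one-vs-rest contrasts (e.g. BAP1 vs
   SF3B1+EIF1AX), a DMR is *unique* to a group when it was emitted by
   that group's contrast and shares zero bp with any DMR from any other
   contrast.
5. **Expression integration.** Genes are differentially expressed when
   `|log2FC| ≥ 1.5` (non-strict) and `FDR < 0.05` (strict). A DMR
   overlapping a gene's promoter or gene body is *concordant* when
   hypomethylated promoter or hypermethylated gene body meets an
   upregulated gene, or hypermethylated promoter or hypomethylated gene
   body meets a downregulated gene. The headline "associated" fraction
   is reported against both denominators: all DMRs, and gene-overlapping
   DMRs only (intergenic DMRs cannot be matched at all).
6. **Clustering.** DMR × sample RPM values are Z-scored per row
   (population SD) and samples are clustered with complete-linkage
   agglomeration under cityblock (L1) distance.

Regions are built from a gene annotation as: promoter = TSS ± 1 kb,
gene body = 1 kb downstream of the TSS to the TES (on the gene's
strand), CpG islands pass through as given. All internal coordinates
are 0-based half-open; BED is read natively, GTF is converted on
ingestion. A site belongs to a region when its motif start lies in
`[start, end)`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | significance after correction |
| `correction` | Bonferroni (sites), BH (regions) | multiple-testing procedure |
| `fc_threshold` | 2 (general), 5 (clustering) | minimum RPM fold change |
| `min_sites` | 10 | significant sites per DMR |
| `min_span_bp` | 100 | minimum DMR span |
| `max_neighbors` | 50 | catalogue sites examined per side of a seed |
| `max_distance_bp` | 1000 | window reach from the seed position |
| `pseudocount` | 0.5 RPM | fold-change regularisation |
| `tss_flank` | 1000 bp | promoter half-width |
| `min_offset`, `max_offset` | 13, 17 bp | read-filter band |
| `lfc_threshold`, `fdr_threshold` | 1.5, 0.05 | DE gene call |

The recognition motif defaults to `CCDG` (IUPAC D = A/G/T), scanned on
both strands (the reverse complement `CHGG` is recorded as a
minus-strand site); it is an argument everywhere it is used, so another
methylation-dependent enzyme's site can be substituted.

## The synthetic-data generator

No patient data ships with the package; every analysis runs on
synthetic inputs with machine-readable ground truth (a JSON manifest of
planted DMRs, DE genes, and library sizes).

**Genome.** Background sequence is uniform over A/C/G/T, scrubbed of
chance motif occurrences, and concrete `CCAG`/`CCTG` instances are
planted at jittered intervals around the target spacing (default one
site per 100 bp). Planted instances are kept as singleton sites: `CCGG`
is avoided because it is its own reverse-complement match (one CpG
would yield two catalogue sites), and a `G` immediately 3′ of an
instance is mutated away because it would create an overlapping
minus-strand occurrence. The recorded site list is produced by
re-scanning the final sequence, so the scanner round-trip is exact by
construction.

**Methylation and counts.** Methylation probability is treated as
fragment-emission probability (hemi-methylation is not modelled — the
enzyme requires full methylation, and the assay gives no hemi signal).
Counts for sample *s* at site *i* are drawn with expectation
`L_s · p_i / Σ p` — the multinomial rate implied by sequencing a fixed
number of fragments — with negative-binomial noise (`size =
1/dispersion`, Poisson at 0). Defaults emulate a desk-scale cohort:
8 samples per group, 100 000 filtered reads per sample, dispersion
0.05, baseline methylation 0.1, planted DMRs of 12 consecutive sites at
fold change 4. Note that planting raises a group's total probability
mass, so the *realised* count-level fold change is slightly below the
planted ratio (by the factor `Σ p_B / Σ p_A`); simulations keep the
planted mass small so this dilution stays within a few percent.

**Digest reads.** Each simulated read is a 32-bp window around one
sampled site, with the motif placed uniformly over the offsets that
leave it 13–17 bp from one end — simulator and filter are mutually
consistent by construction, which the suite asserts (100 % of
error-free reads pass). Reads longer than 32 bp are 3′-padded with the
adapter prefix, exactly what a sequencer reading through a short insert
produces; the trimmer removes the longest read suffix that matches an
adapter prefix (minimum overlap 3). Sites too close to a chromosome end
to allow every placement are excluded from emission.

**Expression.** For a controllable fraction of the genes overlapping
planted DMRs, log2 fold changes are drawn with the sign the concordance
rule expects and FDR < 0.05; all other genes get null log2FC (|x| ≤
1.2) and FDR ≥ 0.05. This makes the integration stage's recovered
associated-fraction directly comparable to the planted fraction.

What the generator does *not* emulate: sequencing errors, PCR
duplicates, copy-number alterations (which in real tumours inflate or
deflate counts regionally and can fake DMRs), tumour purity, and
per-sample biological heterogeneity beyond a single dispersion
parameter. Passing tests therefore demonstrate correctness of the
pipeline's logic under its own model, not robustness to those real-data
artefacts; on real data the expression-integration step is the main
guard against copy-number-driven false positives.

## Numerical and design choices

- **Contingency table.** "Chi-squared on read counts" is realised as
  (reads in site/region, all other reads) per pooled group — the
  natural 2×2 for count enrichment; it is stated explicitly so results
  are reproducible. Pooling across samples within a group means
  per-sample dispersion does not enter the test — a documented
  limitation shared with the pooled design it implements.
- **Correction families.** Sites with zero pooled count (untestable a
  priori) are excluded from the Bonferroni family; region tests are
  corrected within each region kind (BH by default for regions,
  Bonferroni for the genome-wide site scan).
- **Offset semantics.** The filter band counts bases strictly before
  the motif start (5′) or strictly after the motif end (3′), inclusive
  bounds 13 and 17. Whether the original measured to the motif start,
  centre or CpG is ambiguous; start/end semantics are fixed here and
  the simulator uses the same definition.
- **Multi-mapped reads** count once per matching location (unweighted);
  a `fractional` option (1/n per location) exists but is off by
  default. The toy mapper is exact-match because synthetic genomes are
  error-free; real alignments enter through SAM/BAM ingestion
  (secondary alignments included, supplementary and unmapped excluded).
- **Window semantics.** "Within 1000 bp" is measured from the *seed*
  site's position, not from the previously included site; significant
  sites within the budget are collected regardless of non-significant
  gaps. Both are one reading of the under-specified sliding-window
  description; both are configurable.
- **Merging.** Overlapping candidates from adjacent seeds are merged
  (transitive closure over shared sites) and re-tested on the merged
  span — without this, every member of a strong cluster would seed its
  own near-duplicate DMR.
- **Uniqueness.** "Unique" is implemented as zero-bp overlap across
  contrasts. A consequence worth knowing: a very strong private DMR in
  group A echoes as mild hypomethylation in the other one-vs-rest
  contrasts (the rest-pool contains A), and once that echo passes the
  two-fold gate (planted ratio above ~3) the zero-overlap rule excludes
  the DMR from every unique set. The `analysis/` workflow plants a
  moderate tier (2.5-fold) for the uniqueness analysis and a strong
  tier (8-fold) for clustering for exactly this reason.
- **Z-scores** use the population (divide-by-n) SD; zero-variance rows
  are dropped with a warning. Clustering delegates to
  `stats::hclust(dist(method = "manhattan"), "complete")`; the test
  suite checks it against a brute-force O(n³) agglomerative oracle on
  small sample sets. With continuous RPM data, distance ties (the only
  source of platform-dependent order) have measure zero.
- **DE boundary.** `|log2FC| ≥ 1.5` is taken as printed (a log2 value,
  not linear FC 1.5); the threshold is an argument for users who read
  it the other way.
- **Intro vs Methods significance.** Where source descriptions of this
  assay family differ on the FDR cutoff, the defaults here are
  Bonferroni α = 0.05 for the site scan and BH 0.05 for regions; both
  are configurable.

## Problem sizes

Tests and the acceptance script run on catalogues of 200–2 600 sites,
6–8 samples per group and 10⁵ reads per sample; the null-calibration
check uses 20 independent simulations. These sizes were chosen so the
chi-squared is deep in its asymptotic regime at every tested site
(pooled counts in the hundreds) while the whole suite stays fast.

## A worked run

```{r example, eval = FALSE}
library(medseqr)

genome <- generate_toy_genome(1, 50000, 100, seed = 7)
profile <- plant_methylation(genome, c("A", "B"), n_dmrs = 3,
                             dmr_sites = 12, effect_fc = 4,
                             baseline = 0.1, seed = 3)
counts <- simulate_count_matrix(profile, samples_per_group = 6,
                                mean_library_size = 1e5,
                                dispersion = 0.05, seed = 11)
dmrs <- detect_dmrs(counts, group_contrast(counts, "A"), dmr_config())
dmrs[, c("chrom", "start", "end", "n_significant", "fc", "direction")]
```

The numbered scripts under `analysis/` run the full study — simulation,
read processing, DMR detection, unique calling, expression integration
and clustering — and write their tables under `results/`.

## Known limitations

Pooled testing ignores per-sample variability, so with many samples per
group the per-site p-values are anti-conservative relative to a
replicate-aware model (beta-binomial or GLM); the Bonferroni correction
and the fold-change gate absorb this at the DMR level in the simulated
regimes the suite checks, but a replicate-aware per-site test would be
the natural extension. Copy-number effects are out of model entirely.
The exact-match mapper is for synthetic genomes only — real data should
arrive as external alignments.
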