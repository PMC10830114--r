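---
title: "Methods: DMR calling, remethylation metrics and co-purification proteomics"
author: "remethylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR calling, remethylation metrics and co-purification proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(remethylome))
```

# Scope

`remethylome` implements the desk-scale statistical layer of a
whole-genome bisulfite (WGBS) study of DNA-methyltransferase-deficient
mouse bone marrow: genotypes lacking DNMT3A ("3a KO"), DNMT3B ("3b KO"),
both ("DKO"), or carrying the dominant-negative DNMT3A R878H mutation,
plus retroviral "addback" samples in which a methyltransferase cDNA is
re-expressed in deficient cells. The package covers five analysis arms —

1. two-group DMR (differentially methylated region) calling on per-CpG
   methylation matrices;
2. DMR-centric summaries: passive methylation matrices, unified DMR
   sets, aggregate "canyon" profiles, annotation-class means, and
   floxing efficiency estimated from sequencing-coverage dropout over
   excised (loxP-flanked) intervals;
3. quantification of DMR remethylation after addback ("correction
   extent");
4. splice-junction isoform usage and its two-group comparison
   (Dnmt3a1 vs Dnmt3a2, Dnmt3b1 vs Dnmt3b3);
5. a PSM-level proteomics ratio-normalization pipeline feeding
   co-purification stoichiometry estimates.

Everything runs on a built-in synthetic-data generator with recorded
ground truth, so each stage is testable end to end without external
downloads. Read alignment, bisulfite mapping, PSM identification and
all wet-lab steps are out of scope.

# The DMR model

## Data model

Per-CpG methylation is stored in a `CpGMethylome`, a
`RangedSummarizedExperiment` with integer assays `meth` (methylated
reads) and `depth` (total reads) over strand-collapsed CpG dinucleotides
(one record per CpG, 0-based half-open on disk). The methylation
fraction is `beta = meth / depth`, defined only where `depth > 0`;
missing data are encoded as depth 0, never as sentinel betas.

## Calling procedure

`callDMRs(methylome, A, B)` implements the published filter criteria
with a native segmentation stage:

1. **Difference signal.** Per CpG, mean beta over covered samples
   (depth ≥ 1) of each group; CpGs covered in fewer than the required
   number of samples per group (default: all) are dropped.
2. **Segmentation.** CpG runs are broken where neighbouring CpGs are
   more than `max_cpg_spacing` (default 300 bp) apart. Each run is
   recursively split at the boundary maximizing the difference of the
   two segment means of the difference signal, provided both children
   keep at least `min_cpg` CpGs and the split achieves a relative
   variance reduction above `var_reduction_min` (default 0.01). Leaves
   are candidates. This is a binary-segmentation scheme in the spirit
   of the segmentation used by common WGBS callers; it makes no claim
   of byte-compatibility with any external tool — the defining
   contribution here is the published filter set, not a particular
   segmentation implementation.
3. **Testing.** Each candidate is tested by a two-sided Mann–Whitney U
   comparing the pooled per-sample per-CpG betas of the two groups
   (exact when the pooled size is ≤ 50 with no ties; otherwise the
   normal approximation with mid-rank ties). The Mann–Whitney statistic
   is distribution-free and well-behaved at the small group sizes used
   here (3–9 samples per group).
4. **Filtering.** Benjamini–Hochberg across all tested candidates of
   one comparison; retained DMRs must have `n_cpg >= 10`,
   `|mean_A − mean_B| >= 0.2` and `q < 0.05` (all tunable through
   `dmrParams()`).
5. **Merging.** Retained same-direction DMRs within 50 bp are fused;
   CpG counts are summed, group means recombined CpG-weighted, and the
   merged p/q is the minimum of the parts. Merging across direction is
   refused: a hypomethylated and a hypermethylated region 40 bp apart
   are biologically distinct events.

A DMR is annotated `hypo` when group B (the test genotype) lost
methylation relative to group A (the reference, typically WT).

## DMR summaries

* `passiveMethylation()` evaluates a fixed DMR set in any sample
  without re-calling ("passive plotting"). The per-DMR mean is
  unweighted across CpGs by default, matching per-CpG heatmap
  semantics; depth weighting is available and announced, never silent.
  Whether the original analysis weighted by coverage is not stated;
  both modes are provided.
* `unifiedDMRSet()` merges several comparisons' DMR sets by interval
  union, fusing overlapping or book-ended intervals only — deliberately
  *not* the 50-bp gap rule, which belongs to calling time. Provenance
  (contributing comparisons) is kept per unified interval.
* `canyonProfile()` scales every DMR body to a fixed number of bins
  (default 20) with absolutely-binned flanks (default 2 kb in 10 bins)
  and reports the per-bin mean beta per genotype; each CpG occurrence
  contributes to exactly one bin of its window.
* `floxingEfficiency()` estimates the excision fraction as
  `1 − meanDepth(floxed) / meanDepth(control)`, clamped to [0, 1].
  The default control is same-width flanks on each side of each floxed
  interval; a reference (non-floxed) methylome can be used instead,
  rescaled by the genome-wide depth ratio — the published analysis does
  not state which control it used, so both are offered.

## Addback correction extent

Per DMR, `correctionExtent()` computes
`(β_addback − β_KO) / (β_WT − β_KO)`: 0 means no change from the
knockout, 1 means remethylation to WT level. DMRs whose WT−KO contrast
is below `epsilon` (default 0.05) are masked rather than divided —
near-zero denominators would otherwise blow the ratio up; the masked
count is always reported. Extents are not clipped: values above 1
(methylation beyond WT) are preserved and reported as such.

# Isoform usage

Usage is junction-based: `u = J_inc / (J_inc + J_alt)`, where the
alternative junctions are aggregated by sum, or by mean for the
Dnmt3b1 model (several exon-21–24 junctions support the full-length
isoform). Group comparisons pool (sum) counts across samples within
each group and apply a two-sided Fisher's exact test
(minimum-likelihood rule) to the 2×2 table. A mean-aggregated pooled
count can be non-integer; it is rounded half-to-even before testing and
the rounding is logged — how the original analysis reconciled a mean
count with an exact test on integers is not stated, so the
reconciliation is made explicit here. Odds ratios use the Haldane 0.5
correction when a zero cell exists (flagged).

# Proteomics ratio normalization

The pipeline mirrors a PSM-level ratio workflow for affinity-purified
samples:

1. **log2FC conversion.** Each precursor's intensity is divided by its
   average intensity across the samples in which it was observed
   (arithmetic mean by default — the most literal reading of "average
   precursor intensity"; a geometric-mean mode is provided).
2. **Recursive Dixon outlier removal** within each (sample, peptide)
   PSM group with more than two PSMs. The ratio variant follows the
   standard schedule by group size (r10 for n ≤ 7, r11 for 8–10,
   r21 for 11–13, r22 for 14–30); critical values at α = 0.05 are
   embedded from the standard two-tailed 95% table (Rorabacher 1991),
   with the classic one-sided Dean & Dixon Q95 table available as an
   option for n ≤ 7. Above n = 30 the filter refuses to run unless
   explicitly told to reuse the n = 30 critical value. Recursion stops
   when nothing is removed or fewer than 3 values remain, so at most
   n − 3 values are ever removed.
3. **Median roll-ups**: PSM → peptide → protein, per sample.
4. **Mixture mode alignment.** A two-component Gaussian mixture is
   fitted to each sample's protein log2FC by expectation-maximization
   (deterministic: quantile initialization at the 25th/75th
   percentiles, log-likelihood tolerance 1e-8, at most 1000
   iterations). The global mode of the fitted density — located on a
   4096-point grid over the data range ± 1 SD and refined by
   golden-section search — is shifted to zero. "Maximum likelihood
   centered at zero" is interpreted as the mode of the fitted density
   (its maximizer); aligning on the dominant component mean instead is
   available as an option. A degenerate fit (component weight < 1e-3 or
   variance < 1e-8) falls back to a single Gaussian, logged.
5. **Trimmed-SD scaling.** Per sample, the SD is computed over proteins
   lying inside both 5th–95th percentile windows (their own log2FC and
   their intensity); each sample is scaled to the median of those SDs.
   Whether the two trim windows should be intersected or unioned is
   ambiguous; intersection is the default and union is available.
6. **Intensity calibration**: `I' = I · 2^d`, `d` being each
   protein-sample's total log2FC displacement through alignment and
   scaling. Protein raw intensity is the summed PSM intensity.
7. **Stoichiometry**: length-normalized abundance ratios relative to a
   reference (bait) protein, `(A_p/L_p)/(A_ref/L_ref)`, using
   calibrated intensities (or peptide counts). Summed intensity scales
   with amount × length, so dividing by length yields a molar measure,
   the same logic as iBAQ-style quantities.

# The synthetic-data generator

`simulateMethylome()` emulates the statistical structure the analysis
assumes; its defaults are the study conditions and are not tuned
per-test:

* **Genome layout**: 400 CpG clusters over a 2-Mb single chromosome,
  each cluster labeled with an annotation class (CpG island, shore,
  shelf, promoter, gene body, enhancer, open sea) with typical
  mammalian baseline betas (islands/promoters low, 0.10–0.15; gene
  bodies/open sea high, 0.80–0.85). Cluster size is fixed at 15 CpGs by
  default — so planted DMRs carry exactly 15 CpGs, the regime the
  recovery analyses quote — with a Poisson-jitter option.
* **Effects**: 60 of the clusters (those with baseline ≥ 0.5, since
  focal hypomethylation needs methylation to lose) carry genotype
  effects with severity ordering DKO (Δβ 0.5) > 3a KO (0.4) >
  R878H (0.2) > 3b KO (0.1). The ordering is the observed biology; the
  magnitudes are package choices with the 3a KO value set to the 0.4
  used throughout the recovery analyses.
* **Counts**: depth per CpG per sample is negative binomial with mean
  18.6 (the study's mean genome coverage) and dispersion 0.2
  (Var = μ + 0.2 μ²); methylated counts are beta-binomial with
  overdispersion ρ = 0.05. Neither dispersion is reported for the real
  data; these are conventions of WGBS simulation, chosen once as
  realistic values, and both are config knobs.
* **Group sizes** default to the published cohort: WT 9, 3a KO 4,
  3b KO 3, DKO 3, R878H 6.
* **Addback** samples draw from `μ_KO + c · (μ_WT − μ_KO)` at true-DMR
  CpGs (correction level `c`), baseline elsewhere.
* **Floxing** thins depth binomially to `1 − efficiency` (default
  0.96) inside floxed intervals and resamples methylated counts
  hypergeometrically, preserving beta in expectation.
* **Junction counts** are binomial around the target usage
  (defaults 0.886 / 0.885, the regime of the Dnmt3a1 analysis).
* **PSM tables** follow
  `log2 I = protein base + peptide offset + scale·(effect + noise) +
  sample shift`, with 20% of proteins varying biologically
  (per-sample N(0, 1) deviations) so every sample's log2FC distribution
  is a two-component mixture whose dominant mode sits at the sample
  shift; a configurable fraction of precursor-sample cells is displaced
  by 8 PSM-SDs with random sign (outliers). Six PSMs per peptide and
  the 8-SD displacement are deliberate: Dixon's critical values at
  n ≤ 4 are so large (0.829 at n = 4) that a 4-SD outlier is
  undetectable by construction.

All generators are deterministic given their seed; the workflow derives
named substreams from one root seed. What the generator does **not**
emulate: read-level artifacts (bisulfite conversion failure, mapping
bias, strand asymmetries), spatial correlation of methylation beyond
the planted blocks, annotation classes of realistic size distributions,
chromatography/retention-time structure in the proteomics, or missing
PSMs. Passing tests therefore demonstrate the correctness and
calibration of the statistics under the stated models, not performance
on raw sequencing data.

# Numerical choices and degenerate inputs

* Interval I/O is 0-based half-open on disk, 1-based closed in memory
  (`GRanges` convention); converters are pure inverses and
  property-tested.
* Mann–Whitney p-values: all-tied segments return p = 1; the normal
  approximation uses mid-ranks and continuity correction.
* A candidate whose group has no covered sample yields NA and is never
  retained.
* Dixon removal order is deterministic (the more extreme of min/max
  first); exact ties across the range stop the recursion.
* The extent ratio masks |WT − KO| < 0.05 rather than clipping or
  winsorizing.
* Fisher tables built from mean-aggregated counts are rounded
  half-to-even (base R `round`).
* Merged or unified DMRs recompute means CpG-weighted; unified
  `n_cpg` is recomputed against a methylome when one is supplied,
  otherwise summed over members (which can double-count overlaps, and
  says so in the documentation).

# Known limitations

* The segmentation is not a reimplementation of any specific external
  caller; on real data its candidate boundaries will differ from other
  tools even though the filter criteria are identical.
* With log2FC defined against the average precursor intensity, an
  intensity outlier also displaces its own precursor's reference mean
  (by about `log2((n−1+2^D)/n)` for displacement D over n samples).
  This plants an opposite-sign pseudo-value in the sibling samples'
  Dixon groups and inflates their range, masking a substantial fraction
  of injected outliers at realistic contamination rates — and the
  in-sample displacement saturates at `log2(n)`, so larger injected
  outliers do not become easier to detect. The median roll-ups keep the
  protein-level estimates accurate regardless (the end-to-end accuracy
  checks assert this); users should read the Dixon stage as a guard
  against gross single-PSM errors, not a complete outlier census.
* Floxing efficiency from coverage dropout assumes the control region
  (flanks or reference samples) is copy-neutral and equally mappable.
* The per-genotype isoform usage printed for the real cohort depends on
  the deposited RNA-seq data; the package reproduces the estimator and
  its calibration, not those exact percentages.

# Problem sizes used by the test suite

The suite and the acceptance script run entirely on synthetic data:
DMR recovery and correction-extent analyses use the default 400-cluster
(6,000 CpG) genome with the published group sizes; null calibration
uses twenty 100-cluster genomes; the proteomics analyses use 300
proteins × 6 samples (≈ 43,000 PSM rows) and a 40-protein
co-purification table; the orchestrated demo pipeline uses a
120-cluster genome with four genotypes × 3 samples. A full
`runPipeline()` demo completes in well under five minutes on one CPU.
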