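---
title: "Methods: window-level cfDNA 5mC/5hmC analysis in cfepiscan"
author: "cfepiscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-level cfDNA 5mC/5hmC analysis in cfepiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cfepiscan` analyses plasma cell-free DNA (cfDNA) methylation (5mC,
cfMeDIP-seq-style) and hydroxymethylation (5hmC, hMe-Seal-style) enrichment
sequencing in a case-control design — here schizophrenia (SCZ) versus
healthy controls (HC) — together with clinical scales and structural brain
imaging. This vignette describes the statistical models, the tunable
parameters, the synthetic-data generator used for validation, and the
numerical and design choices that were genuinely open.

## Fragment QC and length profiling

The pipeline consumes preprocessed fragment interval files (BED-like
chrom/start/end, 0-based half-open); alignment, deduplication and
read-level quality filtering are upstream of this package. Fragments are
retained when they lie on an autosome and have an insert size of 20–1000 bp
(inclusive bounds). Length classes follow the nucleosomal structure of
cfDNA: *short* < 166 bp, *medial* 166–332 bp (both boundaries inclusive,
matching the class definitions "short (<166), medial (166–332), long
(>332)"), *long* > 332 bp; 166 bp corresponds to DNA wrapped around one
nucleosome plus linker.

Spike-in capture efficiency is the fraction of spike-in reads on the
modality-matched species (5mC-modified species for a 5mC library, and so
on) out of all spike-in reads.

Group comparisons of per-sample statistics (concentration, length
fractions) use the two-sided rank-sum test with tie-corrected normal
approximation. The accompanying effect size is Cohen's d with pooled SD
(sign = SCZ − HC) — the study reports signed effect sizes with rank-sum
p-values without naming the estimator, so this is a documented assumption.
Post hoc power is computed from a two-sided two-sample t-test via the
noncentral t distribution with noncentrality `d*sqrt(n1*n2/(n1+n2))`. The
published fragment-metric powers (0.27/0.68/0.51 at effects
0.23/−0.43/0.35) are not jointly consistent with a single sample-size
convention; `cfepiscan` always uses the actual group sizes `(n1, n2)` as
given, which reproduces the first value and deviates by roughly 0.04–0.07
on the other two.

## Window grid and filters

Windows are 500 bp with a 250 bp step (`[k*250, k*250+500)`); partial
terminal windows are dropped so all windows share one width — the source
protocol does not state this, and uniform width keeps count statistics
comparable. A window is removed when its base-weighted mean mappability is
below 0.9, when it overlaps a dark region by at least one base, or when it
fails the low-coverage rule: strictly more than 3 counts in at least 10
samples, pooled over both groups. "Coverage" is fragment-overlap counting
(≥ 1 bp, half-open), the `bedtools coverage` default, not base-level depth.
Mappability means are base-weighted (interval-weighted averaging is the
alternative; base-weighting is the natural reading of a per-base score).

## Differential-region engine

The engine is a covariate-adjusted negative-binomial (NB) Wald test,
re-implemented rather than delegated:

* **Normalization** — median-of-ratios size factors over windows with
  all-positive counts.
* **Dispersion** — per-window method-of-moments
  `alpha = max((var − mean)/mean², 1e-8)` on normalized counts, blended
  with a robust (Huber-weighted) `a0 + a1/mu` trend across windows; the
  final value is the geometric mean of the window estimate and the trend at
  the window's mean. This is a deliberately simplified trend-blend, not the
  full empirical-Bayes MAP shrinkage of the established packages: the
  package's validation is by calibration and recovery, not by numeric
  identity with another implementation.
* **GLM** — per-window NB log-link IRLS with offset `log(s_j)`, fixed
  dispersion, standard errors from observed Fisher information, at most 100
  iterations; non-converged windows are flagged and excluded from calling.
  Coefficients are reported on the log2 scale.
* **Design** — intercept, group (SCZ = 1), standardized age, gender, and —
  for 5mC only — treatment-coded batch indicators with the
  lexicographically first batch as reference, mirroring a batch structure
  present in one assay only.
* **Calling** — `p < 5e-4` and `|log2FC| > 0.5`, on raw p-values with an
  LFC gate (no multiple-testing adjustment in calling; BH-adjusted values
  are reported alongside). The source protocol states `p < 0.0005` in its
  results and figure captions but `p < 0.005` in its methods text; the
  results-section value is the default here and both are configurable.
  "Absolute fold change > 0.5" is interpreted on the log2 scale,
  consistent with the results wording and figure axes.
* **Power** — per-region effect size `d = |log2FC|/lfcSE` (a Wald-statistic
  scale, used exactly as defined rather than re-interpreted as Cohen's d)
  fed into the noncentral-t power at significance level 0.005.

The VST used for clustering, the disease score and QC is
`log2(count/size_factor + 1)` — a monotone normalized-count transform. It
feeds only those consumers, which justifies the simplification relative to
a fitted mean-variance transform. Sample clustering uses average-linkage
hierarchical clustering on `1 − Pearson` correlation distance, cut at
k = 2.

## Annotation, enrichment, colocalization

CpG classes form rings: *island* (any overlap), *shore* (region midpoint
within 2 kb of an island edge), *shelf* (2–4 kb), *inter-CGI* (rest).
Island overlap takes precedence; boundary-spanning regions are resolved by
the midpoint, a choice the source does not make explicit. Promoters are
strand-aware 1 kb upstream of the TSS. A region may carry several genic
classes (promoter/exon/intron); summaries use the precedence promoter >
exon > intron.

Gene-set enrichment is the upper-tail hypergeometric probability
`P(X ≥ k)` per set with BH adjustment across sets (a two-sided variant —
doubled smaller tail, capped at 1 — is available; "two-sided
hypergeometric" is otherwise undefined). Tissue enrichment is a per-panel
2×2 Fisher's exact test (upper tail) reporting the sample odds ratio.
Loaders accept user-supplied gene sets of the standard shapes; no live
annotation services are queried.

Colocalization is positional: a region and a GWAS locus colocalize when
they overlap by ≥ 1 bp. The proximity null places the observed number of
lead SNPs uniformly over unmasked bases (outside dark regions and
low-mappability intervals), records each simulated SNP's distance to its
nearest region, and pools all 1000 replicates into one null sample (the
aggregation is not specified in the source; pooling is the simplest
exchangeable choice). The observed statistic is measured in the same
direction — each lead SNP to its nearest region — and compared by a
one-sided rank-sum test; the reverse direction (region to nearest lead
SNP) is also implemented. SCZ-specific variants require qual > 30 and
depth > 30 (strict), exact position/ref/alt identity with a lead SNP (no
strand flipping), presence in SCZ calls and absence from HC calls.

## Brain-measure association

Measures are residualized by OLS with the median raw value added back:
cortical thickness against age and gender; volume and surface-area classes
additionally against intracranial volume; region modification values
against age and gender. Group differences use per-measure rank-sum tests
with BH across measures at FDR 0.05.

The Spearman screen computes all region × measure rank correlations (t
approximation for the p-value), adjusts BH *jointly over all pairs of one
modality* (the conservative reading of "FDR-adjusted" consistent with the
quoted pair totals), and retains measures significantly associated with at
least 5 regions (5mC) or 10 regions (5hmC).

Sparse CCA is a penalized matrix decomposition: L1-constrained rank-1
components of `M = X'Z` (column-standardized inputs), alternating
soft-thresholded power iterations with the threshold chosen by bisection
so the L1 constraint binds, rank-1 deflation between components, K = 3
components, initialization at the leading right singular vector. With
penalties at their maxima the components equal the truncated SVD, which is
the main internal correctness check. Sign convention: the first nonzero
element of each `u` is positive. Penalty tuning follows the permutation
z-score rule (Fisher-transformed first canonical correlation against
row-permuted data); a best z below 2 flags "no signal". Two practical
notes from validation: (i) when every grid point captures a strong factor,
z differences fall within permutation noise, so the grid should bracket
the sparsity the analyst considers plausible (fraction-of-`sqrt(p)` grids,
as in standard penalized-CCA practice); (ii) a non-binding (large) penalty
leaves every weight numerically nonzero, so "active set" statements are
only meaningful for binding penalties.

"Contributing" measures are those with a nonzero weight in *any* of the 3
components (the component scope is not stated in the source). The final
report intersects screen-retained measures with sCCA-active measures;
measures also significant in the atrophy comparison are annotated, not
removed — in a cohort where both the epigenome and the brain measures
carry disease effects, disease-mediated correlations are genuine
associations, and the atrophy flag is how the report distinguishes them
from purely epigenome-linked ones.

## Disease-probability score

Gradient boosting (xgboost engine behind the package's own CV wrapper) on
VST values at called regions. Hyperparameters — trees in {50, 100, 200},
depth in {1, 2, 3}, learning rate 0.1 — are selected by mean log-loss over
10 rounds of stratified threefold cross-validation; the reported
per-sample scores are out-of-fold predictions from the selected
configuration, so no sample is scored by a model that saw its label. The
source does not state whether its scores were in-sample; out-of-fold is
chosen to avoid leakage, at the cost of slightly attenuated correlation
magnitudes. Scores are correlated (Spearman) with the PANSS-like total
(expected positive) and the age/gender-normalized cognition score
(expected negative).

## The synthetic-data generator

The generator emulates the *structure* of the study, not its content:

* **Cohort** — 77 HC / 66 SCZ; imaging subset 68 HC / 59 SCZ; age ~
  N(32.1, 10.4²) truncated to [17, 65]; a per-sample latent disease
  severity drives cfDNA concentration (log-scale slope 0.08), the
  PANSS-like total (monotone increasing) and the BACS-like composite
  (monotone decreasing), so severity-score correlation signs are known.
* **Genome** — small named autosomes with disjoint CpG islands,
  low-mappability intervals (scores < 0.9) and dark regions placed by
  stick-breaking so masked fractions are exact; toy gene models with exons
  inside spans.
* **Counts** — NB with log-link mean = baseline + group effect (truth
  windows only, signs alternating) + covariate effects + log depth.
  Covariate defaults: age slope 0.005 per year, gender shift 0.05, batch
  shift 0.1 (5mC only) — small but recoverable; the source gives no
  magnitudes. Baseline log-means N(log 50, 0.7²) and dispersion 0.1 are
  chosen for testability (the real per-window depth and dispersion are not
  published).
* **Fragments** — three-component length mixture: sub-nucleosomal
  N(120, 25²), mono-nucleosomal at 166 bp drawn as a discrete two-sided
  geometric with SD 15 (real cfDNA has a sharp mono-nucleosomal peak; a
  normal component of the same SD makes the histogram argmax unstable),
  di-nucleosomal N(332, 30²); weights 0.25/0.60/0.15 with SCZ shifts
  −0.03/+0.01/+0.02 (fewer short, more long fragments in cases, matching
  the direction of the reported differences); 1% out-of-range lengths and
  1% chrX placements exercise the filters. Spike-in reads are multinomial
  with matched-species efficiency 0.90 (5mC) / 0.85 (5hmC).
* **Brain measures** — 305 measures in the CT/CV/SA/SV layout (68/68/68/101)
  with unit noise SD; 22 planted atrophic measures (group decrease, default
  2 SD); covariate loadings vary per measure, with ICV loading zero for CT.
  Region–measure links add `strength × scale(region value)` to a linked
  measure; planted atrophy and planted links live on disjoint measures so
  each ground-truth set is identifiable.
* **GWAS loci** — one lead SNP per locus; a planted fraction of leads is
  placed inside supplied regions, the rest uniformly over unmasked bases —
  the same distribution the randomization null uses, so the unplanted
  configuration is calibrated by construction. Variant-call tables carry
  high-quality SCZ-exclusive calls at chosen leads plus low-quality and
  both-cohort decoys.

What the generator does **not** emulate: immunoprecipitation chemistry and
CpG-density-dependent capture bias, GC bias, correlated window
neighborhoods (counts are independent across windows given the design),
linkage disequilibrium, and realistic brain-measure covariance. Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under the assumed model, not that the biological conclusions of
any particular cohort would be reproduced.

## Validation problem sizes

The packaged checks run at sizes chosen to give stable statistics on a
single CPU: null calibration on 20,000 windows (full 143-sample design
with covariates; fraction with Wald p < 0.005 expected in [0.003, 0.008]);
recovery of 60 planted regions (|log2FC| = 1, dispersion 0.1) among 5,000
windows (sensitivity ≥ 0.8, false-discovery proportion ≤ 0.1); size-factor
recovery for depth factors {0.5, 1, 2} within 3%; Monte-Carlo power
agreement within 0.02 at 5,000 simulations; sCCA/SVD agreement to 1e-6;
colocalization calibration over 20 seeds against a 500-replicate null; and
a brain-association end-to-end bundle with 1,200 windows, 60 truth
regions at dispersion 0.6 (so per-region group separation is moderate, as
in real enrichment data), 5 linked blocks of 6 hyper regions at strength
1.5, and 22 atrophic measures at 2 SD. The full pipeline determinism check
runs a reduced bundle twice and compares file hashes.

Two honest caveats from the validation design. First, BH at FDR 0.05 over
305 measures with 22 strong effects *admits* an expected ~1 false flag by
construction; completeness (all 22 recovered, correct direction) is the
meaningful check, and the false-flag count is reported rather than forced
to zero. Second, with K = 3 sparse components and more than 3 latent
blocks, per-component active sets cannot cover every block; coverage in
the intersection report comes from the screen side plus moderately dense
tuned penalties, which matches the densely loaded canonical vectors the
study itself reports (188 of 305 measures contributing).

## Known limitations

* The NB engine assumes a common dispersion model per window and no
  outlier replacement (no Cook's-distance handling, no independent
  filtering, no LFC shrinkage) — none are part of the emulated analysis.
* The Spearman screen's t-approximation p-values are standard for n in the
  hundreds but approximate below n ≈ 10.
* The proximity test treats pooled null replicates as one sample; the
  rank-sum p-value is then conditional on the simulated null rather than
  accounting for its Monte-Carlo error.
* Determinism is guaranteed for fixed seeds on a fixed platform; BLAS-level
  rounding differences can change SVD initializations across platforms in
  degenerate (tied) cases.
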