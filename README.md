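# cfepiscan

Window-level analysis of plasma cell-free DNA (cfDNA) 5-methylcytosine
(5mC) and 5-hydroxymethylcytosine (5hmC) enrichment sequencing in
case-control cohorts, built around a schizophrenia (SCZ) versus
healthy-control (HC) study design that pairs the epigenome with clinical
scales and structural brain MRI.

Plasma cfDNA carries the methylation signatures of its tissues of origin,
including brain, which makes it a candidate non-invasive biomarker source
for neuropsychiatric disease. `cfepiscan` implements the full downstream
analysis for such a study:

* **Fragment QC** — the 20–1000 bp autosome filter, nucleosome-anchored
  length fractions (short < 166 bp, medial 166–332 bp, long > 332 bp),
  spike-in capture efficiency, and rank-sum group comparisons with effect
  sizes and post hoc power.
* **Window counting** — a 500 bp / 250 bp-step sliding grid, mappability
  (< 0.9) and dark-region filters, fragment-overlap counting, a
  low-coverage filter (> 3 counts in ≥ 10 samples), and cross-modality
  Spearman correlation.
* **Differential regions** — the core engine: median-of-ratios size
  factors `s_j`, per-window negative-binomial GLMs with log link
  (`log mu_ij = x_j' beta_i + log s_j`, variance `mu + alpha mu²`,
  method-of-moments dispersion blended with an `a0 + a1/mu` trend),
  Wald tests on the group coefficient, and calling at `p < 5e-4` and
  `|log2FC| > 0.5` into hyper/hypo regions (DMRs for 5mC, DhMRs for 5hmC),
  plus a VST, correlation-distance clustering and per-region power at
  `d = |log2FC| / lfcSE`.
* **Annotation & enrichment** — CpG island/shore/shelf rings, strand-aware
  promoter/exon/intron classes, region-to-gene mapping, upper-tail
  hypergeometric gene-set enrichment and Fisher tissue enrichment with BH
  adjustment.
* **Colocalization** — positional overlap of regions with GWAS loci, a
  1000-replicate randomized-SNP proximity null over unmasked bases, a
  one-sided rank-sum proximity test, and SCZ-specific variant rules
  (qual > 30, depth > 30, exact lead-SNP identity, absent from HC).
* **Brain association** — class-specific covariate residualization of 305
  structural measures, rank-sum atrophy testing with BH FDR, an all-pairs
  Spearman screen, sparse CCA by penalized matrix decomposition
  (L1-constrained soft-thresholded power iterations, K = 3 components,
  permutation-tuned penalties), and the screen ∩ sCCA "reliable measure"
  intersection with atrophy annotation.
* **Severity model** — a cross-validated gradient-boosted
  disease-probability score from called regions, correlated with
  PANSS-like and cognition scores.
* **Synthetic data** — generators for every input (genome with masks and
  gene models, 77 HC / 66 SCZ cohort with a 68/59 imaging subset,
  NB counts with injected differential windows, nucleosome-peaked
  fragments with spike-ins, brain measures with planted atrophy and
  region links, GWAS loci with planted leads), so the entire pipeline is
  testable without sequencing data.

## Worked example

Simulate a study-sized count matrix with 40 planted differential windows
(|log2FC| = 1) and call regions:

```r
library(cfepiscan)

cohort <- simulate_cohort(seed = 7)                 # 77 HC, 66 SCZ
sim <- simulate_counts(seed = 8, cohort, n_windows = 2000, n_true = 40,
                       lfc_magnitude = 1, dispersion = 0.1)
res <- diff_regions(sim$counts, design_matrix(cohort, "5mC"))
table(res$call)
#> hyper  hypo  none
#>    20    20  1960
head(subset(res, call != "none",
            select = c(window, base_mean, log2fc, lfcSE, pvalue, call, power)), 4)
#>      window base_mean log2fc  lfcSE   pvalue  call power
#> 105 w000105      76.4  0.907 0.0939 4.64e-22 hyper     1
#> 116 w000116     108.4 -1.061 0.0980 2.54e-27  hypo     1
#> 125 w000125     106.4  1.007 0.0976 5.77e-25 hyper     1
#> 191 w000191      36.1 -0.944 0.0996 2.61e-21  hypo     1
```

All 40 planted windows are recovered with no false calls
(`mean(sim$truth$window %in% res$window[res$call != "none"])` is 1, and
the called set contains nothing else). Each row reports the window id,
its mean normalized count, the covariate-adjusted log2 fold change (SCZ
vs HC) with its standard error, the Wald p-value, the hyper/hypo call and
the per-region power at significance level 0.005. The same power function
reproduces the fragment-metric convention: at effect size 0.43 with
groups of 66 and 77, `region_power(0.43, 66, 77, 0.05)` prints
`0.7210488`.

The full synthetic benchmark — QC through severity model — runs with one
master seed and writes a report directory plus manifest:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "cfepiscan_out"))
```

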