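---
title: "Methods: integrating blood DNA methylation and gene expression for biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating blood DNA methylation and gene expression for biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylexpr)
```

# The analysis problem

Case/control blood studies of neurodegenerative disease often profile two
molecular layers in parallel: genome-wide gene expression (microarray, log2
scale) and Illumina 450K-style DNA methylation (beta values in [0, 1],
probes annotated to gene regions `TSS1500`, `TSS200`, `5'UTR`, `1stExon`,
`Body`, `3'UTR`, or intergenic).  The promise of the combination is a
biologically filtered biomarker panel: genes that are simultaneously
**hypo-methylated and upregulated** in cases ("hypo-up" genes) are candidate
markers whose expression change has a plausible epigenetic driver, and the
gene region carrying the methylation change points at the regulatory
element involved.

`methylexpr` implements this integration end to end:

1. **Differential expression** — per-gene two-group linear model,
   Benjamini–Hochberg FDR across all genes, and the dual threshold
   `adj_p < 0.05` and `|log2FC| > 0.1` (both strict).
2. **Differential methylation** — region-aware summarization, testing on the
   M-value (logit2) scale, and a dual criterion combining an effect-size
   rule on the beta scale (delta beta outside the 0.1/0.8 quantiles of the
   all-feature delta distribution) with `adj_p < 0.05`.
3. **Intergenic CpGs** — the same caller applied to probes with no gene
   assignment, followed by a 2×2 Pearson chi-square test of enhancer-flag
   enrichment among the differential CpGs.
4. **Integration** — overlap classes (hypo-up, hyper-down, hypo-down,
   hyper-up), dominant methylation-altered regions (the 0.005 rule), and
   Pearson correlation of expression against region-level methylation.
5. **Classification** — a random-forest LOOCV classifier over the hypo-up
   panel with importance ranking, one-by-one incremental panel selection,
   Mann–Whitney AUC with a rank-sum p-value, and cross-cohort specificity
   validation.

# Statistical model and conventions

## Two-group fits and moderation

Both layers use the same per-feature two-group linear model
(`fit_group_model()`).  The effect is always the difference of group means,
case minus control: a log2 fold change for expression, an M-value difference
for methylation.  By default the per-feature variances are moderated by
empirical Bayes (the limma moderated t: posterior variance
$(d_0 s_0^2 + d s^2)/(d_0 + d)$ on $d_0 + d$ degrees of freedom, with the
prior estimated from the spread of the observed $s^2$).  Moderation matters
little at hundreds of samples per group but stabilizes the small pilot
cohorts users may start from.  `moderated = FALSE` gives the ordinary
pooled-variance t on $n - 2$ degrees of freedom; this path is retained both
for teaching and as the hand-checkable reference the test suite exploits.
A feature with zero variance and equal group means reports `t = 0, p = 1`;
under moderation a zero sample variance is absorbed by the prior.

## Why test methylation on the M scale but threshold on beta

The M-value, $M = \log_2(\beta / (1 - \beta))$, has approximately constant
variance across the methylation range and is the better testing scale; the
beta value is the interpretable methylated fraction.  The caller therefore
takes its p-values from M-value fits but its effect-size rule from delta
beta, and reports delta beta as the effect.  Betas are clamped to
$[10^{-6}, 1 - 10^{-6}]$ before the logit because background-normalized
arrays can touch 0 or 1 exactly.  P-values that underflow double precision
are floored at the smallest positive normal double so that "< 2.2e-16"
comparisons remain meaningful.

## The delta-beta decile rule

Rather than a fixed delta-beta cutoff, the caller uses the 0.1 and 0.8
quantiles of the all-feature delta distribution, computed by linear
interpolation of order statistics ($h = (n-1)q$, `stats::quantile` type 7).
Two conventions were genuinely open and are fixed as follows: the upper cut
is read literally as the 0.8 quantile (not the 9th decile), and the
interpolation convention is the common type-7 default; both are arguments
to `decile_thresholds()` for users who prefer otherwise.  Note the rule is
*relative*: in a null cohort roughly 30% of features still pass the delta
criterion, and the FDR criterion is what keeps the null call count at zero.

## Region summarization

A gene's methylation level at a region selector is the arithmetic mean beta
over the CpGs assigned to that gene with that region label; `ALL` pools the
gene's CpGs across all six region classes.  A probe annotated to several
genes contributes to each of them; duplicate (gene, region) pairs in the
manifest collapse to one.  Probes missing in more than 20% of samples are
dropped at read time; remaining missing values are excluded per sample from
the averages.  The manifest is silent on multi-gene behavior, so
expand-and-deduplicate is this package's convention.

## Dominant methylation-altered regions

For each gene the per-region delta betas are compared: the region with the
smallest (most negative) delta is dominant, together with every present
region whose delta lies strictly within 0.005 of that minimum.  Ties at
exactly 0.005 are excluded, matching the strict wording of the rule.
Regions with no probes for the gene are never dominant.  The result is
order-invariant in the region enumeration.

## Classifier construction

The forest defaults are 500 trees and $\sqrt{p}$ candidate features per
split with impurity-decrease (Gini) importance — the standard defaults of
the randomForest implementation, all configurable.  Importance is averaged
over leave-one-out folds: one forest per fold on the $n-1$ training
samples, which is the only reading that uses both LOOCV and "average
importance" coherently.  Panel selection adds features one by one in
importance order; the best panel is the smallest $k$ maximizing LOOCV AUC.
The score of a held-out sample is the fraction of trees voting case.  AUC
uses the Mann–Whitney identity with ties counted 1/2; the p-value is the
two-sided normal-approximation rank-sum test with tie correction (no
continuity correction).  Every fold's RNG is derived deterministically from
`(master seed, fold index, panel size)`, so per-k results are independently
reproducible and invariant to sample order.

In routine use the incremental search is capped at the top 30 features
(`max_k`), the scale at which best panels plateau in this setting; the cap
defaults to the full ranked list in the API.  The conditional-inference-
tree forest variant is not implemented; the gender-feature comparison runs
with the standard forest, with gender encoded as a 0/1 feature.

## Expression–methylation correlation

Pearson correlation of a gene's expression against its region-level
methylation requires measurements from the *same* individuals.  Matched
samples are therefore a precondition of `expr_meth_correlation()` (the
synthetic cohorts are matched by construction); drawing unmatched
individuals from two different cohorts does not define a per-gene
correlation and is deliberately not supported.  The function subsamples a
fixed number per group without replacement under a caller-supplied seed.

# The synthetic cohort generator

`sim_config()`/`generate_cohort()` emulate the joint structure the analysis
assumes: two-group log2 expression with per-gene effects; 450K-style beta
values with probes per gene per region plus intergenic probes; planted
hypo-up (and optionally hyper-down/hypo-down/hyper-up) genes with
designated dominant regions; planted differential intergenic CpGs whose
enhancer-flag odds are multiplied by a configurable factor.

Mechanics worth knowing:

* **Effects are planted on the M scale, calibrated on the beta scale.**
  For a probe with baseline beta $b$, the case shift is
  $\Delta M = \mathrm{logit}_2(b \mp \texttt{meth\_effect}) -
  \mathrm{logit}_2(b)$, so the realized case−control mean beta difference of
  a dominant region is ≈ `meth_effect` in magnitude while betas stay
  bounded.  Gaussian noise (`meth_noise_sd`, M scale) is added before
  back-transforming; the mild logistic nonlinearity shrinks the realized
  difference by a percent or two, well inside the 20% band the tests check.
* **Probes within a gene region share one baseline** (drawn from
  `baseline_beta_range`, default (0.2, 0.8)) plus a small per-probe jitter
  (sd 0.1 on the M scale), so region averaging is meaningful, mimicking
  locally correlated CpGs.
* **Two RNG streams.**  Gene-level "biology" (which genes are planted,
  their dominant regions, baselines, the annotation, enhancer flags) is
  drawn from `plant_seed`; patient-level draws (gender assignment, noise)
  from sub-streams of the master `seed`.  `plant_seed` defaults from the
  master seed, so a config is fully reproducible; supplying the same
  `plant_seed` with a different `seed` draws fresh patients from the same
  disease process, which is exactly what cross-cohort validation needs.
  A "different disease" is a cohort with a different `plant_seed`.
* **Defaults are the study conditions.**  200 + 200 samples, 2000 genes,
  2 probes per region, 1000 intergenic probes, 85 planted hypo-up genes
  with one random dominant region each, `expr_effect = 0.3` (log2),
  `meth_effect = 0.05` (beta), `expr_noise_sd = 1.0`, `meth_noise_sd = 0.5`.
  The effect sizes are calibration choices, not estimates from any real
  cohort.  The intergenic enhancer fraction (0.32) and the enhancer odds
  multiplier for planted differential CpGs (2.2) are chosen to reproduce the
  marginal enhancer odds and differential/non-differential odds ratio of a
  published 450K blood contingency table.  Planted differential intergenic
  CpGs are 80% hypo / 20% hyper, the direction balance reported for blood
  in this disease setting.
* **Gender.**  Genders are assigned 1:1 at random; when `gender_effect` is
  nonzero it shifts a random 5% of genes in males, giving the classifier's
  gender feature something detectable without dominating.

What the generator does **not** emulate — and hence what green tests do not
certify about real data: probe cross-hybridization, batch and chip effects,
cell-type composition shifts (a major confounder in whole blood),
correlated gene networks, non-Gaussian expression noise, and raw intensity
artifacts.  Passing recovery tests show the estimators are correct under
the stated generative model, not that the biology of any real cohort
satisfies that model.

# Numerical and design choices

* Strict inequalities at every printed threshold (`> 0.1`, `< 0.05`,
  `< 0.005`, decile cuts).
* Chi-square without Yates correction by default (`correct = TRUE`
  restores it); at the table magnitudes where enrichment matters the choice
  does not change any conclusion.
* BH adjustment excludes missing p-values from the effective test count and
  returns them as `NA`.
* Beta values overshooting [0, 1] by ≤ 1e-9 on input are clamped; larger
  violations are rejected with the offending cell named.
* The YAML pipeline configuration is validated by an explicit field/type/
  range checker (unknown fields are errors) rather than a schema engine;
  the checked contract is the same.
* Coordinates are 1-based, following the 450K manifest MAPINFO convention.

# Problem sizes used by the bundled checks

The package's own calibration and recovery checks run at: 100 null cohorts
of 2000 genes at 40 + 40 samples (one probe per region); one planted cohort
at the full default conditions above; and classifier cohorts of 50 + 50
samples with the 85 planted genes as features, searching panels up to
k = 30 with 500-tree forests.  These sizes keep a complete run in a few
minutes on one core while leaving every estimate's sampling error small
relative to the bands being checked.

# Known limitations

* DEG/DMG recovery rates on planted cohorts are power-limited by design:
  at `expr_effect = 0.3` against `expr_noise_sd = 1.0` with BH control over
  2000 genes, per-gene power is ~0.3–0.5, so roughly a quarter of planted
  hypo-up genes survive both filters.  The *composition* of the overlap is
  the robust signal (the hypo-up fraction is ~1.0 when only hypo-up genes
  are planted), which is why the package reports it alongside raw counts.
* The ALL-region methylation summary dilutes a shift confined to one
  dominant region by the number of regions; region-specific callers are the
  sensitive instrument and the ALL caller the conservative screen.
* LOOCV AUC after best-k selection is optimistically biased (selection sees
  every fold's AUC); the honest generalization figure is the cross-cohort
  AUC on a fresh draw, which is systematically lower.
* GO/KEGG enrichment of the resulting gene lists requires external
  annotation databases and is out of scope; outputs are plain TSV tables
  ready for such tools.
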