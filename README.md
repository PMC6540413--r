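# rccimmune

Immune gene-expression and morphologic tumor-infiltrating-lymphocyte (TIL)
analysis for localized clear cell renal cell carcinoma (ccRCC).

About a third of localized ccRCC patients recur after nephrectomy, and the
tumor immune microenvironment is a candidate prognostic signal. `rccimmune`
implements, as reusable tested R functions, the full analysis chain linking
that microenvironment to recurrence:

* **NanoString nCounter-style count processing** — negative-control
  background flooring (`mean + 2·sd` rule), positive-control geometric-mean
  normalization, log2 transform and quantile normalization; RNA-seq unit
  conversions (FPKM, TPM, log2 FPKM).
* **Deconvolution-by-signature** — per-sample scores for 24 immune cell
  types and 4 immune response categories as log2-mean expression of
  signature genes; the cytolytic activity score
  `CYT = sqrt((GZMA + 0.01)·(PRF1 + 0.01))` on TPM; the Teff score and the
  Teff/Treg ratio with both platform rules (direct division of log2 scores,
  or anti-logged `2^(teff − treg)`).
* **Recurrence association** — per-signature mean-Z differences and
  Wilcoxon rank-sum tests (exact by enumeration for combined n ≤ 12 without
  ties); a from-scratch empirical-Bayes moderated t (method-of-moments
  variance prior on log variances) with Benjamini–Hochberg FDR and the
  FC > 1.5 & FDR < 0.3 reporting filter; hierarchical clustering of
  response-category genes after gene-wise Z-scoring and overlap exclusion.
* **Morphologic TIL statistics** — the 0–4 capped-maximum foci score, both
  published dichotomization cut-offs (high = 2–4, high = 3–4), odds ratios
  with Woolf CIs, chi-square tests, IRLS logistic regression with explicit
  separation detection, and VIF collinearity screening (flag at 5).
* **A synthetic cohort generator** — negative-binomial counts over a
  730 + 40-gene immune panel with spike-in controls, planted signature
  effects, a latent T-cell level, and TIL foci counts linked to it; every
  stage of the package is validated against it.

## Worked example

Simulate a cohort with a planted T-cell deficit in recurrent tumors and run
the full pipeline:

```r
library(rccimmune)

cfg <- pipeline_config(
  mode = "simulate",
  sim = simulation_config(effect_map = list("T-cell" = -1), seed = 1),
  out_dir = "run1", seed = 1)
report <- run_pipeline(cfg, quiet = TRUE)

head(report$summaries$association[
  order(report$summaries$association$p_two_sided),
  c("signature", "mean_z_diff", "p_two_sided", "p_one_sided_less")])
```

```
   signature mean_z_diff  p_two_sided p_one_sided_less
25  Adaptive  -0.9079782 2.984225e-05     1.492112e-05
16    T-cell  -0.8506518 1.446648e-04     7.233239e-05
26    Innate   0.7582868 2.836685e-04     9.998613e-01
```

The planted effect surfaces where it should: the T-cell signature and the
Adaptive category (which contains the T-cell genes) show negative mean-Z
differences — recurrent tumors score almost one SD lower — with small
Wilcoxon p-values. (The positive Innate shift is the compensatory quantile
displacement discussed in the methods vignette.) `report$summaries$deg_reported` counts genes
passing the FC > 1.5 & FDR < 0.3 filter, and `report$summaries$teff_treg`
carries the one-sided Teff/Treg test. All artifacts (normalized matrix,
score and association tables, cluster orders, morphology statistics) are
written to `out_dir` as plain text with provenance headers; reruns with the
same configuration are identical.

Single components work standalone, e.g. the odds ratio of high TIL burden
(scores 2–4) for recurrence in the bundled validation-cohort
cross-tabulation:

```r
odds_ratio(contingency_2x2(38, 89, 15, 56))
#> OR 1.594 (95% CI 0.804-3.162), chi-square 1.797, p = 0.1801 [woolf_wald]
```

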