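---
title: "Methods: immune expression and morphologic TIL analysis in localized ccRCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune expression and morphologic TIL analysis in localized ccRCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccimmune)
```

## The scientific problem

Roughly a third of patients with localized clear cell renal cell carcinoma
(ccRCC) relapse after nephrectomy, and the composition of the tumor immune
microenvironment is a candidate prognostic signal. Two measurement modalities
are combined here:

* **Morphology.** A pathologist counts lymphocyte/plasma-cell foci on every
  available H&E slide; the patient's TIL score is the maximum focus count on
  any slide, capped at 4. The score is analyzed dichotomized, with two
  published cut-offs (high = 2–4 or high = 3–4), against recurrence and
  against clinicopathologic variables (grade, necrosis, stage) using
  contingency tables, odds ratios, chi-square tests, logistic regression and
  VIF collinearity screens.
* **Targeted expression.** A ~770-gene immune profiling panel (NanoString
  nCounter-style digital counts, including 40 housekeeping genes and
  spike-in positive/negative controls) is processed into normalized log2
  expression, scored against 24 immune cell-type signatures and 4 immune
  response categories (Adaptive, Innate, Inflammation, Humoral), and tested
  for association with recurrence.

The package implements both arms end to end plus a synthetic cohort
generator that makes every stage testable without patient-level data, which
is not publicly deposited for these cohorts.

## Count processing

The processing chain for raw panel counts is, in the default order:

1. **Background flooring.** Per sample, background is `mean` and `sd` of the
   negative-control counts; every endogenous/housekeeping count below
   `mean + 2*sd` is set to `mean`. We use the sample SD (n − 1); the choice
   is configurable in the sense that the threshold multiplier is a plain
   number in the code and the rule is isolated in `background_floor()`.
2. **Positive-control normalization.** Sample *j* is scaled by
   `mean_k(geomean_k) / geomean_j`, where `geomean_j` is the geometric mean
   of sample *j*'s positive-control counts. The factor is applied to
   endogenous, housekeeping and positive probes, making post-scaling
   positive-control geometric means equal across samples. Negative controls
   measure additive background and are not scaled. A zero positive count
   makes the geometric mean degenerate and is an error; a pseudo-count
   escape hatch exists but is off by default.
3. **log2 + quantile normalization.** Only endogenous and housekeeping
   probes are carried into the normalized gene space. Quantile normalization
   is the classical sort/average scheme; tied values within a column receive
   the mean of the reference values over their tied ranks, which makes the
   result deterministic and invariant to input permutation. Two consequences
   worth knowing: the procedure is idempotent, and after flooring (which
   creates ties at the background mean) the column value *multisets* agree
   only up to the tie rule — the column sums still agree exactly, because the
   tie rule is mean-preserving.

The ordering floor → positive-normalize → log2 → quantile is a design
choice; the source protocol does not pin the relative order of flooring and
positive-control scaling. The applied order is recorded in the provenance
attribute of every processed object. Housekeeping genes are carried through
but not used for an additional normalization step, which matches the
positive-control-only description of the protocol this mirrors.

For RNA-seq cohorts the unit conversions are `counts_to_fpkm()`
(`counts * 1e9 / (length * libsize)`), `fpkm_to_tpm()` (column
renormalization to 1e6) and `log2_fpkm()` (offset 1 by default; the offset
is recorded).

## Signature scoring

A signature score is the arithmetic mean of the normalized log2 values of
the signature genes present in the matrix (the "log2-mean" score). Coverage
below 50% of the signature triggers a warning, never silent truncation. On
this panel the Treg signature contains the single gene *FOXP3*, so its score
is that gene's expression.

Two derived scores have fixed closed forms:

* **CYT** (cytolytic activity): `sqrt((GZMA + 0.01) * (PRF1 + 0.01))` on TPM
  values.
* **Teff/Treg ratio**: on the NanoString platform the log2-scale scores are
  divided directly; on the RNA-seq platform the scores are anti-logged
  first, giving `2^(teff − treg)`. Both platform rules are implemented
  because the platform convention differs between the two source cohorts;
  the choice is recorded on the returned object. The anti-log rule is
  invariant to shared additive shifts on the log2 scale — a property the
  tests assert.

Scores are standardized per signature (Z scores, sample SD) before group
comparisons.

## Recurrence association

Per signature we report the mean-Z difference (recurrent minus
non-recurrent) and a Wilcoxon rank-sum test. The Wilcoxon p-value is exact
(full enumeration null) when the combined sample size is at most 12 and
there are no ties; beyond that the normal approximation with tie and
continuity corrections is used. The cutoff of 12 trades exactness against
the factorial growth of the enumeration; at larger n the approximation error
is far below the resolution of any decision made here. BH q-values across
the 28 signatures are reported alongside, but the raw p is the headline
number, matching how score-level comparisons are usually reported in this
setting. The one-sided direction "less" means *recurrent below
non-recurrent*, the direction of the published Teff/Treg trend. For the
Teff/Treg ratio the Wilcoxon is computed on the ratios; since ranks are
invariant to monotone transforms, testing log-ratios would give the same
p-value.

### Moderated t

Differential expression uses an empirical-Bayes moderated t implemented
from first principles: per-gene pooled two-group variance `s_g^2` on
`d_g` df, a prior `(d0, s0^2)` fit by method of moments on `log s_g^2`
(digamma/trigamma moment identities, with the inverse trigamma solved by
Newton iteration), posterior variance
`(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`, and p-values on `d0 + d_g` df. Two
limit cases pin the implementation: `d0 = 0` must reproduce the ordinary
pooled t exactly, and `d0 = Inf` gives all genes the shared variance. The
test suite additionally cross-checks the full estimator against the limma
implementation of the same empirical-Bayes scheme on a fixture.

Fold change is the ratio of *linear-scale* group means (anti-logged before
averaging), because "fold change of mean expression" most naturally refers
to means on the measurement scale; a log2-scale alternative
(`fc_scale = "log2"`) is available. Genes are reported when
`max(FC, 1/FC) > 1.5` and `q < 0.3`, both strict.

### Clustering

Genes belonging to the four response categories are gene-wise Z-scored;
genes occurring in two or more categories are excluded first, so every
clustered gene represents one category. Agglomeration is Euclidean/complete
(configurable), deterministic given input order; the result carries the row
and column orders, merge heights and flat sample labels needed to draw a
heatmap — rendering itself is out of scope.

## Morphology statistics

`aggregate_til_score()` is the capped slide maximum; `dichotomize()`
implements both cut-offs. Odds ratios use the cross-product formula with
Woolf/Wald intervals; a zero cell is an error unless the Haldane–Anscombe
0.5 correction is explicitly enabled (and then flagged in the method tag).
The Woolf interval was chosen as the default because it is the standard
closed form; the intervals printed in the source tables do not recompute
under any common CI method from the printed counts, so ORs — which do
recompute — are the comparison surface and CIs are informational.
Logistic regression is maximum likelihood via IRLS with explicit separation
(|coefficient| > 15) and non-convergence errors; for a single binary
covariate its exponentiated slope equals the closed-form OR, an identity the
tests enforce to 1e-6. VIFs are `1/(1 − R²)` with values ≥ 5 flagged and
perfect collinearity reported as an infinite flagged value rather than an
error.

## The synthetic cohort generator

The generator's defaults are the study conditions of the modeled discovery
cohort: 127 samples with a recurrence fraction of 24/127, a 730 + 40 gene
panel, 6 positive controls on a 4-fold ladder (128 … 0.125 units) and 8
negative controls.

Model choices, made once and documented here:

* **Counts.** Endogenous/housekeeping counts are negative-binomial
  (dispersion 0.1, variance `mu + 0.1*mu^2`) — digital counting data are
  overdispersed relative to Poisson; the exact count law of the platform is
  not published, so NB is an explicit assumption. Negative controls are
  Poisson with mean 8; positive controls are Poisson around the ladder
  scaled so the lowest rung sits near 50 counts, the magnitude seen on real
  cartridges (and safely away from zero, where the geometric mean would
  degenerate).
* **Baselines.** Gene baselines are log2-normal (mean 7, SD 1.5);
  signature-member genes center at 8, reflecting that curated marker genes
  are reliably detected above background; housekeeping genes center at 9
  with SD 0.5.
* **Library factors** are log-normal with natural-log SD 0.15, a typical
  magnitude of lane-to-lane variation.
* **Effects.** `effect_map` plants additive log2 fold-changes on a
  signature's genes in recurrent samples. A per-sample latent T-cell level
  (normal, SD 1) additionally shifts the T-cell signature genes, creating
  the biological variation that both the score–latent correlation and the
  morphology link need.
* **Foci.** Each patient gets 1–10 slides (uniform, matching the ~6 slides
  per case of the source protocol); per-slide foci are Poisson with mean
  `1.5 * exp(til_link_strength * latent)`, so strength 0 decouples
  morphology from expression entirely.
* **Labels and covariates.** Recurrence is Bernoulli; if a draw leaves a
  group empty the first label is flipped so two-group statistics remain
  defined. Grade, necrosis and stage carry mild planted associations with
  recurrence so the morphology statistics have signal to find.
* **Seeding.** One seed determines everything; counts and covariates
  consume the stream from `set.seed(seed)` in a fixed documented order, and
  foci use the offset stream `seed + 101` so the morphology arm can be
  re-drawn independently.

What the generator does *not* emulate: spatial slide structure (foci are
abstract integers), probe-level sequence effects, batch/cartridge effects,
tumor purity variation, and survival times. Passing tests therefore
demonstrate the correctness and calibration of the statistical machinery
under the assumed generative model — not that the biological conclusions
would replicate on new patient data.

## Calibration properties the package commits to

Two cohort-level properties are tested at fixed problem sizes (125 samples,
recurrence fraction 0.2, chosen to mirror the modeled cohort while keeping
the default test run fast):

* **Recovery.** With a planted T-cell log2FC of −1, the pipeline reports a
  negative T-cell mean-Z difference with one-sided Wilcoxon p < 0.05 in at
  least 90% of 200 seeds.
* **Null calibration.** With no planted effects, per-signature two-sided
  Wilcoxon tests reject at the 5% level in 5% ± 2% of over 1000
  signature-by-seed draws.

A by-product of quantile normalization worth noting: a strong planted shift
on one gene set slightly displaces the quantiles of *all* genes, so under
planted alternatives other signatures can show small compensatory shifts.
Under the null no such displacement exists, which is why the calibration
property holds.

## Numerical and degenerate-input policy

* Quantile-normalization ties: mean of tied-rank reference values
  (deterministic, permutation-equivariant, mean-preserving).
* Wilcoxon exactness cutoff: combined n ≤ 12, tie-free only.
* Inverse trigamma: Newton iteration to relative 1e-10 with the standard
  asymptotic starting point.
* Logistic separation: error at |coefficient| > 15 rather than a silently
  huge Wald interval; IRLS convergence at deviance tolerance 1e-10.
* Zero-variance genes: excluded (with a warning) from variance-prior
  estimation; zero-variance signatures are an error in standardization, and
  constant genes are dropped with a warning before clustering in the
  pipeline (where they can arise from flooring).
* Degenerate tables: zero cells are errors unless the documented correction
  is requested; zero expected counts are always errors.

## Reproducing a run

```{r, eval = FALSE}
cfg <- pipeline_config(mode = "simulate",
                       sim = simulation_config(effect_map = list("T-cell" = -1)),
                       out_dir = "run1", seed = 1)
report <- run_pipeline(cfg)
report$summaries$association
```

Every artifact is plain text (TSV/CSV/JSON) with provenance headers, and a
rerun with the same configuration is byte-identical apart from file
timestamps. `validate_tables()` recomputes the odds ratios that are
recoverable from the published cohort cross-tabulations bundled in
`inst/extdata/` and reports pass/fail per row; comparisons use one unit in
the last printed digit, since printed values may be truncated rather than
rounded.

## Known limitations

* The Teff gene list of the original analyses is not published; the
  registry treats Teff as user-supplied, and the synthetic panel derives it
  from the T-cell and CD8 T-cell marker sets.
* ESTIMATE-style stromal/immune scores are not re-implemented; the scoring
  interface accepts any externally computed per-sample score should one be
  needed.
* The published expression-level p-values and the 9-gene DEG list depend on
  unpublished patient-level data and cannot be reproduced here; the package
  instead commits to the oracle, limit-case and calibration properties
  above.
* Heatmap rendering and survival modeling are out of scope by design.
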