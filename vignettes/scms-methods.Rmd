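---
title: "Discriminating malignant single cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating malignant single cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(scmalig)
library(dplyr)
```

## The problem

Tumor tissue profiled by droplet scRNA-seq is a mixture: malignant cells sit
alongside immune, stromal, endothelial and normal epithelial populations, and
most downstream questions (tumor-specific targets, malignant-cell trajectories)
require pulling the malignant cells out first. CNV-inference tools do this by
looking for aneuploid expression profiles, but their resolution is limited.
`scmalig` implements the complementary, supervised route: given any cohort in
which cells have already been labeled malignant/normal (by marker genes, CNV
evidence, sorting, or a published atlas), it distills that labeling into a tiny
logistic gene signature — the **single-cell malignant score (scMS)** — that can
be applied to new cells cheaply and transparently.

The pipeline is a funnel:

1. **QC**: drop cells with < 200 or > 7000 detected genes or > 20%
   mitochondrial counts (all three thresholds configurable; the boundary is
   kept on the survivor side — a cell at exactly 200 genes or exactly 20%
   stays).
2. **Normalization**: per-cell depth scaling to a fixed target sum (default
   10,000) followed by `log1p`. The method is deliberately the de-facto
   droplet convention; it is depth-invariant by construction.
3. **DEG screen**: per-gene two-sided Wilcoxon rank-sum test
   (malignant vs normal) with Benjamini–Hochberg FDR, plus a fold-change
   filter `log2((mean_mal + c)/(mean_norm + c))` with pseudocount `c = 1`.
   Defaults: FDR < 0.01 (strict) and |log2FC| >= 0.5 (inclusive).
4. **ROC screen**: per-gene rank-based (Mann–Whitney) AUC with malignant as
   the positive class; genes are kept when the *oriented* AUC
   `max(AUC, 1 - AUC)` strictly exceeds 0.60, so down-regulated
   discriminators survive and are reported with their direction.
5. **Selection**: L1-penalized binomial logistic regression over a 100-point
   log-spaced penalty grid with ten-fold stratified cross-validation;
   the penalty is chosen by minimal held-out deviance (`cv_min`, default),
   the one-standard-error rule (`cv_1se`), or a target support size.
6. **Model**: unpenalized logistic refit on the selected genes;
   `scMS = 1/(1 + exp(-x))` with
   `x = b0 + sum_g b_g z_g` over per-gene z-scores; a Youden-optimal
   probability cut-point classifies `scMS >= cutoff` as malignant.

## The reference signature

The package ships a seven-gene lung adenocarcinoma signature as a ready-made
`scms_model`:

```{r}
tidy(reference_model())
```

with cut-point `scMS >= 0.046`. Two editorial decisions are worth stating
prominently. First, the formula is the standard logistic; a published
rendering with a leading "1 +" would put scores in (1, 2) and contradict a
cut-point of 0.046, so it is treated as a typesetting artifact. Second, the
signature's inputs are *z-scores*, and the reference population's per-gene
means and dispersions were never published — so `reference_model()`
deliberately carries no scaling statistics, and `score_cells()` refuses to run
until you attach statistics fitted on your own (or any stated) population with
`attach_scaling()`. That makes the scale dependence explicit instead of
silently wrong. The very low cut-point is what a Youden-optimal threshold
looks like under ~10% malignant prevalence; models fitted by this package
store their own training cut-point the same way.

## Why a synthetic generator, and what it does (not) emulate

The original cohorts behind such signatures are hundreds of thousands of
cells and are not shippable inside a package, so validation here rests on a
generator whose discriminability is *known by construction*. Each informative
gene is an equal-variance Gaussian with a malignant-vs-normal mean shift
`delta = sd * sqrt(2) * qnorm(AUC)`; two equal-variance Gaussians separated by
`delta` have theoretical ROC AUC `pnorm(delta/(sd*sqrt(2)))`, so the target
AUC is exact up to sampling noise. Values are truncated at zero to stay on an
expression-like scale; with the default `base_mean = 3 = 3 * base_sd` the
truncated mass is below 0.2%, which perturbs the realized AUC by far less
than the Monte-Carlo tolerance used in the tests (±0.01 at 5,000 + 5,000
cells). Optional Bernoulli dropout (`zero_inflation_rate`) pulls every
gene's AUC toward 0.5, mimicking the main distributional feature of droplet
data.

The default scenario is fixed once: 1,000 malignant + 9,000 normal cells
(the roughly 10% malignant prevalence typical of large labeled lung-tumor
atlases), seven informative genes at the reference signature's marginal
AUCs (0.927, 0.921, 0.892, 0.864, 0.835, 0.806, 0.725), 500 noise genes, no
dropout. Mitochondrial fractions are independent Beta(2, 38) draws (mean 5%)
— QC needs the metadata, not mechanistic realism. A single seed drives all
draws in a fixed documented order, so identical configs are bit-identical.

What the generator does **not** emulate: UMI counting noise, gene–gene
correlation, batch structure, multiple tumor subclones, or the
mean–variance relation of real counts. Passing tests therefore demonstrate
the *statistical machinery* is correct and calibrated, not that any
particular biological cohort would yield the same genes.

### A structural note on fold changes

Under this generator the fold-change and AUC of a gene are tied:
`log2FC ~ log2(1 + sqrt(2) qnorm(AUC) / (base_mean + c))`. Keeping truncation
negligible (`base_mean >= 3 sd`) caps the achievable |log2FC| of a gene with
AUC 0.725 near 0.36 — below the default 0.5 filter. Real data decouple the
two (per-gene variances differ wildly); the independent Gaussian model cannot.
Consequently, on synthetic data the default DEG fold-change filter retains
only the strongest planted genes, which is fine for end-to-end accuracy checks
(three genes at AUC ~0.9 already push the combined model past AUC 0.99), while
support-recovery experiments feed all candidate genes to the selection module
directly, which involves no fold-change filter. Scientists applying the
pipeline to real data should regard `min_abs_log2fc` as a data-scale-dependent
knob (the motivating study itself used both 1 and 0.5).

## Numerical choices

* **Wilcoxon p-values**: midranks for ties; exact null distribution below 50
  total cells when tie-free, otherwise normal approximation with tie
  correction and continuity correction (the conventions of
  `stats::wilcox.test`, against which the implementation is tested).
* **AUC**: computed from rank sums in one pass, never by threshold
  enumeration; ties earn half credit. This makes AUC invariant under any
  strictly monotone transform, so the choice of normalization cannot change
  the screen (asserted by test).
* **Youden cut-point**: candidate thresholds are midpoints between adjacent
  distinct scores plus ±infinity; ties on J break toward higher sensitivity,
  then lower threshold. Constant scores return `NaN` with the all-positive
  operating point and a warning.
* **L1 path**: per-observation-average loss, so `lambda` values are
  comparable across sample sizes and `lambda_max = max_j |<x_j, y - ybar>|/n`
  is the exact support-death boundary. The solver is cyclic coordinate
  descent with soft-thresholding on the IRLS quadratic approximation
  (compiled), warm starts, active-set iteration, and a KKT-violation
  admission sweep guarded against penalty-boundary flip-flop. Convergence
  uses the weighted squared-change criterion standard in this family of
  solvers (`tol = 1e-7`; tests that compare against unpenalized fits tighten
  it). Once a fit explains more than `devmax = 0.99` of the null deviance the
  path repeats that solution over the remaining grid — beyond that point the
  problem is effectively separable and further penalty reduction only inflates
  coefficients.
* **Weights floor**: IRLS weights are floored at 1e-5 to keep the working
  response finite near fitted probabilities of 0/1.
* **Final fit**: `stats::glm` IRLS; perfect separation is detected
  (non-convergence, |coef| > 30, or saturated fitted probabilities) and
  raises an error by default, with an optional lightly ridged IRLS fallback
  (`penalty = 1e-4`) for users who want a usable model anyway.
* **Scaling**: per-gene z-scores; sd-zero genes scale to 0 with a warning;
  no post-scaling clipping by default (the scMS formula gives no license for
  it), exposed as an option.

## Design decisions that were genuinely open

* **Test statistic**: the cohort workflow this mirrors uses a Wilcoxon
  rank-sum marker test; we implement the statistic itself (it is also the
  AUC's numerator) rather than wrapping a marker-finder, and cross-check
  against `stats::wilcox.test` and `pROC`.
* **FDR procedure**: only "FDR" is specified upstream; Benjamini–Hochberg is
  the field default and is delegated to `stats::p.adjust`.
* **Fold-change convention**: ratio of class means of normalized values with
  pseudocount 1 — the simplest auditable choice; expm1-based conventions
  exist and would change numbers, not structure.
* **Penalty family**: binomial logistic, not Cox. The selection target is a
  binary cell label; no survival times exist anywhere in the problem, so a
  proportional-hazards penalized fit is not meaningful here.
* **Orientation**: the AUC screen uses `max(AUC, 1 - AUC)` so down-regulated
  markers count; reports carry the direction separately.
* **Cut-point criterion**: Youden's J, the "best" convention of standard ROC
  tooling; alternatives (closest-to-top-left) would move the cut-point
  slightly but not the machinery.
* **Data split**: model metrics are reported on a stratified held-out split
  (default 30%) because training-set AUC of a cross-validated sparse model is
  optimistically biased.

## Problem sizes used in validation

The packaged tests run the full pipeline at 5,000 + 5,000 cells with 507
genes (seven informative + 500 noise), the support-recovery experiment at
the 10,000-cell default scenario, calibration checks at 5,000 cells per
class, and oracle-equivalence suites at up to 1,000 cells over 100 random
instances. These sizes were chosen as the smallest at which the binomial
noise on an AUC (~0.003) sits well inside the ±0.01 calibration tolerance.

## Known limitations

* Genes are simulated independently; correlated blocks (cell cycle, stress
  modules) would make both the DEG screen and the LASSO's behavior harder.
* The scMS is a probability only with respect to the training prevalence;
  applying it to a cohort with different prevalence shifts calibration
  (though not ranking), which is why the cut-point travels with the model.
* The reference signature cannot be used without user-supplied scaling
  statistics, by design; there is no "correct" packaged default.
* `cv_min` on large, highly separable data tends to select generously many
  genes (deviance keeps creeping down); `cv_1se` is much sparser but still
  admits a handful of stray noise genes when the sample is large (fold
  standard errors shrink with n, weakening the one-SE pullback — reference
  solvers behave identically). Exact support identification is therefore not
  a guarantee of cross-validated selection; when a fixed-size panel is the
  goal, the `target_support` rule reproduces it exactly.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  generator = generator_config(seed = 7),
  lambda_rule = "cv_1se",
  seed = 7
)
run <- run_scms_pipeline(cfg)
run$funnel
glance(run$model)
autoplot(run$cv)
plot_score_distribution(run$scores,
                        cell_info(subset_cells(run$data,
                                               cells = run$test_cells))$label,
                        cutoff = run$model$cutoff)
```
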