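---
title: "Methods: sex differences in functional connectomes and the brain gender continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex differences in functional connectomes and the brain gender continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braingender)
```

## The scientific problem

Resting-state fMRI yields, for every subject, a functional connectome: the
Pearson correlations between the BOLD time series of all pairs of brain
regions under a parcellation (e.g. 94 AAL2 regions, giving
$E = 94\cdot 93/2 = 4371$ edges, grouped into 11 functional networks and
hence $11 + \binom{11}{2} = 66$ network connection categories). Sex
differences in these connectomes are reliably detectable but small at the
single-edge level, and — critically — their sign depends on age:
within-network connectivity tends to be stronger in males during
adolescence and young adulthood but stronger in females after middle age.

This package implements a complete analysis chain for that phenomenon:

1. **Effect-size mapping.** Cohen's d (male minus female, pooled SD) at the
   edge, network-category, nodal-degree and global (gFC) levels, with and
   without residualizing confounds (head motion, SNR, intracranial volume,
   site), bootstrap percentile CIs, concordance correlations between raw
   and adjusted maps, and smoothing-spline trajectories of gFC against age
   per sex.
2. **The brain gender continuum.** A linear support-vector machine over all
   edges (no feature selection), after regressing a cubic age polynomial
   out of every edge, calibrated with a Platt sigmoid so each connectome
   receives a posterior probability of being male in $[0,1]$. Scores below
   0.35 are banded female-typical, above 0.65 male-typical, and the
   inclusive middle band is "androgynous".
3. **Sensitivity experiments.** Learning curves over training size,
   elderly-fraction composition of the training set, one-network-at-a-time
   ablation, enrichment of the top 5% |weights| over network categories,
   and cross-atlas score concordance.
4. **Behavioral association.** A U-shape test: the partial correlation of
   the squared score with internalizing symptoms, controlling for the
   linear score plus sex, age, handedness and motion, with significance
   from exchangeability-block (family-aware) permutations and
   Benjamini–Hochberg FDR across the enumerated test family.

Because the large lifespan cohorts suited to this design (UK Biobank, HCP,
IMAGEN and similar) are access-restricted, the package ships a synthetic
cohort generator that plants all of the structure above with known ground truth,
making every stage testable end to end.

## The synthetic generator

`synthetic_config()` / `generate_cohort()` draw, for each subject, an edge
vector

$$x_{ie} = \mu_e(a_i) + \tfrac{1}{2} s_i\, d_e(a_i)\,\sigma + \varepsilon_{ie},
\qquad \varepsilon_{ie} \sim N(0, \sigma^2),$$

with $s_i = \pm 1$ for male/female, edge noise $\sigma$ (`edge_sd`, default
0.1) and baseline mean `fc_mean` (default 0.25, a typical average
resting-state correlation). The planted standardized sex difference on the
intra-network edges of network $k$ is linear in age,

$$d_k(a) = \text{baseline}_k - \text{slope}_k (a - a_{\min}),$$

with the per-network slope chosen by default so every affected network
crosses zero at `crossing_age` (default 50 years — the reversal the data
show after middle age). The linear-with-one-crossing shape is the simplest
profile consistent with the qualitative pattern; the literature does not
parameterize the trajectory, so this is a modeling choice of the package.
The default planted profile (d = 0.7 / 0.65 / 0.6 at the youngest age on
DMN / SN / FPN) matches the size and location of the young-adult
differences reported for association networks.

Because the two sexes share the covariance and differ only in mean, the
Bayes posterior of maleness given an edge vector is a logistic function of
a linear score; the generator records it as `truth$true_score`. The
internalizing symptom score is then generated as a U shape in that truth,

$$y_i = b + a\,(\text{score}_i - c)^2 + u_{f(i)} + e_i,$$

with vertex `c = 0.5` (androgyny minimizes symptoms), curvature `a = 25`
and noise `sigma = 8` on an Adult-Self-Report-like scale (population mean
about 10, SD about 8.6), plus an optional family random effect for
HCP-like family blocks. `behavior_sigma_for_r()` solves the noise level
that yields any desired quadratic partial correlation, which the tests use
to plant r ≈ 0.15. Externalizing scores are generated with no score
dependence, mirroring the empirical null finding for that dimension.

Confounds (FD, SNR, TIV) default to zero sex/age loadings ("null" mode) so
that covariate adjustment provably must not change results; loadings can be
switched on to study adjustment. Two aging knobs exist: `fc_age_slope`
(a global per-year drift of all edges) and `network_age_slope` (additional
intra-network drift, e.g. the well-replicated decline of default-mode
connectivity), the latter being what makes age-confounding experiments
(below) possible. Sites add a constant offset only; hemodynamics, spatial
structure and scanner artifacts are deliberately out of scope, so passing
tests demonstrate statistical correctness of the pipeline, not robustness
to realistic imaging noise.

Edges are generated directly (the fast path — downstream stages consume
edge vectors); `generate_timeseries()` optionally realizes each subject's
connectome as a multivariate Gaussian ROI time-series whose sample
correlation converges to the planted matrix (eigenvalue-clipped to the
nearest positive-definite correlation when needed), so the
time-series-to-connectome stage can be tested from raw input.

Everything is a deterministic function of the config, including its `seed`;
regenerating with the same config is bit-identical.

## Numerical and design choices

* **Edge order.** Edges are the row-major upper triangle over the
  parcellation's region order; all on-disk tables name region pairs rather
  than indices. Raw Pearson r is the feature — no Fisher z (a flagless
  design: aggregation and effect sizes operate on signed r as-is; negative
  correlations are never thresholded or rectified).
* **Cohen's d** uses the classic two-sample pooled-SD form; the bootstrap
  resamples within sex strata (preserving group sizes), default 10,000
  repetitions (stable to about 3 decimals; raise for publication-grade
  CIs). Degenerate resamples (zero pooled SD) are redrawn and counted.
* **Trajectories** use `stats::smooth.spline` with smoothing chosen by
  generalized cross-validation — a cubic smoothing spline reproduces any
  smooth age trend and GCV removes the free parameter. The default
  evaluation grid is 17–78 years in 0.2-year steps (306 points, so
  curve-vs-curve correlations carry 304 df). Grid points outside a sex's
  observed age range are masked, not extrapolated.
* **Age residualization** fits OLS on $(1, a, a^2, a^3)$ per edge; ages are
  centered and scaled before powering (result-invariant for residuals,
  numerically necessary for the cubic design). Out-of-sample data are
  residualized with the *training* coefficients — refitting on test data
  would leak test structure. Note that this extrapolates the training
  polynomial when the scored sample is outside the training age range;
  with small training sets this extrapolation noise is visible in scores.
* **The classifier** is a linear soft-margin SVM (`e1071`, libsvm) with
  the default box constraint C = 1, trained on all edges without feature
  selection. The primal weights are extracted and oriented male-positive.
* **Calibration** maximizes the Bernoulli likelihood of
  $P = 1/(1+e^{Af+B})$ on training decision values with Platt's
  regularized targets $(N_+ + 1)/(N_+ + 2)$ and $1/(N_- + 2)$, so perfect
  separation cannot drive the fit to a degenerate optimum. Scores of
  exactly 0.5 are classified male (a documented, arbitrary tie-break).
  Band thresholds 0.35/0.65 are inclusive on the androgynous side.
* **Cross-validation** stratifies folds by sex and refits all three stages
  (age regression, SVM, calibration) inside each training fold.
* **Permutation inference** builds exchangeability blocks from family IDs:
  admissible rearrangements permute whole blocks among blocks of equal
  size and subjects within blocks. The quadratic test residualizes both
  the squared score and the outcome on the covariates (including the
  linear term) and permutes the outcome residuals (Freedman–Lane style) —
  plain outcome shuffling would inflate error whenever covariates relate
  to the score. P-values are two-sided by absolute value with the +1
  correction, so they are never zero. For tiny samples,
  `enumerate_scheme()` exhaustively lists the admissible group (8
  rearrangements for two size-2 families; 6 for sizes {3, 1}) as an oracle
  for the sampler.
* **FDR** delegates to `stats::p.adjust(method = "BH")` behind input
  validation; correction families follow the design's enumeration (2 sex
  groups × linear/quadratic × internalizing/externalizing; the three
  internalizing subscales form their own family per sex).
* **Top-weight enrichment** selects the top 5% |weights| (random
  tie-breaking so the count is exact) and compares per-category counts to
  a null that permutes the edge-to-category assignment; the intra-category
  case admits a hypergeometric closed form used as a test oracle.

## Problem sizes used by the test-suite and the reproduction script

The package's own experiments run at desk scale, chosen so each stage's
statistical claim is testable with comfortable power: parcellations of
12–30 regions, cohorts of 400–3000 subjects, 10,000-repetition bootstraps,
1000–10,000 permutations, 100–500 simulated null datasets for calibration
checks, and 3–20 repeats of classifier experiments. The full-scale designs
(94–264 regions, 100,000 bootstraps/permutations, 100 repeats) are reached
by raising the corresponding arguments; nothing in the implementation
depends on the small sizes.

## What the synthetic experiments do and do not show

On cohorts generated under the planted conditions, the pipeline recovers
planted effect sizes within sampling error, reproduces the sign flip of
sex differences across the crossing age, yields cross-validated
classification accuracy in the low 80s (percent) under the default planted
profile, collapses to chance when the signal-bearing network is ablated
while null ablations move accuracy by less than 3 points, degrades
selectively on one sex when age residualization is omitted in an
age-confounded design, and recovers the planted U-shape vertex and
curvature of the score–symptom relation. These are internal-validity
results: they show the estimators and inference machinery do what they
claim on data satisfying the generator's assumptions (Gaussian edge noise,
linear-in-age effects, logistic true score). They do not certify
performance on real imaging data, where preprocessing, non-Gaussian noise,
site effects and unmodeled confounds all intervene.

## Known limitations

* The generator's effect trajectories are linear in age with a single
  crossing; real trajectories need not be.
* The Platt calibration is fit on training decision values (matching the
  construct's definition); `fit_continuum(calibration = "crossfit")`
  instead calibrates on out-of-fold decision values, which avoids score
  saturation when the SVM separates its training set and is the sensible
  choice when the continuum itself (not just the label) is of interest.
* `smooth.spline` requires ≥ 10 subjects per sex and unique-ish ages;
  trajectory fitting on tiny strata is refused rather than guessed.
* Band thresholds (0.35/0.65) are design constants, exposed as arguments
  but not data-driven.
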