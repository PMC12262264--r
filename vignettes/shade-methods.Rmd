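---
title: "Modeling directional spatial interactions between cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling directional spatial interactions between cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shade)
```

## The model

Multiplexed tissue images give, per image, a multitype planar point pattern:
micron coordinates and a cell-type label per cell, observed in a rectangular
window. `shade` asks a *directional* question of such data: how does the
presence of a **source** cell type (say, tumor cells) relate to the local
density of a **target** type (say, cytotoxic T cells) as a function of
distance — without assuming the reverse relationship is the same?

The target pattern is modeled, conditional on the source patterns, as an
inhomogeneous Poisson process whose log-intensity is linear in
distance-basis features of the sources:

$$\log \lambda(v) \;=\; z(v)^\top \beta \;+\;
  \sum_{k=1}^{K} q_k(v)^\top \delta_k, \qquad
  q_k(v)_p = \sum_{x \in X_k} \phi_p(\|v - x\|),$$

where the $\phi_p$ are nonnegative basis functions of distance supported on
$[0, r_{\max}]$ and $z(v)$ is a covariate vector (an intercept by default).
The derived summary of interest is the **spatial interaction curve** (SIC)

$$\mathrm{SIC}_{k \to B}(s) = \sum_{p=1}^{P} \delta_{kp}\, \phi_p(s),$$

the expected contribution of one source cell at distance $s$ to the target's
log-intensity: positive values mean attraction, negative repulsion, at that
distance.

### Dummy-point logistic approximation

Fitting the Poisson likelihood directly needs numerical integration of
$\lambda$ over the window. Instead, the package augments the observed target
cells (label 1) with "dummy" points from a homogeneous Poisson process of
known intensity $\lambda_d$ (label 0) and fits the logistic regression

$$\mathrm{logit}\, P(\text{real}) = z^\top \beta + \sum_k q_k^\top \delta_k
  - \log \lambda_d,$$

whose estimates converge to the Poisson maximum-likelihood fit as
$\lambda_d$ grows. The default dummy-to-real ratio is 2, which keeps designs
small while staying close to the Poisson fit; the test suite checks the
convergence directly against an independent quadrature fit. `build_design()`
performs this construction per image.

### The hierarchy

Spatial structure varies across images from the same patient and across
patients from the same cohort. The interaction coefficients are therefore
modeled as a three-level Gaussian cascade

$$\psi_{k p}^{(g)} \sim \mathcal N(0, \sigma_c^2), \quad
  \gamma_{k p}^{(n)} \sim \mathcal N(\psi_{k p}^{(g(n))}, \sigma_p^2), \quad
  \delta_{k p}^{(m)} \sim \mathcal N(\gamma_{k p}^{(n(m))}, \sigma_i^2),$$

so image-level curves are partially pooled toward patient- and cohort-level
curves. SICs can be reconstructed at any of the three levels from the
corresponding coefficients. The per-image intercept $\beta$ is *not* pooled
by default: each image has its own baseline density, which varies with
sectioning and staining; pooling it would let dense images distort sparse
ones. Covariate effects beyond the intercept are likewise per image.

### Priors and parameterization

Hyperpriors are weakly informative on the log-intensity scale: half-Normal(0, 1)
on $\sigma_c, \sigma_p, \sigma_i$ and Normal(0, 5²) on $\beta$ (and on the
flat model's per-image coefficients). On this scale a coefficient of 1 means
one nearby source cell multiplies the target intensity by $e$; values far
beyond ±5 are not biologically plausible, and interval widths of 1 on the
σ's comfortably cover the between-unit spreads seen in tissue data. All
scales are arguments of `shade_priors()`.

Sampling uses the package's own adaptive Hamiltonian Monte Carlo sampler
(no-U-turn tree doubling, dual-averaging step size, diagonal metric learned
during warmup) with analytic gradients, written in C++. The hierarchy is
sampled in its *non-centered* parameterization — raw standard-normal
innovations scaled by the σ's — which removes the funnel coupling between
coefficients and variance components; the posterior is unchanged. Defaults
are 4 chains, 1000 warmup and 1000 retained iterations, target acceptance
0.9; split-$\widehat R$, bulk effective sample size, and divergence counts
are reported per parameter in `fit$diagnostics`.

## Basis choices

Two families are built in:

* **Cubic B-splines** (default for data analysis): `P = 6` functions with
  equally spaced knots on `[0, 150]` μm. The 150 μm ceiling covers the
  short (<25 μm), intermediate (25–75 μm), and long (>75 μm) ranges at which
  cell-cell organization is typically interpreted; beyond it, curves are
  forced to zero. Both `P` and `r_max` are arguments.
* **Gaussian radial basis functions**, truncated at `r_max`: the default
  triple has centers 20/40/60 μm and width 10 μm, giving one bump per
  short/medium/long-range scale. This family is the simulation truth because
  each coefficient then *is* the interaction strength at a nameable scale.

For scale-resolved error summaries each basis function is assigned to
small/medium/large by the location of its peak (thirds of `[0, r_max]`);
with exactly three functions the assignment is by order. No edge correction
is applied to the interaction features: the model conditions on the observed
source pattern, so features near the border are computed from in-window
sources only.

## What the simulator emulates

`simulate_study()` generates the multilevel designs used throughout the
package's validation: cohorts × patients × images, source points uniform
(binomial process, fixed count — matching designs where cell counts per
image are fixed; a Poisson-count mode exists), and target points drawn by
rejection sampling from the density $\propto \exp(\sum_k q_k^\top \delta_k)$
with the bound taken from a 256×256 grid scan inflated by 10%. Coefficients
follow the same Gaussian cascade the model assumes, with the cohort level
fixed at a configured truth.

Defaults are chosen once as a realistic tissue-imaging regime and used
unchanged by tests and the acceptance script: two cohorts of 20 patients
with 4 images each; 150 points of each type in a 1500×1500 μm window;
dummy-to-real ratio 2; cohort truths $\pm(1.0, 0.5, 0.25)$ on the three RBFs
(first cohort attractive — "responder-like" clustering; second repulsive);
$\sigma_{\text{patient}} = 0.2$ and $\sigma_{\text{image}} = 0.1$, i.e.
patients within a cohort differ visibly but rarely flip sign at the strong
scale, and sections within a patient differ less than patients within a
cohort. The replicate harnesses scale the *design* down (fewer patients,
images, and points), never the mechanism.

What the simulator does **not** emulate: segmentation and typing errors,
anisotropy, tissue-wide intensity trends (a covariate column can carry such
a trend for real data), marked interactions, and inhibitory hard cores.
Passing tests therefore validate the estimation machinery under the model's
own assumptions — not robustness to the ways real tissue violates them.

## Numerical choices and degenerate inputs

* Features are computed by chunked distance evaluation; sources beyond
  `r_max` contribute exactly zero and are pruned. Translation invariance and
  agreement with a brute-force double loop are tested.
* B-spline evaluation delegates to `splines::splineDesign` and is checked
  against an independent de Boor recursion; values at `s = r_max` follow the
  closed-at-the-top convention, and anything beyond is zero.
* The rejection sampler aborts with advice if its acceptance rate falls
  below $10^{-4}$ (coefficients so large the grid bound is uninformative).
* An image with zero target cells is dropped from fits with a warning: its
  rows would all be label 0 and would inform only its own intercept.
* The reduced-sample G-cross estimator is regularized to a proper CDF with
  a running maximum, since the border-corrected ratio need not be monotone.
* Chain initialization sets each image's intercept to the logit of its
  real:dummy row ratio plus the offset — the exact zero-coefficient MLE —
  and jitters everything else near zero.
* With `n_sim = 39` envelope simulations the pointwise two-sided CSR test
  has level 2/40 = 0.05; the envelope uses fixed-count uniform resampling of
  the target type, conditioning on the observed source pattern.

## Downstream summaries

* `sign_detection()` labels a distance positive/negative only when the
  pointwise 95% credible interval excludes zero — a deliberately
  conservative reading designed for comparing methods' sign-recovery rates.
* `group_difference()` reports the posterior of the cohort-level SIC
  difference and flags distances where the absolute median difference
  exceeds 0.05 on the log-intensity scale (≈5% change in expected density
  per source cell) — a practical-relevance threshold, not a test.
* `heterogeneity_mad()` summarizes between-patient and between-image spread
  as the raw median absolute deviation (no 1.4826 consistency constant —
  the number is descriptive, not a normal-σ estimate; the constant is an
  argument) of posterior-median unit-level curves. Summarizing point
  estimates rather than pooled draws keeps "spread between units" separate
  from "posterior uncertainty within units"; a posterior-of-MAD option
  would mix the two and is intentionally not the default.
* `predict_auc()` scores real-vs-dummy discrimination with fresh dummy
  points drawn under an evaluation seed distinct from the fitting seed, so
  the score is not computed on the exact rows the model saw. AUC on fitting
  rows is available as a mode.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run everything at reduced scale,
chosen as the smallest designs at which each property is identifiable:
pooling-vs-flat RMSE on 2×5 patients, 2 images, 100 points per type
(20 and 8 replicates respectively); null-calibration on 30–50 independent
images; detection ordering at the sparse-target condition (15 target points, 150
source points) with 3 images per patient and ≥6 replicates; quadrature agreement on one 500 μm image
across dummy ratios 1–8; and cohort recovery over 20 replicates of a
4-patient design. Sampler settings in these runs (2 chains, 200–400
iterations per phase) are sized for stable posterior means and intervals,
not publication-grade effective sample sizes; `sampler_control()` defaults
remain 4×1000/1000.

## Known limitations

* SICs are predictive associations, not causal effects; confounding by
  shared structure (vasculature, tissue margins) can be mitigated only as
  far as supplied covariates allow.
* The conditional model treats source patterns as fixed; it does not model
  feedback from targets to sources. Fitting both directions is two separate
  models.
* Logistic-approximation accuracy degrades at very small dummy ratios; the
  default ratio 2 is a compromise checked empirically, and ratios can be
  raised per design.
* The G-cross screen treats images as independent observations (no
  within-patient clustering of errors); with four images per patient this
  overstates evidence somewhat, which is the conventional caveat for this
  baseline.
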