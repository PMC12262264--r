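# shade

Directional, distance-resolved spatial associations between cell types in
multiplexed tissue images, estimated with a multilevel Bayesian model.

## The problem

Multiplexed imaging (mIF, CODEX, and relatives) turns a tissue section into
a point pattern: a coordinate and a cell type for every cell. A recurring
question is how cell types organize around one another — do cytotoxic T
cells accumulate near tumor cells? at what distances do granulocytes track
vasculature? — and whether that organization differs between patient
groups. Classical summaries (Ripley's K, pair correlation, G-cross) are
symmetric in the two types and are computed per image, so they can neither
express *directional* hypotheses ("A predicts B" is not "B predicts A") nor
share information across the images-within-patients-within-cohorts
structure of real studies.

`shade` models the conditional intensity of a **target** cell type given
one or more **source** types:

    log lambda(v) = z(v)' beta + sum_k q_k(v)' delta_k,
    q_k(v)_p      = sum over source cells x of phi_p(|v - x|),

with nonnegative distance basis functions `phi_p` (cubic B-splines or
Gaussian RBFs, zero beyond `r_max`). The derived **spatial interaction
curve** `SIC(s) = sum_p delta_p phi_p(s)` reads as the log-intensity
contribution of one source cell at distance `s`: positive = attraction,
negative = repulsion. Likelihood evaluation uses the dummy-point logistic
approximation (real cells vs known-intensity Poisson dummies, offset
`-log lambda_dummy`), and the interaction coefficients are partially pooled
through a three-level Gaussian hierarchy — image `delta` around patient
`gamma` around cohort `psi` — sampled by the package's adaptive NUTS
sampler (C++, analytic gradients, non-centered parameterization).

The package also ships the pieces needed to validate such a model end to
end: a hierarchical point-pattern simulator with known ground-truth curves,
a non-hierarchical ("flat") reference model, G-cross envelope baselines,
posterior summaries (credible bands, sign detection, cohort differences,
MAD heterogeneity), and conditional-intensity prediction maps with AUC
evaluation.

## Worked example

Simulate a two-cohort study (attractive vs repulsive truth), fit the
hierarchical model, and summarize:

```r
library(shade)

cfg    <- sim_config(patients_per_cohort = 3, images_per_patient = 2,
                     n_source = 100, n_target = 100, window_side = 1000,
                     seed = 8)
study  <- simulate_study(cfg)
fit    <- fit_shade(study_designs(study), study$meta,
                    sampler = sampler_control(chains = 2, warmup = 300,
                                              draws = 300), seed = 8)
fit
#> shade_fit (hierarchical): 12 image(s), 1 source type(s), P = 3
#>   2 chains x 300 draws; 0 divergence(s); max split-Rhat 1.017

curve <- sic_curve(fit, level = "cohort", unit = "cohort1",
                   source = "source1", distances = c(10, 20, 40, 60, 80))
sic_table(curve)
#>    level    unit  source distance  median   lo95  hi95
#> 1 cohort cohort1 source1       10 0.80875  0.572 1.008
#> 2 cohort cohort1 source1       20 1.39257  1.002 1.719
#> 3 cohort cohort1 source1       40 0.66731  0.331 0.980
#> 4 cohort cohort1 source1       60 0.07247 -0.256 0.395
#> 5 cohort cohort1 source1       80 0.00093 -0.047 0.044
```

The first cohort was simulated attractive (`psi = (1.0, 0.5, 0.25)` on RBFs
at 20/40/60 um): the posterior median curve is positive and largest near
20 um — one source cell there multiplies the expected target density by
about `exp(1.39) ~ 4` — and decays toward zero by 80 um, with 95% bands
excluding zero at short range only.

```r
sign_detection(curve, c(20, 40, 60))
#>           20           40           60
#>   "positive"   "positive" "undetected"

group_difference(fit, "cohort1", "cohort2", distances = 0:100)$flagged_ranges
#>   from to
#> 1    0 78

predict_auc(fit, "img001")
#> [1] 0.82
```

Sign detection recovers the attraction where the data are informative; the
cohort difference (attractive minus repulsive) exceeds the 0.05
log-intensity threshold from 0 to 78 um; and the fitted intensity
discriminates real target cells from background locations with AUC 0.82 in
the first image.

A command-line front end wrapping these functions (subcommands `simulate`,
`fit`, `sic`, `predict`, `gcross`, `study1`, `study2`) ships at
`inst/cli/shade.R`; after installation it resolves to
`system.file("cli", "shade.R", package = "shade")`.

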