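test_that("curve reconstruction is exactly linear in the coefficients", {
  spec <- basis_spec("gaussian_rbf")
  S <- 100
  set.seed(5)
  coefs <- matrix(rnorm(S * 3), S, 3)
  fit <- make_fit(delta = array(coefs, c(S, 1, 3)), spec = spec)
  dist <- seq(0, 100, by = 5)
  cv <- sic_curve(fit, "image", "img1", 1, dist)
  # loop-vs-matrix oracle
  B <- eval_basis(spec, dist)
  for (s in c(1, 27, 100)) {
    expect_equal(cv$draws[s, ], drop(B %*% coefs[s, ]), tolerance = 1e-12)
  }
  # linearity: SIC of a sum of coefficient vectors = sum of SICs
  fit2 <- make_fit(delta = array(2 * coefs, c(S, 1, 3)), spec = spec)
  cv2 <- sic_curve(fit2, "image", "img1", 1, dist)
  expect_equal(cv2$draws, cv$draws * 2, tolerance = 1e-12)
  # quantile sandwich
  expect_true(all(cv$summary$median >= cv$summary$lo95 - 1e-12))
  expect_true(all(cv$summary$median <= cv$summary$hi95 + 1e-12))
})

test_that("degenerate coefficient draws give flat or single-basis curves", {
  spec <- basis_spec("gaussian_rbf")
  zero <- make_fit(delta = array(0, c(20, 1, 3)), spec = spec)
  cv <- sic_curve(zero, "image", "img1", 1, 0:100)
  expect_true(all(cv$draws == 0))
  one <- array(0, c(20, 1, 3)); one[, 1, 2] <- 1.7
  fit <- make_fit(delta = one, spec = spec)
  cv <- sic_curve(fit, "image", "img1", 1, 0:100)
  expect_equal(cv$summary$median, 1.7 * eval_basis(spec, 0:100)[, 2],
               tolerance = 1e-12)
  expect_warning(sic_curve(fit, "image", "img1", 1, c(0, 2 * spec$r_max + 5)),
                 "identically")
})

test_that("sign detection follows the pointwise credible intervals", {
  spec <- basis_spec("gaussian_rbf")
  S <- 200
  # all draws of the basis-2 coefficient positive -> positive at its center
  pos <- array(0, c(S, 1, 3)); pos[, 1, 2] <- runif(S, 0.2, 0.8)
  cv <- sic_curve(make_fit(delta = pos, spec = spec), "image", "img1", 1, 0:80)
  expect_equal(unname(sign_detection(cv, 40)), "positive")
  neg <- array(0, c(S, 1, 3)); neg[, 1, 1] <- -runif(S, 0.2, 0.8)
  cv <- sic_curve(make_fit(delta = neg, spec = spec), "image", "img1", 1, 0:80)
  expect_equal(unname(sign_detection(cv, 20)), "negative")
  mix <- array(0, c(S, 1, 3)); mix[, 1, 3] <- seq(-0.3, 0.4, length.out = S)
  cv <- sic_curve(make_fit(delta = mix, spec = spec), "image", "img1", 1, 0:80)
  expect_equal(unname(sign_detection(cv, 60)), "undetected")
  expect_error(sign_detection(cv, 300), "grid range")
})

test_that("group differences are linear and flag the configured threshold", {
  spec <- basis_spec("gaussian_rbf")
  S <- 50
  psi <- array(0, c(S, 2, 3))
  psi[, 1, ] <- rep(c(0.5, 0.2, -0.1), each = S)
  psi[, 2, ] <- psi[, 1, ]
  fit <- make_fit(delta = array(0, c(S, 1, 3)), psi = psi,
                  gamma = array(0, c(S, 1, 3)), spec = spec,
                  cohorts = c("A", "B"), patients = "p1")
  gd <- group_difference(fit, "A", "B", 1, 0:100)
  expect_true(all(gd$draws == 0))
  expect_equal(nrow(gd$flagged_ranges), 0)
  # constant shift c on basis 2: difference = c * phi_2(s)
  psi2 <- psi; psi2[, 1, 2] <- psi2[, 1, 2] + 0.3
  fit2 <- make_fit(delta = array(0, c(S, 1, 3)), psi = psi2,
                   gamma = array(0, c(S, 1, 3)), spec = spec,
                   cohorts = c("A", "B"), patients = "p1")
  gd2 <- group_difference(fit2, "A", "B", 1, 0:100, threshold = 0.05)
  phi2 <- eval_basis(spec, 0:100)[, 2]
  expect_equal(gd2$summary$median, 0.3 * phi2, tolerance = 1e-12)
  expect_equal(gd2$flagged, abs(0.3 * phi2) > 0.05)
  expect_true(nrow(gd2$flagged_ranges) >= 1)
  expect_error(group_difference(fit2, "A", "Z", 1), "unknown cohort")
})

test_that("MAD heterogeneity: hand values, shift invariance, linear scaling", {
  spec <- basis_spec("gaussian_rbf")
  S <- 40
  # 3 patients in one cohort with constant coefficient offsets {-1, 0, 1}
  # on every basis function -> patient SICs differ by a curve multiple
  gamma <- array(0, c(S, 3, 3))
  for (n in 1:3) gamma[, n, ] <- (n - 2)
  # 2 images per patient, identical to their patient -> image MAD 0
  delta <- array(0, c(S, 6, 3))
  for (m in 1:6) delta[, m, ] <- gamma[1, ceiling(m / 2), ]
  meta <- study_design(paste0("img", 1:6), rep(paste0("p", 1:3), each = 2),
                       rep("g1", 6))
  fit <- make_fit(delta = delta, psi = array(0, c(S, 1, 3)), gamma = gamma,
                  spec = spec, cohorts = "g1", patients = paste0("p", 1:3),
                  image_ids = paste0("img", 1:6), meta = meta)
  het <- heterogeneity_mad(fit, distances = c(20, 40, 60))
  # at s: patient medians are {-1, 0, 1} * sum_p phi_p(s); MAD = sum_p phi_p(s)
  phisum <- rowSums(eval_basis(spec, c(20, 40, 60)))
  expect_equal(het$per_distance$mad_patient, phisum, tolerance = 1e-10)
  expect_equal(het$per_distance$mad_image, rep(0, 3), tolerance = 1e-12)

  # adding a common constant curve to all units leaves MAD unchanged
  gamma_sh <- gamma + 0.7
  delta_sh <- delta + 0.7
  fit_sh <- make_fit(delta = delta_sh, psi = array(0, c(S, 1, 3)),
                     gamma = gamma_sh, spec = spec, cohorts = "g1",
                     patients = paste0("p", 1:3),
                     image_ids = paste0("img", 1:6), meta = meta)
  het_sh <- heterogeneity_mad(fit_sh, distances = c(20, 40, 60))
  expect_equal(het_sh$per_distance$mad_patient,
               het$per_distance$mad_patient, tolerance = 1e-10)
  # scalar multiplication scales MAD linearly
  fit_sc <- make_fit(delta = delta * 3, psi = array(0, c(S, 1, 3)),
                     gamma = gamma * 3, spec = spec, cohorts = "g1",
                     patients = paste0("p", 1:3),
                     image_ids = paste0("img", 1:6), meta = meta)
  het_sc <- heterogeneity_mad(fit_sc, distances = c(20, 40, 60))
  expect_equal(het_sc$per_distance$mad_patient,
               3 * het$per_distance$mad_patient, tolerance = 1e-10)
})

test_that("heterogeneity errors name the level with too few units", {
  spec <- basis_spec("gaussian_rbf")
  meta1 <- study_design(c("i1", "i2"), c("p1", "p1"), c("g1", "g1"))
  fit1 <- make_fit(delta = array(0, c(10, 2, 3)),
                   psi = array(0, c(10, 1, 3)),
                   gamma = array(0, c(10, 1, 3)), spec = spec,
                   cohorts = "g1", patients = "p1",
                   image_ids = c("i1", "i2"), meta = meta1)
  expect_error(heterogeneity_mad(fit1), "patient")
})
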