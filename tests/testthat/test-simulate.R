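test_that("coefficient cascade: degenerate limit, moments, sign inheritance", {
  cfg0 <- sim_config(patients_per_cohort = 3, images_per_patient = 2,
                     sigma_patient = 0, sigma_image = 0, seed = 2)
  tr0 <- draw_coefficient_tree(cfg0)
  for (m in seq_len(dim(tr0$delta)[1])) {
    g <- match(tr0$meta$group_id[m], sort(unique(tr0$meta$group_id)))
    expect_equal(tr0$delta[m, , ], cfg0$psi_truth[g, , ])
  }
  # empirical variance of gamma - psi over 1000 patients ~ sigma_patient^2
  cfg1 <- sim_config(n_cohorts = 1, patients_per_cohort = 1000,
                     images_per_patient = 1, sigma_patient = 0.5,
                     sigma_image = 0.1, psi_truth = matrix(c(1, .5, .25), 1),
                     seed = 3)
  tr1 <- draw_coefficient_tree(cfg1)
  dev <- sweep(tr1$gamma[, 1, ], 2, cfg1$psi_truth[1, 1, ])
  v <- mean(apply(dev, 2, var))
  se <- 0.25 * sqrt(2 / 999) / sqrt(3)
  expect_lt(abs(v - 0.25), 3 * se)
  # opposite-sign cohorts inherit the sign split when sigmas are small
  cfg2 <- sim_config(patients_per_cohort = 4, images_per_patient = 2,
                     sigma_patient = 0.05, sigma_image = 0.02, seed = 4)
  tr2 <- draw_coefficient_tree(cfg2)
  g_of_m <- match(tr2$meta$group_id, sort(unique(tr2$meta$group_id)))
  expect_true(all(sign(tr2$delta[g_of_m == 1, 1, ]) == 1))
  expect_true(all(sign(tr2$delta[g_of_m == 2, 1, ]) == -1))
})

test_that("zero interaction gives CSR targets at the nominal quadrat rate", {
  spec <- basis_spec("gaussian_rbf")
  w <- shade_window(400)
  reject <- vapply(1:40, function(r) {
    im <- simulate_image(c(0, 0, 0), n_source = 40, n_target = 80,
                         window = w, spec = spec, seed = 600 + r)
    qx <- cut(im$targets$x, seq(0, 400, by = 100))
    qy <- cut(im$targets$y, seq(0, 400, by = 100))
    counts <- as.vector(table(qx, qy))
    p <- suppressWarnings(chisq.test(counts)$p.value)
    p < 0.05
  }, logical(1))
  # binomial(40, 0.05): 3 standard errors above the mean is ~ 0.15
  expect_lte(mean(reject), 0.15)
})

test_that("a strong short-range SIC attracts targets toward sources", {
  spec <- basis_spec("gaussian_rbf")
  w <- shade_window(500)
  nnd <- function(t, s) {
    d2 <- outer(t$x, s$x, "-")^2 + outer(t$y, s$y, "-")^2
    mean(sqrt(apply(d2, 1, min)))
  }
  im <- simulate_image(c(3, 0, 0), n_source = 30, n_target = 100,
                       window = w, spec = spec, seed = 11)
  unif <- vapply(1:20, function(r) {
    u <- simulate_image(c(0, 0, 0), n_source = 0, n_target = 100,
                        window = w, spec = spec, seed = 700 + r)
    nnd(u$targets, im$sources[[1]])
  }, numeric(1))
  expect_lt(nnd(im$targets, im$sources[[1]]), min(unif))
})

test_that("rejection sampling reproduces the analytic radial density", {
  # single source at the window center, single RBF: density ~ exp(c phi(r)) r
  spec <- basis_spec("gaussian_rbf", centers = 60, widths = 15, r_max = 150)
  w <- shade_window(600)
  src <- point_pattern(300, 300, "s", w)
  dens <- function(r) exp(2 * exp(-(r - 60)^2 / (2 * 15^2))) * r
  im <- simulate_image(matrix(2, 1, 1), n_source = 1, n_target = 3000,
                       window = w, spec = spec, seed = 17,
                       sources = list(source1 = src))
  r <- sqrt((im$targets$x - 300)^2 + (im$targets$y - 300)^2)
  breaks <- seq(0, 280, by = 40)  # annuli fully inside the window
  obs <- table(cut(r[r < 280], breaks))
  expected <- vapply(seq_len(length(breaks) - 1), function(i) {
    integrate(dens, breaks[i], breaks[i + 1])$value
  }, numeric(1))
  p <- suppressWarnings(
    chisq.test(as.vector(obs), p = expected / sum(expected))$p.value)
  expect_gt(p, 1e-3)
})

test_that("studies are deterministic given the config seed", {
  cfg <- sim_config(patients_per_cohort = 1, images_per_patient = 2,
                    n_source = 25, n_target = 25, window_side = 400,
                    seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$truth, s2$truth)
  # 1 cohort, 1 patient, 1 image reduces to simulate_image
  cfg1 <- sim_config(n_cohorts = 1, patients_per_cohort = 1,
                     images_per_patient = 1, n_source = 25, n_target = 25,
                     window_side = 400, sigma_patient = 0, sigma_image = 0,
                     psi_truth = matrix(c(.5, .2, .1), 1), seed = 5)
  s3 <- simulate_study(cfg1)
  expect_length(s3$images, 1)
  expect_equal(n_points(s3$images[[1]]$targets), 25)
  expect_equal(s3$truth$delta[1, 1, ], c(.5, .2, .1))
})

test_that("oversized coefficients abort rejection sampling informatively", {
  spec <- basis_spec("gaussian_rbf", centers = 20, widths = 5, r_max = 60)
  w <- shade_window(2000)
  expect_error(
    simulate_image(matrix(40, 1, 1), n_source = 200, n_target = 50,
                   window = w, spec = spec, seed = 2),
    "acceptance rate")
})

test_that("rmse_eval recovers hand-computable errors", {
  spec <- basis_spec("gaussian_rbf")
  meta <- study_design(c("img001", "img002"), c("p1", "p1"), c("g1", "g1"))
  truth <- list(delta = array(0, c(2, 1, 3)), meta = meta)
  # posterior mean equal to truth -> RMSE 0
  d0 <- array(0, c(10, 2, 3))
  fit0 <- make_fit(delta = d0, spec = spec,
                   image_ids = c("img001", "img002"))
  e0 <- rmse_eval(fit0, truth)
  expect_equal(e0$aggregate, 0)
  # estimates +a and -a against truth 0 -> RMSE = a
  a <- 0.37
  d1 <- array(0, c(10, 2, 3)); d1[, 1, ] <- a; d1[, 2, ] <- -a
  fit1 <- make_fit(delta = d1, spec = spec,
                   image_ids = c("img001", "img002"))
  e1 <- rmse_eval(fit1, truth)
  expect_equal(e1$aggregate, a, tolerance = 1e-12)
  expect_equal(unname(e1$by_scale), rep(a, 3), tolerance = 1e-12)
  # shape mismatch
  truth_bad <- list(delta = array(0, c(2, 1, 4)), meta = meta)
  expect_error(rmse_eval(fit1, truth_bad), "shape")
})
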