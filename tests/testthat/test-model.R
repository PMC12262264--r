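# hand-construct a minimal design object (bypasses geometry on purpose)
manual_design <- function(X, y, lambda_dummy, image_id = "img1") {
  structure(list(X = X, Z = matrix(1, nrow(X), 1), y = y,
                 offset = log(lambda_dummy), lambda_dummy = lambda_dummy,
                 image_id = image_id,
                 sources = setNames(list(NULL), "s1"),
                 spec = NULL), class = "shade_design")
}

one_image_meta <- study_design("img1", "p1", "g1")

zero_tree <- function(Q) {
  list(psi = matrix(0, 1, Q), gamma = matrix(0, 1, Q),
       delta = matrix(0, 1, Q), beta = matrix(0, 1, 1))
}

test_that("log posterior with zero coefficients matches the closed form", {
  lam <- 0.002
  X <- matrix(runif(9), 3, 3)
  d <- manual_design(X, c(1, 0, 0), lam)
  vc <- list(sigma_cohort = 0.8, sigma_patient = 0.6, sigma_image = 0.4)
  pr <- shade_priors()
  lp <- log_posterior(zero_tree(3), vc, list(d), one_image_meta, pr)
  lik <- plogis(-log(lam), log.p = TRUE) + 2 * plogis(log(lam), log.p = TRUE)
  prior <- sum(dnorm(0, 0, vc$sigma_image, log = TRUE) * 3) +
    sum(dnorm(0, 0, vc$sigma_patient, log = TRUE) * 3) +
    sum(dnorm(0, 0, vc$sigma_cohort, log = TRUE) * 3) +
    dnorm(0, 0, pr$sd_beta, log = TRUE) +
    sum(dnorm(c(0.8, 0.6, 0.4), 0, 1, log = TRUE)) + 3 * log(2)
  expect_equal(lp, lik + prior, tolerance = 1e-12)
})

test_that("log posterior matches a fully hand-computed three-row sum", {
  lam <- 0.01
  X <- matrix(c(0.5, 0.2, 0.0,
                1.0, 0.0, 0.3,
                0.0, 0.4, 0.4), 3, 3, byrow = TRUE)
  y <- c(1, 1, 0)
  d <- manual_design(X, y, lam)
  tree <- list(psi = matrix(c(0.3, -0.1, 0.2), 1),
               gamma = matrix(c(0.25, 0.0, 0.15), 1),
               delta = matrix(c(0.2, 0.1, 0.1), 1),
               beta = matrix(-4.0, 1, 1))
  vc <- list(sigma_cohort = 1.2, sigma_patient = 0.5, sigma_image = 0.3)
  pr <- shade_priors()
  eta <- drop(X %*% tree$delta[1, ]) - 4.0 - log(lam)
  by_hand <- sum(y * eta - log1p(exp(eta))) +
    sum(dnorm(tree$delta, tree$gamma, 0.3, log = TRUE)) +
    sum(dnorm(tree$gamma, tree$psi, 0.5, log = TRUE)) +
    sum(dnorm(tree$psi, 0, 1.2, log = TRUE)) +
    dnorm(-4, 0, pr$sd_beta, log = TRUE) +
    sum(dnorm(c(1.2, 0.5, 0.3), 0, 1, log = TRUE)) + 3 * log(2)
  expect_equal(log_posterior(tree, vc, list(d), one_image_meta, pr), by_hand,
               tolerance = 1e-12)
})

test_that("logit linearity: compensating an intercept shift leaves the likelihood unchanged", {
  lam <- 0.01
  d <- manual_design(matrix(c(1, 0, 0), 1), 1, lam)
  vc <- list(sigma_cohort = 1, sigma_patient = 1, sigma_image = 1)
  t1 <- zero_tree(3); t1$delta[1, 1] <- 0.7
  t2 <- zero_tree(3); t2$beta[1, 1] <- 0.7
  # q'delta enters the logit exactly as z'beta: likelihoods agree, priors differ
  lp1 <- log_posterior(t1, vc, list(d), one_image_meta)
  lp2 <- log_posterior(t2, vc, list(d), one_image_meta)
  prior1 <- dnorm(0.7, 0, 1, log = TRUE) - dnorm(0, 0, 1, log = TRUE)
  prior2 <- dnorm(0.7, 0, 5, log = TRUE) - dnorm(0, 0, 5, log = TRUE)
  expect_equal(lp1 - prior1, lp2 - prior2, tolerance = 1e-12)
})

test_that("sampler-side posterior agrees with the reference implementation", {
  # With the variance components held fixed, differences of the non-centered
  # log posterior between two coefficient configurations must equal the
  # centered-parameterization differences (all Jacobians and constants cancel).
  set.seed(8)
  w <- shade_window(400)
  target <- point_pattern(runif(30, 0, 400), runif(30, 0, 400), "t", w)
  src <- point_pattern(runif(20, 0, 400), runif(20, 0, 400), "s", w)
  spec <- basis_spec("gaussian_rbf")
  des <- build_design(target, list(s = src), spec, seed = 1)
  meta <- study_design("image", "p1", "g1")
  pk <- shade:::pack_designs(list(des), meta, shade_priors(), TRUE)
  dim <- (1 + 1 + 1) * 3 + 1 + 3
  sig <- c(0.9, 0.5, 0.3)
  to_tree <- function(raw) {
    psi <- sig[1] * raw[1:3]
    gam <- psi + sig[2] * raw[4:6]
    del <- gam + sig[3] * raw[7:9]
    list(psi = matrix(psi, 1), gamma = matrix(gam, 1),
         delta = matrix(del, 1), beta = matrix(raw[10], 1, 1))
  }
  vc <- list(sigma_cohort = sig[1], sigma_patient = sig[2],
             sigma_image = sig[3])
  raw1 <- c(rnorm(9, 0, 0.5), -5)
  raw2 <- c(rnorm(9, 0, 0.5), -4.5)
  th1 <- c(raw1, log(sig)); th2 <- c(raw2, log(sig))
  d_cpp <- shade:::.shade_lp_grad(th1, pk$data)$lp -
    shade:::.shade_lp_grad(th2, pk$data)$lp
  d_ref <- log_posterior(to_tree(raw1), vc, list(des), meta) -
    log_posterior(to_tree(raw2), vc, list(des), meta)
  expect_equal(d_cpp, d_ref, tolerance = 1e-8)
})

test_that("analytic gradients match finite differences (both models)", {
  set.seed(9)
  w <- shade_window(300)
  target <- point_pattern(runif(25, 0, 300), runif(25, 0, 300), "t", w)
  src <- point_pattern(runif(15, 0, 300), runif(15, 0, 300), "s", w)
  des <- build_design(target, list(s = src), basis_spec("gaussian_rbf"),
                      seed = 2)
  meta <- study_design("image", "p1", "g1")
  for (hier in c(TRUE, FALSE)) {
    pk <- shade:::pack_designs(list(des), meta, shade_priors(), hier)
    dim <- if (hier) 13 else 4
    theta <- c(rnorm(dim - if (hier) 4 else 1, 0, 0.4),
               -5, if (hier) log(c(0.8, 0.6, 0.4)))
    res <- shade:::.shade_lp_grad(theta, pk$data)
    h <- 1e-5
    num <- vapply(seq_len(dim), function(i) {
      e <- numeric(dim); e[i] <- h
      (shade:::.shade_lp_grad(theta + e, pk$data)$lp -
         shade:::.shade_lp_grad(theta - e, pk$data)$lp) / (2 * h)
    }, numeric(1))
    expect_equal(drop(res$grad), num, tolerance = 1e-5)
  }
})

test_that("with no data rows the sampler reproduces the prior cascade", {
  # two images, one patient, one cohort; empty likelihood
  Q <- 3
  data <- list(X = matrix(0, 0, Q), Z = matrix(0, 0, 1), y = numeric(0),
               offset = numeric(0), img = integer(0),
               pat = c(0L, 0L), coh = 0L, M = 2L, N = 1L, G = 1L, J = 1L,
               Q = Q, hierarchical = TRUE, sd_beta = 5,
               sd_sigma = c(1, 1, 1), sd_delta_flat = 5)
  dim <- (1 + 1 + 2) * Q + 2 + 3
  set.seed(21)
  ch <- shade:::.shade_nuts_chain(data, rnorm(dim, 0, 0.2), 500, 3000, 0.9,
                                  10, 77, rep(1, dim))
  th <- ch$draws
  sig <- exp(th[, dim - 2:0, drop = FALSE])
  psi <- sig[, 1] * th[, 1:Q]
  gam <- psi + sig[, 2] * th[, Q + 1:Q]
  del1 <- gam + sig[, 3] * th[, 2 * Q + 1:Q]
  # marginal variances of the cascade: E[sigma^2] = 1 per level
  expect_equal(mean(apply(psi, 2, var)), 1, tolerance = 0.25)
  expect_equal(mean(apply(gam - psi, 2, var)), 1, tolerance = 0.25)
  expect_equal(mean(apply(del1 - gam, 2, var)), 1, tolerance = 0.25)
  # half-normal hyperprior: E|sigma| = sqrt(2/pi)
  expect_equal(colMeans(sig), rep(sqrt(2 / pi), 3), tolerance = 0.12)
})

test_that("fits are reproducible and respect basic structure", {
  ts <- tiny_study(seed = 31, patients = 2, images = 2, n = 40, side = 600)
  sc <- quick_sampler(chains = 2, warmup = 150, draws = 100)
  f1 <- fit_shade(ts$designs, ts$study$meta, sampler = sc, seed = 5)
  f2 <- fit_shade(ts$designs, ts$study$meta, sampler = sc, seed = 5)
  expect_identical(f1$draws$delta, f2$draws$delta)
  expect_s3_class(f1, "shade_fit")
  expect_equal(length(f1$image_ids), 8)
  expect_true(all(c("rhat", "ess") %in% names(f1$diagnostics)))
  # flat variant drops the hierarchy
  ff <- fit_flat(ts$designs[1:2], sampler = sc, seed = 5)
  expect_null(ff$draws$psi)
  expect_false(ff$hierarchical)
})

test_that("an image with zero target cells is dropped with a warning", {
  ts <- tiny_study(seed = 32, patients = 1, images = 2, n = 30, side = 500)
  empty <- point_pattern(numeric(0), numeric(0), character(0),
                         shade_window(500))
  des <- ts$designs[1:2]
  des[[3]] <- build_design(empty, des[[1]]$sources, ts$cfg$basis,
                           lambda_dummy = des[[1]]$lambda_dummy,
                           seed = 3, image_id = "empty_img")
  meta <- study_design(c(ts$study$meta$image_id[1:2], "empty_img"),
                       rep("p1", 3), rep("g1", 3))
  expect_warning(
    fit_shade(des, meta, sampler = quick_sampler(1, 100, 50), seed = 2),
    "zero target")
})

test_that("identical images give exchangeable image-level posteriors", {
  set.seed(12)
  w <- shade_window(600)
  target <- point_pattern(runif(60, 0, 600), runif(60, 0, 600), "t", w)
  src <- point_pattern(runif(60, 0, 600), runif(60, 0, 600), "s", w)
  spec <- basis_spec("gaussian_rbf")
  d1 <- build_design(target, list(s = src), spec, seed = 4, image_id = "a")
  d2 <- d1; d2$image_id <- "b"
  meta <- study_design(c("a", "b"), c("p1", "p1"), c("g", "g"))
  fit <- fit_shade(list(d1, d2), meta, sampler = quick_sampler(2, 200, 300),
                   seed = 9)
  m1 <- apply(fit$draws$delta[, 1, ], 2, mean)
  m2 <- apply(fit$draws$delta[, 2, ], 2, mean)
  expect_equal(m1, m2, tolerance = 0.12)
})

test_that("partial pooling shrinks image estimates toward the patient mean", {
  ts <- tiny_study(seed = 33, patients = 2, images = 3, n = 50, side = 700)
  sc <- quick_sampler(2, 200, 200)
  fh <- fit_shade(ts$designs, ts$study$meta, sampler = sc, seed = 3)
  ff <- fit_flat(ts$designs, sampler = sc, seed = 3)
  dh <- apply(fh$draws$delta, c(2, 3), mean)
  gh <- apply(fh$draws$gamma, c(2, 3), mean)
  df <- apply(ff$draws$delta, c(2, 3), mean)
  pat <- ts$study$meta$patient_id
  gap_h <- gap_f <- 0
  for (m in seq_len(nrow(dh))) {
    n <- match(pat[m], fh$patients)
    gap_h <- gap_h + mean(abs(dh[m, ] - gh[n, ]))
    gap_f <- gap_f + mean(abs(df[m, ] - colMeans(df[pat == pat[m], , drop = FALSE])))
  }
  expect_lt(gap_h, gap_f)
})
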