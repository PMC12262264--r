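#' Prior settings for the hierarchical and flat models
#'
#' Weakly-informative defaults on the log-intensity scale: Normal(0, 5^2) on
#' covariate coefficients, half-Normal(0, 1) on the three hierarchy standard
#' deviations, and Normal(0, 5^2) on the flat model's per-image interaction
#' coefficients.
#'
#' @param sd_beta Prior SD of covariate coefficients (per image).
#' @param sd_sigma Length-3 half-normal scales for `sigma_cohort`,
#'   `sigma_patient`, `sigma_image`.
#' @param sd_delta_flat Prior SD of the flat model's interaction
#'   coefficients.
#' @return A `shade_priors` list.
#' @export
shade_priors <- function(sd_beta = 5, sd_sigma = c(1, 1, 1),
                         sd_delta_flat = 5) {
  if (length(sd_sigma) == 1) sd_sigma <- rep(sd_sigma, 3)
  stopifnot(sd_beta > 0, length(sd_sigma) == 3, all(sd_sigma > 0),
            sd_delta_flat > 0)
  structure(list(sd_beta = sd_beta, sd_sigma = sd_sigma,
                 sd_delta_flat = sd_delta_flat), class = "shade_priors")
}

#' Sampler settings
#'
#' @param chains Number of NUTS chains (run sequentially).
#' @param warmup,draws Warmup and retained iterations per chain.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_treedepth Maximum tree depth per iteration.
#' @return A `sampler_control` list.
#' @export
sampler_control <- function(chains = 4, warmup = 1000, draws = 1000,
                            target_accept = 0.9, max_treedepth = 10) {
  stopifnot(chains >= 1, warmup >= 50, draws >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth)),
            class = "sampler_control")
}

# ---- data packing -----------------------------------------------------------

# Stack per-image designs into the flat structures the sampler consumes.
pack_designs <- function(designs, meta, priors, hierarchical) {
  stopifnot(length(designs) >= 1)
  ids <- vapply(designs, function(d) d$image_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicated image ids across designs")
  n1 <- vapply(designs, function(d) sum(d$y == 1), numeric(1))
  if (any(n1 == 0)) {
    warnf("dropping %d image(s) with zero target cells: %s",
          sum(n1 == 0), paste(ids[n1 == 0], collapse = ", "))
    designs <- designs[n1 > 0]
    ids <- ids[n1 > 0]
    if (!length(designs)) stopf("no images with target cells remain")
  }
  Q <- ncol(designs[[1]]$X)
  J <- ncol(designs[[1]]$Z)
  for (d in designs) {
    if (ncol(d$X) != Q || ncol(d$Z) != J) {
      stopf("designs disagree in feature or covariate dimension")
    }
  }
  X <- do.call(rbind, lapply(designs, `[[`, "X"))
  Z <- do.call(rbind, lapply(designs, `[[`, "Z"))
  y <- unlist(lapply(designs, `[[`, "y"), use.names = FALSE)
  nrow_i <- vapply(designs, function(d) length(d$y), numeric(1))
  img <- rep(seq_along(designs) - 1L, nrow_i)
  offset <- rep(vapply(designs, `[[`, numeric(1), "offset"), nrow_i)

  if (hierarchical) {
    idx <- design_indices(meta, ids)
    pat <- idx$pat; coh <- idx$coh
    patients <- idx$patients; cohorts <- idx$cohorts
  } else {
    pat <- rep(0L, length(designs)); coh <- 0L
    patients <- character(0); cohorts <- character(0)
  }
  list(data = list(X = X, Z = Z, y = y, offset = offset, img = img,
                   pat = pat, coh = coh,
                   M = length(designs), N = max(length(patients), 1L),
                   G = max(length(cohorts), 1L), J = J, Q = Q,
                   hierarchical = hierarchical,
                   sd_beta = priors$sd_beta, sd_sigma = priors$sd_sigma,
                   sd_delta_flat = priors$sd_delta_flat),
       designs = designs, image_ids = ids,
       patients = patients, cohorts = cohorts)
}

# deterministic chain initialisation near the zero-coefficient MLE
init_theta <- function(pk, chain_seed) {
  d <- pk$data
  dim <- if (d$hierarchical) (d$G + d$N + d$M) * d$Q + d$M * d$J + 3 else
    d$M * d$Q + d$M * d$J
  with_seed(chain_seed, {
    theta <- rnorm(dim, 0, 0.1)
    # per-image intercept matched to the observed real:dummy ratio
    off_beta <- if (d$hierarchical) (d$G + d$N + d$M) * d$Q else d$M * d$Q
    for (m in seq_len(d$M)) {
      rows <- d$img == (m - 1L)
      n1 <- sum(d$y[rows]); n0 <- sum(rows) - n1
      theta[off_beta + (m - 1) * d$J + 1] <-
        log(pmax(n1, 0.5) / pmax(n0, 0.5)) + d$offset[which(rows)[1]] +
        rnorm(1, 0, 0.1)
    }
    if (d$hierarchical) {
      theta[(dim - 2):dim] <- rnorm(3, log(0.5), 0.1)  # log sigma
    }
    theta
  })
}

# ---- fitting ----------------------------------------------------------------

run_chains <- function(pk, sampler, seed) {
  d <- pk$data
  # initial diagonal metric guess: unit scale for the (non-centered) raw
  # coefficients, much tighter for the well-identified per-image intercepts
  dim <- if (d$hierarchical) (d$G + d$N + d$M) * d$Q + d$M * d$J + 3 else
    d$M * d$Q + d$M * d$J
  minv0 <- rep(1, dim)
  off_beta <- if (d$hierarchical) (d$G + d$N + d$M) * d$Q else d$M * d$Q
  minv0[off_beta + seq_len(d$M * d$J)] <- 0.02
  if (d$hierarchical) minv0[(dim - 2):dim] <- 0.1
  chains <- vector("list", sampler$chains)
  for (ch in seq_len(sampler$chains)) {
    init <- init_theta(pk, chain_seed = seed * 131 + ch)
    chains[[ch]] <- .shade_nuts_chain(d, init, sampler$warmup, sampler$draws,
                                      sampler$target_accept,
                                      sampler$max_treedepth,
                                      seed * 1e5 + ch, minv0)
  }
  chains
}

# reshape unconstrained draws into constrained coefficient arrays
constrain_draws <- function(pk, chains, K, P) {
  d <- pk$data
  S <- nrow(chains[[1]]$draws)
  theta <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_along(chains), each = S)
  M <- d$M; N <- d$N; G <- d$G; J <- d$J; Q <- d$Q
  tot <- nrow(theta)
  if (d$hierarchical) {
    ls <- theta[, (G + N + M) * Q + M * J + 1:3, drop = FALSE]
    sig <- exp(ls)
    psi <- array(0, c(tot, G, Q))
    for (g in seq_len(G)) {
      psi[, g, ] <- sig[, 1] * theta[, (g - 1) * Q + seq_len(Q), drop = FALSE]
    }
    gamma <- array(0, c(tot, N, Q))
    idx <- design_indices_cached(pk)
    for (n in seq_len(N)) {
      raw <- theta[, G * Q + (n - 1) * Q + seq_len(Q), drop = FALSE]
      gamma[, n, ] <- psi[, idx$coh_of_pat[n] + 1L, ] + sig[, 2] * raw
    }
    delta <- array(0, c(tot, M, Q))
    for (m in seq_len(M)) {
      raw <- theta[, (G + N) * Q + (m - 1) * Q + seq_len(Q), drop = FALSE]
      delta[, m, ] <- gamma[, idx$pat_of_img[m] + 1L, ] + sig[, 3] * raw
    }
    # packed beta block is image-major, covariate within image
    beta <- array(0, c(tot, M, J))
    for (m in seq_len(M)) {
      beta[, m, ] <- theta[, (G + N + M) * Q + (m - 1) * J + seq_len(J),
                           drop = FALSE]
    }
    list(psi = psi, gamma = gamma, delta = delta, beta = beta,
         sigma = sig, chain = chain_id)
  } else {
    delta <- array(0, c(tot, M, Q))
    for (m in seq_len(M)) {
      delta[, m, ] <- theta[, (m - 1) * Q + seq_len(Q), drop = FALSE]
    }
    beta <- array(0, c(tot, M, J))
    for (m in seq_len(M)) {
      beta[, m, ] <- theta[, M * Q + (m - 1) * J + seq_len(J), drop = FALSE]
    }
    list(delta = delta, beta = beta, chain = chain_id)
  }
}

design_indices_cached <- function(pk) {
  if (pk$data$hierarchical) {
    list(pat_of_img = pk$data$pat, coh_of_pat = pk$data$coh)
  } else {
    list(pat_of_img = rep(0L, pk$data$M), coh_of_pat = 0L)
  }
}

finish_fit <- function(pk, chains, sampler, priors, seed, hierarchical,
                       meta = NULL) {
  spec <- pk$designs[[1]]$spec
  P <- spec$P
  K <- pk$data$Q / P
  con <- constrain_draws(pk, chains, K, P)
  div <- sum(vapply(chains, `[[`, numeric(1), "divergences"))
  total_draws <- sampler$chains * sampler$draws
  diag <- fit_diagnostics(con, sampler)
  if (div >= total_draws) {
    stop(structure(class = c("shade_sampler_error", "error", "condition"),
                   list(message = paste0(
                     "sampler failure: every post-warmup iteration diverged (",
                     div, "/", total_draws, ")"),
                     call = NULL, diagnostics = diag)))
  }
  structure(list(
    draws = con, hierarchical = hierarchical,
    image_ids = pk$image_ids, patients = pk$patients, cohorts = pk$cohorts,
    source_types = names(pk$designs[[1]]$sources),
    K = K, P = P, spec = spec,
    designs = pk$designs, meta = meta,
    diagnostics = diag, divergences = div,
    step_size = vapply(chains, `[[`, numeric(1), "step_size"),
    accept_stat = vapply(chains, `[[`, numeric(1), "accept_stat"),
    sampler = sampler, priors = priors, seed = seed),
    class = "shade_fit")
}

#' Fit the hierarchical spatial interaction model
#'
#' Multilevel Bayesian logistic regression for the dummy-point approximation
#' of the conditional-intensity model: per-image interaction coefficients
#' `delta` are partially pooled toward patient-level `gamma` and cohort-level
#' `psi` through a Gaussian cascade with half-normal hyperpriors on the three
#' level standard deviations. Sampling uses the package's adaptive NUTS
#' sampler on a non-centered parameterization (posterior-invariant).
#'
#' @param designs List of [build_design()] objects, one per image. Images
#'   with zero target cells are dropped with a warning.
#' @param design_meta A [study_design()] covering every design's `image_id`.
#' @param priors A [shade_priors()].
#' @param sampler A [sampler_control()].
#' @param seed Integer seed; fits are reproducible given the seed.
#' @return A `shade_fit` object holding posterior draws of `psi` (cohort),
#'   `gamma` (patient), `delta` (image), `beta`, and the three `sigma`s,
#'   plus split-Rhat/ESS diagnostics and divergence counts.
#' @export
fit_shade <- function(designs, design_meta, priors = shade_priors(),
                      sampler = sampler_control(), seed = 1) {
  pk <- pack_designs(designs, design_meta, priors, hierarchical = TRUE)
  chains <- run_chains(pk, sampler, seed)
  finish_fit(pk, chains, sampler, priors, seed, TRUE, meta = design_meta)
}

#' Fit the non-hierarchical ("flat") model
#'
#' Each image's interaction coefficients get independent weakly-informative
#' Normal priors; there is no pooling across images, patients, or cohorts.
#'
#' @inheritParams fit_shade
#' @return A `shade_fit` with `delta` and `beta` draws only.
#' @export
fit_flat <- function(designs, priors = shade_priors(),
                     sampler = sampler_control(), seed = 1) {
  pk <- pack_designs(designs, NULL, priors, hierarchical = FALSE)
  chains <- run_chains(pk, sampler, seed)
  finish_fit(pk, chains, sampler, priors, seed, FALSE)
}

#' @export
print.shade_fit <- function(x, ...) {
  cat(sprintf("shade_fit (%s): %d image(s), %d source type(s), P = %d\n",
              if (x$hierarchical) "hierarchical" else "flat",
              length(x$image_ids), x$K, x$P))
  cat(sprintf("  %d chains x %d draws; %d divergence(s); max split-Rhat %.3f\n",
              x$sampler$chains, x$sampler$draws, x$divergences,
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

# ---- reference log posterior (centered parameterization) --------------------

#' Joint log posterior of the hierarchical model (reference implementation)
#'
#' Direct, centered-parameterization evaluation of the model's log posterior:
#' Bernoulli log-likelihood of all design rows with logit
#' `z'beta + sum_k q_k' delta_k(m) - log(lambda_dummy)`, plus the Gaussian
#' hierarchy densities and hyperpriors. Used for verification and exposed for
#' diagnostics; the sampler uses an equivalent non-centered form internally.
#'
#' @param tree List with `psi` (G x Q), `gamma` (N x Q), `delta` (M x Q) and
#'   `beta` (M x J) matrices, where `Q = K * P` feature columns.
#' @param vc List with positive scalars `sigma_cohort`, `sigma_patient`,
#'   `sigma_image`.
#' @param designs List of [build_design()] objects (same order as `delta`
#'   rows).
#' @param design_meta A [study_design()].
#' @param priors A [shade_priors()].
#' @return Scalar log posterior (unnormalized).
#' @export
log_posterior <- function(tree, vc, designs, design_meta,
                          priors = shade_priors()) {
  ids <- vapply(designs, function(d) d$image_id, character(1))
  idx <- design_indices(design_meta, ids)
  psi <- as.matrix(tree$psi); gam <- as.matrix(tree$gamma)
  delta <- as.matrix(tree$delta); beta <- as.matrix(tree$beta)
  stopifnot(all(c(vc$sigma_cohort, vc$sigma_patient, vc$sigma_image) > 0))
  lp <- 0
  log1pexp <- function(x) ifelse(x > 35, x, ifelse(x < -35, exp(x), log1p(exp(x))))
  for (m in seq_along(designs)) {
    d <- designs[[m]]
    if (any(!is.finite(d$X))) stopf("non-finite features in image %s", ids[m])
    eta <- drop(d$Z %*% beta[m, ] + d$X %*% delta[m, ]) - d$offset
    lp <- lp + sum(d$y * eta - log1pexp(eta))
  }
  # hierarchy (Gaussian cascade)
  for (m in seq_along(designs)) {
    lp <- lp + sum(dnorm2(delta[m, ], gam[idx$pat[m] + 1L, ], vc$sigma_image))
  }
  for (n in seq_len(nrow(gam))) {
    lp <- lp + sum(dnorm2(gam[n, ], psi[idx$coh[n] + 1L, ], vc$sigma_patient))
  }
  lp <- lp + sum(dnorm2(psi, 0, vc$sigma_cohort))
  lp <- lp + sum(dnorm2(beta, 0, priors$sd_beta))
  # half-normal hyperpriors
  lp <- lp + dnorm2(vc$sigma_cohort, 0, priors$sd_sigma[1]) +
    dnorm2(vc$sigma_patient, 0, priors$sd_sigma[2]) +
    dnorm2(vc$sigma_image, 0, priors$sd_sigma[3]) + 3 * log(2)
  lp
}

dnorm2 <- function(x, mu, sd) {
  -0.5 * ((x - mu) / sd)^2 - log(sd) - 0.5 * log(2 * pi)
}
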