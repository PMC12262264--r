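#' Configuration of a synthetic multilevel study
#'
#' Defines the hierarchical simulation: cohorts of patients with several
#' images each, source points from a homogeneous (binomial) process and
#' target points attracted/repelled according to known spatial interaction
#' curves, with image- and patient-level coefficient variation following the
#' model's Gaussian cascade.
#'
#' Defaults mirror the package's reference simulation design: two cohorts of
#' 20 patients with 4 images each, 150 points of each type in a
#' 1500 x 1500 um window, dummy-to-real ratio 2, three Gaussian RBFs at
#' 20/40/60 um (width 10) as the truth basis, cohort-level truth
#' `+-(1.0, 0.5, 0.25)` (first cohort attractive at all scales, second
#' repulsive), and level SDs `sigma_patient = 0.2`, `sigma_image = 0.1`.
#'
#' @param n_cohorts,patients_per_cohort,images_per_patient Design counts.
#' @param n_source,n_target Points per type per image (fixed counts by
#'   default; see `poisson_counts`).
#' @param window_side Square window side length (microns).
#' @param dummy_ratio Expected dummy-to-real point ratio.
#' @param psi_truth Cohort-level true coefficients: array `[G, K, P]` (or a
#'   G x P matrix when K = 1).
#' @param sigma_patient,sigma_image Level SDs of the coefficient cascade.
#' @param basis A [basis_spec()] for the truth (default: the 3-RBF basis).
#' @param poisson_counts If `TRUE`, per-image counts are Poisson with the
#'   given means instead of fixed.
#' @param seed Base seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 2, patients_per_cohort = 20,
                       images_per_patient = 4, n_source = 150,
                       n_target = 150, window_side = 1500, dummy_ratio = 2,
                       psi_truth = NULL, sigma_patient = 0.2,
                       sigma_image = 0.1, basis = NULL,
                       poisson_counts = FALSE, seed = 1) {
  basis <- basis %||% basis_spec("gaussian_rbf")
  if (is.null(psi_truth)) {
    base <- c(1.0, 0.5, 0.25)[seq_len(min(3, basis$P))]
    base <- c(base, rep(0.25, max(0, basis$P - 3)))
    psi_truth <- array(0, c(n_cohorts, 1, basis$P))
    for (g in seq_len(n_cohorts)) {
      psi_truth[g, 1, ] <- if (g %% 2 == 1) base else -base
    }
  }
  if (length(dim(psi_truth)) == 2) {
    psi_truth <- array(psi_truth, c(nrow(psi_truth), 1, ncol(psi_truth)))
  }
  stopifnot(n_cohorts >= 1, patients_per_cohort >= 1, images_per_patient >= 1,
            n_source >= 0, n_target >= 0, window_side > 0,
            sigma_patient >= 0, sigma_image >= 0,
            dim(psi_truth)[1] == n_cohorts, dim(psi_truth)[3] == basis$P)
  structure(list(n_cohorts = n_cohorts,
                 patients_per_cohort = patients_per_cohort,
                 images_per_patient = images_per_patient,
                 n_source = n_source, n_target = n_target,
                 window_side = window_side, dummy_ratio = dummy_ratio,
                 psi_truth = psi_truth, sigma_patient = sigma_patient,
                 sigma_image = sigma_image, basis = basis,
                 poisson_counts = poisson_counts, seed = seed),
            class = "sim_config")
}

#' Draw the true coefficient hierarchy
#'
#' Cohort-level coefficients are fixed at the configured truth; patient- and
#' image-level coefficients follow the Gaussian cascade
#' `gamma ~ N(psi, sigma_patient^2)`, `delta ~ N(gamma, sigma_image^2)`.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed`).
#' @return List with `psi` `[G, K, P]`, `gamma` `[N, K, P]`, `delta`
#'   `[M, K, P]` arrays and a [study_design()] in `$meta`.
#' @export
draw_coefficient_tree <- function(config, seed = config$seed) {
  G <- config$n_cohorts
  Np <- config$patients_per_cohort
  Mi <- config$images_per_patient
  K <- dim(config$psi_truth)[2]
  P <- dim(config$psi_truth)[3]
  N <- G * Np
  M <- N * Mi
  coh_of_pat <- rep(seq_len(G), each = Np)
  pat_of_img <- rep(seq_len(N), each = Mi)
  with_seed(seed, {
    gamma <- array(0, c(N, K, P))
    for (n in seq_len(N)) {
      gamma[n, , ] <- config$psi_truth[coh_of_pat[n], , ] +
        rnorm(K * P, 0, config$sigma_patient)
    }
    delta <- array(0, c(M, K, P))
    for (m in seq_len(M)) {
      delta[m, , ] <- gamma[pat_of_img[m], , ] +
        rnorm(K * P, 0, config$sigma_image)
    }
    meta <- study_design(
      image_id = sprintf("img%03d", seq_len(M)),
      patient_id = sprintf("pat%03d", pat_of_img),
      group_id = sprintf("cohort%d", coh_of_pat[pat_of_img]))
    list(psi = config$psi_truth, gamma = gamma, delta = delta, meta = meta)
  })
}

#' Simulate one image's source and target patterns
#'
#' Source points are a binomial process (`n_source` i.i.d. uniform points).
#' Targets are drawn from the inhomogeneous density proportional to
#' `exp(sum_k q_k(v)' delta_k)` by rejection sampling against a
#' grid-estimated maximum (256 x 256 proposal grid, bound inflated 10%).
#'
#' @param delta K x P matrix (or length-P vector for K = 1) of true
#'   image-level coefficients.
#' @param n_source,n_target Point counts (the sources may be a vector, one
#'   count per source type).
#' @param window A [shade_window()] or `c(Sx, Sy)`.
#' @param spec A [basis_spec()].
#' @param seed Optional seed.
#' @param source_names Names for the source types.
#' @param grid_n Proposal grid resolution per axis.
#' @param sources Optional named list of fixed source patterns to condition
#'   on (skips source generation; `n_source` is then ignored).
#' @return List with `sources` (named list of patterns), `targets`
#'   (pattern), and `acceptance_rate`.
#' @export
simulate_image <- function(delta, n_source, n_target, window, spec,
                           seed = NULL, source_names = NULL, grid_n = 256,
                           sources = NULL) {
  window <- as_window(window)
  if (is.null(dim(delta))) delta <- matrix(delta, 1)
  K <- nrow(delta)
  stopifnot(ncol(delta) == spec$P, n_target >= 0, all(n_source >= 0))
  if (length(n_source) == 1) n_source <- rep(n_source, K)
  source_names <- source_names %||% paste0("source", seq_len(K))
  with_seed(seed, {
    if (is.null(sources)) {
      sources <- list()
      for (k in seq_len(K)) {
        sources[[source_names[k]]] <- point_pattern(
          runif(n_source[k], window$xrange[1], window$xrange[2]),
          runif(n_source[k], window$yrange[1], window$yrange[2]),
          rep(source_names[k], n_source[k]), window)
      }
    }
    stopifnot(length(sources) == K)
    log_dens <- function(locs) {
      v <- numeric(nrow(locs))
      for (k in seq_len(K)) {
        v <- v + drop(interaction_features(locs, sources[[k]], spec) %*%
                        delta[k, ])
      }
      v
    }
    # grid bound for rejection sampling
    gx <- seq(window$xrange[1], window$xrange[2], length.out = grid_n)
    gy <- seq(window$yrange[1], window$yrange[2], length.out = grid_n)
    grid <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
    log_bound <- max(log_dens(grid)) + log(1.1)
    tx <- numeric(0); ty <- numeric(0)
    proposed <- 0; accepted <- 0
    while (length(tx) < n_target) {
      nb <- max(4 * (n_target - length(tx)), 64)
      px <- runif(nb, window$xrange[1], window$xrange[2])
      py <- runif(nb, window$yrange[1], window$yrange[2])
      keep <- log(runif(nb)) < log_dens(cbind(px, py)) - log_bound
      proposed <- proposed + nb
      accepted <- accepted + sum(keep)
      tx <- c(tx, px[keep]); ty <- c(ty, py[keep])
      if (proposed > 1e4 && accepted / proposed < 1e-4) {
        stopf(paste("rejection sampling acceptance rate below 1e-4;",
                    "use smaller interaction coefficients"))
      }
    }
    list(sources = sources,
         targets = point_pattern(tx[seq_len(n_target)], ty[seq_len(n_target)],
                                 rep("target", n_target), window),
         acceptance_rate = if (proposed > 0) accepted / proposed else 1)
  })
}

#' Simulate a full multilevel study
#'
#' Composes [draw_coefficient_tree()] and [simulate_image()] across the
#' configured design. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `simulated_study`: list with `images` (per-image list of
#'   `sources` and `targets`), `truth` (the realized coefficient tree),
#'   `meta` ([study_design()]) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- draw_coefficient_tree(config, seed = config$seed)
  M <- nrow(truth$meta)
  window <- shade_window(config$window_side)
  images <- vector("list", M)
  names(images) <- truth$meta$image_id
  with_seed(config$seed + 1L, {
    for (m in seq_len(M)) {
      ns <- config$n_source
      nt <- config$n_target
      if (config$poisson_counts) {
        ns <- rpois(1, ns); nt <- rpois(1, nt)
      }
      images[[m]] <- simulate_image(
        matrix(truth$delta[m, , ], dim(truth$delta)[2]),
        ns, nt, window, config$basis)
    }
  })
  structure(list(images = images, truth = truth, meta = truth$meta,
                 config = config),
            class = "simulated_study")
}

#' Build per-image designs from a simulated study
#'
#' @param study A [simulate_study()] result.
#' @param seed Seed for the dummy points (per image, derived).
#' @param dummy_ratio Dummy-to-real ratio (default from the config).
#' @return List of [build_design()] objects.
#' @export
study_designs <- function(study, seed = study$config$seed,
                          dummy_ratio = study$config$dummy_ratio) {
  lapply(seq_along(study$images), function(m) {
    im <- study$images[[m]]
    build_design(im$targets, im$sources, study$config$basis,
                 dummy_ratio = dummy_ratio, seed = seed + 7919L * m,
                 image_id = study$meta$image_id[m])
  })
}

#' Coefficient RMSE against the simulation truth
#'
#' Root-mean-square error of posterior-mean image-level coefficients against
#' the realized truth, per basis index, grouped by spatial scale, and in
#' aggregate.
#'
#' @param fit A `shade_fit` on designs built from the simulated study (image
#'   order must match `truth$delta`).
#' @param truth Truth tree from [simulate_study()]/[draw_coefficient_tree()].
#' @param scale_map Character vector of length P mapping basis index to
#'   `small`/`medium`/`large` (default: the fit's basis `scale_map`).
#' @return List with `aggregate` (scalar RMSE over all image-coefficient
#'   pairs), `by_scale` (named vector), and `per_basis`.
#' @export
rmse_eval <- function(fit, truth, scale_map = NULL) {
  stopifnot(inherits(fit, "shade_fit"))
  scale_map <- scale_map %||% fit$spec$scale_map
  M <- length(fit$image_ids)
  K <- fit$K; P <- fit$P
  td <- truth$delta
  idx <- match(fit$image_ids, truth$meta$image_id)
  if (anyNA(idx)) idx <- seq_len(M)
  if (!all(dim(td)[2:3] == c(K, P)) || max(idx) > dim(td)[1]) {
    stopf("truth and fit coefficient shapes do not match")
  }
  est <- apply(fit$draws$delta, c(2, 3), mean)  # M x (K*P)
  err <- matrix(0, M, K * P)
  for (m in seq_len(M)) {
    err[m, ] <- est[m, ] - as.vector(t(matrix(td[idx[m], , ], K, P)))
  }
  per_basis <- sqrt(colMeans(err^2))  # length K*P, basis within source
  scale_of_col <- rep(scale_map, K)
  by_scale <- vapply(c("small", "medium", "large"), function(s) {
    cols <- scale_of_col == s
    if (any(cols)) mean(per_basis[cols]) else NA_real_
  }, numeric(1))
  list(aggregate = sqrt(mean(err^2)), by_scale = by_scale,
       per_basis = per_basis)
}
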