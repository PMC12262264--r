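# shared fixtures, built in code

quick_sampler <- function(chains = 2, warmup = 150, draws = 150) {
  sampler_control(chains = chains, warmup = warmup, draws = draws)
}

# a small two-cohort study for fitting tests
tiny_study <- function(seed = 7, patients = 2, images = 2, n = 60,
                       side = 700) {
  cfg <- sim_config(n_cohorts = 2, patients_per_cohort = patients,
                    images_per_patient = images, n_source = n, n_target = n,
                    window_side = side, seed = seed)
  study <- simulate_study(cfg)
  list(cfg = cfg, study = study, designs = study_designs(study))
}

# hand-construct a shade_fit from given coefficient draws (no MCMC), for
# testing posterior summaries independently of the sampler
make_fit <- function(delta, beta = NULL, psi = NULL, gamma = NULL,
                     sigma = NULL, spec = basis_spec("gaussian_rbf"),
                     image_ids = NULL, patients = NULL, cohorts = NULL,
                     source_types = "source1", designs = NULL, meta = NULL,
                     seed = 1) {
  S <- dim(delta)[1]; M <- dim(delta)[2]
  P <- spec$P
  K <- dim(delta)[3] / P
  if (is.null(beta)) beta <- array(0, c(S, M, 1))
  draws <- list(delta = delta, beta = beta,
                chain = rep(1:2, length.out = S))
  hier <- !is.null(psi)
  if (hier) {
    draws$psi <- psi
    draws$gamma <- gamma
    draws$sigma <- sigma %||% matrix(0.5, S, 3)
  }
  structure(list(
    draws = draws, hierarchical = hier,
    image_ids = image_ids %||% paste0("img", seq_len(M)),
    patients = patients %||% character(0),
    cohorts = cohorts %||% character(0),
    source_types = source_types, K = K, P = P, spec = spec,
    designs = designs, meta = meta,
    diagnostics = data.frame(), divergences = 0,
    sampler = sampler_control(chains = 2, warmup = 50, draws = S / 2),
    priors = shade_priors(), seed = seed), class = "shade_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Cox-de Boor recursion used as the B-spline oracle
deboor <- function(knots, x, p, ord) {
  if (ord == 1) {
    hi <- knots[p + 1]
    if (knots[p] >= hi) return(numeric(length(x)))  # degenerate interval
    # half-open intervals, except the last one is closed at the top knot
    upper <- if (hi >= max(knots)) x <= hi else x < hi
    return(as.numeric(x >= knots[p] & upper))
  }
  d1 <- knots[p + ord - 1] - knots[p]
  d2 <- knots[p + ord] - knots[p + 1]
  t1 <- if (d1 > 0) (x - knots[p]) / d1 * deboor(knots, x, p, ord - 1) else 0
  t2 <- if (d2 > 0) (knots[p + ord] - x) / d2 * deboor(knots, x, p + 1, ord - 1) else 0
  t1 + t2
}

# Berman-Turner quadrature fit of the inhomogeneous Poisson model (oracle):
# counting-measure quadrature on a regular grid, log-linear intensity
poisson_ml_fit <- function(target, source, spec, spacing) {
  w <- target$window
  gx <- seq(w$xrange[1] + spacing / 2, w$xrange[2], by = spacing)
  gy <- seq(w$yrange[1] + spacing / 2, w$yrange[2], by = spacing)
  quad <- rbind(coords_matrix_test(target),
                cbind(rep(gx, each = length(gy)), rep(gy, length(gx))))
  is_data <- c(rep(TRUE, length(target$x)), rep(FALSE, length(gx) * length(gy)))
  cell <- paste(pmin(floor((quad[, 1] - w$xrange[1]) / spacing),
                     length(gx) - 1),
                pmin(floor((quad[, 2] - w$yrange[1]) / spacing),
                     length(gy) - 1))
  wts <- spacing^2 / as.vector(table(cell)[cell])
  z <- ifelse(is_data, 1 / wts, 0)
  X <- interaction_features(quad, source, spec)
  fit <- suppressWarnings(
    glm(z ~ X, family = poisson(), weights = wts))
  unname(coef(fit))
}

coords_matrix_test <- function(pp) cbind(pp$x, pp$y)
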