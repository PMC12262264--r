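#' Dummy points from a homogeneous Poisson process
#'
#' Quadrature ("dummy") points used to turn the inhomogeneous-Poisson
#' likelihood into a logistic regression: real target cells are labelled 1,
#' dummy points 0, and the known dummy intensity enters the logit as an
#' offset.
#'
#' @param window A [shade_window()] (or `c(Sx, Sy)`).
#' @param lambda_dummy Intensity, points per square micron (> 0).
#' @param seed Optional integer; when given, generation is reproducible and
#'   leaves the global RNG stream untouched.
#' @return A single-type `point_pattern` of dummy points (type `"dummy"`).
#' @export
generate_dummy_points <- function(window, lambda_dummy, seed = NULL) {
  window <- as_window(window)
  if (!is.finite(lambda_dummy) || lambda_dummy <= 0) {
    stopf("lambda_dummy must be positive")
  }
  area <- window_area(window)
  with_seed(seed, {
    n <- rpois(1, lambda_dummy * area)
    point_pattern(runif(n, window$xrange[1], window$xrange[2]),
                  runif(n, window$yrange[1], window$yrange[2]),
                  rep("dummy", n), window)
  })
}

#' Assemble the logistic design matrix for one image
#'
#' Rows are the observed target cells (label 1) followed by dummy points
#' (label 0). Each row carries the interaction features `q_k(v)` for every
#' source type, the covariate vector `z(v)` (an intercept column by default),
#' and the constant offset `log(lambda_dummy)`.
#'
#' @param target Single-type `point_pattern` of the target cell type.
#' @param sources Named list of single-type `point_pattern`s (one per source
#'   type); all windows must match the target's.
#' @param spec A [basis_spec()].
#' @param lambda_dummy Dummy intensity; default `dummy_ratio` times the
#'   observed target intensity.
#' @param dummy_ratio Expected dummy-to-real point ratio used when
#'   `lambda_dummy` is not given (default 2).
#' @param covariates Optional function `(x, y) -> matrix` of extra covariate
#'   columns; an intercept column of ones is always prepended.
#' @param seed Optional integer seed for the dummy points.
#' @param image_id Identifier attached to the design (default `"image"`).
#' @return An object of class `shade_design`: list with `X` (n x K*P
#'   features), `Z` (n x J covariates), `y` (labels), `offset`
#'   (`log(lambda_dummy)`), `lambda_dummy`, `image_id`, `sources`, `target`,
#'   `dummy`, `spec`.
#' @export
build_design <- function(target, sources, spec, lambda_dummy = NULL,
                         dummy_ratio = 2, covariates = NULL, seed = NULL,
                         image_id = "image") {
  stopifnot(inherits(target, "point_pattern"), is.list(sources),
            inherits(spec, "basis_spec"))
  if (is.null(names(sources)) || any(names(sources) == "")) {
    stopf("sources must be a named list of point patterns")
  }
  for (nm in names(sources)) {
    if (!inherits(sources[[nm]], "point_pattern")) {
      stopf("unknown source type '%s': not a point pattern", nm)
    }
    if (!same_window(sources[[nm]]$window, target$window)) {
      stopf("source '%s' has a different window than the target", nm)
    }
  }
  n1 <- length(target$x)
  area <- window_area(target$window)
  if (is.null(lambda_dummy)) {
    if (n1 == 0) stopf("cannot derive lambda_dummy from an empty target")
    lambda_dummy <- dummy_ratio * n1 / area
  }
  dummy <- generate_dummy_points(target$window, lambda_dummy, seed = seed)
  locs <- rbind(coords_matrix(target), coords_matrix(dummy))
  K <- length(sources)
  P <- spec$P
  X <- matrix(0, nrow(locs), K * P)
  for (k in seq_len(K)) {
    X[, (k - 1) * P + seq_len(P)] <-
      interaction_features(locs, sources[[k]], spec)
  }
  colnames(X) <- paste(rep(names(sources), each = P), rep(seq_len(P), K),
                       sep = ".")
  Z <- matrix(1, nrow(locs), 1)
  colnames(Z) <- "intercept"
  if (!is.null(covariates)) {
    extra <- as.matrix(covariates(locs[, 1], locs[, 2]))
    stopifnot(nrow(extra) == nrow(locs))
    Z <- cbind(Z, extra)
  }
  structure(list(X = X, Z = Z,
                 y = c(rep(1, n1), rep(0, length(dummy$x))),
                 offset = log(lambda_dummy), lambda_dummy = lambda_dummy,
                 image_id = image_id, sources = sources, target = target,
                 dummy = dummy, spec = spec),
            class = "shade_design")
}

#' @export
print.shade_design <- function(x, ...) {
  cat(sprintf(
    "shade_design '%s': %d real + %d dummy rows, %d source type(s), P = %d\n",
    x$image_id, sum(x$y == 1), sum(x$y == 0), length(x$sources), x$spec$P))
  invisible(x)
}
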