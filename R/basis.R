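#' Distance basis specification
#'
#' The spatial interaction curve is expanded in `P` nonnegative basis
#' functions of distance, `phi_p(s)`, supported on `[0, r_max]`. Two families
#' are provided: cubic B-splines with equally spaced knots (the default for
#' data analysis) and Gaussian radial basis functions (used for
#' short/medium/long-range simulation truths). Both families are truncated to
#' zero beyond `r_max`.
#'
#' @param family `"bspline"` or `"gaussian_rbf"`.
#' @param P Number of basis functions (>= 1). For `gaussian_rbf`, defaults to
#'   `length(centers)`.
#' @param r_max Support radius in microns; `phi_p(s) = 0` for `s > r_max`.
#' @param knots Optional full knot vector for the B-spline family; by default
#'   cubic splines with boundary knots at 0 and `r_max` and equally spaced
#'   interior knots.
#' @param centers,widths Gaussian RBF centers and widths (microns). Defaults:
#'   centers `c(20, 40, 60)`, width 10, matching short-, medium- and
#'   long-range interaction scales.
#' @param scale_map Optional character vector of length `P` with values in
#'   `"small"`, `"medium"`, `"large"` used to group coefficients when
#'   reporting error by spatial scale. Default: for `P = 3`, basis order maps
#'   to small/medium/large; otherwise each basis function is assigned by the
#'   location of its peak within thirds of `[0, r_max]`.
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(family = c("bspline", "gaussian_rbf"), P = NULL,
                       r_max = NULL, knots = NULL, centers = NULL,
                       widths = NULL, scale_map = NULL) {
  family <- match.arg(family)
  if (family == "bspline") {
    P <- P %||% 6L
    r_max <- r_max %||% 150
    if (r_max <= 0) stopf("r_max must be positive")
    if (P < 4) stopf("cubic B-spline basis needs P >= 4")
    if (is.null(knots)) {
      interior <- if (P > 4) seq(0, r_max, length.out = P - 2)[-c(1, P - 2)] else numeric(0)
      knots <- c(rep(0, 4), interior, rep(r_max, 4))
    }
    if (length(knots) != P + 4) stopf("knot vector must have length P + 4")
    spec <- list(family = family, P = as.integer(P), r_max = r_max,
                 knots = as.numeric(knots))
  } else {
    centers <- centers %||% c(20, 40, 60)
    P <- P %||% length(centers)
    if (length(centers) != P) stopf("need one center per basis function")
    widths <- widths %||% rep(10, P)
    if (length(widths) == 1) widths <- rep(widths, P)
    r_max <- r_max %||% (max(centers) + 4 * max(widths))
    if (r_max <= 0) stopf("r_max must be positive")
    spec <- list(family = family, P = as.integer(P), r_max = r_max,
                 centers = as.numeric(centers), widths = as.numeric(widths))
  }
  spec$scale_map <- scale_map %||% default_scale_map(spec)
  stopifnot(length(spec$scale_map) == spec$P,
            all(spec$scale_map %in% c("small", "medium", "large")))
  structure(spec, class = "basis_spec")
}

# peak location of each basis function (RBF center / B-spline Greville site)
basis_peaks <- function(spec) {
  if (spec$family == "gaussian_rbf") return(spec$centers)
  k <- spec$knots
  vapply(seq_len(spec$P), function(p) mean(k[(p + 1):(p + 3)]), numeric(1))
}

default_scale_map <- function(spec) {
  if (spec$P == 3) return(c("small", "medium", "large"))
  peaks <- basis_peaks(spec)
  cuts <- c(spec$r_max / 3, 2 * spec$r_max / 3)
  ifelse(peaks < cuts[1], "small", ifelse(peaks < cuts[2], "medium", "large"))
}

#' Evaluate the distance basis
#'
#' @param spec A [basis_spec()].
#' @param distances Nonnegative distances in microns.
#' @return A `length(distances) x P` matrix with entry `(i, p)` equal to
#'   `phi_p(distances[i])`; rows are identically zero beyond `r_max`.
#' @export
eval_basis <- function(spec, distances) {
  stopifnot(inherits(spec, "basis_spec"))
  distances <- as.numeric(distances)
  if (length(distances) && any(distances < 0, na.rm = TRUE)) {
    stopf("distances must be nonnegative")
  }
  if (anyNA(distances)) stopf("distances must be finite")
  B <- matrix(0, length(distances), spec$P)
  inside <- distances <= spec$r_max
  if (any(inside)) {
    s <- distances[inside]
    if (spec$family == "bspline") {
      B[inside, ] <- splines::splineDesign(spec$knots, s, ord = 4,
                                           outer.ok = TRUE)
    } else {
      for (p in seq_len(spec$P)) {
        B[inside, p] <- exp(-(s - spec$centers[p])^2 / (2 * spec$widths[p]^2))
      }
    }
  }
  B
}

#' Spatial interaction features
#'
#' For each target location `v`, the feature vector is the basis-weighted sum
#' of distances to all points of one source pattern:
#' `q_p(v) = sum_x phi_p(dist(v, x))`. Source points farther than `r_max`
#' contribute exactly zero and are pruned from the computation.
#'
#' @param targets A `point_pattern`, or an `n x 2` matrix of locations
#'   (microns). When a pattern, its window must match the source's.
#' @param source A single-type `point_pattern` of source cells.
#' @param spec A [basis_spec()].
#' @param chunk Internal chunk size for the distance computation.
#' @return An `n x P` feature matrix.
#' @export
interaction_features <- function(targets, source, spec, chunk = 2048L) {
  stopifnot(inherits(source, "point_pattern"), inherits(spec, "basis_spec"))
  if (inherits(targets, "point_pattern")) {
    if (!same_window(targets$window, source$window)) {
      stopf("target and source patterns live in different windows")
    }
    targets <- coords_matrix(targets)
  }
  targets <- as.matrix(targets)
  n <- nrow(targets)
  out <- matrix(0, n, spec$P)
  ns <- length(source$x)
  if (n == 0 || ns == 0) return(out)
  sx <- source$x; sy <- source$y
  r2 <- spec$r_max^2
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    dx <- outer(targets[lo:hi, 1], sx, "-")
    dy <- outer(targets[lo:hi, 2], sy, "-")
    d2 <- dx * dx + dy * dy
    keep <- which(d2 <= r2)
    if (length(keep)) {
      B <- eval_basis(spec, sqrt(d2[keep]))
      row_of <- ((keep - 1L) %% (hi - lo + 1L)) + 1L
      for (p in seq_len(spec$P)) {
        acc <- rowsum(B[, p], row_of)
        out[lo - 1L + as.integer(rownames(acc)), p] <-
          out[lo - 1L + as.integer(rownames(acc)), p] + acc[, 1]
      }
    }
  }
  out
}
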