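#' Posterior-mean conditional-intensity map
#'
#' Evaluates the fitted conditional intensity
#' `lambda(v) = exp(z(v)'beta + sum_k q_k(v)' delta_k)` on a regular grid
#' over the image's window, averaging `exp()` over posterior draws.
#'
#' @param fit A `shade_fit`.
#' @param image Image identifier (must be part of the fit).
#' @param grid_spacing Grid node spacing in microns (> 0; default 5).
#' @param chunk Internal node chunk size.
#' @return An `intensity_map`: list with `x`, `y` (node centre coordinates),
#'   `values` (matrix `length(y)` rows x `length(x)` cols, intensity per
#'   square micron), `grid_spacing`, `image`.
#' @export
intensity_map <- function(fit, image, grid_spacing = 5, chunk = 4096L) {
  stopifnot(inherits(fit, "shade_fit"))
  if (grid_spacing <= 0) stopf("grid_spacing must be positive")
  m <- match(as.character(image), fit$image_ids)
  if (is.na(m)) stopf("image '%s' is not part of the fit", image)
  d <- fit$designs[[m]]
  w <- d$target$window
  gx <- seq(w$xrange[1] + grid_spacing / 2, w$xrange[2], by = grid_spacing)
  gy <- seq(w$yrange[1] + grid_spacing / 2, w$yrange[2], by = grid_spacing)
  nodes <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  S <- dim(fit$draws$delta)[1]
  coefs <- cbind(matrix(fit$draws$beta[, m, ], S),
                 matrix(fit$draws$delta[, m, ], S))  # S x (J + Q)
  vals <- numeric(nrow(nodes))
  P <- fit$P
  for (lo in seq(1, nrow(nodes), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(nodes))
    loc <- nodes[lo:hi, , drop = FALSE]
    X <- matrix(0, nrow(loc), fit$K * P)
    for (k in seq_len(fit$K)) {
      X[, (k - 1) * P + seq_len(P)] <-
        interaction_features(loc, d$sources[[k]], fit$spec)
    }
    Z <- matrix(1, nrow(loc), ncol(d$Z))
    if (ncol(d$Z) > 1) stopf("intensity maps support intercept-only covariates")
    eta <- cbind(Z, X) %*% t(coefs)  # nodes x S
    vals[lo:hi] <- rowMeans(exp(eta))
  }
  structure(list(x = gx, y = gy,
                 values = matrix(vals, nrow = length(gy), ncol = length(gx)),
                 grid_spacing = grid_spacing, image = fit$image_ids[m]),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("intensity_map '%s': %d x %d nodes at %g um spacing\n",
              x$image, length(x$x), length(x$y), x$grid_spacing))
  invisible(x)
}

#' Discrimination AUC of the fitted conditional intensity
#'
#' Scores each row of a real-vs-dummy design with the posterior-mean
#' probability `P(real) = plogis(z'beta + sum_k q_k' delta_k(m) -
#' log(lambda_dummy))` and reports the area under the ROC curve for
#' separating real target cells from dummy points. By default the dummy
#' points are regenerated with an evaluation seed distinct from the fitting
#' seed, so scoring does not reuse the exact fitting rows.
#'
#' @param fit A `shade_fit`.
#' @param image Image identifier.
#' @param eval_seed Seed for the fresh evaluation dummies (default: derived
#'   from the fit seed).
#' @param mode `"fresh_dummy"` (default) or `"fitting_rows"` (score the rows
#'   used in fitting).
#' @return AUC in `[0, 1]`.
#' @export
predict_auc <- function(fit, image, eval_seed = NULL,
                        mode = c("fresh_dummy", "fitting_rows")) {
  stopifnot(inherits(fit, "shade_fit"))
  mode <- match.arg(mode)
  m <- match(as.character(image), fit$image_ids)
  if (is.na(m)) stopf("image '%s' is not part of the fit", image)
  d <- fit$designs[[m]]
  if (mode == "fresh_dummy") {
    eval_seed <- eval_seed %||% (fit$seed * 7 + 1000003L + m)
    d <- build_design(d$target, d$sources, fit$spec,
                      lambda_dummy = d$lambda_dummy, seed = eval_seed,
                      image_id = d$image_id)
  }
  if (!any(d$y == 1) || !any(d$y == 0)) {
    stopf("AUC needs both real and dummy rows")
  }
  S <- dim(fit$draws$delta)[1]
  coefs <- cbind(matrix(fit$draws$beta[, m, ], S),
                 matrix(fit$draws$delta[, m, ], S))
  eta <- cbind(d$Z, d$X) %*% t(coefs) - d$offset
  scores <- rowMeans(plogis(eta))
  as.numeric(pROC::auc(pROC::roc(response = d$y, predictor = scores,
                                 quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}
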