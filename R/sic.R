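#' Posterior draws of interaction coefficients for one unit
#'
#' @param fit A `shade_fit`.
#' @param level `"image"`, `"patient"`, or `"cohort"` (the latter two only
#'   for hierarchical fits).
#' @param unit Unit identifier at that level.
#' @param source Source type name (or index).
#' @return An S x P matrix of coefficient draws.
#' @export
coef_draws <- function(fit, level = c("image", "patient", "cohort"), unit,
                       source = 1) {
  stopifnot(inherits(fit, "shade_fit"))
  level <- match.arg(level)
  k <- if (is.character(source)) match(source, fit$source_types) else source
  if (is.na(k) || k < 1 || k > fit$K) stopf("unknown source type")
  cols <- (k - 1) * fit$P + seq_len(fit$P)
  arr <- switch(level,
    image = {
      i <- match(as.character(unit), fit$image_ids)
      if (is.na(i)) stopf("unknown image '%s'", unit)
      fit$draws$delta[, i, cols, drop = FALSE]
    },
    patient = {
      if (!fit$hierarchical) stopf("flat fits have no patient level")
      i <- match(as.character(unit), fit$patients)
      if (is.na(i)) stopf("unknown patient '%s'", unit)
      fit$draws$gamma[, i, cols, drop = FALSE]
    },
    cohort = {
      if (!fit$hierarchical) stopf("flat fits have no cohort level")
      i <- match(as.character(unit), fit$cohorts)
      if (is.na(i)) stopf("unknown cohort '%s'", unit)
      fit$draws$psi[, i, cols, drop = FALSE]
    })
  matrix(arr, nrow = dim(arr)[1], ncol = fit$P)
}

#' Reconstruct a spatial interaction curve from posterior draws
#'
#' The spatial interaction curve (SIC) at distance `s` is the linear
#' combination `sum_p coef_p phi_p(s)` of that draw's coefficients: the
#' expected contribution of one source cell at distance `s` to the
#' log-intensity of the target type. Positive values indicate attraction,
#' negative values repulsion.
#'
#' @inheritParams coef_draws
#' @param distances Distance grid in microns (default 0-150 by 1).
#' @return A `sic_curve`: list with `distances`, `draws` (S x n matrix),
#'   and `summary` data frame (`distance`, `median`, `lo95`, `hi95`), plus
#'   the level/unit/source identifiers.
#' @export
sic_curve <- function(fit, level = c("image", "patient", "cohort"), unit,
                      source = 1, distances = 0:150) {
  level <- match.arg(level)
  if (any(distances > 2 * fit$spec$r_max)) {
    warnf("distances beyond 2 * r_max requested; the curve is identically ~0 there")
  }
  cf <- coef_draws(fit, level, unit, source)
  sic_from_coefs(cf, fit$spec, distances, level = level, unit = unit,
                 source = if (is.character(source)) source else
                   fit$source_types[source])
}

# shared constructor: curve draws = coefficient draws %*% t(basis)
sic_from_coefs <- function(coefs, spec, distances, level = "image",
                           unit = NA, source = NA) {
  B <- eval_basis(spec, distances)
  draws <- coefs %*% t(B)
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(distances = as.numeric(distances), draws = draws,
                 summary = data.frame(distance = as.numeric(distances),
                                      median = qs[2, ], lo95 = qs[1, ],
                                      hi95 = qs[3, ]),
                 level = level, unit = unit, source = source),
            class = "sic_curve")
}

#' @export
print.sic_curve <- function(x, ...) {
  cat(sprintf("sic_curve (%s '%s', source %s): %d draws on [%g, %g] um\n",
              x$level, x$unit, x$source, nrow(x$draws),
              min(x$distances), max(x$distances)))
  invisible(x)
}

#' Sign detection from pointwise credible intervals
#'
#' Labels each test distance `positive` when the 95% credible interval lies
#' entirely above zero, `negative` when entirely below, otherwise
#' `undetected`.
#'
#' @param curve A [sic_curve()].
#' @param test_distances Distances (microns) within the curve's grid range.
#' @return Named character vector of labels.
#' @export
sign_detection <- function(curve, test_distances = c(20, 40, 60)) {
  stopifnot(inherits(curve, "sic_curve"))
  rng <- range(curve$distances)
  if (any(test_distances < rng[1] | test_distances > rng[2])) {
    stopf("test distances outside the curve's grid range")
  }
  lo <- approx(curve$distances, curve$summary$lo95, xout = test_distances)$y
  hi <- approx(curve$distances, curve$summary$hi95, xout = test_distances)$y
  setNames(ifelse(lo > 0, "positive", ifelse(hi < 0, "negative", "undetected")),
           test_distances)
}

#' Between-cohort difference of spatial interaction curves
#'
#' Per-draw difference of the two cohorts' cohort-level SICs, with distances
#' flagged where the absolute posterior median difference exceeds a
#' log-intensity threshold.
#'
#' @param fit A hierarchical `shade_fit`.
#' @param cohort_a,cohort_b Cohort identifiers; the difference is `a - b`.
#' @param source Source type.
#' @param distances Distance grid (microns).
#' @param threshold Flagging threshold on the absolute median difference in
#'   log-intensity (default 0.05).
#' @return A `sic_difference`: the difference `sic_curve` plus `flagged`
#'   (logical per distance) and `flagged_ranges` (data frame of contiguous
#'   flagged distance runs).
#' @export
group_difference <- function(fit, cohort_a, cohort_b, source = 1,
                             distances = 0:150, threshold = 0.05) {
  stopifnot(inherits(fit, "shade_fit"))
  if (!fit$hierarchical) stopf("group differences need a hierarchical fit")
  ca <- coef_draws(fit, "cohort", cohort_a, source)
  cb <- coef_draws(fit, "cohort", cohort_b, source)
  curve <- sic_from_coefs(ca - cb, fit$spec, distances, level = "cohort",
                          unit = paste(cohort_a, "-", cohort_b),
                          source = if (is.character(source)) source else
                            fit$source_types[source])
  flagged <- abs(curve$summary$median) > threshold
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  keep <- which(runs$values)
  curve$flagged <- flagged
  curve$flagged_ranges <- data.frame(
    from = curve$distances[starts[keep]],
    to = curve$distances[ends[keep]])
  curve$threshold <- threshold
  class(curve) <- c("sic_difference", class(curve))
  curve
}

#' Between-patient and between-image heterogeneity of interaction curves
#'
#' Summarizes spatial-structure variability with median absolute deviations
#' of posterior-median SICs: between-patient MAD is taken over the
#' patient-level curves within each cohort (then averaged over cohorts);
#' between-image MAD over each patient's image-level curves (then averaged
#' over patients). The raw MAD (no normal-consistency constant) is used by
#' default.
#'
#' @param fit A hierarchical `shade_fit`.
#' @param distances Distance grid (microns).
#' @param constant MAD scale constant (default 1; use 1.4826 for
#'   normal-consistency).
#' @return List with `per_distance` (data frame: source, distance,
#'   mad_patient, mad_image) and `aggregate` (data frame: source,
#'   mad_patient, mad_image averaged over the grid).
#' @export
heterogeneity_mad <- function(fit, distances = 0:150, constant = 1) {
  stopifnot(inherits(fit, "shade_fit"))
  if (!fit$hierarchical) stopf("heterogeneity needs a hierarchical fit")
  meta <- fit$meta
  pat_of_img <- meta$patient_id[match(fit$image_ids, meta$image_id)]
  coh_of_pat <- meta$group_id[match(fit$patients, meta$patient_id)]
  per_coh <- table(coh_of_pat)
  if (all(per_coh < 2)) stopf("between-patient MAD needs >= 2 patients in a cohort")
  per_pat <- table(pat_of_img)
  if (all(per_pat < 2)) stopf("between-image MAD needs >= 2 images for a patient")
  B <- eval_basis(fit$spec, distances)
  out <- list()
  for (k in seq_len(fit$K)) {
    cols <- (k - 1) * fit$P + seq_len(fit$P)
    med_pat <- t(vapply(seq_along(fit$patients), function(n) {
      cf <- apply(fit$draws$gamma[, n, cols, drop = FALSE], 3, median)
      drop(B %*% cf)
    }, numeric(length(distances))))
    med_img <- t(vapply(seq_along(fit$image_ids), function(m) {
      cf <- apply(fit$draws$delta[, m, cols, drop = FALSE], 3, median)
      drop(B %*% cf)
    }, numeric(length(distances))))
    mad_p <- rep(NA_real_, length(distances))
    cohs <- names(per_coh)[per_coh >= 2]
    if (length(cohs)) {
      mad_p <- rowMeans(vapply(cohs, function(g) {
        rows <- which(coh_of_pat == g)
        apply(med_pat[rows, , drop = FALSE], 2, mad, constant = constant)
      }, numeric(length(distances))))
    }
    mad_i <- rep(NA_real_, length(distances))
    pats <- names(per_pat)[per_pat >= 2]
    if (length(pats)) {
      mad_i <- rowMeans(vapply(pats, function(pp) {
        rows <- which(pat_of_img == pp)
        apply(med_img[rows, , drop = FALSE], 2, mad, constant = constant)
      }, numeric(length(distances))))
    }
    out[[k]] <- data.frame(source = fit$source_types[k],
                           distance = as.numeric(distances),
                           mad_patient = mad_p, mad_image = mad_i,
                           stringsAsFactors = FALSE)
  }
  per_distance <- do.call(rbind, out)
  aggregate <- do.call(rbind, lapply(split(per_distance, per_distance$source),
    function(d) data.frame(source = d$source[1],
                           mad_patient = mean(d$mad_patient),
                           mad_image = mean(d$mad_image))))
  rownames(aggregate) <- NULL
  list(per_distance = per_distance, aggregate = aggregate)
}
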