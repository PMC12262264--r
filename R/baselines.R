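#' Cross-type nearest-neighbour distance function (G-cross)
#'
#' Empirical distribution of the distance from each point of type A to its
#' nearest neighbour of type B. The default reduced-sample (border)
#' correction counts, at each distance `r`, only A points at least `r` from
#' the window boundary; because the risk set changes with `r`, the corrected
#' ratio is regularized to a proper CDF with a running maximum.
#'
#' @param from Single-type `point_pattern` (type A; nonempty).
#' @param to Single-type `point_pattern` (type B; nonempty, same window).
#' @param r_grid Distance grid (microns).
#' @param correction `"rs"` (reduced sample) or `"none"`.
#' @return Data frame with `r`, `G` (estimate) and `theo`
#'   (`1 - exp(-lambda_B * pi * r^2)`, the CSR closed form).
#' @export
gcross <- function(from, to, r_grid = 0:80, correction = c("rs", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(from, "point_pattern"), inherits(to, "point_pattern"))
  if (!length(from$x)) stopf("empty 'from' pattern")
  if (!length(to$x)) stopf("empty 'to' pattern")
  if (!same_window(from$window, to$window)) stopf("windows differ")
  d2 <- outer(from$x, to$x, "-")^2 + outer(from$y, to$y, "-")^2
  nnd <- sqrt(apply(d2, 1, min))
  w <- from$window
  bdist <- pmin(from$x - w$xrange[1], w$xrange[2] - from$x,
                from$y - w$yrange[1], w$yrange[2] - from$y)
  lambda_to <- length(to$x) / window_area(w)
  G <- vapply(r_grid, function(r) {
    if (correction == "rs") {
      ok <- bdist >= r
      if (!any(ok)) return(NA_real_)
      mean(nnd[ok] <= r)
    } else {
      mean(nnd <= r)
    }
  }, numeric(1))
  if (correction == "rs") {
    # the raw reduced-sample ratio need not be monotone (the risk set shrinks
    # with r); enforce the CDF property with a running maximum
    fin <- !is.na(G)
    G[fin] <- cummax(G[fin])
  }
  data.frame(r = as.numeric(r_grid), G = G,
             theo = 1 - exp(-lambda_to * pi * r_grid^2))
}

#' CSR envelope test for the G-cross function
#'
#' Simulates `n_sim` completely-spatially-random re-samplings of the
#' to-type (fixed observed count, uniform locations; the from-type is held
#' fixed) and forms the pointwise min/max envelope. With the conventional
#' `n_sim = 39` the pointwise two-sided test has level `2/(39+1) = 0.05`.
#'
#' @param pattern Multitype `point_pattern` containing both types.
#' @param from_type,to_type Type labels.
#' @param r_grid Distance grid (microns).
#' @param n_sim Number of CSR simulations (default 39).
#' @param seed Optional seed.
#' @param test_distances Distances at which to report detection.
#' @return A `gcross_envelope`: data frame columns `r`, `G`, `theo`, `lo`,
#'   `hi` plus a `detection` attribute-like element: named character vector
#'   (`positive` above the envelope, `negative` below, else `undetected`).
#' @export
csr_envelope <- function(pattern, from_type, to_type, r_grid = 0:80,
                         n_sim = 39, seed = NULL,
                         test_distances = c(20, 40, 60)) {
  stopifnot(inherits(pattern, "point_pattern"), n_sim >= 1)
  from <- subset_type(pattern, from_type)
  to <- subset_type(pattern, to_type)
  obs <- gcross(from, to, r_grid)
  w <- pattern$window
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      ruv <- point_pattern(runif(length(to$x), w$xrange[1], w$xrange[2]),
                           runif(length(to$x), w$yrange[1], w$yrange[2]),
                           rep(to_type, length(to$x)), w)
      gcross(from, ruv, r_grid)$G
    }, numeric(length(r_grid)))
  })
  lo <- apply(sims, 1, min, na.rm = TRUE)
  hi <- apply(sims, 1, max, na.rm = TRUE)
  curve <- data.frame(r = obs$r, G = obs$G, theo = obs$theo, lo = lo, hi = hi)
  det <- vapply(test_distances, function(d) {
    i <- which.min(abs(obs$r - d))
    if (is.na(obs$G[i])) return("undetected")
    if (obs$G[i] > hi[i]) "positive"
    else if (obs$G[i] < lo[i]) "negative"
    else "undetected"
  }, character(1))
  structure(list(curve = curve, detection = setNames(det, test_distances),
                 n_sim = n_sim), class = "gcross_envelope")
}

#' Cohort screen: logistic regression of group on per-image G-cross values
#'
#' For each requested (from, to) type pair and distance, the G-cross value is
#' extracted per image and the cohort label is regressed on it (binomial GLM,
#' single predictor plus intercept). Coefficients are reported as log-odds
#' ratios with Benjamini-Hochberg adjusted p-values across all tests.
#'
#' @param patterns List of multitype `point_pattern`s (one per image).
#' @param groups Cohort label per image (exactly two levels).
#' @param pairs Data frame with columns `from`, `to`; default all ordered
#'   pairs of types present in the first pattern.
#' @param distances Distances (microns) at which G is read off.
#' @param fdr_level Significance level on adjusted p-values (default 0.05).
#' @return Data frame: `from`, `to`, `distance`, `log_or`, `p`, `p_adj`,
#'   `significant`, `separation` (flag for unbounded estimates).
#' @export
gcross_group_screen <- function(patterns, groups, pairs = NULL,
                                distances = c(20, 40, 60),
                                fdr_level = 0.05) {
  stopifnot(length(patterns) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two cohorts are required")
  if (any(table(groups) < 2)) stopf("each cohort needs >= 2 images")
  if (is.null(pairs)) {
    types <- levels(patterns[[1]]$type)
    pairs <- expand.grid(from = types, to = types,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  }
  r_grid <- sort(unique(c(0, distances)))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    gvals <- t(vapply(patterns, function(pp) {
      from <- subset_type(pp, pairs$from[i])
      to <- subset_type(pp, pairs$to[i])
      if (!length(from$x) || !length(to$x)) {
        return(rep(NA_real_, length(distances)))
      }
      g <- gcross(from, to, r_grid)
      g$G[match(distances, g$r)]
    }, numeric(length(distances))))
    for (j in seq_along(distances)) {
      gv <- gvals[, j]
      ok <- is.finite(gv)
      sep <- FALSE
      if (sum(ok) < 4 || length(unique(gv[ok])) < 2) {
        lor <- NA_real_; p <- NA_real_
      } else {
        fit <- withCallingHandlers(
          glm(groups[ok] ~ gv[ok], family = binomial()),
          warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
              sep <<- TRUE
              invokeRestart("muffleWarning")
            }
          })
        lor <- unname(coef(fit)[2])
        p <- summary(fit)$coefficients[2, 4]
        if (sep) {
          warnf("complete separation for %s -> %s at %g um; log-OR unbounded",
                pairs$from[i], pairs$to[i], distances[j])
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        from = pairs$from[i], to = pairs$to[i], distance = distances[j],
        log_or = lor, p = p, separation = sep, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr_level
  out
}
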