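# Split-Rhat and effective sample size for the sampled scalars.

#' Split-chain potential scale reduction factor
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar split-Rhat (NA for constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  S <- nrow(x)
  if (S < 4) return(NA_real_)
  half <- floor(S / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(S - half + 1):S, , drop = FALSE])
  m <- ncol(splits); n <- nrow(splits)
  mu <- colMeans(splits)
  s2 <- apply(splits, 2, var)
  W <- mean(s2)
  B <- n * var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size (bulk, Geyer initial monotone truncation)
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar ESS estimate.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  S <- nrow(x); m <- ncol(x)
  if (S < 4) return(NA_real_)
  s2 <- apply(x, 2, var)
  W <- mean(s2)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  lag_max <- min(S - 1, 250)
  rho_ch <- sapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * s2[j]
  })
  var_plus <- W * (S - 1) / S + (if (m > 1) var(colMeans(x)) else 0)
  rho <- 1 - (W - rowMeans(as.matrix(rho_ch))[-1]) / var_plus
  # Geyer: sum consecutive pairs while positive and monotone
  tau <- 1
  t <- 1
  prev <- Inf
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    t <- t + 2
  }
  max(m * S / tau, 1)
}

# per-parameter diagnostics table over the constrained draws
fit_diagnostics <- function(con, sampler) {
  S <- length(con$chain) / sampler$chains
  split_by_chain <- function(v) matrix(v, nrow = S, ncol = sampler$chains)
  entries <- list()
  add <- function(name, v) {
    m <- split_by_chain(v)
    entries[[length(entries) + 1]] <<- data.frame(
      param = name, mean = mean(v), sd = sd(v),
      rhat = if (sampler$chains * S >= 8) split_rhat(m) else NA_real_,
      ess = if (sampler$chains * S >= 8) ess_bulk(m) else NA_real_,
      stringsAsFactors = FALSE)
  }
  walk_array <- function(arr, name) {
    d <- dim(arr)
    for (i in seq_len(d[2])) {
      for (j in seq_len(d[3])) {
        add(sprintf("%s[%d,%d]", name, i, j), arr[, i, j])
      }
    }
  }
  walk_array(con$delta, "delta")
  walk_array(con$beta, "beta")
  if (!is.null(con$psi)) {
    walk_array(con$psi, "psi")
    walk_array(con$gamma, "gamma")
    for (k in 1:3) {
      add(c("sigma_cohort", "sigma_patient", "sigma_image")[k], con$sigma[, k])
    }
  }
  do.call(rbind, entries)
}
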