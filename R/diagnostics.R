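#' Split-chain potential scale reduction factor
#'
#' Classic split-R-hat: each chain is halved, the between- and within-
#' sequence variances are combined into the overvariance estimate, and the
#' ratio to the within variance is returned. Values near 1 indicate the
#' chains have mixed; > 1.01 is treated as a convergence failure by the
#' fitting functions.
#'
#' @param draws A matrix of posterior draws, iterations x chains.
#' @return The split R-hat (scalar).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  n <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1) # degenerate chains (e.g. boundary-pinned)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based effective sample size over split chains, using the
#' combined between/within autocorrelation estimate and Geyer's initial
#' positive sequence rule (sum lag-pair autocorrelations while positive).
#'
#' @param draws A matrix of posterior draws, iterations x chains.
#' @return Estimated effective sample size (scalar).
#' @export
ess_mean <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  n <- nrow(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(colMeans(split))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(m * n)
  max_lag <- min(n - 1, 1000)
  # per-chain autocovariances (biased, FFT-backed via stats::acf)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(split[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)
    a$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov) * (n - 1) / n
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer initial positive sequence on lag pairs
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Summarize draws the way fitted objects report them
#'
#' Median plus the 68% equal-tailed credible interval (16th and 84th
#' percentiles), the reporting convention used for the regulatory
#' parameters.
#'
#' @param x Numeric vector of draws.
#' @return Named numeric: `median`, `ci68_lower`, `ci68_upper`.
#' @export
ci68_summary <- function(x) {
  q <- stats::quantile(x, c(0.16, 0.5, 0.84), names = FALSE, na.rm = TRUE)
  c(median = q[2], ci68_lower = q[1], ci68_upper = q[3])
}
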