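#' Stabilization-only alternative model
#'
#' Fits the restricted model in which the TF regulates solely by
#' (de)stabilizing RNAP (`alpha = 1`): every position's manifold is governed
#' by a single stabilization value, with
#' \deqn{FC_{max} = \frac{\beta}{1 + \frac{P}{1+P}(\beta - 1)}, \qquad
#'       K = 1 + P\beta,}
#' and the promoter binding energy is shared globally across positions
#' (sampled with a uniform prior, default \[-10, -2\] kBT). The structural
#' consequence is a hard ceiling on achievable activation: the maximal fold
#' change is \eqn{(1+P)/P}, so data activating beyond that bound cannot be
#' captured at the measured promoter strength — which is how the model is
#' falsified.
#'
#' Parameters (global energy; per-position beta and likelihood sd) are
#' sampled by adaptive Metropolis-within-Gibbs over several chains.
#'
#' @param datasets Manifold data for all positions: data frame with
#'   `position_label`, `fc_plus1`, `fc_query`.
#' @param promoter A [promoter_params()]; supplies the RNAP copy number used
#'   to turn a sampled energy into P.
#' @param energy_prior Uniform prior bounds on the promoter energy (kBT).
#' @param beta_upper Upper bound of the uniform beta prior (lower bound 0).
#' @param chains,draws,warmup MCMC size per chain.
#' @param seed RNG seed.
#' @return Object of class `stab_only_fit`: wide draw tibble (`chain`,
#'   `iter`, `energy`, `beta_<pos>`, `sigma_<pos>`), position labels,
#'   diagnostics for the energy and each beta, and the promoter object.
#' @export
fit_stabilization_only <- function(datasets, promoter = promoter_params(),
                                   energy_prior = c(-10, -2),
                                   beta_upper = 1000,
                                   chains = 4, draws = 2000, warmup = 1000,
                                   seed = 1) {
  stopifnot(is.data.frame(datasets),
            all(c("position_label", "fc_plus1", "fc_query") %in% names(datasets)))
  labels <- unique(as.character(datasets$position_label))
  m <- length(labels)
  dat <- lapply(labels, function(p) {
    d <- datasets[as.character(datasets$position_label) == p, ]
    list(u = d$fc_plus1, y = d$fc_query, sigma_max = max(abs(d$fc_query)))
  })
  P_of <- function(energy) exp(log(promoter$n_p) - log(promoter$n_ns) - energy)
  ll_pos <- function(k, P, beta, lsig) {
    d <- dat[[k]]
    fcm <- beta / (1 + (P / (1 + P)) * (beta - 1))
    mu <- manifold_steric_reference(d$u, fcm, 1 + P * beta)
    sum(stats::dnorm(d$y, mu, exp(lsig), log = TRUE))
  }
  run_chain <- function(ch) {
    with_preserved_seed(seed + ch, {
      energy <- stats::runif(1, energy_prior[1], energy_prior[2])
      P <- P_of(energy)
      beta <- rep(5, m) * exp(stats::rnorm(m, 0, 0.2))
      lsig <- vapply(dat, function(d) log(max(stats::sd(d$y) / 2, 1e-4)),
                     numeric(1))
      ll_k <- vapply(seq_len(m), function(k) ll_pos(k, P, beta[k], lsig[k]),
                     numeric(1))
      sc_e <- 0.3
      sc_b <- rep(0.4, m) # log-scale beta walk
      sc_s <- rep(0.3, m)
      acc_e <- 0L
      acc_b <- integer(m)
      acc_s <- integer(m)
      total <- warmup + draws
      out <- matrix(NA_real_, draws, 1 + 2 * m)
      for (it in seq_len(total)) {
        prop_e <- energy + stats::rnorm(1, 0, sc_e)
        if (prop_e >= energy_prior[1] && prop_e <= energy_prior[2]) {
          Pp <- P_of(prop_e)
          llp <- vapply(seq_len(m), function(k) ll_pos(k, Pp, beta[k], lsig[k]),
                        numeric(1))
          if (log(stats::runif(1)) < sum(llp) - sum(ll_k)) {
            energy <- prop_e
            P <- Pp
            ll_k <- llp
            acc_e <- acc_e + 1L
          }
        }
        for (k in seq_len(m)) {
          prop_b <- beta[k] * exp(stats::rnorm(1, 0, sc_b[k]))
          if (prop_b <= beta_upper) {
            llp <- ll_pos(k, P, prop_b, lsig[k])
            # log-scale walk on beta with a uniform prior: Jacobian term
            if (log(stats::runif(1)) < llp + log(prop_b) - ll_k[k] - log(beta[k])) {
              beta[k] <- prop_b
              ll_k[k] <- llp
              acc_b[k] <- acc_b[k] + 1L
            }
          }
          prop_s <- lsig[k] + stats::rnorm(1, 0, sc_s[k])
          if (exp(prop_s) <= dat[[k]]$sigma_max) {
            llp <- ll_pos(k, P, beta[k], prop_s)
            if (log(stats::runif(1)) < llp + prop_s - ll_k[k] - lsig[k]) {
              lsig[k] <- prop_s
              ll_k[k] <- llp
              acc_s[k] <- acc_s[k] + 1L
            }
          }
        }
        if (it <= warmup && it %% 50 == 0) {
          bump <- function(sc, acc) sc * exp(ifelse(acc / 50 > 0.44, 0.15, -0.15))
          sc_e <- bump(sc_e, acc_e)
          sc_b <- bump(sc_b, acc_b)
          sc_s <- bump(sc_s, acc_s)
          acc_e <- 0L
          acc_b <- integer(m)
          acc_s <- integer(m)
        }
        if (it > warmup) out[it - warmup, ] <- c(energy, beta, exp(lsig))
      }
      colnames(out) <- c("energy", paste0("beta_", labels),
                         paste0("sigma_", labels))
      tibble::as_tibble(out) |>
        dplyr::mutate(chain = ch, iter = dplyr::row_number(), .before = 1)
    })
  }
  all_draws <- dplyr::bind_rows(lapply(seq_len(chains), run_chain))
  par_cols <- c("energy", paste0("beta_", labels))
  diagnostics <- tibble::tibble(
    parameter = par_cols,
    rhat = vapply(par_cols, function(p) {
      split_rhat(matrix(all_draws[[p]], nrow = draws))
    }, numeric(1)),
    ess = vapply(par_cols, function(p) {
      ess_mean(matrix(all_draws[[p]], nrow = draws))
    }, numeric(1))
  )
  structure(
    list(draws = all_draws, labels = labels, diagnostics = diagnostics,
         promoter = promoter, energy_prior = energy_prior,
         chains = chains, n_draws = draws),
    class = "stab_only_fit"
  )
}

#' Posterior-predictive residuals of the stabilization-only model
#'
#' Evaluates the fitted model at the posterior medians and returns, per
#' position, the data-minus-model residuals and their mean. A one-sided mean
#' residual at the strongest activating position is the signature of the
#' model's \eqn{(1+P)/P} activation ceiling binding.
#'
#' @param fit A `stab_only_fit`.
#' @param datasets The manifold data the fit was run on.
#' @return A tibble: `position_label`, `n`, `mean_residual`,
#'   `frac_positive` (share of points above the model curve).
#' @export
stab_only_residuals <- function(fit, datasets) {
  stopifnot(inherits(fit, "stab_only_fit"))
  energy <- stats::median(fit$draws$energy)
  P <- exp(log(fit$promoter$n_p) - log(fit$promoter$n_ns) - energy)
  purrr::map_dfr(fit$labels, function(p) {
    d <- datasets[as.character(datasets$position_label) == p, ]
    beta <- stats::median(fit$draws[[paste0("beta_", p)]])
    fcm <- beta / (1 + (P / (1 + P)) * (beta - 1))
    mu <- manifold_steric_reference(d$fc_plus1, fcm, 1 + P * beta)
    r <- d$fc_query - mu
    tibble::tibble(position_label = p, n = length(r),
                   mean_residual = mean(r), frac_positive = mean(r > 0))
  })
}

#' Maximal fold change without acceleration
#'
#' With `alpha = 1` the largest achievable fold change is set by RNAP
#' occupancy alone: \eqn{(1+P)/P} (full occupancy over basal occupancy).
#'
#' @param P Promoter occupancy parameter.
#' @return The activation ceiling.
#' @export
stab_only_max_fold <- function(P) (1 + P) / P

#' @export
print.stab_only_fit <- function(x, ...) {
  cat("<stab_only_fit> ", length(x$labels), "positions,", x$chains,
      "chains x", x$n_draws, "draws\n")
  cat("  promoter energy median:", signif(stats::median(x$draws$energy), 4),
      "kBT\n")
  invisible(x)
}
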