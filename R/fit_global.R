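#' Global TF binding-affinity fit
#'
#' With per-position effective parameters (`fc_max`, `K`) already inferred
#' from the concentration manifolds, the one remaining unknown of the
#' fold-change-versus-TF-number curves is the scaled binding affinity
#' \eqn{\lambda = e^{-\Delta\varepsilon_{TF}}/N_{NS}}, shared across
#' positions because the binding sequence is. Each position's effective
#' coefficient is \eqn{\chi^k = \lambda K^k/(1+P)} and the likelihood is the
#' product over positions and points of Normal densities around the
#' weak-form fold change. The +1 reference must be present with its
#' parameters pinned to steric hindrance (`fc_max = 0`, `K = 1`). `lambda`
#' (log10 scale) and the per-position likelihood sd are sampled by adaptive
#' Metropolis-within-Gibbs.
#'
#' @param curves Fold-change data for all positions including +1: data frame
#'   with `position_label`, `n_tf`, `fc`.
#' @param fixed_effective Per-position (`position_label`, `fc_max`,
#'   `k_factor`) point values (posterior means from the manifold fits; the
#'   +1 row with `fc_max = 0`, `k_factor = 1`).
#' @param promoter A [promoter_params()] (supplies P).
#' @param log10_lambda_prior Uniform prior bounds on log10(lambda).
#' @param chains,draws,warmup MCMC size (per chain; warmup discarded).
#' @param seed RNG seed.
#' @return Object of class `global_affinity_fit`: `lambda_samples`,
#'   posterior summary, diagnostics.
#' @export
fit_global_affinity <- function(curves, fixed_effective,
                                promoter = promoter_params(),
                                log10_lambda_prior = c(-12, 4),
                                chains = 4, draws = 2000, warmup = 1000,
                                seed = 1) {
  stopifnot(is.data.frame(curves), is.data.frame(fixed_effective))
  pos_c <- unique(as.character(curves$position_label))
  pos_e <- as.character(fixed_effective$position_label)
  if (!setequal(pos_c, pos_e)) {
    stop("position sets of curves and fixed_effective differ", call. = FALSE)
  }
  plus1 <- fixed_effective[pos_e %in% c("1", "+1"), ]
  if (nrow(plus1) != 1 || plus1$fc_max != 0 || plus1$k_factor != 1) {
    stop("the +1 reference must be present with fc_max = 0 and k_factor = 1",
         call. = FALSE)
  }
  P <- promoter$P
  dat <- lapply(pos_e, function(p) {
    d <- curves[as.character(curves$position_label) == p & curves$n_tf >= 0, ]
    e <- fixed_effective[pos_e == p, ]
    list(n = d$n_tf, fc = d$fc, fc_max = e$fc_max, K = e$k_factor,
         sigma_max = max(abs(d$fc)))
  })
  m <- length(dat)
  ll_pos <- function(k, l10lam, lsig) {
    d <- dat[[k]]
    chi <- 10^l10lam * d$K / (1 + P)
    x <- chi * d$n
    mu <- (1 + d$fc_max * x) / (1 + x)
    sum(stats::dnorm(d$fc, mu, exp(lsig), log = TRUE))
  }
  run_chain <- function(ch) {
    with_preserved_seed(seed + ch, {
      # moment init for lambda from the +1 curve: fc ~ 1/(1+chi n)
      d1 <- dat[[which(pos_e %in% c("1", "+1"))]]
      sel <- d1$n > 0 & d1$fc < 1 & d1$fc > 0
      chi0 <- if (any(sel)) {
        stats::median((1 / d1$fc[sel] - 1) / d1$n[sel])
      } else 10^mean(log10_lambda_prior)
      l10 <- min(max(log10(chi0 * (1 + P)) + stats::rnorm(1, 0, 0.2),
                     log10_lambda_prior[1]), log10_lambda_prior[2])
      lsig <- vapply(dat, function(d) log(max(stats::sd(d$fc) / 2, 1e-4)),
                     numeric(1))
      ll_k <- vapply(seq_len(m), function(k) ll_pos(k, l10, lsig[k]), numeric(1))
      sc_l <- 0.1
      sc_s <- rep(0.3, m)
      acc_l <- 0L
      acc_s <- integer(m)
      total <- warmup + draws
      out <- numeric(draws)
      for (it in seq_len(total)) {
        prop <- l10 + stats::rnorm(1, 0, sc_l)
        if (prop >= log10_lambda_prior[1] && prop <= log10_lambda_prior[2]) {
          llp <- vapply(seq_len(m), function(k) ll_pos(k, prop, lsig[k]),
                        numeric(1))
          if (log(stats::runif(1)) < sum(llp) - sum(ll_k)) {
            l10 <- prop
            ll_k <- llp
            acc_l <- acc_l + 1L
          }
        }
        for (k in seq_len(m)) {
          props <- lsig[k] + stats::rnorm(1, 0, sc_s[k])
          if (exp(props) <= dat[[k]]$sigma_max) {
            llp <- ll_pos(k, l10, props)
            # log-scale RW on sigma: include the Jacobian of the uniform prior
            if (log(stats::runif(1)) < llp + props - ll_k[k] - lsig[k]) {
              lsig[k] <- props
              ll_k[k] <- llp
              acc_s[k] <- acc_s[k] + 1L
            }
          }
        }
        if (it <= warmup && it %% 50 == 0) {
          sc_l <- sc_l * exp(ifelse(acc_l / 50 > 0.44, 0.15, -0.15))
          sc_s <- sc_s * exp(ifelse(acc_s / 50 > 0.44, 0.15, -0.15))
          acc_l <- 0L
          acc_s <- integer(m)
        }
        if (it > warmup) out[it - warmup] <- 10^l10
      }
      out
    })
  }
  samples <- vapply(seq_len(chains), run_chain, numeric(draws))
  s <- ci68_summary(as.vector(samples))
  structure(
    list(
      lambda_samples = as.vector(samples),
      lambda_mean = mean(samples),
      lambda_median = s[["median"]],
      lambda_ci68 = c(s[["ci68_lower"]], s[["ci68_upper"]]),
      rhat = split_rhat(samples),
      ess = ess_mean(samples),
      P = P, positions = pos_e
    ),
    class = "global_affinity_fit"
  )
}

#' @export
print.global_affinity_fit <- function(x, ...) {
  cat("<global_affinity_fit>  lambda =", signif(x$lambda_median, 4),
      "[", signif(x$lambda_ci68[1], 4), ",", signif(x$lambda_ci68[2], 4),
      "]  rhat =", round(x$rhat, 3), "\n")
  invisible(x)
}
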