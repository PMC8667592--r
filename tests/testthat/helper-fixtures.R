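# Shared fixtures: default promoter, the published regulatory-parameter
# table used as ground truth in recovery scenarios, and an independent
# brute-force oracle for the thermodynamic model.

default_promoter <- promoter_params()
P_DEFAULT <- default_promoter$P

# inferred (alpha, beta) medians per binding position (upstream sweep)
REG_TABLE <- list(
  `-48` = c(3.506, 116.257), `-50` = c(0.675, 161.766),
  `-54` = c(0.049, 34.496), `-56` = c(3.38, 14.72),
  `-58` = c(3.107, 10.519), `-60` = c(2.161, 219.757),
  `-64` = c(24.911, 29.545), `-70` = c(6.995, 6.224),
  `-72` = c(0.813, 20.905), `-74` = c(2.329, 2.982),
  `-80` = c(0.289, 27.025), `-82` = c(0.271, 24.811)
)

# brute-force fold change: plain Boltzmann-weight arithmetic, no shared code
# with fold_change_full()
oracle_fold_change <- function(n_p, dep, n_ns, det, dei, alpha, n_tf) {
  w_p <- (n_p / n_ns) * exp(-dep)
  w_t <- (n_tf / n_ns) * exp(-det)
  w_co <- (n_p * n_tf / n_ns^2) * exp(-(dep + det + dei))
  Z <- 1 + w_p + w_t + w_co
  expr <- (w_p + alpha * w_co) / Z
  expr0 <- w_p / (1 + w_p)
  expr / expr0
}

# random mechanistic parameter draw in a numerically tame range
random_param_draw <- function() {
  list(
    n_p = stats::runif(1, 10, 5000),
    dep = stats::runif(1, -10, 2),
    n_ns = 4.6e6,
    det = stats::runif(1, -15, 0),
    dei = stats::runif(1, -5, 5), # beta = exp(-dei) in [e^-5, e^5]
    alpha = exp(stats::runif(1, -3, 3)),
    n_tf = stats::runif(1, 0, 1e4)
  )
}

make_tf <- function(alpha, beta, det = -5) {
  tf_params(alpha = alpha, beta = beta, delta_eps_tf = det)
}
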