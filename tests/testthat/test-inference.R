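test_that("bootstrap curve fit is exact on noise-free steric data", {
  x <- 10^seq(1, 5, length.out = 11)
  curve <- tibble::tibble(condition_id = seq_along(x), n_tf = x,
                          fc = 1 / (1 + 1e-3 * x))
  fit <- fit_curve_bootstrap(curve, n_boot = 50, seed = 1)
  expect_lt(fit$fc_max, 1e-6)
  expect_equal(fit$chi, 1e-3, tolerance = 1e-6)
  expect_true(fit$diagnostic_ok)
  td <- tidy(fit)
  expect_equal(td$parameter, c("fc_max", "chi"))
  # percentile intervals bracket the bootstrap means
  expect_true(all(td$ci95_lower <= td$boot_mean & td$boot_mean <= td$ci95_upper))
})

test_that("bootstrap intervals cover truth on replicated noisy curves", {
  # strongly repressing, unsaturated regime: fc_max consistent with zero
  eff <- effective_params(fc_max = 0, chi = 2e-3)
  x <- round(10^seq(log10(3), log10(3000), length.out = 11))
  set.seed(52)
  n_rep <- 40
  covered_chi <- logical(n_rep)
  fcmax_lower_at_zero <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    curve <- purrr::map_dfr(1:5, function(rep_id) {
      tibble::tibble(
        condition_id = seq_along(x), replicate_id = rep_id, n_tf = x,
        fc = pmax(fold_change_weak(x, eff) * exp(stats::rnorm(11, 0, 0.15)),
                  1e-6)
      )
    })
    fit <- fit_curve_bootstrap(curve, n_boot = 200)
    covered_chi[r] <- fit$chi_ci95[1] <= eff$chi && eff$chi <= fit$chi_ci95[2]
    fcmax_lower_at_zero[r] <- fit$fc_max_ci95[1] < 1e-3
  }
  expect_gte(mean(covered_chi), 0.9)
  # the lower interval edge sits at zero: repression indistinguishable from
  # perfect shutdown
  expect_gte(mean(fcmax_lower_at_zero), 0.9)
})

test_that("manifold posterior concentrates on the generating parameters", {
  ab <- REG_TABLE[["-64"]]
  fcm <- fcmax_exact(ab[1], ab[2], P_DEFAULT)
  K <- 1 + P_DEFAULT * ab[2]
  d <- simulate_manifold_pairs(fcm, K, sigma = 0.02 * fcm, seed = 61)
  fit <- fit_manifold_bayes(d, chains = 4, draws = 4000, warmup = 1000,
                            seed = 62)
  expect_true(fit$converged)
  expect_true(all(fit$diagnostics$rhat < 1.01))
  expect_true(all(fit$diagnostics$ess > 400))
  expect_true(all(fit$draws$k_factor >= 1))
  fit <- derive_alpha_beta(fit, P_DEFAULT)
  expect_true(all(fit$draws$beta >= 0))
  td <- tidy(fit)
  get <- function(p) td[td$parameter == p, ]
  expect_equal(get("fc_max")$median, fcm, tolerance = 0.05)
  expect_equal(get("k_factor")$median, K, tolerance = 0.15)
  expect_equal(get("alpha")$median, ab[1], tolerance = 0.25)
  expect_equal(get("beta")$median, ab[2], tolerance = 0.35)
  # sampled fc_max equals the exact-form recomputation from (alpha, beta)
  rt <- fcmax_exact(fit$draws$alpha, fit$draws$beta, P_DEFAULT)
  expect_equal(rt, fit$draws$fc_max, tolerance = 1e-9)
})

test_that("weak-stabilization data pin K at 1 and expose the alpha-beta ridge", {
  d <- simulate_manifold_pairs(4, 1.0001, sigma = 0.05, seed = 63)
  fit <- suppressWarnings(
    fit_manifold_bayes(d, chains = 4, draws = 4000, warmup = 1000, seed = 64)
  )
  # the posterior piles against the K = 1 floor: the recorded signature of
  # the weak-stabilization limit
  expect_gt(fit$saturation[["k_floor"]], 0.25)
  fit <- suppressWarnings(derive_alpha_beta(fit, P_DEFAULT))
  td <- tidy(fit)
  expect_lt(td$median[td$parameter == "k_factor"], 1.2)
  expect_equal(td$median[td$parameter == "fc_max"], 4, tolerance = 0.1)
  dr <- dplyr::filter(fit$draws, beta > 0)
  expect_lte(stats::cor(log(dr$alpha), log(dr$beta)), -0.9)
})

test_that("a zero-information dataset returns the prior", {
  d <- tibble::tibble(fc_plus1 = rep(1, 8), fc_query = rep(1, 8))
  fit <- suppressWarnings(
    fit_manifold_bayes(d, priors = list(fc_max = c(0, 1), k_factor = c(1, 50),
                                        sigma = c(1e-6, 1)),
                       chains = 4, draws = 4000, warmup = 1000, seed = 65)
  )
  # fc_max marginal ~ Uniform(0, 1)
  expect_equal(mean(fit$draws$fc_max), 0.5, tolerance = 0.12)
  expect_equal(stats::sd(fit$draws$fc_max), sqrt(1 / 12), tolerance = 0.12)
})

test_that("alpha is flagged undefined when the chain sits at K = 1 exactly", {
  fake <- structure(
    list(draws = tibble::tibble(chain = 1L, iter = 1:10,
                                fc_max = rep(2, 10),
                                k_factor = rep(1, 10),
                                sigma = rep(0.1, 10)),
         diagnostics = tibble::tibble(parameter = character(),
                                      rhat = numeric(), ess = numeric()),
         dataset = tibble::tibble(fc_plus1 = 1, fc_query = 1)),
    class = "manifold_fit"
  )
  expect_warning(out <- derive_alpha_beta(fake, P_DEFAULT), "undefined")
  expect_true(all(out$draws$beta == 0))
  expect_true(all(is.na(out$draws$alpha)))
  expect_equal(out$alpha_undefined_frac, 1)
})

test_that("global affinity is identified from a steric reference curve", {
  lambda_true <- 5e-6
  P <- P_DEFAULT
  chi <- lambda_true / (1 + P) # steric: K = 1
  x <- 10^seq(3, 7, length.out = 15)
  set.seed(71)
  curves <- tibble::tibble(position_label = "+1", n_tf = x,
                           fc = 1 / (1 + chi * x) +
                             stats::rnorm(15, 0, 0.005))
  fixed <- tibble::tibble(position_label = "+1", fc_max = 0, k_factor = 1)
  fit <- fit_global_affinity(curves, fixed, chains = 4, draws = 1500,
                             warmup = 750, seed = 72)
  expect_equal(fit$lambda_median, lambda_true, tolerance = 0.05)
  expect_lt(fit$rhat, 1.05)

  expect_error(
    fit_global_affinity(curves,
                        tibble::tibble(position_label = "-61",
                                       fc_max = 2, k_factor = 2)),
    "position sets"
  )
  expect_error(
    fit_global_affinity(
      curves, tibble::tibble(position_label = "+1", fc_max = 2, k_factor = 1)
    ),
    "fc_max = 0"
  )
})

test_that("multi-position data recover a shared affinity", {
  lambda_true <- 2e-5
  P <- P_DEFAULT
  x <- 10^seq(2.5, 6, length.out = 12)
  specs <- list(`+1` = c(0, 1), `-61` = c(4, 3), `-54` = c(0.5, 2.5))
  set.seed(73)
  curves <- purrr::imap_dfr(specs, function(s, nm) {
    chi <- lambda_true * s[2] / (1 + P)
    mu <- (1 + s[1] * chi * x) / (1 + chi * x)
    tibble::tibble(position_label = nm, n_tf = x,
                   fc = mu + stats::rnorm(length(x), 0, 0.02 * max(mu)))
  })
  fixed <- purrr::imap_dfr(specs, function(s, nm) {
    tibble::tibble(position_label = nm, fc_max = s[1], k_factor = s[2])
  })
  fit <- fit_global_affinity(curves, fixed, chains = 4, draws = 1500,
                             warmup = 750, seed = 74)
  expect_equal(fit$lambda_median, lambda_true, tolerance = 0.1)
})

test_that("stabilization-only fit recovers beta when the data obey alpha = 1", {
  P <- P_DEFAULT
  betas <- c(`-61` = 8, `-50` = 60)
  datasets <- purrr::imap_dfr(betas, function(b, nm) {
    fcm <- b / (1 + (P / (1 + P)) * (b - 1))
    d <- simulate_manifold_pairs(fcm, 1 + P * b, sigma = 0.03 * max(fcm, 1),
                                 seed = 80 + b)
    dplyr::mutate(d, position_label = nm)
  })
  fit <- fit_stabilization_only(datasets, chains = 4, draws = 3000,
                                warmup = 1500, seed = 81)
  for (nm in names(betas)) {
    dr <- fit$draws[[paste0("beta_", nm)]]
    expect_equal(stats::median(dr), betas[[nm]], tolerance = 0.15)
  }
  # the sampled promoter energy stays compatible with the generating occupancy
  e_med <- stats::median(fit$draws$energy)
  expect_lt(abs(e_med - default_promoter$delta_eps_p), 1.5)
  # residuals show no systematic one-sided misfit when the model is true
  r <- stab_only_residuals(fit, datasets)
  expect_true(all(r$frac_positive > 0.15 & r$frac_positive < 0.85))
})

test_that("the no-acceleration activation ceiling is (1+P)/P", {
  expect_equal(stab_only_max_fold(P_DEFAULT), 16.03, tolerance = 1e-3)
  # FC_max of the restricted model approaches the ceiling as beta grows
  b <- 1e9
  expect_equal(b / (1 + (P_DEFAULT / (1 + P_DEFAULT)) * (b - 1)),
               stab_only_max_fold(P_DEFAULT), tolerance = 1e-6)
})

test_that("split R-hat and ESS behave on reference chains", {
  set.seed(90)
  good <- matrix(stats::rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.01)
  expect_gt(ess_mean(good), 2000)
  bad <- good + matrix(rep(c(0, 0, 0, 5), each = 1000), ncol = 4)
  expect_gt(split_rhat(bad), 1.5)
  # heavily autocorrelated chains have far fewer effective samples
  ar <- apply(good, 2, function(x) as.numeric(stats::filter(x, 0.95, "recursive")))
  expect_lt(ess_mean(ar), 400)
  s <- ci68_summary(1:100)
  expect_equal(unname(s["median"]), 50.5)
  expect_lt(s[["ci68_lower"]], s[["median"]])
})
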