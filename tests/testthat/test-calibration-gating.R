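test_that("calibration estimator is exact on a noise-free line", {
  s <- seq(100, 1000, by = 100)
  d <- sqrt(7 * s)
  pairs <- tibble::tibble(i1 = (s + d) / 2, i2 = (s - d) / 2)
  fit <- estimate_calibration_factor(pairs, n_boot = 50, seed = 1)
  expect_equal(fit$v, 7, tolerance = 1e-12)

  # single-molecule mothers: one daughter gets the molecule
  one <- simulate_division_pairs(3.5, 200, c(1, 1), seed = 2)
  fit1 <- estimate_calibration_factor(one, n_boot = 50, seed = 1)
  expect_equal(fit1$v, 3.5, tolerance = 1e-12)

  expect_error(
    estimate_calibration_factor(tibble::tibble(i1 = rep(2, 5), i2 = rep(2, 5))),
    "singular"
  )
})

test_that("calibration estimator is unbiased on binomial-partitioned pairs", {
  # bias (averaged over independent experiments) stays under 2%
  vhat <- vapply(1:20, function(s) {
    pairs <- simulate_division_pairs(10, 5000, c(100, 1000), seed = 700 + s)
    estimate_calibration_factor(pairs, n_boot = 2, seed = s)$v
  }, numeric(1))
  expect_lt(abs(mean(vhat) - 10) / 10, 0.02)

  pairs <- simulate_division_pairs(10, 1e4, c(100, 1000), seed = 7)
  fit <- estimate_calibration_factor(pairs, n_boot = 200, seed = 8)
  expect_lt(abs(fit$v - 10) / 10, 0.05)
  expect_gt(fit$v_se, 0)
  expect_equal(tidy(fit)$estimate, fit$v)
})

test_that("ellipsoid gate retains the configured chi-square(2) fraction", {
  set.seed(23)
  n <- 20000
  z1 <- stats::rnorm(n)
  z2 <- 0.7 * z1 + sqrt(1 - 0.49) * stats::rnorm(n)
  ev <- tibble::tibble(rfp = stats::runif(n, 10, 1000),
                       fsc = 10^(4.5 + 0.15 * z1),
                       ssc = 10^(4.2 + 0.15 * z2))
  for (level in c(0.95, 0.05)) {
    g <- ellipsoid_gate(ev, level, n_bins = 16)
    frac <- mean(g$retained, na.rm = TRUE)
    halfwidth <- 2.576 * sqrt(level * (1 - level) / n)
    expect_lt(abs(frac - level), halfwidth + 1e-3)
    # retention log conserves events
    log <- attr(g, "gate_log")
    expect_equal(sum(log$n), n)
  }
  # global variant agrees with the per-bin one on homogeneous scatter
  g_global <- ellipsoid_gate(ev, 0.95, per_bin = FALSE)
  expect_lt(abs(mean(g_global$retained) - 0.95), 0.005)
  # an event at (essentially) the center of its bin is always retained, even
  # at a very tight gate
  sub <- ev[1:200, ]
  center <- tibble::tibble(rfp = mean(sub$rfp),
                           fsc = 10^mean(log10(sub$fsc)),
                           ssc = 10^mean(log10(sub$ssc)))
  g_tight <- ellipsoid_gate(dplyr::bind_rows(sub, center), 0.05, n_bins = 1)
  expect_true(g_tight$retained[nrow(g_tight)])
})

test_that("proportional binning keeps counts flat and conserves events", {
  ev <- tibble::tibble(rfp = stats::runif(160, 0, 100),
                       fc = stats::runif(160))
  b <- bin_events_proportional(ev, 16)
  expect_equal(b$n_events, rep(10, 16))
  expect_equal(sum(b$n_events), nrow(ev))
  expect_error(bin_events_proportional(ev, 200), "exceeds")

  # medians of a monotone signal stay monotone across bins
  ev2 <- tibble::tibble(rfp = sort(stats::runif(500, 1, 100)))
  ev2$fc <- 1 / (1 + 0.05 * ev2$rfp)
  b2 <- bin_events_proportional(ev2, 10)
  expect_true(all(diff(b2$median_rfp) > 0))
  expect_true(all(diff(b2$median_fc) < 0))

  # the two-stage scheme: gating bins then analysis bins re-partition cleanly
  ev3 <- tibble::tibble(rfp = stats::runif(660), fsc = 10^stats::rnorm(660, 4.5, 0.1),
                        ssc = 10^stats::rnorm(660, 4.2, 0.1), fc = stats::runif(660))
  gated <- ellipsoid_gate(ev3, 0.95, n_bins = 16)
  kept <- dplyr::filter(gated, retained)
  b3 <- bin_events_proportional(kept, 22)
  expect_equal(nrow(b3), 22)
  expect_equal(sum(b3$n_events), nrow(kept))
  expect_lte(diff(range(b3$n_events)), 1)
})

test_that("low-RFP threshold filtering is strict and logged", {
  ev <- tibble::tibble(rfp = c(1, 5, 10, 50), yfp = 1, fsc = 1, ssc = 1)
  expect_identical(rfp_threshold_filter(ev, 0), tibble::as_tibble(ev))
  expect_message(out <- rfp_threshold_filter(ev, 6), "2 events")
  expect_equal(out$rfp, c(10, 50))
  expect_warning(suppressMessages(rfp_threshold_filter(ev, 51)), "every event")

  # dim events carry disproportionate reporter noise; dropping them tightens
  # the control fold-change profile
  set.seed(31)
  n <- 4000
  rfp <- stats::rlnorm(n, log(200), 1.2)
  ctrl <- tibble::tibble(rfp = rfp,
                         yfp = 1000 + stats::rnorm(n, 0, 6000 / sqrt(rfp + 1)))
  ctrl$fc <- ctrl$yfp / mean(ctrl$yfp)
  thr <- stats::median(ctrl$rfp)
  kept <- suppressMessages(rfp_threshold_filter(ctrl, thr))
  expect_lt(stats::var(kept$fc), stats::var(ctrl$fc))
  expect_equal(nrow(kept) + sum(ctrl$rfp < thr), n)
})

test_that("mu scaling is the fitted ratio between unit systems", {
  x <- 10^seq(1, 5, length.out = 30)
  mic <- tibble::tibble(n_tf = x, fc = 1 / (1 + 1.3e-4 * x))
  expect_equal(fit_mu_scaling(mic, mic)$mu, 1, tolerance = 1e-6)

  # cytometry curve = microscopy curve with a rescaled abscissa
  m <- 2.7
  cyt <- tibble::tibble(n_tf = x, fc = 1 / (1 + 1.3e-4 * m * x))
  fit <- fit_mu_scaling(cyt, mic)
  expect_equal(fit$mu, m, tolerance = 1e-4)

  up <- tibble::tibble(n_tf = x, fc = 1 + 3 * (1.3e-4 * x) / (1 + 1.3e-4 * x))
  expect_warning(fit_steric <- try(fit_mu_scaling(up, mic), silent = TRUE),
                 "repressive")
})
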