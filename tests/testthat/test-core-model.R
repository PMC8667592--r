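test_that("default promoter configuration reproduces the measured occupancy", {
  expect_equal(default_promoter$P, 6.65e-2, tolerance = 1e-2)
  # occupancy is computed in log space, so extreme energies stay finite
  expect_true(is.finite(promoter_params(delta_eps_p = -200)$P) ||
                promoter_params(delta_eps_p = -200)$P > 0)
  expect_equal(p_bound(0, promoter_params(delta_eps_p = -200),
                       tf_params()), 1, tolerance = 1e-10)
})

test_that("state weights have the right structure at the trivial corners", {
  tf <- make_tf(2, 3)
  w0 <- state_weights(default_promoter, tf, 0)
  expect_equal(w0$w_tf, 0)
  expect_equal(w0$w_cobound, 0)
  expect_equal(w0$Z, 1 + default_promoter$P)

  # energies cancel: n_p = n_tf = n_ns and zero binding energies
  pp <- promoter_params(n_p = 4.6e6, delta_eps_p = 0)
  tf2 <- tf_params(beta = 7, delta_eps_tf = 0)
  w <- state_weights(pp, tf2, 4.6e6)
  expect_equal(unlist(w[1, c("w_empty", "w_rnap", "w_tf", "w_cobound")]),
               c(w_empty = 1, w_rnap = 1, w_tf = 1, w_cobound = 7))

  # co-bound weight = RNAP weight * TF weight * beta / unbound weight
  w3 <- state_weights(default_promoter, tf, 123)
  expect_equal(w3$w_cobound, w3$w_rnap * w3$w_tf * tf$beta / w3$w_empty,
               tolerance = 1e-12)
  expect_error(state_weights(default_promoter, tf, -1), "n_tf")
})

test_that("partition function and p_bound agree with brute-force enumeration", {
  set.seed(401)
  for (i in 1:1000) {
    d <- random_param_draw()
    pp <- promoter_params(n_p = d$n_p, delta_eps_p = d$dep, n_ns = d$n_ns)
    tf <- tf_params(alpha = d$alpha, beta = exp(-d$dei), delta_eps_tf = d$det)
    w <- state_weights(pp, tf, d$n_tf)
    Z_oracle <- 1 + (d$n_p / d$n_ns) * exp(-d$dep) +
      (d$n_tf / d$n_ns) * exp(-d$det) +
      (d$n_p * d$n_tf / d$n_ns^2) * exp(-(d$dep + d$det + d$dei))
    expect_equal(w$Z, Z_oracle, tolerance = 1e-12)
    pb <- p_bound(d$n_tf, pp, tf)
    expect_equal(pb, (w$w_rnap + w$w_cobound) / w$Z, tolerance = 1e-12)
    expect_gt(pb, 0)
    expect_lt(pb, 1)
  }
})

test_that("p_bound limits: two-state value at zero TF, saturation in beta", {
  tf <- make_tf(1, 1)
  expect_equal(p_bound(0, default_promoter, tf),
               P_DEFAULT / (1 + P_DEFAULT), tolerance = 1e-12)
  betas <- 10^seq(0, 6, length.out = 13)
  pb <- vapply(betas, function(b) {
    p_bound(100, default_promoter, make_tf(1, b))
  }, numeric(1))
  expect_true(all(diff(pb) > 0))
  expect_equal(pb[length(pb)], 1, tolerance = 1e-2)
})

test_that("exact fold change: anchors, inert TF, saturation limit", {
  tf <- make_tf(2.5, 4)
  expect_identical(fold_change_full(0, default_promoter, tf), 1)
  inert <- make_tf(1, 1)
  expect_equal(fold_change_full(c(0, 1, 10, 1e4, 1e8), default_promoter, inert),
               rep(1, 5), tolerance = 1e-12)
  expect_equal(fold_change_full(1e13, default_promoter, tf),
               fcmax_exact(2.5, 4, P_DEFAULT), tolerance = 1e-6)
})

test_that("fold change agrees with the brute-force oracle to 1e-12", {
  set.seed(402)
  for (i in 1:1000) {
    d <- random_param_draw()
    pp <- promoter_params(n_p = d$n_p, delta_eps_p = d$dep, n_ns = d$n_ns)
    tf <- tf_params(alpha = d$alpha, beta = exp(-d$dei), delta_eps_tf = d$det)
    fc <- fold_change_full(d$n_tf, pp, tf)
    fc_o <- oracle_fold_change(d$n_p, d$dep, d$n_ns, d$det, d$dei, d$alpha,
                               d$n_tf)
    expect_equal(fc, fc_o, tolerance = 1e-12)
  }
})

test_that("weak form: anchors, monotonicity, saturation, weak-promoter bound", {
  expect_equal(fold_change_weak(1, effective_params(0, 1)), 0.5)
  expect_equal(fold_change_weak(0, effective_params(37, 0.1)), 1)
  # saturation: chi*n = 1e6 within 1e-5 of fc_max
  expect_lt(abs(fold_change_weak(1e6, effective_params(5, 1)) - 5) / 5, 1e-5)
  # monotone toward fc_max, direction set by sign(fc_max - 1)
  grid <- 10^seq(-3, 4, length.out = 50)
  up <- fold_change_weak(grid, effective_params(100, 1))
  dn <- fold_change_weak(grid, effective_params(1 / 100, 1))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) < 0))
  expect_equal(up[length(up)], 100, tolerance = 0.02)
  expect_equal(dn[length(dn)], 1 / 100, tolerance = 0.02)

  # relative discrepancy between exact and weak form never exceeds P
  set.seed(403)
  for (i in 1:50) {
    d <- random_param_draw()
    pp <- promoter_params(n_p = d$n_p, delta_eps_p = d$dep, n_ns = d$n_ns)
    tf <- tf_params(alpha = d$alpha, beta = exp(-d$dei), delta_eps_tf = d$det)
    eff <- effective_from_mechanistic(tf, pp)
    n <- 10^seq(-2, 9, length.out = 60)
    rel <- abs(fold_change_full(n, pp, tf) - fold_change_weak(n, eff)) /
      fold_change_weak(n, eff)
    expect_lte(max(rel), pp$P * (1 + 1e-10))
  }
})

test_that("effective parameters match their defining transforms", {
  eff <- effective_from_mechanistic(make_tf(1, 1), default_promoter)
  expect_equal(eff$fc_max, 1 / (1 + P_DEFAULT), tolerance = 1e-12)
  expect_equal(eff$fc_max, 0.9376, tolerance = 1e-3)
  expect_equal(effective_from_mechanistic(make_tf(5, 0),
                                          default_promoter)$fc_max, 0)
  # saturating fold change of the weak curve is fc_max itself
  ab <- REG_TABLE[["-64"]]
  eff64 <- effective_from_mechanistic(make_tf(ab[1], ab[2]), default_promoter)
  expect_equal(fold_change_weak(1e12 / eff64$chi, eff64), eff64$fc_max,
               tolerance = 1e-9)
  expect_equal(eff64$k_factor, 1 + P_DEFAULT * ab[2])
})

test_that("curves sharing fc_max collapse onto one function of chi*n_tf", {
  # same fc_max via different mechanisms: baseline, stronger affinity,
  # beta = 10 with alpha rebalanced
  pp <- default_promoter
  base <- make_tf(100 * (1 + pp$P), 1, det = -7)
  aff <- make_tf(100 * (1 + pp$P), 1, det = -9)
  target_fcmax <- effective_from_mechanistic(base, pp)$fc_max
  a10 <- target_fcmax * (1 + pp$P * 10) / 10
  stab <- make_tf(a10, 10, det = -7)
  effs <- lapply(list(base, aff, stab), effective_from_mechanistic, promoter = pp)
  expect_equal(effs[[1]]$fc_max, effs[[2]]$fc_max, tolerance = 1e-12)
  expect_equal(effs[[1]]$fc_max, effs[[3]]$fc_max, tolerance = 1e-12)
  x <- 10^seq(-3, 4, length.out = 100) # common effective-concentration grid
  fcs <- lapply(effs, function(e) fold_change_weak(x / e$chi, e))
  expect_lt(max(abs(fcs[[1]] - fcs[[2]])), 1e-12)
  expect_lt(max(abs(fcs[[1]] - fcs[[3]])), 1e-12)

  # collapse_transform rescales the abscissa; chi = 1 is the identity
  curve <- tibble::tibble(n_tf = c(1, 10, 100), fc = c(0.9, 0.5, 0.1))
  out <- collapse_transform(curve, effective_params(0, 1))
  expect_equal(out$n_eff, curve$n_tf)
  out2 <- collapse_transform(curve, effs[[1]])
  expect_equal(out2$n_eff, curve$n_tf * effs[[1]]$chi)

  # steric limit: collapsed curve is 1/(1+x)
  x <- 10^seq(-2, 2, length.out = 30)
  expect_equal(fold_change_weak(x, effective_params(0, 1)), 1 / (1 + x),
               tolerance = 1e-12)
})
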