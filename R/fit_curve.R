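#' Bootstrap least-squares fit of a fold-change curve
#'
#' Fits the weak-promoter fold-change model
#' \eqn{FC = (1 + FC_{max}\chi N)/(1 + \chi N)} to a titration curve by
#' nonlinear least squares and builds confidence intervals by resampling:
#' each bootstrap iteration redraws the replicate fold-change points within
#' every induction condition (with replacement) and refits. The point fit
#' uses a multi-start strategy (5 starts, log-spaced chi across the abundance
#' range) to avoid local minima on unsaturated curves; resample fits start
#' from the point estimate and fall back to multi-start on failure.
#'
#' @param curve Fold-change curve: data frame with `n_tf`, `fc` and (for
#'   within-condition resampling) `condition_id` columns; at least 3 distinct
#'   abundance levels.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional RNG seed for the resampling.
#' @return Object of class `tf_curve_fit`: `fc_max`/`chi` point estimates,
#'   bootstrap means and percentile 95% intervals, resample table, and a
#'   `diagnostic_ok` flag (FALSE when more than 20% of resample fits failed
#'   to converge).
#' @export
fit_curve_bootstrap <- function(curve, n_boot = 1000, seed = NULL) {
  stopifnot(is.data.frame(curve), all(c("n_tf", "fc") %in% names(curve)))
  curve <- dplyr::filter(tibble::as_tibble(curve), is.finite(.data$fc),
                         .data$fc > 0)
  if (length(unique(curve$n_tf)) < 3) {
    stop("need at least 3 distinct abundance levels", call. = FALSE)
  }
  if (!"condition_id" %in% names(curve)) {
    curve$condition_id <- seq_len(nrow(curve))
  }
  point <- fit_fc_nls(curve, multi_start = TRUE)
  if (is.null(point)) stop("point fit failed to converge", call. = FALSE)

  resample_once <- function() {
    res <- curve |>
      dplyr::group_by(.data$condition_id) |>
      dplyr::slice_sample(prop = 1, replace = TRUE) |>
      dplyr::ungroup()
    fit <- fit_fc_nls(res, start = point, multi_start = FALSE)
    if (is.null(fit)) fit <- fit_fc_nls(res, multi_start = TRUE)
    fit
  }
  runner <- function() {
    fits <- vector("list", n_boot)
    for (b in seq_len(n_boot)) fits[[b]] <- resample_once()
    fits
  }
  fits <- if (is.null(seed)) runner() else with_preserved_seed(seed, runner())
  ok <- !vapply(fits, is.null, logical(1))
  boot <- dplyr::bind_rows(fits[ok])
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  structure(
    list(
      fc_max = point$fc_max, chi = point$chi,
      fc_max_mean = mean(boot$fc_max), chi_mean = mean(boot$chi),
      fc_max_ci95 = ci(boot$fc_max), chi_ci95 = ci(boot$chi),
      n_boot = n_boot, converged_frac = mean(ok),
      diagnostic_ok = mean(ok) >= 0.8,
      boot = boot
    ),
    class = "tf_curve_fit"
  )
}

# single weak-form NLS fit; returns tibble(fc_max, chi) or NULL on failure
fit_fc_nls <- function(curve, start = NULL, multi_start = TRUE) {
  df <- dplyr::filter(curve, .data$n_tf > 0)
  if (nrow(df) < 3) return(NULL)
  starts <- if (!is.null(start)) {
    list(list(fc_max = max(start$fc_max, 1e-8), lchi = log(start$chi)))
  } else {
    fc_end <- mean(df$fc[df$n_tf >= stats::quantile(df$n_tf, 0.8)])
    lapply(log(10^seq(-2, 2, length.out = 5) / stats::median(df$n_tf)),
           function(lc) list(fc_max = max(fc_end, 1e-6), lchi = lc))
  }
  if (!multi_start) starts <- starts[1]
  best <- NULL
  best_rss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fc ~ (1 + fc_max * exp(lchi) * n_tf) / (1 + exp(lchi) * n_tf),
        data = df, start = s,
        lower = c(fc_max = 0, lchi = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- fit
      }
    }
  }
  if (is.null(best)) return(NULL)
  cf <- stats::coef(best)
  tibble::tibble(fc_max = cf[["fc_max"]], chi = exp(cf[["lchi"]]))
}

#' @export
print.tf_curve_fit <- function(x, ...) {
  cat("<tf_curve_fit>  fc_max =", signif(x$fc_max, 4),
      "[", signif(x$fc_max_ci95[1], 4), ",", signif(x$fc_max_ci95[2], 4), "]",
      "  chi =", signif(x$chi, 4),
      "[", signif(x$chi_ci95[1], 4), ",", signif(x$chi_ci95[2], 4), "]\n")
  if (!x$diagnostic_ok) cat("  ! >20% of bootstrap fits failed\n")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.tf_curve_fit <- function(x, ...) {
  tibble::tibble(
    parameter = c("fc_max", "chi"),
    estimate = c(x$fc_max, x$chi),
    boot_mean = c(x$fc_max_mean, x$chi_mean),
    ci95_lower = c(x$fc_max_ci95[1], x$chi_ci95[1]),
    ci95_upper = c(x$fc_max_ci95[2], x$chi_ci95[2])
  )
}

#' @rdname glance
#' @export
glance.tf_curve_fit <- function(x, ...) {
  tibble::tibble(
    n_boot = x$n_boot,
    converged_frac = x$converged_frac,
    diagnostic_ok = x$diagnostic_ok
  )
}

#' @rdname tidy
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(parameter = "v", estimate = x$v, std_error = x$v_se)
}

#' @rdname tidy
#' @export
tidy.mu_fit <- function(x, ...) {
  tibble::tibble(
    parameter = c("mu", "chi_rfp", "chi_mic"),
    estimate = c(x$mu, x$chi_rfp, x$chi_mic)
  )
}
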