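#' Fluctuation-counting calibration factor
#'
#' Estimates the fluorescence-per-molecule conversion factor v from
#' mother-daughter partitioning noise. Binomial partitioning of N molecules
#' implies \eqn{E[(I_1-I_2)^2] = v\,(I_1+I_2)}, so v is the through-origin
#' slope of the squared daughter difference on the daughter sum. The fit is
#' weighted least squares with weights \eqn{1/(I_1+I_2)^2} (the residual
#' variance of a squared difference grows with the square of its mean),
#' which reduces to the mean of \eqn{(I_1-I_2)^2/(I_1+I_2)}. The standard
#' error comes from a bootstrap over pairs.
#'
#' @param pairs Division pairs: data frame with `i1`, `i2` columns (see
#'   [simulate_division_pairs()]).
#' @param n_boot Bootstrap resamples for the standard error.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `calibration_fit`: list with `v`, `v_se`,
#'   `n_pairs`, `boot` (the bootstrap replicates).
#' @export
estimate_calibration_factor <- function(pairs, n_boot = 1000, seed = NULL) {
  stopifnot(is.data.frame(pairs), all(c("i1", "i2") %in% names(pairs)))
  s <- pairs$i1 + pairs$i2
  d2 <- (pairs$i1 - pairs$i2)^2
  keep <- s > 0
  s <- s[keep]
  d2 <- d2[keep]
  if (length(s) < 2 || nrow(unique(cbind(pairs$i1, pairs$i2)[keep, , drop = FALSE])) < 2) {
    stop("all division pairs are identical: singular fit", call. = FALSE)
  }
  ratio <- d2 / s
  v <- mean(ratio)
  boot_fun <- function() {
    idx <- sample.int(length(ratio), replace = TRUE)
    mean(ratio[idx])
  }
  boot <- if (is.null(seed)) {
    replicate(n_boot, boot_fun())
  } else {
    with_preserved_seed(seed, replicate(n_boot, boot_fun()))
  }
  structure(
    list(v = v, v_se = stats::sd(boot), n_pairs = length(ratio), boot = boot),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>  v =", signif(x$v, 5), "+/-", signif(x$v_se, 3),
      " (", x$n_pairs, "pairs )\n")
  invisible(x)
}

#' Cytometry-to-TF-number scaling factor
#'
#' Fits the steric-repression curve \eqn{FC = 1/(1 + \chi x)} independently
#' to a cytometry-unit curve and a microscopy-unit (TF-number) curve of the
#' same +1 strain, and returns the unit conversion
#' \eqn{\mu = \chi_{RFP}/\chi_{mic}} (TFs per RFP unit): because
#' \eqn{\chi_{RFP}\,RFP = \chi\,N_{TF}} must hold for the same cells, the
#' ratio of the fitted coefficients is the abscissa rescaling between the
#' two instruments.
#'
#' @param curve_cytometry +1 fold-change curve in cytometry units: data frame
#'   with `n_tf` (here: RFP units) and `fc` columns.
#' @param curve_microscopy +1 fold-change curve in TF-number units, same
#'   schema.
#' @return Object of class `mu_fit`: list with `mu`, `chi_rfp`, `chi_mic`.
#' @export
fit_mu_scaling <- function(curve_cytometry, curve_microscopy) {
  chi_rfp <- fit_steric_chi(curve_cytometry)
  chi_mic <- fit_steric_chi(curve_microscopy)
  structure(
    list(mu = chi_rfp / chi_mic, chi_rfp = chi_rfp, chi_mic = chi_mic),
    class = "mu_fit"
  )
}

# one-parameter least-squares fit of FC = 1/(1 + chi * x), chi on log scale
fit_steric_chi <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("n_tf", "fc") %in% names(curve)))
  if (mean(utils::tail(curve$fc[order(curve$n_tf)], 3)) > 1) {
    warning("curve does not look repressive; the steric model may not apply",
            call. = FALSE)
  }
  df <- dplyr::filter(curve, .data$n_tf > 0)
  # moment start: FC = 1/(1+chi x) => chi = (1/FC - 1)/x
  chi0 <- stats::median(pmax((1 / pmax(df$fc, 1e-6) - 1), 1e-8) / df$n_tf)
  fit <- minpack.lm::nlsLM(
    fc ~ 1 / (1 + exp(lchi) * n_tf),
    data = df,
    start = list(lchi = log(chi0)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  exp(stats::coef(fit)[["lchi"]])
}

#' @export
print.mu_fit <- function(x, ...) {
  cat("<mu_fit>  chi_rfp =", signif(x$chi_rfp, 4),
      " chi_mic =", signif(x$chi_mic, 4),
      " mu =", signif(x$mu, 4), "\n")
  invisible(x)
}
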