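#' Promoter parameters
#'
#' Bundles the RNAP-side quantities of the thermodynamic model: the number of
#' polymerase molecules per cell, their binding energy to the core promoter,
#' the size of the nonspecific background (the genome, in base pairs) and the
#' basal transcription rate. The single derived quantity that matters
#' downstream is the promoter occupancy parameter
#' \eqn{P = (N_p/N_{NS}) e^{-\Delta\varepsilon_p}}, the Boltzmann weight of
#' the RNAP-bound state relative to the empty promoter.
#'
#' The defaults reproduce the weak synthetic promoter used throughout the
#' package: \eqn{P \approx 6.65\times 10^{-2}}.
#'
#' @param n_p RNAP copy number per cell (> 0).
#' @param delta_eps_p RNAP-promoter binding energy in kBT (negative =
#'   favorable).
#' @param n_ns Number of nonspecific background sites; by convention the
#'   genome size in base pairs, 4.6e6, and never fitted.
#' @param r Basal transcription rate from the RNAP-only state (arbitrary
#'   expression units per time).
#'
#' @return An object of class `promoter_params`: a list with the four fields
#'   plus the derived occupancy `P`.
#' @examples
#' pp <- promoter_params()
#' pp$P # ~0.0665
#' @export
promoter_params <- function(n_p = 460, delta_eps_p = -6.5, n_ns = 4.6e6, r = 1) {
  stopifnot(is.numeric(n_p), length(n_p) == 1, n_p > 0)
  stopifnot(is.numeric(n_ns), length(n_ns) == 1, n_ns > 0)
  stopifnot(is.numeric(delta_eps_p), length(delta_eps_p) == 1, is.finite(delta_eps_p))
  stopifnot(is.numeric(r), length(r) == 1, r > 0)
  # log-space so extreme energies do not overflow before the ratio is taken
  P <- exp(log(n_p) - log(n_ns) - delta_eps_p)
  structure(
    list(n_p = n_p, delta_eps_p = delta_eps_p, n_ns = n_ns, r = r, P = P),
    class = "promoter_params"
  )
}

#' TF regulatory parameters
#'
#' The TF-side quantities: acceleration `alpha` (fold change in the
#' initiation rate when TF and RNAP are co-bound), stabilization `beta`
#' (multiplicative change in the co-bound state's statistical weight,
#' \eqn{\beta = e^{-\Delta\varepsilon_I}}), and the TF operator binding
#' energy `delta_eps_tf` (kBT). Two derived quantities are attached: the
#' scaled affinity \eqn{\lambda = e^{-\Delta\varepsilon_{TF}}/N_{NS}} and
#' \eqn{\epsilon = e^{-\Delta\varepsilon_{TF}}}.
#'
#' `beta = 0` encodes steric hindrance (the co-bound state is forbidden); the
#' interaction energy is then \eqn{-\infty} and reported as such via
#' `delta_eps_i`.
#'
#' @param alpha Acceleration factor (> 0). 1 = no effect on initiation.
#' @param beta Stabilization factor (>= 0). 1 = no effect on RNAP dwell time,
#'   0 = steric exclusion.
#' @param delta_eps_tf TF-operator binding energy in kBT.
#' @param n_ns Nonspecific site count used to scale the affinity.
#'
#' @return An object of class `tf_params` with fields `alpha`, `beta`,
#'   `delta_eps_tf`, `delta_eps_i` (log-beta interaction energy, `-Inf` when
#'   `beta = 0`), `lambda_aff`, `epsilon`, `n_ns`.
#' @examples
#' tf_params(alpha = 24.911, beta = 29.545, delta_eps_tf = -5)
#' @export
tf_params <- function(alpha = 1, beta = 1, delta_eps_tf = -5, n_ns = 4.6e6) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  stopifnot(is.numeric(delta_eps_tf), length(delta_eps_tf) == 1, is.finite(delta_eps_tf))
  lambda_aff <- exp(-delta_eps_tf - log(n_ns))
  structure(
    list(
      alpha = alpha, beta = beta, delta_eps_tf = delta_eps_tf,
      delta_eps_i = if (beta > 0) -log(beta) else Inf,
      lambda_aff = lambda_aff, epsilon = exp(-delta_eps_tf), n_ns = n_ns
    ),
    class = "tf_params"
  )
}

#' Effective regulatory parameters
#'
#' The two-number summary that defines every regulatory curve: the saturating
#' fold change `fc_max` and the effective-concentration coefficient `chi`
#' (per TF molecule), together with the stabilization factor
#' \eqn{K = 1 + P\beta}.
#'
#' @param fc_max Saturating fold change (>= 0).
#' @param chi Effective-concentration coefficient (> 0).
#' @param k_factor Stabilization factor K = 1 + P*beta (>= 0).
#' @return Object of class `effective_params`.
#' @seealso [effective_from_mechanistic()] to derive these from mechanistic
#'   parameters.
#' @export
effective_params <- function(fc_max, chi, k_factor = NA_real_) {
  stopifnot(is.numeric(fc_max), length(fc_max) == 1, fc_max >= 0)
  stopifnot(is.numeric(chi), length(chi) == 1, chi > 0)
  structure(
    list(fc_max = fc_max, chi = chi, k_factor = k_factor),
    class = "effective_params"
  )
}

#' @export
print.promoter_params <- function(x, ...) {
  cat("<promoter_params>  n_p =", x$n_p, " delta_eps_p =", x$delta_eps_p,
      "kBT  n_ns =", format(x$n_ns, scientific = TRUE), "\n")
  cat("  occupancy P =", signif(x$P, 4), "\n")
  invisible(x)
}

#' @export
print.tf_params <- function(x, ...) {
  cat("<tf_params>  alpha =", x$alpha, " beta =", x$beta,
      " delta_eps_tf =", x$delta_eps_tf, "kBT\n")
  cat("  lambda_aff =", signif(x$lambda_aff, 4), "\n")
  invisible(x)
}

#' @export
print.effective_params <- function(x, ...) {
  cat("<effective_params>  fc_max =", signif(x$fc_max, 5),
      " chi =", signif(x$chi, 5), " K =", signif(x$k_factor, 5), "\n")
  invisible(x)
}
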