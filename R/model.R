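#' Statistical weights of the four promoter states
#'
#' The promoter can be empty, bound by RNAP only, bound by the TF only, or
#' co-bound. Relative to the empty state the weights are
#' \deqn{w = (1,\; P,\; \lambda N_{TF},\; P \lambda N_{TF} \beta)}
#' with \eqn{P = (N_p/N_{NS})e^{-\Delta\varepsilon_p}} and
#' \eqn{\lambda = e^{-\Delta\varepsilon_{TF}}/N_{NS}}. Their sum is the
#' partition function Z. Arithmetic is done in log space so extreme binding
#' energies (tens of kBT either way) do not overflow intermediate products.
#'
#' @param promoter A [promoter_params()] object.
#' @param tf A [tf_params()] object.
#' @param n_tf TF copy number (vectorized, >= 0).
#' @return A tibble with columns `n_tf`, `w_empty`, `w_rnap`, `w_tf`,
#'   `w_cobound`, `Z`.
#' @examples
#' state_weights(promoter_params(), tf_params(beta = 2), n_tf = c(0, 10, 100))
#' @export
state_weights <- function(promoter, tf, n_tf) {
  stopifnot(inherits(promoter, "promoter_params"), inherits(tf, "tf_params"))
  if (any(n_tf < 0)) stop("n_tf must be >= 0", call. = FALSE)
  lw_rnap <- log(promoter$n_p) - log(promoter$n_ns) - promoter$delta_eps_p
  lw_tf <- ifelse(n_tf > 0,
                  log(n_tf) - log(tf$n_ns) - tf$delta_eps_tf,
                  -Inf)
  lw_co <- if (tf$beta > 0) lw_rnap + lw_tf + log(tf$beta) else rep(-Inf, length(n_tf))
  w_rnap <- exp(lw_rnap)
  tibble::tibble(
    n_tf = n_tf,
    w_empty = 1,
    w_rnap = w_rnap,
    w_tf = exp(lw_tf),
    w_cobound = exp(lw_co),
    Z = 1 + w_rnap + exp(lw_tf) + exp(lw_co)
  )
}

#' Probability that RNAP is bound
#'
#' The occupancy of the promoter by polymerase as a function of TF number:
#' the RNAP-only plus co-bound weights over the partition function. At
#' `n_tf = 0` this is the two-state value \eqn{P/(1+P)}; strong stabilization
#' drives it monotonically toward 1.
#'
#' @inheritParams state_weights
#' @return Numeric vector of probabilities in (0, 1).
#' @export
p_bound <- function(n_tf, promoter, tf) {
  if (any(n_tf < 0)) stop("n_tf must be >= 0", call. = FALSE)
  # log-sum-exp over the four states keeps this finite for extreme energies
  lw_rnap <- log(promoter$n_p) - log(promoter$n_ns) - promoter$delta_eps_p
  lw_tf <- ifelse(n_tf > 0, log(n_tf) - log(tf$n_ns) - tf$delta_eps_tf, -Inf)
  lw_co <- if (tf$beta > 0) lw_rnap + lw_tf + log(tf$beta) else rep(-Inf, length(n_tf))
  num <- logsumexp2(rep(lw_rnap, length(n_tf)), lw_co)
  den <- apply(cbind(0, lw_rnap, lw_tf, lw_co), 1, logsumexp_vec)
  exp(num - den)
}

logsumexp_vec <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

logsumexp2 <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log(exp(la - m) + exp(lb - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

#' Fold change in expression, exact form
#'
#' Expression at TF copy number `n_tf` divided by expression at zero TF,
#' without the weak-promoter approximation:
#' \deqn{FC = \frac{(1+P)\,(1 + \alpha\beta\, a)}{1 + P + a(1 + P\beta)},
#'   \qquad a = \lambda N_{TF}.}
#' It equals 1 exactly at `n_tf = 0`, is monotone in `n_tf`, and saturates at
#' \eqn{\alpha\beta(1+P)/(1+P\beta)} as `n_tf` grows.
#'
#' @inheritParams state_weights
#' @return Numeric vector of fold changes (> 0).
#' @seealso [fold_change_weak()] for the weak-promoter two-parameter form.
#' @export
fold_change_full <- function(n_tf, promoter, tf) {
  if (any(n_tf < 0)) stop("n_tf must be >= 0", call. = FALSE)
  P <- promoter$P
  a <- n_tf * tf$lambda_aff
  (1 + P) * (1 + tf$alpha * tf$beta * a) / (1 + P + a * (1 + P * tf$beta))
}

#' Fold change, weak-promoter form
#'
#' The two-parameter reduction of the fold-change model:
#' \deqn{FC = \frac{1 + FC_{max}\,\chi N_{TF}}{1 + \chi N_{TF}}}
#' where \eqn{\chi N_{TF}} acts as an effective TF concentration. Equals 1 at
#' `n_tf = 0` and approaches `fc_max` as the effective concentration grows.
#'
#' @param n_tf TF copy number (vectorized, >= 0).
#' @param eff An [effective_params()] object, or anything with `fc_max` and
#'   `chi` fields.
#' @return Numeric vector of fold changes.
#' @examples
#' fold_change_weak(0:3, effective_params(fc_max = 0, chi = 1))
#' @export
fold_change_weak <- function(n_tf, eff) {
  if (any(n_tf < 0)) stop("n_tf must be >= 0", call. = FALSE)
  stopifnot(eff$chi > 0)
  x <- eff$chi * n_tf
  (1 + eff$fc_max * x) / (1 + x)
}

#' Effective parameters from mechanistic ones
#'
#' Collapses the mechanistic parameter set (alpha, beta, TF affinity, P) into
#' the weak-promoter effective pair
#' \deqn{FC_{max} = \frac{\alpha\beta}{1+P\beta}, \qquad
#'       \chi = \lambda\,(1+P\beta)}
#' plus the stabilization factor \eqn{K = 1+P\beta}.
#'
#' @param tf A [tf_params()] object.
#' @param promoter A [promoter_params()] object.
#' @return An [effective_params()] object.
#' @examples
#' effective_from_mechanistic(tf_params(alpha = 1, beta = 1), promoter_params())
#' @export
effective_from_mechanistic <- function(tf, promoter) {
  stopifnot(inherits(promoter, "promoter_params"), inherits(tf, "tf_params"))
  K <- 1 + promoter$P * tf$beta
  effective_params(
    fc_max = tf$alpha * tf$beta / K,
    chi = tf$lambda_aff * K,
    k_factor = K
  )
}

#' Saturating fold change, exact form
#'
#' The large-`n_tf` limit of [fold_change_full()]:
#' \eqn{\alpha\beta(1+P)/(1+P\beta)}. This is the FC_max convention implied
#' by the acceleration back-transform (see [alpha_from_fcmax_beta()]); it
#' exceeds the weak-limit value of [effective_from_mechanistic()] by the
#' factor \eqn{(1+P)}.
#'
#' @param alpha,beta Mechanistic regulatory parameters.
#' @param P Promoter occupancy parameter.
#' @return Saturating fold change.
#' @export
fcmax_exact <- function(alpha, beta, P) {
  alpha * beta * (1 + P) / (1 + P * beta)
}

#' Re-express a fold-change curve against effective TF concentration
#'
#' Adds the collapse abscissa \eqn{n_{eff} = \chi N_{TF}} to a fold-change
#' curve. Curves that share `fc_max` but differ in affinity or stabilization
#' become pointwise identical functions of `n_eff`.
#'
#' @param curve A fold-change curve: a data frame with at least an `n_tf`
#'   column (see [fold_change_table()] for the full schema).
#' @param eff An [effective_params()] object supplying `chi`.
#' @return The curve as a tibble with an added `n_eff` column.
#' @export
collapse_transform <- function(curve, eff) {
  stopifnot(is.data.frame(curve), "n_tf" %in% names(curve), eff$chi > 0)
  dplyr::mutate(tibble::as_tibble(curve), n_eff = .data$n_tf * eff$chi)
}
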