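#' Concentration manifold, general two-position form
#'
#' Fold change at a query position `y` as a function of fold change at a
#' reference position `x`, with TF copy number eliminated between the two
#' weak-promoter curves. Writing \eqn{t = (FC^x - 1)/(FC^x_{max} - FC^x)} and
#' \eqn{R = (\epsilon^y K^y)/(\epsilon^x K^x)},
#' \deqn{FC^y = \frac{1 + FC^y_{max}\, R\, t}{1 + R\, t}.}
#' When the binding sequence (hence affinity) is shared between the two
#' positions, `affinity_ratio = 1` and R reduces to \eqn{K^y/K^x}.
#'
#' @param fc_x Fold change at the reference position (vectorized); must lie
#'   strictly between `fc_max_x` and 1 (or equal 1, the zero-TF anchor).
#' @param fc_max_x,k_x Effective parameters of the reference position.
#' @param fc_max_y,k_y Effective parameters of the query position.
#' @param affinity_ratio \eqn{\epsilon^y/\epsilon^x}; 1 when the binding
#'   sequence is identical at both positions.
#' @return Fold change at the query position.
#' @examples
#' manifold_general(0.5, 0, 1, 4, 2) # steric reference, activating query
#' @export
manifold_general <- function(fc_x, fc_max_x, k_x, fc_max_y, k_y,
                             affinity_ratio = 1) {
  stopifnot(all(fc_x > 0), k_x > 0, k_y > 0, affinity_ratio > 0)
  if (any(fc_x == fc_max_x)) {
    stop("fc_x equals fc_max_x: the manifold is singular there; ",
         "treat it as the saturation limit fc_max_y", call. = FALSE)
  }
  t_x <- (fc_x - 1) / (fc_max_x - fc_x)
  R <- affinity_ratio * k_y / k_x
  (1 + fc_max_y * R * t_x) / (1 + R * t_x)
}

#' Concentration manifold against a steric +1 reference
#'
#' Fold change at a query position as a function of the fold change `u` at a
#' perfectly repressing reference site (+1, where steric hindrance makes
#' \eqn{FC_{max} = 0}, \eqn{K = 1}):
#' \deqn{FC^y = \frac{1 + FC^y_{max} K^y (1-u)/u}{1 + K^y (1-u)/u}.}
#' The curve always passes through (1, 1) (zero TF) and tends to
#' `fc_max_y` as `u -> 0` (saturating TF). For `k_y = 1` (weak
#' stabilization) it is exactly the straight line
#' \eqn{u + FC^y_{max}(1-u)}; `k_y > 1` bends the curve away from that
#' chord, which is what makes stabilization inferable from manifold data.
#'
#' @param fc_plus1 Fold change at the +1 reference, in \[0, 1\] (vectorized).
#'   `0` is handled as the analytic saturation limit.
#' @param fc_max_y Saturating fold change of the query position (>= 0).
#' @param k_y Stabilization factor K = 1 + P*beta of the query position.
#' @param P Promoter occupancy parameter (unused in the formula itself but
#'   accepted for interface symmetry; `k_y` already carries P*beta).
#' @return Fold change at the query position.
#' @examples
#' manifold_steric_reference(c(1, 0.5, 0), fc_max_y = 4, k_y = 1)
#' @export
manifold_steric_reference <- function(fc_plus1, fc_max_y, k_y, P = NULL) {
  stopifnot(fc_max_y >= 0, k_y > 0)
  if (any(fc_plus1 < 0 | fc_plus1 > 1)) {
    stop("fc_plus1 must lie in [0, 1]", call. = FALSE)
  }
  out <- numeric(length(fc_plus1))
  sat <- fc_plus1 == 0
  out[sat] <- fc_max_y # analytic u -> 0 limit, no epsilon fudging
  u <- fc_plus1[!sat]
  t <- k_y * (1 - u) / u
  out[!sat] <- (1 + fc_max_y * t) / (1 + t)
  out
}

#' Stabilization from the manifold K factor
#'
#' Inverts \eqn{K = 1 + P\beta}: \eqn{\beta = (K-1)/P}. Under the prior
#' convention used throughout (beta >= 0, i.e. K >= 1), K below 1 is a
#' domain error rather than silently mapped to negative stabilization.
#'
#' @param k_factor K values (vectorized, >= 1).
#' @param P Promoter occupancy parameter (> 0).
#' @return beta values.
#' @export
beta_from_k <- function(k_factor, P) {
  stopifnot(P > 0)
  if (any(k_factor < 1)) {
    stop("k_factor < 1 is outside the beta >= 0 convention", call. = FALSE)
  }
  (k_factor - 1) / P
}

#' Acceleration from FC_max and stabilization
#'
#' Back-transforms a saturating fold change and a stabilization value into
#' the acceleration:
#' \deqn{\alpha = \frac{FC_{max}}{\beta}\left(1 +
#'   \frac{P}{1+P}(\beta - 1)\right).}
#' Because \eqn{1 + \frac{P}{1+P}(\beta-1) = \frac{1+P\beta}{1+P}}, the
#' FC_max in this relation is the exact-form saturating fold change
#' ([fcmax_exact()]), not the weak-limit one.
#'
#' @param fc_max Saturating fold change (vectorized, >= 0).
#' @param beta Stabilization (> 0; `beta = 0` leaves alpha unidentifiable and
#'   is an error, not a guess).
#' @param P Promoter occupancy parameter.
#' @return alpha values.
#' @export
alpha_from_fcmax_beta <- function(fc_max, beta, P) {
  stopifnot(P > 0, all(fc_max >= 0))
  if (any(beta <= 0)) {
    stop("alpha is unidentifiable at beta = 0 (steric exclusion)", call. = FALSE)
  }
  (fc_max / beta) * (1 + (P / (1 + P)) * (beta - 1))
}

#' Pair two binned fold-change curves by effective TF concentration
#'
#' Builds a concentration-manifold dataset by matching a query-position curve
#' with the +1 reference curve on a shared abundance grid: each retained bin
#' contributes one (fc_plus1, fc_query) pair measured at the same effective
#' TF concentration. Bins present in only one curve are dropped (and
#' reported via the `dropped_bins` attribute).
#'
#' @param curve_plus1 Binned +1 reference curve: data frame with `bin_id`
#'   (or `condition_id`) and `fc` columns; `fc_se` is carried if present.
#' @param curve_query Binned query-position curve, same schema; a
#'   `position_label` column is carried if present.
#' @param by Column to match bins on, default `"bin_id"` falling back to
#'   `"condition_id"`.
#' @return A tibble with columns `position_label`, `bin_id`, `fc_plus1`,
#'   `fc_query`, `fc_plus1_se`, `fc_query_se`.
#' @export
pair_by_concentration <- function(curve_plus1, curve_query, by = NULL) {
  stopifnot(is.data.frame(curve_plus1), is.data.frame(curve_query))
  if (is.null(by)) {
    by <- if ("bin_id" %in% names(curve_plus1) && "bin_id" %in% names(curve_query)) {
      "bin_id"
    } else "condition_id"
  }
  stopifnot(by %in% names(curve_plus1), by %in% names(curve_query))
  ref <- tibble::tibble(
    bin_id = curve_plus1[[by]],
    fc_plus1 = curve_plus1$fc,
    fc_plus1_se = if ("fc_se" %in% names(curve_plus1)) curve_plus1$fc_se else NA_real_
  )
  qry <- tibble::tibble(
    bin_id = curve_query[[by]],
    fc_query = curve_query$fc,
    fc_query_se = if ("fc_se" %in% names(curve_query)) curve_query$fc_se else NA_real_
  )
  pairs <- dplyr::inner_join(ref, qry, by = "bin_id")
  if (nrow(pairs) == 0) {
    stop("no common bins between the two curves", call. = FALSE)
  }
  pairs$position_label <- if ("position_label" %in% names(curve_query)) {
    curve_query$position_label[match(pairs$bin_id, curve_query[[by]])]
  } else NA_integer_
  dropped <- setdiff(union(ref$bin_id, qry$bin_id), pairs$bin_id)
  out <- dplyr::select(
    pairs, "position_label", "bin_id",
    "fc_plus1", "fc_query", "fc_plus1_se", "fc_query_se"
  )
  attr(out, "dropped_bins") <- dropped
  out
}
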