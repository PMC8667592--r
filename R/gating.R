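#' Assign equal-count bins on a channel
#'
#' Proportional binning: ranks the events on the stated channel and cuts the
#' ranks into `n_bins` nearly equal-count bins (so bin widths vary in signal
#' space but occupancy is flat). Alternatively, explicit `edges` impose a
#' common grid, e.g. to put several strains on the reference strain's bins.
#'
#' @param events Event tibble.
#' @param n_bins Number of bins (>= 1, <= number of events).
#' @param channel Column to bin on (default `"rfp"`).
#' @param edges Optional numeric vector of cut points (length `n_bins + 1`);
#'   when supplied, bins are fixed intervals rather than equal-count.
#' @return `events` with an integer `bin_id` column.
#' @export
assign_bins <- function(events, n_bins, channel = "rfp", edges = NULL) {
  stopifnot(is.data.frame(events), n_bins >= 1, channel %in% names(events))
  if (n_bins > nrow(events)) {
    stop("n_bins exceeds the number of events", call. = FALSE)
  }
  x <- events[[channel]]
  ids <- if (is.null(edges)) {
    dplyr::ntile(x, n_bins)
  } else {
    as.integer(cut(x, breaks = edges, include.lowest = TRUE))
  }
  out <- tibble::as_tibble(events)
  out$bin_id <- ids # overwrite any bin assignment from an earlier stage
  out
}

#' Proportionally bin events and report per-bin medians
#'
#' Bins single events into equal-count intervals on a channel and reports the
#' per-bin median of that channel and of the per-event fold change (when an
#' `fc` column is present), the representative values carried forward to
#' curve fitting and manifold pairing.
#'
#' @inheritParams assign_bins
#' @return A tibble: `bin_id`, `n_events`, `median_rfp` (median of the
#'   binning channel), `median_fc` (or `NA` without an `fc` column).
#' @export
bin_events_proportional <- function(events, n_bins, channel = "rfp", edges = NULL) {
  if (nrow(events) == 0) stop("no events to bin", call. = FALSE)
  assign_bins(events, n_bins, channel, edges) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      median_rfp = stats::median(.data[[channel]]),
      median_fc = if ("fc" %in% names(events)) stats::median(.data$fc) else NA_real_,
      .groups = "drop"
    )
}

#' Ellipsoid gate on the scatter channels
#'
#' Retains events whose log10 forward/side-scatter pair lies inside the
#' Mahalanobis ellipsoid of its RFP bin: per bin, the mean and covariance of
#' `(log10 fsc, log10 ssc)` are estimated and events with squared Mahalanobis
#' distance at most `qchisq(percentile_level, df = 2)` are kept (for jointly
#' normal scatter the squared distance is chi-square with 2 degrees of
#' freedom, so `percentile_level` is the expected retained fraction). With
#' `per_bin = FALSE` a single global ellipsoid is fit instead.
#'
#' @param events Event tibble with `fsc`, `ssc` and the binning channel.
#' @param percentile_level Chi-square(2) level of the cut; the default 0.95
#'   retains the central 95% of events. `0.05` reproduces a literal
#'   5th-percentile cut (retaining only the innermost 5%).
#' @param n_bins Number of proportional RFP bins for the per-bin gate.
#' @param channel Binning channel.
#' @param per_bin Fit the ellipsoid per RFP bin (default) or globally.
#' @return `events` with `bin_id` and a logical `retained` column (`NA` for
#'   bins whose covariance was singular, which are skipped with a warning).
#'   A per-bin retention log is attached as attribute `"gate_log"`.
#' @export
ellipsoid_gate <- function(events, percentile_level = 0.95, n_bins = 16,
                           channel = "rfp", per_bin = TRUE) {
  stopifnot(percentile_level > 0, percentile_level < 1)
  binned <- if (per_bin) {
    assign_bins(events, n_bins, channel)
  } else {
    dplyr::mutate(tibble::as_tibble(events), bin_id = 1L)
  }
  cutoff <- stats::qchisq(percentile_level, df = 2)
  gate_one <- function(df) {
    X <- cbind(log10(df$fsc), log10(df$ssc))
    if (nrow(X) < 3) {
      warning("bin with fewer than 3 events skipped", call. = FALSE)
      df$retained <- NA
      return(df)
    }
    S <- stats::cov(X)
    if (!is.finite(determinant(S)$modulus) || det(S) <= 0) {
      warning("singular scatter covariance; bin skipped", call. = FALSE)
      df$retained <- NA
      return(df)
    }
    d2 <- stats::mahalanobis(X, colMeans(X), S)
    df$retained <- d2 <= cutoff
    df
  }
  out <- binned |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::group_modify(~ gate_one(.x)) |>
    dplyr::ungroup()
  log <- out |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_retained = sum(.data$retained, na.rm = TRUE),
      .groups = "drop"
    )
  attr(out, "gate_log") <- log
  out
}

#' Drop low-RFP events
#'
#' Removes events whose RFP signal falls below a threshold. At low TF
#' abundance the reporter ratio is dominated by background fluctuations, so
#' discarding the dimmest events stabilizes the low-abundance end of the
#' fold-change curve. The threshold has no principled value; it is chosen by
#' inspecting the control circuit's profile.
#'
#' @param events Event tibble with an `rfp` column.
#' @param threshold Minimum retained RFP value (>= 0).
#' @return The retained events; the number removed is reported via message,
#'   and an empty result triggers a warning.
#' @export
rfp_threshold_filter <- function(events, threshold) {
  stopifnot(threshold >= 0)
  keep <- events$rfp >= threshold
  removed <- sum(!keep)
  if (removed > 0) message(removed, " events below the RFP threshold removed")
  out <- dplyr::filter(tibble::as_tibble(events), .data$rfp >= threshold)
  if (nrow(out) == 0) warning("RFP threshold removed every event", call. = FALSE)
  out
}

#' Per-event fold change against a control population
#'
#' Adds an `fc` column: each event's background-subtracted reporter signal
#' divided by the mean background-subtracted reporter signal of the control
#' (no-binding-site) population. Used to carry single-event fold changes into
#' proportional binning.
#'
#' @param events Regulated-strain events.
#' @param control_events Control-strain events.
#' @param af_yfp Reporter-channel autofluorescence mean to subtract.
#' @return `events` with an added `fc` column.
#' @export
event_fold_change <- function(events, control_events, af_yfp = 0) {
  ref <- mean(control_events$yfp - af_yfp)
  dplyr::mutate(tibble::as_tibble(events), fc = (.data$yfp - af_yfp) / ref)
}
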