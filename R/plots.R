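#' Plot a fold-change titration curve
#'
#' Fold change against TF number on log-log axes, optionally overlaying the
#' weak-form model curve for a given effective parameterization.
#'
#' @param curve Curve tibble (`n_tf`, `fc`, optional `fc_se`,
#'   `position_label`).
#' @param eff Optional [effective_params()] whose model curve is overlaid.
#' @return A ggplot object.
#' @export
plot_fold_change <- function(curve, eff = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_tf, y = .data$fc)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$position_label))) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "TF copy number", y = "fold change", colour = "position")
  if ("fc_se" %in% names(curve)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fc - .data$fc_se, ymax = .data$fc + .data$fc_se,
                   colour = factor(.data$position_label)),
      width = 0
    )
  }
  if (!is.null(eff)) {
    grid <- tibble::tibble(
      n_tf = 10^seq(log10(max(min(curve$n_tf[curve$n_tf > 0]), 1e-3)),
                    log10(max(curve$n_tf)), length.out = 200)
    )
    grid$fc <- fold_change_weak(grid$n_tf, eff)
    p <- p + ggplot2::geom_line(data = grid, colour = "black")
  }
  p
}

#' Plot a concentration manifold fit
#'
#' The manifold pairs (query fold change against +1 reference fold change)
#' with the posterior-median model curve and a 68% posterior band. The x
#' axis is reversed so increasing TF concentration reads left to right from
#' the (1, 1) anchor.
#'
#' @param object A `manifold_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.manifold_fit <- function(object, ...) {
  u_grid <- seq(1e-3, 1, length.out = 200)
  idx <- sample.int(nrow(object$draws), min(400, nrow(object$draws)))
  curves <- purrr::map_dfr(idx, function(i) {
    tibble::tibble(
      u = u_grid,
      fc = manifold_steric_reference(u_grid, object$draws$fc_max[i],
                                     object$draws$k_factor[i])
    )
  })
  band <- curves |>
    dplyr::group_by(.data$u) |>
    dplyr::summarise(
      lo = stats::quantile(.data$fc, 0.16),
      hi = stats::quantile(.data$fc, 0.84),
      mid = stats::median(.data$fc),
      .groups = "drop"
    )
  ggplot2::ggplot(object$dataset,
                  ggplot2::aes(x = .data$fc_plus1, y = .data$fc_query)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$u, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.25, fill = "firebrick") +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$u, y = .data$mid),
                       inherit.aes = FALSE, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "fold change at +1 (steric reference)",
                  y = "fold change at query position")
}

#' Phase-plane plot of regulatory modes
#'
#' Posterior clouds of (alpha, beta) per position on log-log axes, with the
#' alpha = 1 / beta = 1 quadrant boundaries that separate coherent from
#' incoherent regulation.
#'
#' @param fits Named list of `manifold_fit` objects with derived
#'   alpha/beta draws.
#' @param n_points Posterior points drawn per position.
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(fits, n_points = 500) {
  cloud <- purrr::imap_dfr(fits, function(fit, pos) {
    d <- dplyr::filter(fit$draws, !is.na(.data$alpha), .data$alpha > 0,
                       .data$beta > 0)
    d <- d[sample.int(nrow(d), min(n_points, nrow(d))), ]
    dplyr::mutate(d, position_label = pos)
  })
  ggplot2::ggplot(cloud, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                      colour = .data$position_label)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(alpha ~ "(acceleration)"),
                  y = expression(beta ~ "(stabilization)"),
                  colour = "position")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
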