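#' Define a synthetic single-cell measurement scenario
#'
#' Describes everything needed to simulate a TF titration experiment with
#' known ground truth: the promoter, the true regulatory parameters of one or
#' more binding positions, the induction series (mean TFs/cell per
#' condition), cell numbers, noise levels, backgrounds, the
#' fluorescence-per-molecule calibration factor, and the RNG seed.
#'
#' Defaults emulate the study conditions of the titration experiments: an
#' 11-point induction series spanning a few to a few thousand TFs per cell,
#' lognormal cell-to-cell TF copy-number noise (CV 0.3), multiplicative
#' lognormal reporter noise (CV 0.2), additive Gaussian autofluorescence in
#' both fluorescence channels, and log10-bivariate-normal forward/side
#' scatter with correlation 0.7.
#'
#' @param truth A [tf_params()] object, or a named list of them (names =
#'   position labels such as `"-64"`).
#' @param promoter A [promoter_params()] object.
#' @param induction_means Mean TFs/cell per induction condition.
#' @param cells_per_condition Cells simulated per condition and replicate.
#' @param n_replicates Number of replicate cultures per condition.
#' @param tf_noise_cv Lognormal CV of per-cell TF copy number.
#' @param yfp_noise_cv Lognormal CV of multiplicative reporter noise.
#' @param yfp_baseline Mean reporter signal of the unregulated promoter
#'   (arbitrary units).
#' @param calib_v Fluorescence units per TF molecule in the mCherry channel.
#' @param autofluorescence List with `rfp_mean`, `rfp_sd`, `yfp_mean`,
#'   `yfp_sd`: additive Gaussian background per channel.
#' @param scatter List with `fsc_mean`, `ssc_mean`, `fsc_sd`, `ssc_sd`,
#'   `corr` describing the log10 scatter-channel distribution.
#' @param seed Mandatory RNG seed; identical seeds give byte-identical
#'   simulated tables.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(truth = tf_params(),
                               promoter = promoter_params(),
                               induction_means = round(10^seq(log10(3), log10(3000), length.out = 11)),
                               cells_per_condition = 500,
                               n_replicates = 3,
                               tf_noise_cv = 0.3,
                               yfp_noise_cv = 0.2,
                               yfp_baseline = 1000,
                               calib_v = 10,
                               autofluorescence = list(rfp_mean = 50, rfp_sd = 5,
                                                       yfp_mean = 20, yfp_sd = 5),
                               scatter = list(fsc_mean = 4.5, ssc_mean = 4.2,
                                              fsc_sd = 0.15, ssc_sd = 0.15,
                                              corr = 0.7),
                               seed) {
  if (missing(seed)) stop("a seed is mandatory for a synthetic scenario", call. = FALSE)
  if (inherits(truth, "tf_params")) truth <- list(truth)
  stopifnot(all(vapply(truth, inherits, logical(1), "tf_params")))
  stopifnot(all(induction_means > 0), cells_per_condition > 0, n_replicates > 0)
  stopifnot(tf_noise_cv >= 0, yfp_noise_cv >= 0, calib_v > 0)
  structure(
    list(
      truth = truth, promoter = promoter,
      induction_means = induction_means,
      cells_per_condition = cells_per_condition,
      n_replicates = n_replicates,
      tf_noise_cv = tf_noise_cv, yfp_noise_cv = yfp_noise_cv,
      yfp_baseline = yfp_baseline, calib_v = calib_v,
      autofluorescence = autofluorescence, scatter = scatter,
      seed = as.integer(seed)
    ),
    class = "synthetic_scenario"
  )
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate single-cell cytometry events
#'
#' Draws per-cell events for every induction condition and replicate of a
#' scenario. Per cell: the TF count is lognormal around the condition mean
#' (rounded to an integer); the mCherry/RFP signal is `calib_v * TF` plus
#' additive background; the YFP reporter follows the thermodynamic fold
#' change of the true parameters ([fold_change_full()]) times the baseline,
#' with multiplicative lognormal noise plus additive background; log10
#' scatter channels are correlated bivariate normal. Control events (a
#' circuit with no TF binding site) use fold change identically 1.
#'
#' @param scenario A [synthetic_scenario()].
#' @param position Which entry of `scenario$truth` to simulate (name or
#'   index); defaults to the first.
#' @param control If `TRUE`, simulate the no-binding-site control circuit
#'   (fold change 1 at every TF level).
#' @param seed RNG seed; defaults to the scenario seed, offset for control
#'   draws so regulated and control populations are independent.
#' @return A tibble of events: `position_label`, `condition_id`,
#'   `replicate_id`, `is_control`, `tf_true`, `fsc`, `ssc`, `rfp`, `yfp`.
#' @export
simulate_cells <- function(scenario, position = 1, control = FALSE, seed = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  tf <- scenario$truth[[position]]
  label <- if (is.character(position)) {
    position
  } else if (!is.null(names(scenario$truth))) {
    names(scenario$truth)[position]
  } else {
    as.character(position)
  }
  if (is.null(seed)) seed <- scenario$seed + if (control) 10000L else 0L
  af <- scenario$autofluorescence
  sc <- scenario$scatter
  n_cond <- length(scenario$induction_means)
  with_preserved_seed(seed, {
    grid <- tidyr::expand_grid(
      condition_id = seq_len(n_cond),
      replicate_id = seq_len(scenario$n_replicates)
    )
    purrr::pmap_dfr(grid, function(condition_id, replicate_id) {
      m <- scenario$induction_means[condition_id]
      nc <- scenario$cells_per_condition
      tf_n <- round(rlnorm_mean_cv(nc, m, scenario$tf_noise_cv))
      fc <- if (control) rep(1, nc) else fold_change_full(tf_n, scenario$promoter, tf)
      yfp_sig <- scenario$yfp_baseline * fc *
        rlnorm_mean_cv(nc, 1, scenario$yfp_noise_cv)
      rfp <- scenario$calib_v * tf_n + stats::rnorm(nc, af$rfp_mean, af$rfp_sd)
      yfp <- yfp_sig + stats::rnorm(nc, af$yfp_mean, af$yfp_sd)
      z1 <- stats::rnorm(nc)
      z2 <- sc$corr * z1 + sqrt(1 - sc$corr^2) * stats::rnorm(nc)
      tibble::tibble(
        position_label = label,
        condition_id = condition_id,
        replicate_id = replicate_id,
        is_control = control,
        tf_true = tf_n,
        fsc = 10^(sc$fsc_mean + sc$fsc_sd * z1),
        ssc = 10^(sc$ssc_mean + sc$ssc_sd * z2),
        rfp = rfp,
        yfp = yfp
      )
    })
  })
}

#' Simulate mother-daughter division pairs
#'
#' Generates the fluctuation-counting calibration data: mother cells with a
#' known molecule count divide, partitioning molecules binomially between the
#' two daughters; daughter fluorescence is `calib_v` times the inherited
#' count (plus optional additive measurement noise). The partitioning
#' identity \eqn{E[(I_1-I_2)^2] = v\, E[I_1+I_2]} is what the calibration
#' estimator exploits.
#'
#' @param calib_v Fluorescence units per molecule (> 0).
#' @param n_pairs Number of mother-daughter pairs.
#' @param count_range Length-2 integer range of mother molecule counts
#'   (drawn uniformly).
#' @param seed RNG seed.
#' @param background_sd Additive Gaussian noise sd on each daughter intensity
#'   (default 0).
#' @return A tibble: `n_mother`, `i1`, `i2`.
#' @export
simulate_division_pairs <- function(calib_v, n_pairs, count_range = c(100, 1000),
                                    seed, background_sd = 0) {
  stopifnot(calib_v > 0, n_pairs >= 1, length(count_range) == 2)
  with_preserved_seed(seed, {
    n <- sample.int(count_range[2] - count_range[1] + 1L, n_pairs, replace = TRUE) +
      count_range[1] - 1L
    n1 <- stats::rbinom(n_pairs, n, 0.5)
    tibble::tibble(
      n_mother = n,
      i1 = calib_v * n1 + stats::rnorm(n_pairs, 0, background_sd),
      i2 = calib_v * (n - n1) + stats::rnorm(n_pairs, 0, background_sd)
    )
  })
}

#' Fold-change curve from regulated and control event tables
#'
#' Computes, per condition and replicate, the fold change as the ratio of
#' mean background-subtracted reporter signal in the regulated strain to the
#' matched control strain, and the mean TF number from the
#' background-subtracted mCherry signal divided by the calibration factor
#' (optionally times the cytometry scaling `mu`). The standard error per
#' point is propagated from the cell-level variances of the two means
#' (delta method for a ratio).
#'
#' @param events Regulated-strain events (as from [simulate_cells()]).
#' @param control_events Matched control-strain events (no binding site).
#' @param calib_v Fluorescence units per TF molecule.
#' @param af_rfp,af_yfp Autofluorescence channel means to subtract before any
#'   ratio. Negative post-subtraction values are kept, not clipped, so the
#'   ratio of means stays unbiased.
#' @param mu Cytometry-to-TF-number scaling factor (1 for microscopy-style
#'   units).
#' @return A fold-change curve tibble: `position_label`, `condition_id`,
#'   `replicate_id`, `n_tf`, `fc`, `fc_se`.
#' @export
fold_change_table <- function(events, control_events, calib_v,
                              af_rfp = 0, af_yfp = 0, mu = 1) {
  stopifnot(is.data.frame(events), is.data.frame(control_events), calib_v > 0)
  key <- c("condition_id", "replicate_id")
  ctrl <- control_events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      yfp_ctrl = mean(.data$yfp - af_yfp),
      yfp_ctrl_var = stats::var(.data$yfp - af_yfp) / dplyr::n(),
      .groups = "drop"
    )
  reg <- events |>
    dplyr::group_by(.data$position_label, dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      n_tf = mu * mean(.data$rfp - af_rfp) / calib_v,
      yfp_reg = mean(.data$yfp - af_yfp),
      yfp_reg_var = stats::var(.data$yfp - af_yfp) / dplyr::n(),
      .groups = "drop"
    )
  missing <- dplyr::anti_join(reg, ctrl, by = key)
  if (nrow(missing) > 0) {
    stop("conditions without a control partner: ",
         paste(unique(missing$condition_id), collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(reg, ctrl, by = key) |>
    dplyr::mutate(
      fc = .data$yfp_reg / .data$yfp_ctrl,
      fc_se = abs(.data$fc) * sqrt(.data$yfp_reg_var / .data$yfp_reg^2 +
                                     .data$yfp_ctrl_var / .data$yfp_ctrl^2)
    ) |>
    dplyr::select("position_label", dplyr::all_of(key), "n_tf", "fc", "fc_se")
}

#' Average replicate fold-change points per condition
#'
#' Aggregates a per-replicate fold-change curve into one point per condition:
#' the mean across replicates with the standard error of that mean, for both
#' the TF number and the fold change.
#'
#' @param curve A fold-change curve from [fold_change_table()].
#' @return A tibble with one row per (`position_label`, `condition_id`):
#'   `n_tf`, `fc`, `fc_se`, `n_rep`.
#' @export
aggregate_replicates <- function(curve) {
  curve |>
    dplyr::group_by(.data$position_label, .data$condition_id) |>
    dplyr::summarise(
      n_tf = mean(.data$n_tf),
      fc_se = stats::sd(.data$fc) / sqrt(dplyr::n()),
      fc = mean(.data$fc),
      n_rep = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("position_label", "condition_id", "n_tf", "fc", "fc_se", "n_rep")
}

#' Simulate binned concentration-manifold pairs
#'
#' Generates the manifold data the Bayesian inference consumes, directly at
#' the binned level: a log-spaced grid of effective TF concentrations sets
#' the +1 reference fold change \eqn{u = 1/(1+\chi N)}, the query fold
#' change follows [manifold_steric_reference()] with the true
#' (`fc_max`, `K`), and additive Gaussian noise of scale `sigma` is applied
#' (matching the Gaussian likelihood the inference assumes). The default
#' noise scale is 15% of the dynamic range `|fc_max - 1|` (floored at 0.2),
#' which reproduces posterior interval widths comparable to the fitted
#' single-cell datasets this package emulates.
#'
#' @param fc_max True saturating fold change of the query position.
#' @param k_factor True stabilization factor K = 1 + P*beta.
#' @param n_pairs Number of manifold pairs (abundance bins).
#' @param sigma Noise sd on the query fold change; default
#'   `0.15 * max(abs(fc_max - 1), 0.2)`.
#' @param conc_range Range of effective TF concentration (chi*N) spanned by
#'   the log-spaced grid.
#' @param seed RNG seed.
#' @return A manifold dataset tibble (`position_label`, `bin_id`,
#'   `fc_plus1`, `fc_query`, SE columns as `NA`), with the truth recorded in
#'   the `"truth"` attribute.
#' @export
simulate_manifold_pairs <- function(fc_max, k_factor, n_pairs = 22,
                                    sigma = NULL,
                                    conc_range = c(0.02, 20), seed = 1) {
  stopifnot(fc_max >= 0, k_factor >= 1, n_pairs >= 2)
  if (is.null(sigma)) sigma <- 0.15 * max(abs(fc_max - 1), 0.2)
  x <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
              length.out = n_pairs)
  u <- 1 / (1 + x)
  with_preserved_seed(seed, {
    y <- manifold_steric_reference(u, fc_max, k_factor) +
      stats::rnorm(n_pairs, 0, sigma)
    out <- tibble::tibble(
      position_label = NA_character_, bin_id = seq_len(n_pairs),
      fc_plus1 = u, fc_query = y,
      fc_plus1_se = NA_real_, fc_query_se = NA_real_
    )
    attr(out, "truth") <- list(fc_max = fc_max, k_factor = k_factor,
                               sigma = sigma)
    out
  })
}
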