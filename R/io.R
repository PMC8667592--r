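#' Read / write fold-change curves
#'
#' Fold-change curves are exchanged as UTF-8 CSV with a header row and the
#' columns `position_label`, `condition_id`, `replicate_id`, `n_tf`, `fc`,
#' `fc_se`.
#'
#' @param path File path.
#' @return `read_fold_change_curve()` returns the curve tibble;
#'   `write_fold_change_curve()` returns `path` invisibly.
#' @export
read_fold_change_curve <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    position_label = readr::col_character(),
                    condition_id = readr::col_integer(),
                    replicate_id = readr::col_integer(),
                    n_tf = readr::col_double(),
                    fc = readr::col_double(),
                    fc_se = readr::col_double()
                  ))
}

#' @param curve Curve tibble with the schema above.
#' @rdname read_fold_change_curve
#' @export
write_fold_change_curve <- function(curve, path) {
  cols <- c("position_label", "condition_id", "replicate_id", "n_tf", "fc", "fc_se")
  stopifnot(all(cols %in% names(curve)))
  readr::write_csv(curve[cols], path)
  invisible(path)
}

#' Read / write manifold datasets
#'
#' Manifold pair tables use the CSV columns `position_label`, `bin_id`,
#' `fc_plus1`, `fc_query`, `fc_plus1_se`, `fc_query_se`.
#'
#' @param path File path.
#' @return The dataset tibble, or `path` invisibly for the writer.
#' @export
read_manifold_dataset <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @param dataset Dataset tibble with the schema above.
#' @rdname read_manifold_dataset
#' @export
write_manifold_dataset <- function(dataset, path) {
  cols <- c("position_label", "bin_id", "fc_plus1", "fc_query",
            "fc_plus1_se", "fc_query_se")
  stopifnot(all(cols %in% names(dataset)))
  readr::write_csv(dataset[cols], path)
  invisible(path)
}

#' Write simulated cytometry events
#'
#' Events CSV schema: `condition_id`, `replicate_id`, `is_control`, `fsc`,
#' `ssc`, `rfp`, `yfp` (plus any extra columns present, e.g. `bin_id`,
#' `retained`, `position_label`, `tf_true`).
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("condition_id", "replicate_id", "is_control",
                  "fsc", "ssc", "rfp", "yfp") %in% names(events)))
  readr::write_csv(events, path)
  invisible(path)
}
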