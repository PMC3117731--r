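# Time-series dataset handling.
#
# Canonical schema (one row per compound/compartment/time point):
#   individual, time_min, compound, compartment ("m" medium, "c" intracellular
#   free), replicate_mean, sd, n_replicates, flag ("ok" or "bloq" for below
#   the quantification range).

.dataset_columns <- c("individual", "time_min", "compound", "compartment",
                      "replicate_mean", "sd", "n_replicates", "flag")

#' Validate a time-series dataset
#'
#' Checks the column schema, compound and compartment codes, non-negative
#' standard deviations and a non-negative increasing time grid per series.
#' Violations raise errors naming the offending fields and rows.
#'
#' @param dataset A data.frame in the canonical time-series schema.
#' @return The dataset, invisibly, on success.
#' @export
validate_timeseries <- function(dataset) {
  missing_cols <- setdiff(.dataset_columns, names(dataset))
  if (length(missing_cols) > 0) {
    stop("time-series dataset lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!dataset$compound %in% .compounds)
  if (length(bad) > 0) stop("unknown compound in rows ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!dataset$compartment %in% c("m", "c"))
  if (length(bad) > 0) stop("compartment must be 'm' or 'c' (rows ", paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  bad <- which(!is.na(dataset$sd) & dataset$sd < 0)
  if (length(bad) > 0) stop("negative sd in rows ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(dataset$time_min < 0)) stop("time_min must be non-negative", call. = FALSE)
  split_key <- interaction(dataset$individual, dataset$compound, dataset$compartment, drop = TRUE)
  for (s in split(dataset$time_min, split_key)) {
    if (any(diff(s) <= 0)) stop("time grid out of order within a series", call. = FALSE)
  }
  invisible(dataset)
}

#' Effective measurement standard deviations with a floor
#'
#' The weighting of the least-squares criterion uses per-point triplicate
#' standard deviations floored at the LC-MS/MS quantification limit
#' equivalent (0.5 pmol/ml) and at 2% of the series maximum mean, so that
#' points with vanishing replicate scatter do not receive infinite weight.
#'
#' @param dataset A validated time-series dataset.
#' @param floor_abs Absolute floor (pmol/ml).
#' @param floor_rel Relative floor as a fraction of each series' maximum mean.
#' @return Numeric vector `s_eff`, one entry per row.
#' @export
effective_sd <- function(dataset, floor_abs = 0.5, floor_rel = 0.02) {
  key <- interaction(dataset$individual, dataset$compound, dataset$compartment, drop = TRUE)
  series_max <- stats::ave(ifelse(is.na(dataset$replicate_mean), 0, dataset$replicate_mean),
                           key, FUN = max)
  s <- ifelse(is.na(dataset$sd), 0, dataset$sd)
  pmax(s, floor_abs, floor_rel * series_max)
}

#' Model predictions matched to dataset rows
#'
#' Simulates on the union of dataset time points (plus t = 0) and returns the
#' predicted concentration for every row: medium rows map to the medium pool,
#' intracellular rows to the free pool (bound material is lost in the
#' cell-disruption supernatant and is not part of the measurement).
#'
#' @param params,geometry Model configuration.
#' @param dataset A validated time-series dataset (single individual).
#' @param rtol,atol Solver tolerances.
#' @return Numeric vector of predictions, one per row.
#' @export
predict_dataset <- function(params, geometry, dataset, rtol = 1e-6, atol = 1e-8) {
  times <- sort(unique(c(0, dataset$time_min)))
  res <- simulate_model(params, geometry, t_grid = times, rtol = rtol, atol = atol)
  idx_t <- match(dataset$time_min, res$time)
  cols <- paste0(dataset$compound, ".", dataset$compartment)
  res$states[cbind(idx_t, match(cols, colnames(res$states)))]
}
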