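# CSV/JSON/YAML input and output.

#' Read a time-series dataset from CSV
#'
#' Expects the canonical schema (individual, time_min, compound, compartment,
#' replicate_mean, sd, n_replicates, flag) and validates it; malformed files
#' are rejected with errors naming the offending fields.
#'
#' @param path CSV file path.
#' @return A validated time-series data.frame.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$flag <- as.character(d$flag)
  validate_timeseries(d)
  d
}

#' Write a time-series dataset to CSV
#' @param dataset A validated time-series data.frame.
#' @param path Output path.
#' @export
write_timeseries <- function(dataset, path) {
  validate_timeseries(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a liver-bank CSV (subject_id, cyp3a4_level, ugt1a3_level, basis)
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_liver_bank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "cyp3a4_level", "ugt1a3_level")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) stop("bank lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(d$cyp3a4_level <= 0) || any(d$ugt1a3_level <= 0)) {
    stop("bank enzyme levels must be positive", call. = FALSE)
  }
  d
}

#' Write a liver-bank CSV
#' @param bank data.frame as from [generate_liver_bank()].
#' @param path Output path.
#' @export
write_liver_bank <- function(bank, path) {
  utils::write.csv(bank, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Validates the presence and types of the blocks a run needs: `variant`,
#' `geometry` (named numbers), optional `parameters` (dotted path -> value),
#' `optimizer` (mu, lambda, budget, seeds), `identifiability` thresholds and
#' `population` settings. Unknown top-level blocks are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("variant", "geometry", "parameters", "optimizer",
             "identifiability", "population", "paths", "seed", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) stop("unknown config blocks: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$variant) &&
      !cfg$variant %in% c("full", "reduced", "reduced_betaox")) {
    stop("config field 'variant' must be full, reduced or reduced_betaox", call. = FALSE)
  }
  if (!is.null(cfg$geometry)) {
    bad <- !vapply(cfg$geometry, is.numeric, logical(1))
    if (any(bad)) stop("config geometry entries must be numeric: ",
                       paste(names(cfg$geometry)[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$parameters) && is.null(names(cfg$parameters))) {
    stop("config 'parameters' must map dotted paths to values", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write run provenance (resolved config, seeds, package version, checksums)
#'
#' Every analysis stage writes this sidecar next to its outputs so that a
#' deterministic stage can be re-run bit-compatibly.
#'
#' @param dir Output directory (created if needed).
#' @param config Resolved configuration list.
#' @param seed Seed(s) used.
#' @param inputs Character vector of input file paths to checksum (md5).
#' @return The sidecar path, invisibly.
#' @export
write_provenance <- function(dir, config = list(), seed = NA, inputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sums <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  meta <- list(package = "atorkin",
               version = as.character(utils::packageVersion("atorkin")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = seed, config = config, input_md5 = sums)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
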