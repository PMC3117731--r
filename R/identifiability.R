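# Local sensitivity analysis, Fisher-information identifiability and the
# iterative transport-lumping model reduction.

#' Local parameter sensitivities by central finite differences
#'
#' S[(j,n), k] = d c_calc(j, t_n) / d theta_k, evaluated one parameter at a
#' time with a relative step (default 1e-3) on the natural scale. Rows follow
#' the dataset rows (observed compound/compartment/time combinations).
#'
#' @param params,geometry Model configuration at the evaluation point.
#' @param dataset Observation grid: a validated time-series dataset (the
#'   means are not used, only which pools are observed when).
#' @param paths Dotted parameter paths to differentiate with respect to.
#' @param rel_step Relative finite-difference step.
#' @param rtol,atol Solver tolerances (tighter than the fitting defaults so
#'   the differences are not dominated by integration error).
#' @return Matrix (rows = dataset rows, columns = paths) of class
#'   `sensitivity_matrix` with attribute `theta` (the evaluation point).
#'   Columns whose perturbed simulations failed are flagged in attribute
#'   `failed_paths` and filled with NA.
#' @export
local_sensitivities <- function(params, geometry, dataset, paths,
                                rel_step = 1e-3, rtol = 1e-10, atol = 1e-12) {
  validate_timeseries(dataset)
  theta <- vapply(paths, function(p) param_get(params, p), numeric(1))
  S <- matrix(NA_real_, nrow(dataset), length(paths),
              dimnames = list(NULL, paths))
  failed <- character()
  for (k in seq_along(paths)) {
    h <- rel_step * max(abs(theta[k]), 1e-12)
    pred <- tryCatch({
      up <- param_set(params, stats::setNames(theta[k] + h, paths[k]))
      dn <- param_set(params, stats::setNames(theta[k] - h, paths[k]))
      (predict_dataset(up, geometry, dataset, rtol = rtol, atol = atol) -
         predict_dataset(dn, geometry, dataset, rtol = rtol, atol = atol)) / (2 * h)
    }, error = function(e) NULL)
    if (is.null(pred)) failed <- c(failed, paths[k]) else S[, k] <- pred
  }
  structure(S, theta = theta, failed_paths = failed,
            class = c("sensitivity_matrix", "matrix"))
}

#' Fisher information, covariance, relative errors and correlations
#'
#' FIM = S' W S with W = diag(1/s_eff^2). The covariance is the inverse, or
#' the Moore-Penrose pseudo-inverse with a singularity flag when the
#' condition number exceeds 1e12 (e.g. exactly collinear columns). Relative
#' standard errors are 100 sqrt(cov_kk) / |theta_k| (the Cramer-Rao bound).
#'
#' @param S Sensitivity matrix (observations x parameters).
#' @param weights Per-observation weights 1/s_eff^2.
#' @param theta Parameter values (defaults to the attribute stored by
#'   [local_sensitivities()]).
#' @return Object of class `fim_report`: `fim`, `cov`, `rel_error_pct`,
#'   `correlation`, `eigenvalues`, `condition`, `singular`.
#' @export
fisher_information <- function(S, weights, theta = attr(S, "theta")) {
  if (nrow(S) != length(weights)) stop("weights must match the number of observations", call. = FALSE)
  if (is.null(theta)) stop("parameter values 'theta' are required for relative errors", call. = FALSE)
  bad <- apply(S, 2, function(x) any(!is.finite(x)))
  if (any(bad)) stop("non-finite sensitivity columns: ", paste(colnames(S)[bad], collapse = ", "), call. = FALSE)
  Sw <- S * sqrt(weights)
  fim <- crossprod(Sw)
  fim <- (fim + t(fim)) / 2
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  condition <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  singular <- !is.finite(condition) || condition > 1e12
  if (singular) {
    sv <- svd(fim)
    pos <- sv$d > max(sv$d) * 1e-12
    covm <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  } else {
    covm <- solve(fim)
  }
  covm <- (covm + t(covm)) / 2
  se <- sqrt(pmax(diag(covm), 0))
  rel_error <- 100 * se / pmax(abs(theta), 1e-300)
  denom <- outer(se, se)
  corr <- ifelse(denom > 0, covm / denom, 0)
  diag(corr) <- 1
  corr <- pmin(pmax(corr, -1), 1)
  dimnames(corr) <- dimnames(fim)
  structure(list(fim = fim, cov = covm,
                 rel_error_pct = stats::setNames(rel_error, colnames(S)),
                 correlation = corr, eigenvalues = ev,
                 condition = condition, singular = singular,
                 theta = stats::setNames(theta, colnames(S))),
            class = "fim_report")
}

#' @export
print.fim_report <- function(x, ...) {
  cat("Fisher-information report (", length(x$theta), " parameters)\n", sep = "")
  cat("  condition number:", format(x$condition, digits = 4),
      if (x$singular) " [singular / rank-deficient]" else "", "\n")
  tab <- data.frame(parameter = names(x$theta), value = x$theta,
                    rel_error_pct = round(x$rel_error_pct, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Identifiability report at a fit context
#'
#' Composes [local_sensitivities()] and [fisher_information()] on a dataset's
#' observation grid and flags parameters with a relative error above
#' `rel_error_threshold` (default 100%) or involved in a pairwise correlation
#' above `corr_threshold` in magnitude (default 0.95).
#'
#' @inheritParams local_sensitivities
#' @param rel_error_threshold,corr_threshold Flagging thresholds.
#' @return A `fim_report` with additional fields `flagged_error`,
#'   `flagged_correlation` (character vectors of parameter paths).
#' @export
identifiability_report <- function(params, geometry, dataset, paths,
                                   rel_error_threshold = 100,
                                   corr_threshold = 0.95, rel_step = 1e-3) {
  S <- local_sensitivities(params, geometry, dataset, paths, rel_step = rel_step)
  if (length(attr(S, "failed_paths")) > 0) {
    stop("sensitivity computation failed for: ",
         paste(attr(S, "failed_paths"), collapse = ", "), call. = FALSE)
  }
  w <- 1 / effective_sd(dataset)^2
  rep_ <- fisher_information(S, w)
  rep_$flagged_error <- names(rep_$rel_error_pct)[rep_$rel_error_pct > rel_error_threshold]
  offdiag <- rep_$correlation
  diag(offdiag) <- 0
  rep_$flagged_correlation <- colnames(offdiag)[apply(abs(offdiag), 2, max) > corr_threshold]
  rep_$thresholds <- c(rel_error = rel_error_threshold, corr = corr_threshold)
  rep_
}

# transport parameter paths of the not-yet-lumped sides of a full block
.full_transport_paths <- function(params) {
  tr <- params$transport
  if (!inherits(tr, "transport_full")) return(character())
  paths <- character()
  for (j in .compounds) {
    if (!tr$lumped_im[j]) {
      paths <- c(paths, if (j == "AS") {
        c("transport.rmax_1b1", "transport.rmax_2b1")
      } else {
        paste0("transport.k_im.", j)
      }, paste0("transport.P.", j))
    }
    if (!tr$lumped_ex[j]) {
      paths <- c(paths, if (j == "AS") "transport.rmax_ex" else paste0("transport.k_ex.", j),
                 paste0("transport.P.", j))
    }
  }
  unique(paths)
}

# low-concentration import/export clearance equivalents (ml/min)
.import_clearance <- function(tr, j) {
  if (j == "AS") tr$rmax_1b1 / tr$km_1b1 + tr$rmax_2b1 / tr$km_2b1 else tr$k_im[[j]]
}
.export_clearance <- function(tr, j) {
  if (j == "AS") tr$rmax_ex / tr$km_ex else tr$k_ex[[j]]
}

#' Iterative transport-lumping model reduction
#'
#' Starting from the full variant, repeatedly computes an identifiability
#' report over the remaining non-lumped transport parameters and lumps the
#' flagged side (active import or export plus that side's share of passive
#' diffusion) of one compound per iteration into a single apparent clearance:
#' kappa_im_j = CL_im_j + P_j and kappa_ex_j = CL_ex_j + P_j, where the
#' active Michaelis-Menten steps of AS enter through their low-concentration
#' clearance rmax/K_M. Parameters whose sensitivity column is essentially
#' zero (below `sens_frac` of the largest column norm) are also grounds for
#' lumping their side. The loop terminates when nothing is flagged or when
#' the model is fully lumped, in which case the transport block is converted
#' to the reduced variant.
#'
#' @inheritParams identifiability_report
#' @param thresholds List with `rel_error` (%), `corr`, `sens_frac`.
#' @param refit Optional function `params -> params` applied after every
#'   lumping action (e.g. a short re-estimation of the remaining free
#'   parameters); whether a refit ran is recorded in the trace.
#' @return List with `params` (possibly reduced), `trace` (data.frame of
#'   actions with triggering diagnostic and post-action free-parameter
#'   count) and `reports` (the per-iteration `fim_report`s).
#' @export
reduce_model <- function(params, geometry, dataset,
                         thresholds = list(rel_error = 100, corr = 0.95,
                                           sens_frac = 1e-8),
                         refit = NULL) {
  trace <- data.frame(iteration = integer(), compound = character(),
                      side = character(), diagnostic = character(),
                      kappa_ul_min = numeric(), refit = logical(),
                      free_params_after = integer(), stringsAsFactors = FALSE)
  reports <- list()
  if (!inherits(params$transport, "transport_full")) {
    return(list(params = params, trace = trace, reports = reports))
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    paths <- .full_transport_paths(params)
    if (length(paths) == 0) break
    S <- local_sensitivities(params, geometry, dataset, paths)
    w <- 1 / effective_sd(dataset)^2
    rep_ <- fisher_information(S, w)
    norms <- sqrt(colSums((S * sqrt(w))^2))
    low_sens <- names(norms)[norms < thresholds$sens_frac * max(norms)]
    offdiag <- rep_$correlation; diag(offdiag) <- 0
    high_corr <- colnames(offdiag)[apply(abs(offdiag), 2, max) > thresholds$corr]
    high_err <- names(rep_$rel_error_pct)[rep_$rel_error_pct > thresholds$rel_error]
    flagged <- unique(c(low_sens, high_corr, high_err))
    reports[[iter]] <- rep_
    if (length(flagged) == 0) break

    # translate the first flagged path into a compound/side action
    path <- flagged[[1]]
    diagn <- if (path %in% low_sens) "low sensitivity" else if (path %in% high_corr) "high correlation" else "high rel. error"
    tr <- params$transport
    if (grepl("rmax_ex|k_ex", path)) {
      j <- if (path == "transport.rmax_ex") "AS" else sub("transport.k_ex.", "", path, fixed = TRUE)
      side <- "export"
    } else if (grepl("rmax_1b1|rmax_2b1|k_im", path)) {
      j <- if (grepl("rmax_[12]b1", path)) "AS" else sub("transport.k_im.", "", path, fixed = TRUE)
      side <- "import"
    } else { # a P_j: lump its import side first, then export
      j <- sub("transport.P.", "", path, fixed = TRUE)
      side <- if (!tr$lumped_im[j]) "import" else "export"
    }
    if (side == "import") {
      tr$kappa_im[j] <- .import_clearance(tr, j) + tr$P[[j]]
      tr$lumped_im[j] <- TRUE
    } else {
      tr$kappa_ex[j] <- .export_clearance(tr, j) + tr$P[[j]]
      tr$lumped_ex[j] <- TRUE
    }
    params$transport <- tr
    if (!is.null(refit)) params <- refit(params)
    trace <- rbind(trace, data.frame(
      iteration = iter, compound = j, side = side, diagnostic = diagn,
      kappa_ul_min = 1000 * (if (side == "import") tr$kappa_im[[j]] else tr$kappa_ex[[j]]),
      refit = !is.null(refit),
      free_params_after = length(.full_transport_paths(params)),
      stringsAsFactors = FALSE))
    if (iter > 24) break # bounded by parameter count: 12 sides at most
  }
  tr <- params$transport
  if (inherits(tr, "transport_full") && all(tr$lumped_im) && all(tr$lumped_ex)) {
    params$transport <- transport_reduced(kappa_im_ul = tr$kappa_im * 1000,
                                          kappa_ex_ul = tr$kappa_ex * 1000)
    params$variant <- "reduced"
  }
  list(params = params, trace = trace, reports = reports)
}
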