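# Single-individual and simultaneous multi-individual fits.

#' Fit free parameters to one individual's time-series data
#'
#' Minimizes the penalized weighted least-squares criterion with the
#' evolutionary strategy, multi-started over `n_starts` consecutive seeds
#' (the ES is stochastic), optionally followed by a Nelder-Mead polish of the
#' best run. Literature-fixed constants stay at their values in
#' `base_params`; rows of `specs` with `status = "fixed"` are applied to the
#' template before fitting.
#'
#' @param dataset Time-series dataset of one individual (validated).
#' @param geometry An [experiment_geometry()].
#' @param base_params Template `kinetic_parameter_set` holding fixed values.
#' @param specs A [parameter_spec()] addressing model parameters by path.
#' @param constraints Inequality pairs (see [default_constraints()]).
#' @param seed First seed of the multi-start.
#' @param n_starts Number of ES starts.
#' @param budget Objective-evaluation budget per start.
#' @param polish Run the local polish on the best start.
#' @param mu,lambda ES population sizes.
#' @param init Optional named start vector (natural scale) seeding the first
#'   start's population.
#' @return A `fit_result` with fields `par`, `value` (J* re-evaluated at
#'   `par`), `evals`, `seed`, `trace`, `params` (the fitted parameter set),
#'   `constraints` (violation report) and `starts` (per-start summary).
#' @export
fit_single <- function(dataset, geometry, base_params, specs,
                       constraints = default_constraints(base_params$variant),
                       seed = 1, n_starts = 3, budget = 2000, polish = TRUE,
                       mu = 8, lambda = 4, init = NULL) {
  validate_timeseries(dataset)
  if (length(unique(dataset$time_min)) < 2) stop("dataset must cover at least 2 time points", call. = FALSE)
  fixed <- specs[specs$status == "fixed", , drop = FALSE]
  if (nrow(fixed) > 0) {
    base_params <- param_set(base_params, stats::setNames(fixed$value, fixed$name))
  }
  s_eff <- effective_sd(dataset)
  fn <- function(theta) {
    p <- param_set(base_params, theta)
    penalized_objective(p, geometry, dataset, constraints, s_eff = s_eff)
  }
  runs <- lapply(seq_len(n_starts) - 1L, function(k) {
    es_optimize(fn, specs, mu = mu, lambda = lambda, seed = seed + k,
                budget = budget, init = if (k == 0) init else NULL)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  if (polish) best <- polish_fit(fn, specs, best)
  best$value <- fn(best$par) # invariant: reported J* equals re-evaluation
  best$params <- param_set(base_params, best$par)
  best$constraints <- constraint_report(best$params, constraints)
  best$starts <- data.frame(seed = seed + seq_len(n_starts) - 1L,
                            value = vapply(runs, `[[`, numeric(1), "value"))
  best
}

#' Simultaneous fit across individuals with relative-abundance-fixed rates
#'
#' The reference individual's maximal CYP3A4/UGT1A3 rates are taken from
#' `reference_rmax_values` (or freed via `fit_reference_rmax`); every other
#' individual's maximal rates are tied to them by the relative-abundance
#' scaling through the measured protein concentrations, and are therefore not
#' free parameters. Per-individual transport clearances, PON hydrolysis rate
#' constants and (optionally) fractions unbound are free. With
#' `adjust_proteins = TRUE` the per-individual enzyme concentrations
#' themselves become bounded free parameters within mean +/- sd (the UGT1A3
#' sd is taken as 30% of the mean); with entries in `betaox_individuals` a
#' first-order beta-oxidation sink on the acids is enabled and estimated for
#' those individuals.
#'
#' Free parameters are addressed as `"<individual>:<path>"`, protein levels
#' as `"protein:<individual>:cyp3a4"` / `":ugt1a3"`, reference rates as
#' `"ref:<channel>"` and `"ref:UGT1A3"`.
#'
#' @param datasets Named list of per-individual datasets; names are
#'   individual ids matching `protein_table$individual`.
#' @param protein_table data.frame: `individual`, `cyp3a4`, `cyp3a4_sd`,
#'   `ugt1a3` (relative), as from [generate_protein_table()].
#' @param geometry Shared [experiment_geometry()] (or named list).
#' @param base_params Template parameter set (or named list per individual).
#' @param reference Individual id of the reference donor.
#' @param free_paths Dotted paths freed per individual (default: lumped
#'   import/export clearances and PON rate constants).
#' @param reference_rmax_values Named vector: four CYP channels + `UGT1A3`
#'   (defaults to [reference_rmax()]).
#' @param fit_reference_rmax Free the reference rates instead of fixing them.
#' @param adjust_proteins Free per-individual enzyme concentrations in
#'   mean +/- sd.
#' @param betaox_individuals Ids for which the beta-oxidation sink is enabled.
#' @param constraints Inequality pairs applied to every individual's set.
#' @inheritParams fit_single
#' @return A `fit_result`; `params` is a named list of fitted per-individual
#'   parameter sets.
#' @export
fit_simultaneous <- function(datasets, protein_table, geometry, base_params,
                             reference = names(datasets)[1],
                             free_paths = c(.kappa_paths(), "hyd.k_pon_asl", "hyd.k_pon_asloh"),
                             reference_rmax_values = reference_rmax(),
                             fit_reference_rmax = FALSE,
                             adjust_proteins = FALSE,
                             betaox_individuals = character(),
                             constraints = default_constraints("reduced"),
                             seed = 1, n_starts = 3, budget = 3000,
                             polish = TRUE, mu = 8, lambda = 4) {
  ids <- names(datasets)
  if (length(ids) < 2) stop("simultaneous fit needs at least two individuals", call. = FALSE)
  if (!reference %in% ids) stop("reference individual not among datasets", call. = FALSE)
  missing_ids <- setdiff(ids, as.character(protein_table$individual))
  if (length(missing_ids) > 0) {
    stop("protein table lacks individuals: ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  lapply(datasets, validate_timeseries)
  if (!is.list(geometry) || inherits(geometry, "experiment_geometry")) {
    geometry <- stats::setNames(rep(list(geometry), length(ids)), ids)
  }
  if (inherits(base_params, "kinetic_parameter_set")) {
    base_params <- stats::setNames(rep(list(base_params), length(ids)), ids)
  }
  for (id in betaox_individuals) {
    base_params[[id]]$variant <- "reduced_betaox"
  }
  pt <- protein_table[match(ids, as.character(protein_table$individual)), ]
  rownames(pt) <- ids
  s_eff <- lapply(datasets, effective_sd)

  # specification table
  specs <- do.call(rbind, lapply(ids, function(id) {
    sp <- default_bounds(free_paths)
    sp$name <- paste0(id, ":", sp$name)
    sp
  }))
  if (fit_reference_rmax) {
    specs <- rbind(specs, parameter_spec(paste0("ref:", names(reference_rmax_values)),
                                         1, 1e5, scale = "log"))
  }
  if (adjust_proteins) {
    for (id in ids) {
      cm <- pt[id, "cyp3a4"]; cs <- pt[id, "cyp3a4_sd"]
      um <- pt[id, "ugt1a3"]; us <- 0.3 * um
      specs <- rbind(specs,
        parameter_spec(paste0("protein:", id, ":cyp3a4"), max(cm - cs, 1e-6), cm + cs, scale = "linear"),
        parameter_spec(paste0("protein:", id, ":ugt1a3"), max(um - us, 1e-9), um + us, scale = "linear"))
    }
  }
  for (id in betaox_individuals) {
    sp <- default_bounds(c("betaox.k_as", "betaox.k_asoh"))
    sp$name <- paste0(id, ":", sp$name)
    specs <- rbind(specs, sp)
  }

  assemble <- function(theta) {
    ref_r <- reference_rmax_values
    if (fit_reference_rmax) {
      for (nm in names(ref_r)) ref_r[nm] <- theta[[paste0("ref:", nm)]]
    }
    prot <- function(id, enzyme) {
      key <- paste0("protein:", id, ":", enzyme)
      if (key %in% names(theta)) theta[[key]] else pt[id, if (enzyme == "cyp3a4") "cyp3a4" else "ugt1a3"]
    }
    out <- list()
    for (id in ids) {
      p <- base_params[[id]]
      own <- theta[startsWith(names(theta), paste0(id, ":"))]
      if (length(own) > 0) {
        names(own) <- sub(paste0("^", id, ":"), "", names(own))
        p <- param_set(p, own)
      }
      cyp_ratio <- prot(id, "cyp3a4") / prot(reference, "cyp3a4")
      ugt_ratio <- prot(id, "ugt1a3") / prot(reference, "ugt1a3")
      p$cyp$rmax[.cyp_channels] <- scale_rmax(ref_r[.cyp_channels], 1, cyp_ratio)
      p$ugt$rmax <- scale_rmax(ref_r[["UGT1A3"]], 1, ugt_ratio)
      out[[id]] <- p
    }
    out
  }

  fn <- function(theta) {
    ps <- assemble(theta)
    J <- 0
    for (id in ids) {
      J <- J + objective(ps[[id]], geometry[[id]], datasets[[id]], s_eff = s_eff[[id]])
      J <- J + constraint_penalty(ps[[id]], constraints)
    }
    J
  }

  runs <- lapply(seq_len(n_starts) - 1L, function(k) {
    es_optimize(fn, specs, mu = mu, lambda = lambda, seed = seed + k, budget = budget)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  if (polish) best <- polish_fit(fn, specs, best)
  best$value <- fn(best$par)
  best$params <- assemble(best$par)
  best$constraints <- lapply(best$params, constraint_report, constraints = constraints)
  best$starts <- data.frame(seed = seed + seq_len(n_starts) - 1L,
                            value = vapply(runs, `[[`, numeric(1), "value"))
  best
}
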