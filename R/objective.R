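# Weighted least-squares criterion and inequality constraints.

#' Weighted least-squares objective
#'
#' J = sum over metabolites and time points of
#' ((c_calc - c_meas) / s_eff)^2, with per-point effective standard
#' deviations (see [effective_sd()]). Rows flagged below quantification or
#' with missing means are excluded. A failed simulation yields a large finite
#' penalty (1e12) with a warning rather than an error, so that stochastic
#' optimizers can continue.
#'
#' @param params,geometry Model configuration.
#' @param dataset A validated time-series dataset (single individual).
#' @param s_eff Optional precomputed effective sds (row-aligned).
#' @param rtol,atol Solver tolerances used during fitting.
#' @return Scalar J >= 0.
#' @export
objective <- function(params, geometry, dataset, s_eff = effective_sd(dataset),
                      rtol = 1e-6, atol = 1e-8) {
  keep <- dataset$flag == "ok" & !is.na(dataset$replicate_mean)
  pred <- tryCatch(
    predict_dataset(params, geometry, dataset, rtol = rtol, atol = atol),
    error = function(e) {
      warning("simulation failed during objective evaluation: ", conditionMessage(e),
              call. = FALSE)
      NULL
    }
  )
  if (is.null(pred)) return(1e12)
  sum(((pred[keep] - dataset$replicate_mean[keep]) / s_eff[keep])^2)
}

#' Default inequality constraints of the optimization
#'
#' Ordered pairs `greater > smaller` over dotted parameter paths. The binding
#' constraint (acids less bound than lactones) always applies; the
#' permeability ordering only binds in the full variant where the P
#' parameters exist.
#'
#' @param variant Model variant.
#' @return data.frame with columns `greater`, `smaller`.
#' @export
default_constraints <- function(variant = "reduced") {
  cs <- data.frame(greater = "bind.fu_acid", smaller = "bind.fu_lactone",
                   stringsAsFactors = FALSE)
  if (identical(variant, "full")) {
    cs <- rbind(cs, data.frame(
      greater = c("transport.P.ASL", "transport.P.AS", "transport.P.ASL"),
      smaller = c("transport.P.AS", "transport.P.ASpOH", "transport.P.ASLpOH"),
      stringsAsFactors = FALSE
    ))
  }
  cs
}

#' Constraint violations of a parameter set
#'
#' @param params A `kinetic_parameter_set`.
#' @param constraints data.frame as from [default_constraints()].
#' @return data.frame with one row per constraint: values and relative
#'   violation (0 when satisfied).
#' @export
constraint_report <- function(params, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0) {
    return(data.frame(greater = character(), smaller = character(),
                      violation = numeric()))
  }
  a <- vapply(constraints$greater, function(p) param_get(params, p), numeric(1))
  b <- vapply(constraints$smaller, function(p) param_get(params, p), numeric(1))
  viol <- ifelse(a > b, 0, (b - a) / pmax(abs(b), 1e-12))
  data.frame(greater = constraints$greater, smaller = constraints$smaller,
             violation = viol, stringsAsFactors = FALSE)
}

#' Penalized objective
#'
#' Adds 1e6 (1 + relative violation) per violated inequality to the raw
#' objective; feasible parameter sets are left unchanged, so the feasible
#' optima of penalized and raw objectives coincide.
#'
#' @inheritParams objective
#' @param constraints data.frame of ordered pairs (see [default_constraints()]).
#' @return Scalar J_pen >= J.
#' @export
penalized_objective <- function(params, geometry, dataset, constraints,
                                s_eff = effective_sd(dataset),
                                rtol = 1e-6, atol = 1e-8) {
  J <- objective(params, geometry, dataset, s_eff = s_eff, rtol = rtol, atol = atol)
  J + constraint_penalty(params, constraints)
}

#' @rdname penalized_objective
#' @export
constraint_penalty <- function(params, constraints) {
  rep_ <- constraint_report(params, constraints)
  v <- rep_$violation[rep_$violation > 0]
  if (length(v) == 0) 0 else sum(1e6 * (1 + v))
}
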