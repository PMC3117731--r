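#' Time derivative of the 18-state compartment model
#'
#' Balances each compound over medium (`m`), intracellular free (`c`) and
#' intracellular bound (`b`) pools. Transport moves amount between medium and
#' the free pool; CYP3A4 hydroxylation, UGT1A3 lactonization, chemical and PON
#' hydrolysis, unspecific binding and (optionally) beta-oxidation act on the
#' intracellular pools; chemical hydrolysis also proceeds in the medium.
#'
#' @param t Time (min; the system is autonomous).
#' @param state Named 18-vector (see [state_names()]).
#' @param params A `kinetic_parameter_set`.
#' @param geometry An [experiment_geometry()].
#' @return Named 18-vector d(state)/dt (pmol/ml/min).
#' @export
ode_rhs <- function(t, state, params, geometry) {
  cm <- state[paste0(.compounds, ".m")]
  cc <- state[paste0(.compounds, ".c")]
  cb <- state[paste0(.compounds, ".b")]
  names(cm) <- names(cc) <- names(cb) <- .compounds

  # rates are evaluated on non-negative concentrations; the solver may
  # undershoot zero within tolerance
  cmp <- pmax(cm, 0); ccp <- pmax(cc, 0); cbp <- pmax(cb, 0)

  r_cyp <- cyp3a4_rates(ccp[["AS"]], ccp[["ASL"]], params$cyp)
  r_ugt <- ugt1a3_rate(ccp[["AS"]], params$ugt)
  k_cr <- params$hyd$k_cr
  r_pon <- c(ASL = params$hyd$k_pon_asl * ccp[["ASL"]],
             ASLpOH = params$hyd$k_pon_asloh * ccp[["ASLpOH"]],
             ASLoOH = params$hyd$k_pon_asloh * ccp[["ASLoOH"]])
  fu <- ifelse(.compounds %in% .acids, params$bind$fu_acid, params$bind$fu_lactone)
  r_bind <- params$bind$k_dis * (((1 - fu) / fu) * ccp - cbp)
  names(r_bind) <- .compounds

  flux <- transport_fluxes(stats::setNames(c(rbind(cmp, ccp, cbp)), state_names()), params)

  # net intracellular reaction term per compound (pmol/min/ml intracellular)
  rx <- stats::setNames(numeric(6), .compounds)
  rx["AS"] <- -r_cyp[["ASpOH"]] - r_cyp[["ASoOH"]] - r_ugt +
    k_cr * ccp[["ASL"]] + r_pon[["ASL"]]
  rx["ASL"] <- r_ugt - r_cyp[["ASLpOH"]] - r_cyp[["ASLoOH"]] -
    k_cr * ccp[["ASL"]] - r_pon[["ASL"]]
  rx["ASpOH"] <- r_cyp[["ASpOH"]] + k_cr * ccp[["ASLpOH"]] + r_pon[["ASLpOH"]]
  rx["ASoOH"] <- r_cyp[["ASoOH"]] + k_cr * ccp[["ASLoOH"]] + r_pon[["ASLoOH"]]
  rx["ASLpOH"] <- r_cyp[["ASLpOH"]] - k_cr * ccp[["ASLpOH"]] - r_pon[["ASLpOH"]]
  rx["ASLoOH"] <- r_cyp[["ASLoOH"]] - k_cr * ccp[["ASLoOH"]] - r_pon[["ASLoOH"]]

  bx <- c(AS = params$betaox$k_as, ASpOH = params$betaox$k_asoh,
          ASoOH = params$betaox$k_asoh)
  sink <- stats::setNames(numeric(6), .compounds)
  sink[names(bx)] <- bx * ccp[names(bx)]

  is_lac <- .compounds %in% .lactones
  dcm <- -flux / geometry$V_m - k_cr * cmp * is_lac
  dcm[.lactone_to_acid] <- dcm[.lactone_to_acid] + k_cr * cmp[names(.lactone_to_acid)]
  dcc <- flux / geometry$V_c + rx - r_bind - sink
  dcb <- r_bind

  stats::setNames(c(rbind(dcm, dcc, dcb)), state_names())
}

#' Simulate the compartment model
#'
#' Stiff integration with `deSolve::lsoda` (the binding step with
#' k_dis = 600/min makes the system stiff). Defaults rtol 1e-8, atol 1e-10.
#'
#' @param params A `kinetic_parameter_set`.
#' @param geometry An [experiment_geometry()].
#' @param t_grid Strictly increasing output times (min), starting at the
#'   initial time.
#' @param initial Named 18-vector; default all drug as extracellular AS.
#' @param rtol,atol Solver tolerances.
#' @param compiled Use the compiled C right-hand side (default); the plain R
#'   implementation [ode_rhs()] is retained as a reference and used when
#'   `FALSE`.
#' @return Object of class `simulation_result`: list with `time`, `states`
#'   (matrix time x 18), `geometry`, `params`, `diagnostics`.
#' @export
simulate_model <- function(params, geometry, t_grid = seq(0, 600, by = 5),
                           initial = initial_state(geometry),
                           rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing", call. = FALSE)
  if (length(initial) != 18) stop("initial state must have 18 entries", call. = FALSE)
  initial <- initial[state_names()]
  if (anyNA(initial)) stop("initial state must be named by state_names()", call. = FALSE)
  out <- if (compiled) {
    deSolve::lsoda(
      y = initial, times = t_grid, func = "atorkin_derivs",
      dllname = "atorkin", initfunc = "atorkin_initmod",
      parms = params_to_cvec(params, geometry),
      rtol = rtol, atol = atol, maxsteps = 20000
    )
  } else {
    deSolve::lsoda(
      y = initial, times = t_grid,
      func = function(t, y, p) list(ode_rhs(t, y, params, geometry)),
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 20000
    )
  }
  diagn <- attr(out, "istate")
  if (is.null(diagn) || diagn[1] < 0 || nrow(out) < length(t_grid)) {
    stop("ODE integration failed (istate = ", if (is.null(diagn)) NA else diagn[1],
         ", returned ", nrow(out), "/", length(t_grid), " time points)", call. = FALSE)
  }
  structure(list(time = out[, "time"],
                 states = out[, state_names(), drop = FALSE],
                 geometry = geometry, params = params,
                 diagnostics = list(istate = diagn[1])),
            class = "simulation_result")
}

#' Recovery time course: measured drug equivalents over initial dose
#'
#' Mirrors the experimental material balance: the sum over compounds of
#' extracellular amount plus intracellular free amount (the bound pool is lost
#' in the cell-disruption supernatant and is excluded by default), divided by
#' the initial extracellular AS amount.
#'
#' @param result A [simulate_model()] result.
#' @param include_bound Count the bound pool as measured (closed-system check).
#' @return Numeric vector, one recovery fraction per time point.
#' @export
recovery_timecourse <- function(result, include_bound = FALSE) {
  g <- result$geometry
  a0 <- g$initial_AS_m * g$V_m
  if (a0 <= 0) stop("initial extracellular AS amount must be positive", call. = FALSE)
  s <- result$states
  m_amt <- rowSums(s[, paste0(.compounds, ".m"), drop = FALSE]) * g$V_m
  c_amt <- rowSums(s[, paste0(.compounds, ".c"), drop = FALSE]) * g$V_c
  tot <- m_amt + c_amt
  if (include_bound) {
    tot <- tot + rowSums(s[, paste0(.compounds, ".b"), drop = FALSE]) * g$V_c
  }
  unname(tot / a0)
}

#' Tidy data.frame view of a simulation result
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return data.frame with columns time, compound, compartment, concentration.
#' @export
as.data.frame.simulation_result <- function(x, ...) {
  long <- expand.grid(time = x$time, col = colnames(x$states),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(long$col, ".", fixed = TRUE))
  data.frame(time = long$time, compound = parts[, 1], compartment = parts[, 2],
             concentration = as.vector(x$states), stringsAsFactors = FALSE)
}
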