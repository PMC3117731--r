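# Kinetic rate laws. Enzymatic rates are intrinsic rates per intracellular
# volume (pmol/min/ml); transport fluxes are amount fluxes (pmol/min).

#' CYP3A4 hydroxylation rates with alternative-substrate competition
#'
#' AS and ASL compete for the same enzyme; each of the four product channels
#' draws on one shared competitive denominator:
#' r_P = rmax_P (c_S / K_M_P) / (1 + c_AS/K_M_ASpOH + c_AS/K_M_ASoOH +
#'       c_ASL/K_M_ASLpOH + c_ASL/K_M_ASLoOH).
#' With every competitor concentration at zero but one substrate present the
#' expression reduces to single-substrate Michaelis-Menten kinetics.
#'
#' @param c_as,c_asl Intracellular free concentrations (pmol/ml).
#' @param cyp A [cyp_parameters()] block.
#' @return Named rates (pmol/min/ml) for channels ASpOH, ASoOH, ASLpOH, ASLoOH.
#' @export
cyp3a4_rates <- function(c_as, c_asl, cyp) {
  if (c_as < 0 || c_asl < 0) stop("concentrations must be non-negative", call. = FALSE)
  km <- cyp$km
  den <- 1 + c_as / km["ASpOH"] + c_as / km["ASoOH"] +
    c_asl / km["ASLpOH"] + c_asl / km["ASLoOH"]
  subs <- c(ASpOH = c_as, ASoOH = c_as, ASLpOH = c_asl, ASLoOH = c_asl)
  cyp$rmax * (subs / km) / unname(den)
}

#' UGT1A3 lactonization rate (substrate-inhibition kinetics)
#'
#' r = rmax c / (K_M + c + c^2/K_I); non-monotone with its maximum at
#' c = sqrt(K_M K_I), and reducing to Michaelis-Menten as K_I grows large.
#'
#' @param c_as Intracellular free AS concentration (pmol/ml).
#' @param ugt A [ugt_parameters()] block.
#' @return Rate (pmol/min/ml).
#' @export
ugt1a3_rate <- function(c_as, ugt) {
  if (c_as < 0) stop("concentration must be non-negative", call. = FALSE)
  ugt$rmax * c_as / (ugt$km + c_as + c_as^2 / ugt$ki)
}

#' First-order lactone hydrolysis rate
#'
#' @param c_lactone Lactone concentration (pmol/ml).
#' @param k Rate constant (1/min); chemical hydrolysis applies in both
#'   compartments, PON hydrolysis intracellularly only.
#' @return Rate (pmol/min/ml).
#' @export
hydrolysis_rate <- function(c_lactone, k) {
  if (any(c_lactone < 0) || any(k < 0)) stop("concentration and rate constant must be non-negative", call. = FALSE)
  k * c_lactone
}

#' Net unspecific binding rate (free to bound)
#'
#' The on-rate constant is tied to the dissociation constant through the
#' fraction unbound, k_on = k_dis (1-fu)/fu, so that at equilibrium
#' c_free/(c_free + c_bound) = fu and the net rate vanishes:
#' r = k_dis ( (1-fu)/fu c_free - c_bound ).
#'
#' @param c_free,c_bound Intracellular concentrations (pmol/ml).
#' @param bind A [binding_parameters()] block.
#' @param compound_class `"acid"` or `"lactone"` (selects the fraction unbound).
#' @return Net rate (pmol/min/ml), positive when material binds.
#' @export
binding_net_rate <- function(c_free, c_bound, bind, compound_class = c("acid", "lactone")) {
  compound_class <- match.arg(compound_class)
  if (any(c_free < 0) || any(c_bound < 0)) stop("concentrations must be non-negative", call. = FALSE)
  fu <- if (compound_class == "acid") bind$fu_acid else bind$fu_lactone
  if (fu <= 0 || fu > 1) stop("fraction unbound must lie in (0, 1]", call. = FALSE)
  bind$k_dis * (((1 - fu) / fu) * c_free - c_bound)
}

#' Net medium-to-cell transport amount fluxes
#'
#' Reduced variant: flux_j = kappa_im_j c_j^m - kappa_ex_j c_j^c. Full
#' variant: AS is imported by two Michaelis-Menten uptake steps and exported
#' by a Michaelis-Menten efflux step, the other compounds by first-order
#' clearances; all compounds additionally diffuse passively,
#' P_j (c_j^m - c_j^c). During model reduction the full block may carry
#' per-compound lumped sides, in which case the lumped clearance replaces the
#' active term and that side's share of passive diffusion.
#'
#' @param state Named 18-vector of concentrations (see [state_names()]).
#' @param params A `kinetic_parameter_set`.
#' @return Named vector (pmol/min) per compound, positive into the cell.
#' @export
transport_fluxes <- function(state, params) {
  cm <- state[paste0(.compounds, ".m")]
  cc <- state[paste0(.compounds, ".c")]
  names(cm) <- names(cc) <- .compounds
  tr <- params$transport
  if (inherits(tr, "transport_reduced")) {
    return(tr$kappa_im * cm - tr$kappa_ex * cc)
  }
  if (!inherits(tr, "transport_full")) stop("transport block does not match any model variant", call. = FALSE)
  flux <- stats::setNames(numeric(6), .compounds)
  for (j in .compounds) {
    imp <- if (tr$lumped_im[j]) {
      tr$kappa_im[j] * cm[j]
    } else if (j == "AS") {
      tr$rmax_1b1 * cm[j] / (tr$km_1b1 + cm[j]) +
        tr$rmax_2b1 * cm[j] / (tr$km_2b1 + cm[j]) + tr$P[j] * cm[j]
    } else {
      tr$k_im[j] * cm[j] + tr$P[j] * cm[j]
    }
    exp_ <- if (tr$lumped_ex[j]) {
      tr$kappa_ex[j] * cc[j]
    } else if (j == "AS") {
      tr$rmax_ex * cc[j] / (tr$km_ex + cc[j]) + tr$P[j] * cc[j]
    } else {
      tr$k_ex[j] * cc[j] + tr$P[j] * cc[j]
    }
    flux[j] <- imp - exp_
  }
  flux
}
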