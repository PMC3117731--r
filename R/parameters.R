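# Parameter containers for the kinetic model.
#
# Unit canon: time min, amount pmol, concentration pmol/ml, volume ml.
# Enzymatic r_max and K_M are per intracellular volume (pmol/min/ml and
# pmol/ml, as printed in the parameter tables); transport parameters are
# clearances (ml/min internally; the lumped kappa values are accepted in
# uL/min, the unit of the printed tables, and converted on construction).

#' CYP3A4 hydroxylation parameters
#'
#' Four product channels (ASpOH, ASoOH from AS; ASLpOH, ASLoOH from ASL) share
#' one competitive denominator; see [cyp3a4_rates()].
#'
#' @param rmax Named vector of maximal rates (pmol/min/ml intracellular) for
#'   channels `ASpOH`, `ASoOH`, `ASLpOH`, `ASLoOH`.
#' @param km Named vector of Michaelis constants (pmol/ml), same channels.
#' @export
cyp_parameters <- function(rmax, km) {
  rmax <- rmax[.cyp_channels]; km <- km[.cyp_channels]
  if (anyNA(rmax) || anyNA(km)) stop("CYP parameters must cover channels ",
                                     paste(.cyp_channels, collapse = ", "), call. = FALSE)
  if (any(rmax <= 0) || any(km <= 0)) stop("CYP parameters must be strictly positive", call. = FALSE)
  structure(list(rmax = rmax, km = km), class = "cyp_parameters")
}

#' UGT1A3 lactonization parameters (substrate-inhibition kinetics)
#' @param rmax Maximal rate (pmol/min/ml intracellular).
#' @param km Michaelis constant (pmol/ml).
#' @param ki Substrate-inhibition constant (pmol/ml).
#' @export
ugt_parameters <- function(rmax, km, ki) {
  if (any(c(rmax, km, ki) <= 0)) stop("UGT parameters must be strictly positive", call. = FALSE)
  structure(list(rmax = rmax, km = km, ki = ki), class = "ugt_parameters")
}

#' Lactone hydrolysis rate constants
#' @param k_cr Chemical hydrolysis (1/min), all three lactones, both compartments.
#' @param k_pon_asl PON-mediated hydrolysis of ASL (1/min), intracellular only.
#' @param k_pon_asloh PON-mediated hydrolysis shared by ASLpOH and ASLoOH (1/min).
#' @export
hydrolysis_parameters <- function(k_cr = 0.0025, k_pon_asl = 0, k_pon_asloh = 0) {
  if (any(c(k_cr, k_pon_asl, k_pon_asloh) < 0)) stop("hydrolysis rate constants must be non-negative", call. = FALSE)
  structure(list(k_cr = k_cr, k_pon_asl = k_pon_asl, k_pon_asloh = k_pon_asloh),
            class = "hydrolysis_parameters")
}

#' Unspecific intracellular binding parameters
#'
#' One fraction unbound per compound class (all acids share `fu_acid`, all
#' lactones `fu_lactone`); `k_dis` is the dissociation rate constant.
#'
#' @param k_dis Dissociation rate constant (1/min).
#' @param fu_acid,fu_lactone Fractions unbound in (0, 1].
#' @export
binding_parameters <- function(k_dis = 600, fu_acid = 0.2, fu_lactone = 0.05) {
  if (k_dis < 0) stop("k_dis must be non-negative", call. = FALSE)
  if (fu_acid <= 0 || fu_acid > 1 || fu_lactone <= 0 || fu_lactone > 1) {
    stop("fractions unbound must lie in (0, 1]", call. = FALSE)
  }
  structure(list(k_dis = k_dis, fu_acid = fu_acid, fu_lactone = fu_lactone),
            class = "binding_parameters")
}

#' Lumped (reduced-variant) transport clearances
#'
#' One apparent import and one export clearance per compound, the sum of
#' active transport and passive diffusion. Values are given in uL/min (the
#' unit of the printed parameter tables) and stored internally in ml/min.
#'
#' @param kappa_im_ul,kappa_ex_ul Named vectors (uL/min) over all six compounds.
#' @export
transport_reduced <- function(kappa_im_ul, kappa_ex_ul) {
  kappa_im_ul <- kappa_im_ul[.compounds]; kappa_ex_ul <- kappa_ex_ul[.compounds]
  if (anyNA(kappa_im_ul) || anyNA(kappa_ex_ul)) {
    stop("lumped transport needs kappa_im and kappa_ex for all six compounds", call. = FALSE)
  }
  if (any(kappa_im_ul < 0) || any(kappa_ex_ul < 0)) stop("clearances must be non-negative", call. = FALSE)
  structure(list(kappa_im = kappa_im_ul / 1000, kappa_ex = kappa_ex_ul / 1000),
            class = "transport_reduced")
}

#' Full-variant transport parameters
#'
#' AS is imported by OATP1B1 and OATP2B1 (Michaelis-Menten, maximal amount
#' fluxes in pmol/min) and exported by a Michaelis-Menten efflux step; the
#' other five compounds have first-order import/export clearances (ml/min).
#' Every compound additionally crosses the membrane by passive diffusion with
#' permeability-area product `P` (ml/min).
#'
#' @param rmax_1b1,km_1b1 OATP1B1 import of AS (pmol/min; pmol/ml).
#' @param rmax_2b1,km_2b1 OATP2B1 import of AS.
#' @param rmax_ex,km_ex Active MM export of AS.
#' @param k_im,k_ex Named clearances (ml/min) for the five non-AS compounds.
#' @param P Named permeability-area products (ml/min) for all six compounds.
#' @export
transport_full <- function(rmax_1b1, km_1b1 = 18900, rmax_2b1, km_2b1 = 200,
                           rmax_ex, km_ex, k_im, k_ex, P) {
  non_as <- setdiff(.compounds, "AS")
  k_im <- k_im[non_as]; k_ex <- k_ex[non_as]; P <- P[.compounds]
  if (anyNA(k_im) || anyNA(k_ex) || anyNA(P)) {
    stop("full transport needs k_im/k_ex for non-AS compounds and P for all compounds", call. = FALSE)
  }
  vals <- c(rmax_1b1, km_1b1, rmax_2b1, km_2b1, rmax_ex, km_ex, k_im, k_ex, P)
  if (any(vals < 0)) stop("transport parameters must be non-negative", call. = FALSE)
  structure(list(rmax_1b1 = rmax_1b1, km_1b1 = km_1b1,
                 rmax_2b1 = rmax_2b1, km_2b1 = km_2b1,
                 rmax_ex = rmax_ex, km_ex = km_ex,
                 k_im = k_im, k_ex = k_ex, P = P,
                 lumped_im = stats::setNames(rep(FALSE, 6), .compounds),
                 lumped_ex = stats::setNames(rep(FALSE, 6), .compounds),
                 kappa_im = stats::setNames(rep(NA_real_, 6), .compounds),
                 kappa_ex = stats::setNames(rep(NA_real_, 6), .compounds)),
            class = "transport_full")
}

#' Beta-oxidation sink parameters (acid metabolites, intracellular)
#' @param k_as First-order sink on AS (1/min).
#' @param k_asoh Shared sink on ASpOH/ASoOH (1/min).
#' @export
betaox_parameters <- function(k_as = 0, k_asoh = 0) {
  if (k_as < 0 || k_asoh < 0) stop("beta-oxidation rate constants must be non-negative", call. = FALSE)
  structure(list(k_as = k_as, k_asoh = k_asoh), class = "betaox_parameters")
}

#' Assemble a complete kinetic parameter set
#'
#' @param cyp,ugt,hyd,bind,transport,betaox Component parameter blocks.
#' @param variant `"full"`, `"reduced"` or `"reduced_betaox"`.
#' @return Object of class `kinetic_parameter_set`.
#' @export
kinetic_parameter_set <- function(cyp, ugt, hyd, bind, transport,
                                  betaox = betaox_parameters(),
                                  variant = c("reduced", "full", "reduced_betaox")) {
  variant <- match.arg(variant)
  if (variant == "full" && !inherits(transport, "transport_full")) {
    stop("variant 'full' requires a transport_full block", call. = FALSE)
  }
  if (variant != "full" && !inherits(transport, "transport_reduced")) {
    stop("reduced variants require a transport_reduced block", call. = FALSE)
  }
  if (variant != "reduced_betaox" && (betaox$k_as != 0 || betaox$k_asoh != 0)) {
    stop("beta-oxidation sinks require variant 'reduced_betaox'", call. = FALSE)
  }
  structure(list(cyp = cyp, ugt = ugt, hyd = hyd, bind = bind,
                 transport = transport, betaox = betaox, variant = variant),
            class = "kinetic_parameter_set")
}

#' Published kinetic parameter sets for the three hepatocyte donors
#'
#' Returns the reduced-variant parameter set of one of the three individuals
#' of the simultaneous model verification: literature-fixed constants (CYP and
#' transporter K_M, UGT1A3 K_M/K_I, k_CR, k_dis) together with the fitted
#' maximal rates, PON hydrolysis constants and lumped transport clearances.
#' The intracellular fractions unbound were estimated but not published; the
#' package defaults (`fu_acid` 0.2, `fu_lactone` 0.05) reflect the stronger
#' macromolecular binding of the lipophilic lactones and the optimization
#' constraint `fu_acid > fu_lactone`.
#'
#' @param individual 1, 2 or 3.
#' @param fu_acid,fu_lactone Fractions unbound (not published; defaults used).
#' @param betaox Logical; enable the beta-oxidation sink reported for
#'   individual 3 (k = 0.015/min on AS).
#' @return A [kinetic_parameter_set()].
#' @export
default_parameters <- function(individual = 1, fu_acid = 0.2, fu_lactone = 0.05,
                               betaox = FALSE) {
  stopifnot(individual %in% 1:3)
  i <- individual
  rmax <- rbind(
    ASpOH  = c(1108, 660, 606),
    ASoOH  = c(3345, 1991, 1830),
    ASLpOH = c(1228, 731, 672),
    ASLoOH = c(2756, 1640, 1508)
  )
  ugt_rmax <- c(957, 281, 120)
  kpon_asl <- c(308, 99.2, 0) * 1e-3
  kpon_asloh <- c(280, 545, 82.9) * 1e-3
  kim <- rbind(
    AS = c(20.3, 4.42, 3.45), ASL = c(275, 25.8, 82.7),
    ASpOH = c(3.96, 2.01, 2.53), ASoOH = c(0.39, 0.22, 0.00),
    ASLpOH = c(33.7, 7.24, 8.59), ASLoOH = c(26.1, 530, 2.43)
  )
  kex <- rbind(
    AS = c(2.17, 0.16, 0.17), ASL = c(21.8, 2.48, 10.5),
    ASpOH = c(0.80, 1.25, 0.52), ASoOH = c(1.60, 3.62, 0.91),
    ASLpOH = c(1.13, 1.01, 0.59), ASLoOH = c(2.67, 86.3, 0.77)
  )
  bx <- if (betaox && i == 3) betaox_parameters(k_as = 15.0e-3, k_asoh = 0) else betaox_parameters()
  kinetic_parameter_set(
    cyp = cyp_parameters(rmax = rmax[, i],
                         km = c(ASpOH = 25600, ASoOH = 29700, ASLpOH = 1400, ASLoOH = 3900)),
    ugt = ugt_parameters(rmax = ugt_rmax[i], km = 12000, ki = 75000),
    hyd = hydrolysis_parameters(k_cr = 0.0025, k_pon_asl = kpon_asl[i],
                                k_pon_asloh = kpon_asloh[i]),
    bind = binding_parameters(k_dis = 600, fu_acid = fu_acid, fu_lactone = fu_lactone),
    transport = transport_reduced(kappa_im_ul = kim[, i], kappa_ex_ul = kex[, i]),
    betaox = bx,
    variant = if (betaox && i == 3) "reduced_betaox" else "reduced"
  )
}

#' Reference maximal enzyme rates of individual 1
#'
#' The verified CYP3A4 channel rates and the UGT1A3 rate used as the reference
#' in relative-abundance scaling.
#'
#' @return Named vector (pmol/min/ml): four CYP channels plus `UGT1A3`.
#' @export
reference_rmax <- function() {
  c(ASpOH = 1108, ASoOH = 3345, ASLpOH = 1228, ASLoOH = 2756, UGT1A3 = 956)
}

# ---- flat parameter addressing ------------------------------------------
# Free parameters are addressed by dotted paths, e.g. "cyp.rmax.ASpOH",
# "transport.kappa_im.AS" (uL/min on the user side for kappa), "bind.fu_acid".

.kappa_paths <- function() {
  c(paste0("transport.kappa_im.", .compounds), paste0("transport.kappa_ex.", .compounds))
}

#' Read a parameter value by dotted path
#' @param params A `kinetic_parameter_set`.
#' @param path Dotted path, e.g. `"cyp.rmax.ASpOH"`; lumped clearances
#'   (`transport.kappa_*`) are read and written in uL/min.
#' @export
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- params
  for (p in parts) {
    if (is.null(x[[p]])) stop("unknown parameter path: ", path, call. = FALSE)
    x <- x[[p]]
  }
  if (length(x) != 1 || !is.numeric(x)) stop("path does not resolve to a scalar: ", path, call. = FALSE)
  if (path %in% .kappa_paths() && inherits(params$transport, "transport_reduced")) x <- x * 1000
  unname(x)
}

#' Write parameter values by dotted path
#' @param params A `kinetic_parameter_set`.
#' @param values Named numeric vector; names are dotted paths.
#' @return The updated parameter set.
#' @export
param_set <- function(params, values) {
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    v <- unname(values[[nm]])
    if (nm %in% .kappa_paths() && inherits(params$transport, "transport_reduced")) v <- v / 1000
    if (length(parts) == 2) {
      if (is.null(params[[parts[1]]][[parts[2]]])) stop("unknown parameter path: ", nm, call. = FALSE)
      params[[parts[1]]][[parts[2]]] <- v
    } else if (length(parts) == 3) {
      if (is.null(params[[parts[1]]][[parts[2]]]) ||
          !parts[3] %in% names(params[[parts[1]]][[parts[2]]])) {
        stop("unknown parameter path: ", nm, call. = FALSE)
      }
      params[[parts[1]]][[parts[2]]][[parts[3]]] <- v
    } else {
      stop("unknown parameter path: ", nm, call. = FALSE)
    }
  }
  params
}
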