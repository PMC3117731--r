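# Bridge between the kinetic_parameter_set and the compiled RHS.

#' Flatten a parameter set and geometry to the compiled-RHS parameter vector
#'
#' Layout documented in src/atorkin_rhs.c. Reduced-variant sets are encoded
#' as fully lumped transport; full-variant sets carry per-compound lumping
#' flags used during model reduction.
#'
#' @param params A `kinetic_parameter_set`.
#' @param geometry An [experiment_geometry()].
#' @return Numeric vector of length 68.
#' @keywords internal
params_to_cvec <- function(params, geometry) {
  v <- numeric(68)
  v[1:4] <- params$cyp$rmax[.cyp_channels]
  v[5:8] <- params$cyp$km[.cyp_channels]
  v[9:11] <- c(params$ugt$rmax, params$ugt$km, params$ugt$ki)
  v[12:14] <- c(params$hyd$k_cr, params$hyd$k_pon_asl, params$hyd$k_pon_asloh)
  v[15:17] <- c(params$bind$k_dis, params$bind$fu_acid, params$bind$fu_lactone)
  v[18:19] <- c(params$betaox$k_as, params$betaox$k_asoh)
  v[20:21] <- c(geometry$V_m, geometry$V_c)
  tr <- params$transport
  if (inherits(tr, "transport_reduced")) {
    v[22] <- 0
    v[57:62] <- tr$kappa_im[.compounds]
    v[63:68] <- tr$kappa_ex[.compounds]
  } else {
    non_as <- setdiff(.compounds, "AS")
    v[22] <- 1
    v[23:28] <- c(tr$rmax_1b1, tr$km_1b1, tr$rmax_2b1, tr$km_2b1, tr$rmax_ex, tr$km_ex)
    v[29:33] <- tr$k_im[non_as]
    v[34:38] <- tr$k_ex[non_as]
    v[39:44] <- tr$P[.compounds]
    v[45:50] <- as.numeric(tr$lumped_im[.compounds])
    v[51:56] <- as.numeric(tr$lumped_ex[.compounds])
    ki <- tr$kappa_im[.compounds]; ke <- tr$kappa_ex[.compounds]
    ki[is.na(ki)] <- 0; ke[is.na(ke)] <- 0
    v[57:62] <- ki
    v[63:68] <- ke
  }
  v
}
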