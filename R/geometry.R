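#' Single-hepatocyte volume from a spherical approximation
#'
#' @param diameter_um Cell diameter in micrometres.
#' @return Volume in picolitres: (pi/6) d^3, with 1 um^3 = 1e-3 pL.
#' @examples
#' cell_volume_pl(30) # 14.1 pL
#' @export
cell_volume_pl <- function(diameter_um) {
  if (!is.numeric(diameter_um) || any(diameter_um <= 0)) {
    stop("cell diameter must be positive", call. = FALSE)
  }
  (pi / 6) * diameter_um^3 * 1e-3
}

#' Experiment geometry of a hepatocyte culture well
#'
#' Defaults describe one 6-well-plate well: 2 ml medium over 1.5e6 attached
#' hepatocytes of 30 um diameter (14.1 pL each), dosed with 10 uM atorvastatin
#' acid (10000 pmol/ml). The total cell surface area uses the same spherical
#' approximation as the cell volume.
#'
#' @param V_m Medium volume (ml).
#' @param n_cells Number of cells.
#' @param cell_diameter_um Cell diameter (um); sets the single-cell volume.
#' @param initial_AS_m Initial extracellular AS concentration (pmol/ml).
#' @return An object of class `experiment_geometry`: list with `V_m`, `n_cells`,
#'   `v_cell_pl`, `V_c` (ml), `A_cells` (cm^2), `initial_AS_m`.
#' @export
experiment_geometry <- function(V_m = 2, n_cells = 1.5e6,
                                cell_diameter_um = 30,
                                initial_AS_m = 10000) {
  stopifnot(V_m > 0, n_cells > 0, cell_diameter_um > 0, initial_AS_m >= 0)
  v_cell_pl <- cell_volume_pl(cell_diameter_um)
  geom <- list(
    V_m = V_m,
    n_cells = n_cells,
    v_cell_pl = v_cell_pl,
    V_c = n_cells * v_cell_pl * 1e-9, # pL -> ml
    A_cells = n_cells * pi * cell_diameter_um^2 * 1e-8, # um^2 -> cm^2
    initial_AS_m = initial_AS_m
  )
  class(geom) <- "experiment_geometry"
  geom
}

#' Default initial state: all drug as extracellular atorvastatin acid
#'
#' @param geometry An [experiment_geometry()].
#' @return Named numeric vector of length 18 (see [state_names()]).
#' @export
initial_state <- function(geometry) {
  x <- stats::setNames(numeric(18), state_names())
  x["AS.m"] <- geometry$initial_AS_m
  x
}
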