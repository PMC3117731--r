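#' Atorvastatin compound table
#'
#' The model tracks six species: atorvastatin acid (AS), atorvastatin lactone
#' (ASL) and their para-/ortho-hydroxy metabolites. Each lactone hydrolyzes to
#' exactly one acid (ASL to AS, ASLpOH to ASpOH, ASLoOH to ASoOH).
#'
#' @return A data.frame with columns `id`, `class` (`"acid"` or `"lactone"`)
#'   and `hydrolyzes_to` (the acid product for lactones, `NA` for acids).
#' @export
compound_table <- function() {
  data.frame(
    id = c("AS", "ASL", "ASpOH", "ASoOH", "ASLpOH", "ASLoOH"),
    class = c("acid", "lactone", "acid", "acid", "lactone", "lactone"),
    hydrolyzes_to = c(NA, "AS", NA, NA, "ASpOH", "ASoOH"),
    stringsAsFactors = FALSE
  )
}

# canonical orderings used throughout the package
.compounds <- c("AS", "ASL", "ASpOH", "ASoOH", "ASLpOH", "ASLoOH")
.acids <- c("AS", "ASpOH", "ASoOH")
.lactones <- c("ASL", "ASLpOH", "ASLoOH")
.lactone_to_acid <- c(ASL = "AS", ASLpOH = "ASpOH", ASLoOH = "ASoOH")
.cyp_channels <- c("ASpOH", "ASoOH", "ASLpOH", "ASLoOH")
.cyp_substrate <- c(ASpOH = "AS", ASoOH = "AS", ASLpOH = "ASL", ASLoOH = "ASL")
.compartments <- c("m", "c", "b")

#' Names of the 18 model state variables
#'
#' One entry per compound and compartment: `m` medium, `c` intracellular free,
#' `b` intracellular bound, named `"<compound>.<compartment>"` in compound-major
#' order.
#'
#' @return Character vector of length 18.
#' @export
state_names <- function() {
  as.vector(t(outer(.compounds, .compartments, paste, sep = ".")))
}
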