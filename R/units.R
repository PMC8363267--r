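# molecules per nM per um^3: 1e-9 mol/L * N_A * 1e-15 L/um^3
.COUNTS_PER_NM_UM3 <- 1e-9 * 6.02214076e23 * 1e-15

#' Convert a concentration to a molecule count
#'
#' Bridges the deterministic (nM) and stochastic (molecule-count)
#' descriptions of the model for a well-mixed compartment.
#'
#' @param conc_nM concentration in nanomolar (non-negative).
#' @param volume_um3 compartment volume in cubic micrometres (non-negative).
#' @return integer molecule count, `round(conc * N_A * V)` in consistent units.
#' @examples
#' concentration_to_count(50, 4)  # ~120 molecules in a 4 um^3 compartment
#' @export
concentration_to_count <- function(conc_nM, volume_um3) {
  if (any(conc_nM < 0) || any(volume_um3 < 0))
    stop("concentration and volume must be non-negative")
  as.integer(round(conc_nM * .COUNTS_PER_NM_UM3 * volume_um3))
}

#' Convert a molecule count to a concentration
#'
#' @param count molecule count (non-negative).
#' @param volume_um3 compartment volume in cubic micrometres (positive).
#' @return concentration in nM.
#' @export
count_to_concentration <- function(count, volume_um3) {
  if (any(count < 0)) stop("count must be non-negative")
  if (any(volume_um3 <= 0)) stop("volume must be positive")
  count / (.COUNTS_PER_NM_UM3 * volume_um3)
}

# counts per nM for a given volume (internal)
.omega <- function(volume_um3) .COUNTS_PER_NM_UM3 * volume_um3
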