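#' Unit system and physical constants
#'
#' All internal computations use \{energy: kBT, length: nm\}. The thermal
#' energy is fixed at \eqn{k_B T = 4.14\times10^{-21}} J (body-temperature
#' convention common in membrane mechanics), so that 1 mN/m = 10^-21 J/nm^2
#' corresponds to 1/4.14 kBT/nm^2 and 1 kBT/nm = 4.14 pN.
#'
#' @name poredge-units
NULL

#' Thermal energy in joules used for all unit bridges (4.14e-21 J).
#' @export
kBT_joules <- 4.14e-21

#' Convert a surface or lateral tension from mN/m to kBT/nm^2
#'
#' 1 mN/m = 1e-3 J/m^2 = 1e-21 J/nm^2.
#'
#' @param value tension in mN/m (finite numeric).
#' @return tension in kBT/nm^2.
#' @seealso [tension_to_mN_per_m()] for the inverse.
#' @examples
#' tension_to_internal(36) # ~8.6957
#' @export
tension_to_internal <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value) | is.na(value)))
  value * 1e-21 / kBT_joules
}

#' Convert a tension from kBT/nm^2 back to mN/m
#' @param value tension in kBT/nm^2.
#' @return tension in mN/m.
#' @export
tension_to_mN_per_m <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value) | is.na(value)))
  value * kBT_joules / 1e-21
}

#' Convert a line tension from kBT/nm to piconewtons
#'
#' 1 pN = 1e-21 J/nm, so 1 kBT/nm = 4.14 pN.
#'
#' @param value line tension in kBT/nm.
#' @return line tension in pN.
#' @export
line_tension_to_pN <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value) | is.na(value)))
  value * kBT_joules / 1e-21
}

#' Convert a line tension from pN to kBT/nm
#' @param value line tension in pN.
#' @return line tension in kBT/nm.
#' @export
line_tension_from_pN <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value) | is.na(value)))
  value * 1e-21 / kBT_joules
}
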