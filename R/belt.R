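# Water-filled cylindrical hydrophobic belt (Marcelja-type integrated energy).

#' Energy of the cylindrical hydrophobic belt
#'
#' Mean-field water-ordering result for a water-filled cylinder of radius r
#' whose side wall (area 4 pi r L) exposes lipid tails:
#' `W_h = 4 pi r L sigma_h I1(r/xi_h) / I0(r/xi_h)`,
#' with I0, I1 modified Bessel functions of the first kind. The Bessel ratio
#' is evaluated with exponentially scaled functions so large r/xi_h does not
#' overflow; the ratio tends to 1 there (flat-wall limit `4 pi r L sigma_h`)
#' and to r/(2 xi_h) as r tends to 0.
#'
#' @param r belt radius, nm (>= 0).
#' @param L belt half-height, nm (>= 0); the belt height is 2L.
#' @param env [environment_parameters()] supplying `sigma_h` and `xi_h`, or
#'   NULL if both are given explicitly.
#' @param sigma_h interfacial tension, kBT/nm^2 (overrides `env`).
#' @param xi_h hydrophobic decay length, nm (overrides `env`).
#' @return energy in kBT (vectorized over `r` and `L`).
#' @export
belt_energy <- function(r, L, env = NULL, sigma_h = env$sigma_h, xi_h = env$xi_h) {
  stopifnot(all(r >= 0), all(L >= 0), sigma_h > 0, xi_h > 0)
  x <- r / xi_h
  ratio <- ifelse(x == 0, 0,
                  besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE))
  4 * pi * r * L * sigma_h * ratio
}
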