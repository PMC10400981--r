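#' Nonadiabatic electron-transfer rate between heme pairs
#'
#' Empirical distance-ruler estimate of the interheme electron-transfer rate
#' for an average-packing protein medium:
#' \deqn{\log_{10} k = 15 - 0.6 R - 3.1 (\Delta G + \lambda)^2 / \lambda}
#' with the edge-to-edge distance R in Angstrom and energies in eV. The
#' `driving_force` argument is the magnitude of the exergonic driving force,
#' i.e. \eqn{\Delta G = -}`driving_force` in the Franck-Condon term. A
#' negative `driving_force` denotes the endergonic (uphill) direction, which
#' is evaluated by detailed balance:
#' \eqn{\log_{10} k_{up} = \log_{10} k_{down} - \Delta G / 0.059}.
#'
#' @param edge_distance Edge-to-edge distance R (Angstrom). Values below the
#'   van der Waals contact floor of 3.6 A are clamped with a warning.
#' @param driving_force Driving force magnitude (eV); negative for the
#'   endergonic direction. Default 0.06.
#' @param lambda Reorganization energy (eV), > 0. Default 0.7.
#'
#' @return List with elements `log10k` and `k` (s^-1).
#' @export
ket <- function(edge_distance, driving_force = 0.06, lambda = 0.7) {
  if (!is.finite(edge_distance) || !is.finite(driving_force) ||
      !is.finite(lambda) || lambda <= 0)
    stop("ket: edge_distance and driving_force must be finite, lambda > 0",
         call. = FALSE)
  if (edge_distance < 3.6) {
    warning(sprintf(
      "ket: edge distance %.2f A below van der Waals contact; clamped to 3.6 A",
      edge_distance))
    edge_distance <- 3.6
  }
  dg_mag <- abs(driving_force)
  log10k <- 15 - 0.6 * edge_distance - 3.1 * (dg_mag - lambda)^2 / lambda
  if (driving_force < 0)
    log10k <- log10k - dg_mag / 0.059
  list(log10k = log10k, k = 10^log10k)
}
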