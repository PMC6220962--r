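#' Atomic-unit conversion constants
#'
#' All internal quantities are in Hartree atomic units: energies in hartree,
#' time in a.u. of time, coordinates either dimensionless
#' (mass-frequency-weighted normal modes) or bohr, masses in electron masses.
#' These constants convert to the units typically used in reports and file
#' headers.
#'
#' @format A named list with elements
#' \describe{
#'   \item{fs}{a.u. of time per femtosecond (41.341373).}
#'   \item{ev}{electron volt per hartree (27.211386).}
#'   \item{angstrom}{angstrom per bohr (0.529177211).}
#'   \item{k_boltzmann}{Boltzmann constant in hartree per kelvin.}
#'   \item{cm1}{hartree per reciprocal centimetre.}
#' }
#' @examples
#' 0.5 * au_units$fs   # a 0.5 fs time step in a.u.
#' @export
au_units <- list(
  fs          = 41.341373,
  ev          = 27.211386,
  angstrom    = 0.529177211,
  k_boltzmann = 3.166811563e-6,
  cm1         = 4.556335e-6
)
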