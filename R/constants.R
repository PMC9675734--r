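# Central unit registry. Everything that converts between instrument units
# (nA, pN, nm, RU, M) and SI lives here so no magic numbers leak into the
# analysis code.

.const <- list(
  kB       = 1.380649e-23,    # J/K
  e        = 1.602176634e-19, # C
  NA_mol   = 6.02214076e23,   # 1/mol
  eps0     = 8.8541878128e-12 # F/m
)

#' Conductance quantum
#'
#' @param unit `"S"` (siemens, default) or `"uS"`.
#' @return G0 = 2e^2/h, reported at the precision conventional in
#'   single-molecule junction work (77.5 uS).
#' @export
#' @examples
#' conductance_quantum("uS")  # 77.5
conductance_quantum <- function(unit = c("S", "uS")) {
  unit <- match.arg(unit)
  g0 <- 77.5e-6
  if (unit == "uS") g0 * 1e6 else g0
}

#' Thermal energy in piconewton-nanometres
#'
#' @param temperature Temperature in kelvin.
#' @return k_B * T in pN nm (4.114 pN nm at 298 K).
#' @export
thermal_energy <- function(temperature = 298) {
  # kB [J/K] * T -> J; 1 J = 1e21 pN nm
  .const$kB * temperature * 1e21
}

#' Debye screening length of a symmetric 1:1 electrolyte
#'
#' @param ionic_strength Ionic strength in mol/L.
#' @param temperature Temperature in kelvin.
#' @param eps_r Relative permittivity of the solvent.
#' @return Debye length in nm (about 1.36 nm at 50 mM, 298 K, water).
#' @export
debye_length <- function(ionic_strength, temperature = 298, eps_r = 78.5) {
  stopifnot(ionic_strength >= 0)
  if (ionic_strength == 0) return(Inf)
  num <- .const$eps0 * eps_r * .const$kB * temperature
  den <- 2 * .const$NA_mol * .const$e^2 * ionic_strength * 1e3  # mol/L -> mol/m^3
  sqrt(num / den) * 1e9
}

#' Bjerrum length
#'
#' Distance at which the Coulomb energy of two unit charges equals k_B T;
#' the natural prefactor when potentials are expressed in kT/e.
#'
#' @inheritParams debye_length
#' @return Bjerrum length in nm (about 0.71 nm in water at 298 K).
#' @export
bjerrum_length <- function(temperature = 298, eps_r = 78.5) {
  .const$e^2 / (4 * pi * .const$eps0 * eps_r * .const$kB * temperature) * 1e9
}
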