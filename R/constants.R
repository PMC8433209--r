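## Physical constants and unit conversions used throughout the package.
## Internal convention for the transport model:
##   volumes      um^3
##   amounts      "litre-moles" n such that n / V[um^3] is mol/L directly
##                (i.e. n = moles * 1e15; the factor cancels everywhere)
##   time         s
##   Lp           um min^-1 atm^-1 at the user surface, um s^-1 atm^-1 inside
##   Ps           um s^-1
##   osmolality   osmol/L (ideal-dilute: osmolar == osmolal, activity 1)

#' Physical constants
#'
#' Boltzmann constant (J/K) and the gas constant in L atm mol^-1 K^-1,
#' the unit in which the osmotic driving force `R T dOsm` comes out in atm
#' when osmolality is expressed in osmol/L.
#' @keywords internal
.const <- list(
  k_B   = 1.380649e-23,   # J/K
  R_atm = 0.0820573661    # L atm mol^-1 K^-1
)

#' Cryoprotectant property registry
#'
#' Per-solute constants for the permeant cryoprotectants used in the
#' perfusion experiments: ethylene glycol (EG) and 1,2-propanediol (PG).
#' `vbar` is the partial molar volume (L/mol) used to convert intracellular
#' solute amount to volume; `r_hydro` the hydrodynamic (van der Waals)
#' radius (m) and `eta` the solution dynamic viscosity (Pa s) entering the
#' Stokes-Einstein diffusivity; `molar_mass` in g/mol.
#'
#' The radii and viscosity are dilute-aqueous literature-typical values,
#' chosen so the Stokes-Einstein diffusivity lands near 1e-9 m^2/s for EG
#' at room temperature; they are declared defaults, not measured here.
#'
#' @param name `"EG"` or `"PG"` (case-insensitive).
#' @return A list of class `cpa_properties` with fields `name`,
#'   `molar_mass`, `vbar`, `r_hydro`, `eta`.
#' @examples
#' cpa_properties("EG")$vbar
#' @export
cpa_properties <- function(name) {
  key <- toupper(name)
  reg <- list(
    EG = list(name = "EG", molar_mass = 62.07, vbar = 0.0558,
              r_hydro = 2.2e-10, eta = 1.0e-3),
    PG = list(name = "PG", molar_mass = 76.09, vbar = 0.0735,
              r_hydro = 2.6e-10, eta = 1.0e-3)
  )
  if (!key %in% names(reg))
    stop("unknown CPA '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  structure(reg[[key]], class = "cpa_properties")
}
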