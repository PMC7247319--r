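# Physical constants (CODATA 2018) and unit helpers.
# SI units throughout: concentrations in mol/L at the interface, converted to
# mol/m^3 where the electrostatics needs them; areas in A^2 at the interface,
# m^2 internally.

.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  F    = 96485.33212,       # Faraday constant, C/mol
  R    = 8.314462618,       # molar gas constant, J/mol/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  Na   = 6.02214076e23      # Avogadro constant, 1/mol
)

# square Angstrom -> square metre
.A2_TO_M2 <- 1e-20
# mol/L -> mol/m^3
.M_TO_MOL_M3 <- 1000

#' Physical constants used by the package
#'
#' Returns the CODATA 2018 values of the elementary charge, Faraday constant,
#' molar gas constant, vacuum permittivity and Avogadro constant used in all
#' electrostatic and thermodynamic calculations.
#'
#' @return Named list with elements `e` (C), `F` (C/mol), `R` (J/mol/K),
#'   `eps0` (F/m) and `Na` (1/mol).
#' @export
#' @examples
#' physical_constants()$F
physical_constants <- function() .const

# thermal voltage RT/F in volts
.thermal_voltage <- function(temperature) {
  .const$R * temperature / .const$F
}
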