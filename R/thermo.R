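# Gas constant in kJ mol^-1 K^-1 (CODATA, PLUMED convention)
.R_GAS <- 0.0083144621
# 1 debye in C m
.DEBYE <- 3.33564e-30
.AVOGADRO <- 6.02214076e23

#' Thermodynamic state
#'
#' Bundles the temperature with the derived thermal energy kT and inverse
#' temperature beta used by every estimator in the package. Units are fixed
#' package-wide: kJ mol^-1 for energies, K for temperature, so
#' kT = R * T with R = 0.0083144621 kJ mol^-1 K^-1.
#'
#' @param temperature Temperature in kelvin. Default 310 K, body temperature,
#'   the condition all default landscapes and pKa values refer to.
#' @return An object of class `thermo_state` with fields `temperature`,
#'   `kT` (kJ mol^-1) and `beta` (mol kJ^-1).
#' @examples
#' th <- thermo_state(310)
#' th$kT          # ~2.577 kJ/mol
#' th$beta * th$kT  # 1
#' @export
thermo_state <- function(temperature = 310) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)")
  }
  kT <- .R_GAS * temperature
  structure(
    list(temperature = temperature, kT = kT, beta = 1 / kT),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, kT = %.6g kJ/mol\n",
              x$temperature, x$kT))
  invisible(x)
}

.as_thermo <- function(thermo) {
  if (inherits(thermo, "thermo_state")) return(thermo)
  if (is.numeric(thermo) && length(thermo) == 1L) return(thermo_state(thermo))
  stop("`thermo` must be a thermo_state or a temperature in kelvin")
}
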