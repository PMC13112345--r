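#' Boltzmann constant in kJ mol^-1 K^-1
#'
#' @keywords internal
#' @export
KB_KJMOL <- 0.0083145

#' kJ per kcal
#' @keywords internal
#' @export
KJ_PER_KCAL <- 4.184

#' Thermodynamic context
#'
#' Bundles the inverse temperature `beta = 1/(kB * T)` (mol/kJ) and the
#' energy equivalent of one pH unit, `ln10_kT = ln(10) * kB * T` (kJ/mol),
#' so that `beta * ln10_kT == log(10)` by construction.
#'
#' @param temperature Temperature in Kelvin (default 300).
#' @return An object of class `thermo` with fields `temperature`, `beta`,
#'   `kT` and `ln10_kT`.
#' @examples
#' th <- thermo(300)
#' th$beta * th$ln10_kT  # log(10)
#' @export
thermo <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  kT <- KB_KJMOL * temperature
  structure(
    list(temperature = temperature,
         beta = 1 / kT,
         kT = kT,
         ln10_kT = log(10) * kT),
    class = "thermo")
}

#' @export
print.thermo <- function(x, ...) {
  cat(sprintf("thermo: T = %g K, kT = %.4f kJ/mol, beta = %.4f mol/kJ\n",
              x$temperature, x$kT, x$beta))
  invisible(x)
}
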