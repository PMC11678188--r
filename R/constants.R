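# Gas constant in the calorie units used throughout (DSC tables are in
# kcal/mol, van't Hoff outputs in cal/mol).
.RGAS_CAL <- 1.987204    # cal mol^-1 K^-1
.RGAS_KCAL <- 1.987204e-3

.KELVIN <- 273.15

#' Convert between Celsius and Kelvin
#'
#' All internal computation uses kelvin; instrument files and the
#' calorimetric literature use degrees Celsius. These helpers perform the
#' fixed-offset conversion (273.15).
#'
#' @param x numeric vector of temperatures.
#' @return numeric vector in the other unit.
#' @examples
#' celsiusToKelvin(41)    # 314.15
#' kelvinToCelsius(314.15)
#' @export
celsiusToKelvin <- function(x) x + .KELVIN

#' @rdname celsiusToKelvin
#' @export
kelvinToCelsius <- function(x) x - .KELVIN
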