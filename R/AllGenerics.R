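#' Accessors for CoexTherm data classes
#'
#' Slot access goes through these generics: `temperature()` (kelvin),
#' `heatCapacity()` (kcal mol^-1 K^-1), `fieldAxis()` / `intensities()`
#' (gauss / arbitrary units), `populations()` (a data.frame with columns
#' temperatureK, pOrdered, pDisordered, residualRms), `specialTemperatures()`
#' and `curvesTable()` for [ThermoCurves-class].
#'
#' @param object a CoexTherm object.
#' @return see details per method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))

#' @rdname accessors
#' @export
setGeneric("heatCapacity", function(object) standardGeneric("heatCapacity"))

#' @rdname accessors
#' @export
setGeneric("fieldAxis", function(object) standardGeneric("fieldAxis"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("specialTemperatures",
           function(object) standardGeneric("specialTemperatures"))

#' @rdname accessors
#' @export
setGeneric("curvesTable", function(object) standardGeneric("curvesTable"))

#' @rdname accessors
#' @export
setMethod("temperature", "Thermogram", function(object) object@temperature)

#' @rdname accessors
#' @export
setMethod("temperature", "EsrSpectrum", function(object) object@temperature)

#' @rdname accessors
#' @export
setMethod("temperature", "PopulationSeries",
          function(object) object@temperature)

#' @rdname accessors
#' @export
setMethod("heatCapacity", "Thermogram", function(object) object@cp)

#' @rdname accessors
#' @export
setMethod("fieldAxis", "EsrSpectrum", function(object) object@field)

#' @rdname accessors
#' @export
setMethod("intensities", "EsrSpectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("populations", "PopulationSeries", function(object) {
  data.frame(temperatureK = object@temperature,
             pOrdered = object@pOrdered,
             pDisordered = object@pDisordered,
             residualRms = object@residualRms)
})

#' @rdname accessors
#' @export
setMethod("specialTemperatures", "ThermoCurves",
          function(object) object@special)

#' @rdname accessors
#' @export
setMethod("curvesTable", "ThermoCurves", function(object) {
  data.frame(temperatureK = object@tGrid, dG = object@dG, dH = object@dH,
             dS = object@dS, dC = object@dC)
})

#' @rdname accessors
#' @param ... unused.
#' @export
setMethod("coef", "VantHoffModel", function(object, ...) object@coeffs)

setMethod("show", "Thermogram", function(object) {
  cat(sprintf("Thermogram: %d points, %.2f-%.2f K (%.2f-%.2f C)\n",
              length(object@temperature), min(object@temperature),
              max(object@temperature),
              kelvinToCelsius(min(object@temperature)),
              kelvinToCelsius(max(object@temperature))))
  if (!is.null(object@metadata$label))
    cat("  label:", object@metadata$label, "\n")
})

setMethod("show", "EsrSpectrum", function(object) {
  cat(sprintf("EsrSpectrum: %d points, %.1f-%.1f G", length(object@field),
              min(object@field), max(object@field)))
  if (!is.na(object@temperature))
    cat(sprintf(", T = %.2f K", object@temperature))
  cat("\n")
})

setMethod("show", "PopulationSeries", function(object) {
  cat(sprintf("PopulationSeries: %d temperatures, %.2f-%.2f K\n",
              length(object@temperature), min(object@temperature),
              max(object@temperature)))
  cat(sprintf("  P(disordered): %.3f-%.3f\n",
              min(object@pDisordered, na.rm = TRUE),
              max(object@pDisordered, na.rm = TRUE)))
})

setMethod("show", "DSCTransitionResult", function(object) {
  cat("DSC transition parameters:\n")
  cat(sprintf("  Tm      = %.2f C\n", object@tmC))
  if (!is.na(object@tpC)) cat(sprintf("  Tp      = %.1f C\n", object@tpC))
  cat(sprintf("  dHcal   = %.2f kcal/mol\n", object@dHcal))
  cat(sprintf("  dTm,1/2 = %s C\n",
              if (is.na(object@dTmHalf)) "NA" else
                sprintf("%.2f", object@dTmHalf)))
  cat(sprintf("  dS(Tm)  = %.1f cal/mol/K\n", object@dSAtTm))
  cat(sprintf("  dHvH    = %.0f kcal/mol\n", object@dHvH))
  cat(sprintf("  CUS     = %.0f molecules\n", object@cus))
})

setMethod("show", "BindingModelResult", function(object) {
  cat("Gel/fluid partitioning fit (", object@modelId, "):\n", sep = "")
  cat(sprintf("  KG = %.3g, KF = %.3g\n", object@kG, object@kF))
  cat(sprintf("  KF/KG = %.2f +/- %.2f%s\n", object@ratio, object@ratioSe,
              if (object@degenerate) "  [degenerate: no depression]" else ""))
})

setMethod("show", "VantHoffModel", function(object) {
  cat(sprintf("VantHoffModel: degree %d, Kp = %g, T range %.2f-%.2f K\n",
              object@degree, object@kp, object@tRange[1], object@tRange[2]))
  cat(sprintf("  ln K = a + b/T + c/T^2 + d/T^3; adj R^2 = %.4f\n",
              object@adjR2))
  print(signif(object@coeffs, 6))
})

setMethod("show", "ThermoCurves", function(object) {
  cat(sprintf("ThermoCurves on %d points, %.2f-%.2f K\n",
              length(object@tGrid), min(object@tGrid), max(object@tGrid)))
  if (nrow(object@special)) {
    cat("  special temperatures:\n")
    for (i in seq_len(nrow(object@special)))
      cat(sprintf("    %s at %.2f K (%.2f C)\n", object@special$kind[i],
                  object@special$tempK[i],
                  kelvinToCelsius(object@special$tempK[i])))
  }
})
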