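#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Thermogram: an excess heat capacity scan
#'
#' Container for a DSC scan: a strictly increasing temperature axis (kelvin,
#' internally) and the excess molar heat capacity in kcal mol^-1 K^-1.
#' Metadata (scan rate, lipid concentration, label, generator ground truth)
#' travels in a free-form list.
#'
#' @slot temperature numeric, kelvin, strictly increasing, >= 50 points.
#' @slot cp numeric, excess heat capacity, kcal mol^-1 K^-1.
#' @slot metadata list.
#' @export
setClass("Thermogram",
  representation(temperature = "numeric", cp = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("Thermogram", function(object) {
  msg <- character()
  if (length(object@temperature) != length(object@cp))
    msg <- c(msg, "temperature and cp must have equal length")
  if (length(object@temperature) < 50)
    msg <- c(msg, "a thermogram needs at least 50 points")
  if (any(diff(object@temperature) <= 0))
    msg <- c(msg, "temperature must be strictly increasing")
  if (anyNA(object@temperature) || anyNA(object@cp))
    msg <- c(msg, "temperature/cp must be finite")
  if (length(msg)) msg else TRUE
})

#' @param temperature,cp,metadata see slots.
#' @rdname Thermogram-class
#' @export
thermogram <- function(temperature, cp, metadata = list()) {
  new("Thermogram", temperature = as.numeric(temperature),
      cp = as.numeric(cp), metadata = metadata)
}

#' EsrSpectrum: a first-derivative nitroxide ESR spectrum
#'
#' One continuous-wave ESR record: magnetic field axis (gauss, strictly
#' increasing) and first-derivative intensity (arbitrary units), tagged with
#' the acquisition temperature (kelvin; NA when unknown).
#'
#' @slot field numeric, gauss, strictly increasing, >= 200 points.
#' @slot intensity numeric, first-derivative amplitude.
#' @slot temperature numeric scalar, kelvin (NA allowed).
#' @slot label character scalar.
#' @export
setClass("EsrSpectrum",
  representation(field = "numeric", intensity = "numeric",
                 temperature = "numeric", label = "character"),
  prototype(temperature = NA_real_, label = ""))

setValidity("EsrSpectrum", function(object) {
  msg <- character()
  if (length(object@field) != length(object@intensity))
    msg <- c(msg, "field and intensity must have equal length")
  if (length(object@field) < 200)
    msg <- c(msg, "a spectrum needs at least 200 points")
  if (any(diff(object@field) <= 0))
    msg <- c(msg, "field must be strictly increasing")
  if (length(object@temperature) != 1)
    msg <- c(msg, "temperature must be a scalar")
  if (length(msg)) msg else TRUE
})

#' @param field,intensity,temperature,label see slots.
#' @rdname EsrSpectrum-class
#' @export
esrSpectrum <- function(field, intensity, temperature = NA_real_, label = "") {
  new("EsrSpectrum", field = as.numeric(field),
      intensity = as.numeric(intensity),
      temperature = as.numeric(temperature)[1], label = label)
}

#' PopulationSeries: ordered/disordered populations versus temperature
#'
#' The bridge between spectral decomposition and thermodynamics: for each
#' temperature, the fractions of the spin probe residing in the ordered
#' (gel-like) and disordered (fluid-like) environment. Fractions in a row
#' sum to one; rows where the decomposition failed carry NA.
#'
#' @slot temperature numeric, kelvin, increasing.
#' @slot pOrdered,pDisordered numeric fractions in [0, 1].
#' @slot residualRms numeric, per-spectrum fit residual (NA when not from a
#'   decomposition).
#' @export
setClass("PopulationSeries",
  representation(temperature = "numeric", pOrdered = "numeric",
                 pDisordered = "numeric", residualRms = "numeric"))

setValidity("PopulationSeries", function(object) {
  n <- length(object@temperature)
  msg <- character()
  if (length(object@pOrdered) != n || length(object@pDisordered) != n ||
      length(object@residualRms) != n)
    msg <- c(msg, "all slots must have equal length")
  ok <- !is.na(object@pOrdered) & !is.na(object@pDisordered)
  if (any(abs(object@pOrdered[ok] + object@pDisordered[ok] - 1) > 1e-9))
    msg <- c(msg, "fractions must sum to 1 within 1e-9")
  if (any(object@pOrdered[ok] < -1e-12 | object@pOrdered[ok] > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param temperature,pOrdered,pDisordered,residualRms see slots.
#' @rdname PopulationSeries-class
#' @export
populationSeries <- function(temperature, pOrdered,
                             pDisordered = 1 - pOrdered,
                             residualRms = rep(NA_real_, length(temperature))) {
  o <- order(temperature)
  new("PopulationSeries", temperature = as.numeric(temperature)[o],
      pOrdered = as.numeric(pOrdered)[o],
      pDisordered = as.numeric(pDisordered)[o],
      residualRms = as.numeric(residualRms)[o])
}

#' ThermogramSpec: ground truth for a synthetic DSC scan
#'
#' Parameters of the two-state main melting endotherm (plus optional
#' pretransition, baseline, noise) used by [generateTwoStateThermogram()].
#'
#' @slot tm numeric, main transition temperature, K.
#' @slot dHcal numeric, calorimetric enthalpy, kcal/mol (area of the peak).
#' @slot dHvH numeric, van't Hoff enthalpy, kcal/mol (sets the sharpness).
#' @slot tp numeric, pretransition temperature, K (NA for none).
#' @slot dHpre numeric, pretransition area, kcal/mol.
#' @slot preWidth numeric, pretransition full width at half maximum, K.
#' @slot baselineCoeffs numeric, polynomial coefficients (kcal mol^-1 K^-1)
#'   in ascending powers of (T - tm).
#' @slot noiseSd numeric, additive Gaussian noise sd, kcal mol^-1 K^-1.
#' @slot tGrid numeric, kelvin, strictly increasing, spanning tm.
#' @slot seed integer.
#' @export
setClass("ThermogramSpec",
  representation(tm = "numeric", dHcal = "numeric", dHvH = "numeric",
                 tp = "numeric", dHpre = "numeric", preWidth = "numeric",
                 baselineCoeffs = "numeric", noiseSd = "numeric",
                 tGrid = "numeric", seed = "integer"))

setValidity("ThermogramSpec", function(object) {
  msg <- character()
  if (object@dHcal < 0) msg <- c(msg, "dHcal must be >= 0")
  if (object@dHvH <= 0) msg <- c(msg, "dHvH must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(diff(object@tGrid) <= 0))
    msg <- c(msg, "tGrid must be strictly increasing")
  if (object@tm <= min(object@tGrid) || object@tm >= max(object@tGrid))
    msg <- c(msg, "tGrid must span tm")
  if (length(msg)) msg else TRUE
})

#' @param tm,dHcal,dHvH,tp,dHpre,preWidth,baselineCoeffs,noiseSd,tGrid,seed
#'   see slots. Defaults reproduce a fully hydrated DPPC multilamellar
#'   vesicle scan: Tm = 314.15 K (41 C), dHcal = 8.74 kcal/mol,
#'   dHvH = 2930 kcal/mol, pretransition at 307.15 K (34 C) of 1.2 kcal/mol.
#' @rdname ThermogramSpec-class
#' @export
thermogramSpec <- function(tm = 314.15, dHcal = 8.74, dHvH = 2930,
                           tp = 307.15, dHpre = 1.2, preWidth = 1.5,
                           baselineCoeffs = 0, noiseSd = 0,
                           tGrid = seq(293.15, 328.15, by = 0.005),
                           seed = 1L) {
  new("ThermogramSpec", tm = tm, dHcal = dHcal, dHvH = dHvH,
      tp = as.numeric(tp), dHpre = dHpre, preWidth = preWidth,
      baselineCoeffs = as.numeric(baselineCoeffs), noiseSd = noiseSd,
      tGrid = as.numeric(tGrid), seed = as.integer(seed))
}

#' NitroxideComponent: a three-line first-derivative lineshape model
#'
#' Parameters of one spectral component: three pseudo-Voigt lines at
#' centerField - A, centerField, centerField + A with per-line peak-to-peak
#' widths. Stands in for the "broad" (ordered) and "narrow" (disordered)
#' components of two-environment nitroxide spectra.
#'
#' @slot centerField numeric, G.
#' @slot hyperfineA numeric, isotropic hyperfine line spacing, G, > 0.
#' @slot widths numeric length 3, peak-to-peak linewidths, G, > 0.
#' @slot amplitude numeric, overall scale (arbitrary units).
#' @slot gaussFraction numeric in [0, 1]; 0 = pure Lorentzian.
#' @export
setClass("NitroxideComponent",
  representation(centerField = "numeric", hyperfineA = "numeric",
                 widths = "numeric", amplitude = "numeric",
                 gaussFraction = "numeric"))

setValidity("NitroxideComponent", function(object) {
  msg <- character()
  if (object@hyperfineA <= 0) msg <- c(msg, "hyperfineA must be > 0")
  if (length(object@widths) != 3 || any(object@widths <= 0))
    msg <- c(msg, "widths must be three positive values")
  if (object@gaussFraction < 0 || object@gaussFraction > 1)
    msg <- c(msg, "gaussFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param centerField,hyperfineA,widths,amplitude,gaussFraction see slots.
#' @rdname NitroxideComponent-class
#' @export
nitroxideComponent <- function(centerField = 3350, hyperfineA = 15,
                               widths = c(1.8, 1.6, 2.0), amplitude = 1,
                               gaussFraction = 0.4) {
  new("NitroxideComponent", centerField = centerField,
      hyperfineA = hyperfineA, widths = as.numeric(widths),
      amplitude = amplitude, gaussFraction = gaussFraction)
}

#' SeriesSpec: ground truth for a temperature series of mixed spectra
#'
#' Describes a two-component spectral series whose mixing fractions follow
#' a polynomial ln K versus 1/T law (the non-linear van't Hoff model), used
#' by [generateTwoComponentSeries()].
#'
#' @slot temperatures numeric, kelvin, strictly increasing.
#' @slot vhCoeffs named numeric (a, b, c, d): ln K = a + b/T + c/T^2 + d/T^3
#'   with b in K, c in K^2, d in K^3.
#' @slot kp numeric > 0, probe partition coefficient (K = kp * Pdis/Pord).
#' @slot coexWindow numeric length 2, kelvin: the phase-coexistence
#'   window inside which the van't Hoff law applies; temperatures below
#'   it are pure ordered (P_dis = 0), above it pure disordered
#'   (P_dis = 1), emulating the single-component spectra observed outside
#'   coexistence.
#' @slot ordered,disordered the two component models.
#' @slot driftWidth,driftHyperfine numeric, linear temperature drift of the
#'   component linewidths and hyperfine spacing, G per K (0 = none).
#' @slot fieldGrid numeric, G, shared field axis.
#' @slot noiseSd numeric, spectral noise sd as a fraction of the maximum
#'   mixed amplitude.
#' @slot fractionNoiseSd numeric, sd of additive Gaussian perturbation
#'   applied to the mixing fractions themselves (0 = none).
#' @slot seed integer.
#' @export
setClass("SeriesSpec",
  representation(temperatures = "numeric", vhCoeffs = "numeric",
                 kp = "numeric", coexWindow = "numeric",
                 ordered = "NitroxideComponent",
                 disordered = "NitroxideComponent",
                 driftWidth = "numeric", driftHyperfine = "numeric",
                 fieldGrid = "numeric", noiseSd = "numeric",
                 fractionNoiseSd = "numeric", seed = "integer"))

setValidity("SeriesSpec", function(object) {
  msg <- character()
  if (any(diff(object@temperatures) <= 0))
    msg <- c(msg, "temperatures must be strictly increasing")
  if (object@kp <= 0) msg <- c(msg, "kp must be > 0")
  if (object@noiseSd < 0 || object@fractionNoiseSd < 0)
    msg <- c(msg, "noise sds must be >= 0")
  if (!all(c("a", "b", "c", "d") %in% names(object@vhCoeffs)))
    msg <- c(msg, "vhCoeffs must be named a, b, c, d")
  if (length(object@coexWindow) != 2 || diff(object@coexWindow) <= 0)
    msg <- c(msg, "coexWindow must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' @param temperatures,vhCoeffs,kp,coexWindow,ordered,disordered,driftWidth,driftHyperfine,fieldGrid,noiseSd,fractionNoiseSd,seed
#'   see slots. Defaults emulate a 16-PCSL series through the DPPC
#'   gel-fluid coexistence window (25 temperatures over 300-313.2 K,
#'   DPPC-like cubic law of [dppcVantHoffCoefficients()]) flanked by
#'   pure-phase temperatures on both sides (295-299 K gel, 314-317 K
#'   fluid), with a broad ordered and a narrow disordered component on a
#'   3300-3400 G axis.
#' @rdname SeriesSpec-class
#' @export
seriesSpec <- function(temperatures = c(295, 297, 299,
                                        seq(300, 313.2, length.out = 25),
                                        314, 315.5, 317),
                       vhCoeffs = dppcVantHoffCoefficients(),
                       kp = 1, coexWindow = c(299.5, 313.65),
                       ordered = nitroxideComponent(hyperfineA = 20,
                                                    widths = c(5, 5, 6),
                                                    gaussFraction = 0.5),
                       disordered = nitroxideComponent(),
                       driftWidth = 0, driftHyperfine = 0,
                       fieldGrid = seq(3300, 3400, length.out = 1024),
                       noiseSd = 0, fractionNoiseSd = 0, seed = 1L) {
  new("SeriesSpec", temperatures = as.numeric(temperatures),
      vhCoeffs = vhCoeffs, kp = kp,
      coexWindow = as.numeric(coexWindow), ordered = ordered,
      disordered = disordered, driftWidth = driftWidth,
      driftHyperfine = driftHyperfine, fieldGrid = as.numeric(fieldGrid),
      noiseSd = noiseSd, fractionNoiseSd = fractionNoiseSd,
      seed = as.integer(seed))
}

#' OrderingPotential: orienting potential coefficients
#'
#' Coefficients of the orienting pseudopotential expanded in Wigner
#' functions, in units of kT: U/kT = -[c20 D^2_00 + c22 (D^2_02 + D^2_0-2)
#' + c40 D^4_00 + c42 (...) + c44 (...)]. Only the rank-2 terms are usually
#' fitted for spin-labelled lipids; rank-4 terms default to zero.
#'
#' @slot c20,c22,c40,c42,c44 numeric coefficients (dimensionless).
#' @slot temperature numeric, K (metadata; the coefficients already carry
#'   the 1/kT factor).
#' @export
setClass("OrderingPotential",
  representation(c20 = "numeric", c22 = "numeric", c40 = "numeric",
                 c42 = "numeric", c44 = "numeric", temperature = "numeric"),
  prototype(c22 = 0, c40 = 0, c42 = 0, c44 = 0, temperature = NA_real_))

setValidity("OrderingPotential", function(object) {
  v <- c(object@c20, object@c22, object@c40, object@c42, object@c44)
  if (any(!is.finite(v))) "coefficients must be finite" else TRUE
})

#' @param c20,c22,c40,c42,c44,temperature see slots.
#' @rdname OrderingPotential-class
#' @export
orderingPotential <- function(c20 = 0, c22 = 0, c40 = 0, c42 = 0, c44 = 0,
                              temperature = NA_real_) {
  new("OrderingPotential", c20 = c20, c22 = c22, c40 = c40, c42 = c42,
      c44 = c44, temperature = temperature)
}

#' DSCTransitionResult: calorimetric parameters of one thermogram
#'
#' The single-peak melting metrics reported for phospholipid scans:
#' transition temperatures in degrees Celsius, enthalpies in kcal/mol,
#' transition entropy in cal mol^-1 K^-1, cooperative unit size in
#' molecules.
#'
#' @slot tmC numeric, main transition temperature, C.
#' @slot tpC numeric, pretransition temperature, C (NA if not requested).
#' @slot dHcal numeric, calorimetric enthalpy, kcal/mol.
#' @slot dTmHalf numeric, full width at half maximum, C (NA if the half
#'   height is not bracketed on both flanks).
#' @slot dSAtTm numeric, transition entropy at Tm, cal mol^-1 K^-1.
#' @slot cpMax numeric, refined peak height, kcal mol^-1 K^-1.
#' @slot dHvH numeric, van't Hoff enthalpy, kcal/mol.
#' @slot cus numeric, cooperative unit size, molecules.
#' @export
setClass("DSCTransitionResult",
  representation(tmC = "numeric", tpC = "numeric", dHcal = "numeric",
                 dTmHalf = "numeric", dSAtTm = "numeric", cpMax = "numeric",
                 dHvH = "numeric", cus = "numeric"))

#' BindingModelResult: two-phase ligand partitioning fit
#'
#' Result of fitting the melting-point depression model
#' 1/Tm(x) - 1/Tm0 = (R/dHvH0) ln[(1 + KF x)/(1 + KG x)], where x is the
#' drug:lipid mole ratio and KG, KF are the per-mole-ratio affinities of
#' the ligand for the gel and fluid phase.
#'
#' @slot kG,kF numeric affinities (> 0).
#' @slot ratio numeric, KF/KG.
#' @slot ratioSe numeric, delta-method standard error of the ratio.
#' @slot covariance matrix, covariance of (log kG, log kF).
#' @slot modelId character, functional form identifier.
#' @slot degenerate logical, TRUE when the depression signal is absent and
#'   the ratio is reported as 1 with unbounded uncertainty.
#' @export
setClass("BindingModelResult",
  representation(kG = "numeric", kF = "numeric", ratio = "numeric",
                 ratioSe = "numeric", covariance = "matrix",
                 modelId = "character", degenerate = "logical"))

#' VantHoffModel: polynomial ln K versus 1/T fit
#'
#' The non-linear van't Hoff model ln K = a + b/T + c/T^2 + d/T^3 (terms
#' above the chosen degree fixed at zero), with the probe partition
#' coefficient Kp, the coefficient covariance in the raw 1/T basis, the
#' temperature range of validity and the adjusted R^2 of the fit.
#'
#' @slot kp numeric > 0.
#' @slot degree integer in 1..3.
#' @slot coeffs named numeric (a, b, c, d); units 1, K, K^2, K^3.
#' @slot covariance matrix (degree+1 x degree+1) for (a, ..., coefficient
#'   of u^degree) in the raw u = 1/T basis.
#' @slot tRange numeric length 2, K.
#' @slot adjR2 numeric.
#' @slot fitTable data.frame with columns invT, lnK used in the fit.
#' @export
setClass("VantHoffModel",
  representation(kp = "numeric", degree = "integer", coeffs = "numeric",
                 covariance = "matrix", tRange = "numeric",
                 adjR2 = "numeric", fitTable = "data.frame"))

setValidity("VantHoffModel", function(object) {
  msg <- character()
  if (!(object@degree %in% 1:3)) msg <- c(msg, "degree must be 1, 2 or 3")
  if (length(object@tRange) != 2 || diff(object@tRange) <= 0)
    msg <- c(msg, "tRange must be an increasing pair")
  if (!all(c("a", "b", "c", "d") %in% names(object@coeffs)))
    msg <- c(msg, "coeffs must be named a, b, c, d")
  if (length(msg)) msg else TRUE
})

#' ThermoCurves: temperature-dependent transfer thermodynamics
#'
#' Gibbs energy, enthalpy, entropy and heat capacity changes for the
#' ordered-to-disordered lipid transfer, evaluated on a temperature grid
#' from a fitted [VantHoffModel-class], plus the special temperatures:
#' roots of dG (ln K = 0) and roots of dS (stationary points of dG).
#'
#' @slot tGrid numeric, K.
#' @slot dG,dH numeric, cal/mol.
#' @slot dS,dC numeric, cal mol^-1 K^-1.
#' @slot special data.frame with columns kind ("G_root" or "S_zero") and
#'   tempK.
#' @export
setClass("ThermoCurves",
  representation(tGrid = "numeric", dG = "numeric", dH = "numeric",
                 dS = "numeric", dC = "numeric", special = "data.frame"))

setValidity("ThermoCurves", function(object) {
  n <- length(object@tGrid)
  if (length(object@dG) != n || length(object@dH) != n ||
      length(object@dS) != n || length(object@dC) != n)
    return("curves must share the grid length")
  tol <- 1e-6 * max(abs(object@dH), 1)
  if (max(abs(object@dG - (object@dH - object@tGrid * object@dS))) > tol)
    return("dG = dH - T dS violated beyond tolerance")
  TRUE
})
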