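#' DPPC-like coefficients for the cubic van't Hoff law
#'
#' Constructs default ground-truth coefficients (a, b, c, d) of
#' ln K = a + b/T + c/T^2 + d/T^3 for a DPPC-like gel-fluid coexistence
#' window from four physical constraints: (i) ln K = 0 at the main
#' transition temperature `tm` (the free energy of ordered-to-disordered
#' transfer vanishes at the melting point); (ii) ln K = `lnKOnset` at the
#' cold onset of coexistence `tOnset` (the disordered population is just
#' emerging); (iii) the transfer entropy dS is zero at the pretransition
#' temperature `tp`; and (iv) dC is zero there as well, which together make
#' dS a parabola touching zero at `tp` -- dH and dS stay positive across
#' the window and dC crosses from negative to positive at `tp`.
#'
#' The constraints form a linear system in (a, b, c, d) that is solved at
#' full precision each call: the four terms cancel to order unity, so
#' rounding the coefficients to a few digits would distort ln K by O(1).
#'
#' @param lnKOnset ln K at the onset temperature (default -3, i.e. about
#'   5 percent disordered probe).
#' @param tOnset,tm,tp temperatures in kelvin (defaults 300, 314.15,
#'   307.15 K).
#' @return named numeric vector (a, b, c, d).
#' @examples
#' co <- dppcVantHoffCoefficients()
#' # ln K at Tm is zero by construction:
#' sum(co * c(1, 1/314.15, 1/314.15^2, 1/314.15^3))
#' @export
dppcVantHoffCoefficients <- function(lnKOnset = -3, tOnset = 300,
                                     tm = 314.15, tp = 307.15) {
  um <- 1 / tm; u0 <- 1 / tOnset; u1 <- 1 / tp
  # with dS(tp)=0 and dC(tp)=0: c = -3 d u1, a = -d u1^3; solve for (b, d)
  A <- rbind(c(um, -u1^3 - 3 * u1 * um^2 + um^3),
             c(u0, -u1^3 - 3 * u1 * u0^2 + u0^3))
  s <- solve(A, c(0, lnKOnset))
  b <- s[1]; d <- s[2]
  c(a = -d * u1^3, b = b, c = -3 * d * u1, d = d)
}

#' Ternary-mixture-like coefficients for a quadratic van't Hoff law
#'
#' Quadratic ln K = a + b/T + c/T^2 with ln K = 0 at two temperatures
#' (the two melting points of a binary-component mixture) and a free
#' energy maximum `dGMax` (cal/mol) between them, emulating the
#' two-root free-energy profile of a DPPC/POPC/POPG-like mixture.
#'
#' @param tRootLow,tRootHigh kelvin, the two ln K roots (defaults 271.15
#'   and 301.45 K).
#' @param dGMax cal/mol, the approximate free-energy maximum between the
#'   roots (default 250).
#' @return named numeric vector (a, b, c, d) with d = 0.
#' @export
ternaryVantHoffCoefficients <- function(tRootLow = 271.15,
                                        tRootHigh = 301.45, dGMax = 250) {
  u1 <- 1 / tRootLow; u2 <- 1 / tRootHigh
  umid <- (u1 + u2) / 2
  tmid <- 1 / umid
  lnKmid <- -dGMax / (.RGAS_CAL * tmid)
  k <- lnKmid / ((umid - u1) * (umid - u2))
  c(a = k * u1 * u2, b = -k * (u1 + u2), c = k, d = 0)
}

#' Generate a two-state DSC melting endotherm
#'
#' Builds the excess heat capacity trace of a cooperative two-state melting
#' transition: Cp(T) = dHcal (dHvH / (R T^2)) K / (1 + K)^2 with
#' K(T) = exp[-(dHvH/R)(1/T - 1/Tm)]. The trace integrates exactly to
#' dHcal and its peak height is dHcal dHvH / (4 R Tm^2), so the standard
#' van't Hoff enthalpy estimate 4 R Tm^2 Cp,max / dHcal recovers dHvH.
#' An optional Gaussian pretransition peak (area dHpre, FWHM preWidth at
#' tp), a polynomial baseline in (T - Tm) and i.i.d. Gaussian noise are
#' added on top. The generating spec is attached to the metadata as ground
#' truth.
#'
#' @param spec a [ThermogramSpec-class].
#' @return a [Thermogram-class].
#' @examples
#' tg <- generateTwoStateThermogram(thermogramSpec(tp = NA))
#' pracma::trapz(temperature(tg), heatCapacity(tg))  # ~ 8.74 + baseline
#' @export
generateTwoStateThermogram <- function(spec) {
  stopifnot(is(spec, "ThermogramSpec"))
  validObject(spec)
  T <- spec@tGrid
  cp <- numeric(length(T))
  if (spec@dHcal > 0) {
    lnK <- -(spec@dHvH / .RGAS_KCAL) * (1 / T - 1 / spec@tm)
    p <- stats::plogis(lnK)              # K/(1+K), overflow-safe
    cp <- spec@dHcal * (spec@dHvH / (.RGAS_KCAL * T^2)) * p * (1 - p)
  }
  if (!is.na(spec@tp) && spec@dHpre > 0) {
    sig <- spec@preWidth / (2 * sqrt(2 * log(2)))
    cp <- cp + spec@dHpre / (sig * sqrt(2 * pi)) *
      exp(-(T - spec@tp)^2 / (2 * sig^2))
  }
  dt <- T - spec@tm
  base <- 0
  for (k in seq_along(spec@baselineCoeffs))
    base <- base + spec@baselineCoeffs[k] * dt^(k - 1)
  cp <- cp + base
  if (spec@noiseSd > 0) {
    set.seed(spec@seed)
    cp <- cp + stats::rnorm(length(T), 0, spec@noiseSd)
  }
  thermogram(T, cp, metadata = list(
    kind = "synthetic_two_state",
    groundTruth = list(tm = spec@tm, dHcal = spec@dHcal, dHvH = spec@dHvH,
                       tp = spec@tp, dHpre = spec@dHpre,
                       baselineCoeffs = spec@baselineCoeffs,
                       noiseSd = spec@noiseSd, seed = spec@seed)))
}

# First derivative of a unit-area pseudo-Voigt absorption line with
# peak-to-peak width w (G): Gaussian sigma = w/2, Lorentzian HWHM =
# w*sqrt(3)/2 reproduce w as the derivative extremum separation.
.pvDeriv <- function(x, w, gaussFraction) {
  sig <- w / 2
  gam <- w * sqrt(3) / 2
  dg <- -(x / sig^2) * exp(-x^2 / (2 * sig^2)) / (sig * sqrt(2 * pi))
  dl <- -2 * gam * x / (pi * (x^2 + gam^2)^2)
  gaussFraction * dg + (1 - gaussFraction) * dl
}

#' Generate a three-line nitroxide first-derivative spectrum
#'
#' Sum of three first-derivative pseudo-Voigt lines centred at
#' centerField - A, centerField and centerField + A, with the component's
#' per-line peak-to-peak widths, scaled by the amplitude. Each line
#' derives from a unit-area absorption profile, so the double integral of
#' the spectrum (the absorption area) equals 3 x amplitude.
#'
#' @param model a [NitroxideComponent-class].
#' @param fieldGrid numeric, G, strictly increasing; must span
#'   centerField +/- 2 hyperfineA.
#' @return an [EsrSpectrum-class].
#' @export
generateNitroxideSpectrum <- function(model,
                                      fieldGrid = seq(3300, 3400,
                                                      length.out = 1024)) {
  stopifnot(is(model, "NitroxideComponent"))
  validObject(model)
  if (any(diff(fieldGrid) <= 0))
    stop("fieldGrid must be strictly increasing")
  lo <- model@centerField - 2 * model@hyperfineA
  hi <- model@centerField + 2 * model@hyperfineA
  if (min(fieldGrid) > lo || max(fieldGrid) < hi)
    stop("fieldGrid too narrow: must span centerField +/- 2 hyperfineA")
  centers <- model@centerField + c(-1, 0, 1) * model@hyperfineA
  y <- numeric(length(fieldGrid))
  for (i in 1:3)
    y <- y + .pvDeriv(fieldGrid - centers[i], model@widths[i],
                      model@gaussFraction)
  esrSpectrum(fieldGrid, model@amplitude * y)
}

# Absorption area of a first-derivative spectrum: double trapezoid
# integral over the field axis.
.absorptionArea <- function(field, intensity) {
  pracma::trapz(field, as.numeric(pracma::cumtrapz(field, intensity)))
}

.scaleComponent <- function(model, dT, driftWidth, driftHyperfine) {
  nitroxideComponent(centerField = model@centerField,
                     hyperfineA = max(model@hyperfineA + driftHyperfine * dT,
                                      1e-3),
                     widths = pmax(model@widths + driftWidth * dT, 1e-3),
                     amplitude = model@amplitude,
                     gaussFraction = model@gaussFraction)
}

#' Generate a temperature series of two-component spectra
#'
#' For every temperature T inside the coexistence window the disordered
#' fraction follows the polynomial van't Hoff law of the spec,
#' ln(Pdis/Pord) = a + b/T + c/T^2 + d/T^3 (equivalently K = Kp Pdis/Pord
#' with ln K = ln Kp + that polynomial); below the window the membrane is
#' pure ordered (Pdis = 0), above it pure disordered (Pdis = 1), matching
#' the single-component spectra observed outside coexistence. Each
#' spectrum is the fraction-weighted sum of the two area-normalised
#' component lineshapes plus optional spectral noise. Optionally the
#' in-window fractions are perturbed before mixing (fractionNoiseSd),
#' which emulates population-level scatter. The returned PopulationSeries
#' holds the exact fractions used in the mixing.
#'
#' @param spec a [SeriesSpec-class].
#' @return list with elements `spectra` (list of [EsrSpectrum-class]) and
#'   `populations` (a [PopulationSeries-class], the ground truth).
#' @export
generateTwoComponentSeries <- function(spec) {
  stopifnot(is(spec, "SeriesSpec"))
  validObject(spec)
  set.seed(spec@seed)
  Ts <- spec@temperatures
  co <- spec@vhCoeffs[c("a", "b", "c", "d")]
  lnRatio <- co[["a"]] + co[["b"]] / Ts + co[["c"]] / Ts^2 + co[["d"]] / Ts^3
  pDis <- stats::plogis(lnRatio)
  inWin <- Ts >= spec@coexWindow[1] & Ts <= spec@coexWindow[2]
  pDis[Ts < spec@coexWindow[1]] <- 0
  pDis[Ts > spec@coexWindow[2]] <- 1
  if (spec@fractionNoiseSd > 0) {
    pDis[inWin] <- pDis[inWin] +
      stats::rnorm(sum(inWin), 0, spec@fractionNoiseSd)
    pDis <- pmin(pmax(pDis, 1e-6), 1 - 1e-6)
    pDis[Ts < spec@coexWindow[1]] <- 0
    pDis[Ts > spec@coexWindow[2]] <- 1
  }
  tRef <- mean(Ts)
  spectra <- vector("list", length(Ts))
  for (i in seq_along(Ts)) {
    dT <- Ts[i] - tRef
    ordM <- .scaleComponent(spec@ordered, dT, spec@driftWidth,
                            spec@driftHyperfine)
    disM <- .scaleComponent(spec@disordered, dT, spec@driftWidth,
                            spec@driftHyperfine)
    yo <- intensities(generateNitroxideSpectrum(ordM, spec@fieldGrid))
    yd <- intensities(generateNitroxideSpectrum(disM, spec@fieldGrid))
    yo <- yo / .absorptionArea(spec@fieldGrid, yo)
    yd <- yd / .absorptionArea(spec@fieldGrid, yd)
    y <- (1 - pDis[i]) * yo + pDis[i] * yd
    if (spec@noiseSd > 0)
      y <- y + stats::rnorm(length(y), 0, spec@noiseSd * max(abs(y)))
    spectra[[i]] <- esrSpectrum(spec@fieldGrid, y, temperature = Ts[i],
                                label = sprintf("T=%.2fK", Ts[i]))
  }
  list(spectra = spectra,
       populations = populationSeries(Ts, pOrdered = 1 - pDis,
                                      pDisordered = pDis))
}

#' Henderson-Hasselbalch protonated fraction
#'
#' Fraction of a monoprotic base carrying the proton at a given pH:
#' 1 / (1 + 10^(pH - pKa)).
#'
#' @param pH,pKa numeric.
#' @return numeric fraction in (0, 1).
#' @examples
#' protonationFraction(7.4, 7.65)  # 0.640
#' @export
protonationFraction <- function(pH, pKa) 1 / (1 + 10^(pH - pKa))
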