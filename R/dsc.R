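#' Subtract buffer scan and/or a window-fitted polynomial baseline
#'
#' Standard DSC pre-processing: an optional buffer scan (interpolated onto
#' the sample grid) is subtracted first; then, if two flanking windows are
#' given, a polynomial baseline fitted to the points inside those windows
#' is removed. The method is recorded in the metadata.
#'
#' @param raw a [Thermogram-class].
#' @param buffer optional [Thermogram-class] buffer scan.
#' @param windows optional list of two numeric length-2 intervals (kelvin)
#'   flanking the transition; the baseline polynomial is fitted inside
#'   them.
#' @param degree polynomial degree for the window baseline (default 1).
#' @return baseline-subtracted [Thermogram-class].
#' @export
subtractBaseline <- function(raw, buffer = NULL, windows = NULL,
                             degree = 1) {
  stopifnot(is(raw, "Thermogram"))
  T <- raw@temperature
  cp <- raw@cp
  method <- character()
  if (!is.null(buffer)) {
    stopifnot(is(buffer, "Thermogram"))
    bint <- stats::approx(buffer@temperature, buffer@cp, xout = T,
                          rule = 2)$y
    cp <- cp - bint
    method <- c(method, "buffer")
  }
  if (!is.null(windows)) {
    if (length(windows) != 2)
      stop("windows must be a list of two temperature intervals")
    inWin <- rep(FALSE, length(T))
    for (w in windows) {
      if (length(w) != 2 || w[1] >= w[2])
        stop("each window must be an increasing length-2 interval")
      if (w[1] < min(T) || w[2] > max(T))
        stop("windows must lie inside the data range")
      inWin <- inWin | (T >= w[1] & T <= w[2])
    }
    if (!any(inWin)) stop("empty baseline windows")
    ipk <- which.max(cp)
    if (inWin[ipk])
      warning("baseline window overlaps the transition peak")
    v <- T - mean(T[inWin])
    X <- outer(v, 0:degree, `^`)
    beta <- stats::lm.fit(X[inWin, , drop = FALSE], cp[inWin])$coefficients
    beta[is.na(beta)] <- 0
    cp <- cp - drop(X %*% beta)
    method <- c(method, sprintf("windows_poly%d", degree))
  }
  md <- raw@metadata
  md$baseline <- paste(method, collapse = "+")
  thermogram(T, cp, metadata = md)
}

#' Transition entropy at the melting temperature
#'
#' dS = dHcal / Tm, converted to cal mol^-1 K^-1 (input enthalpy in
#' kcal/mol, temperature in kelvin).
#'
#' @param dHcal kcal/mol.
#' @param tm kelvin, > 0.
#' @return cal mol^-1 K^-1.
#' @examples
#' entropyAtTm(8.74, 314.15)  # 27.8
#' @export
entropyAtTm <- function(dHcal, tm) {
  stopifnot(all(tm > 0))
  1000 * dHcal / tm
}

#' Van't Hoff enthalpy from peak height
#'
#' dHvH = 4 R Tm^2 Cp,max / dHcal, the two-state estimate of the enthalpy
#' of the cooperatively melting unit from the sharpness of the transition.
#'
#' @param cpMax peak excess heat capacity, kcal mol^-1 K^-1.
#' @param tm kelvin.
#' @param dHcal kcal/mol, > 0.
#' @return kcal/mol.
#' @examples
#' vantHoffEnthalpy(32.6, 314.15, 8.74)  # ~ 2.93e3
#' @export
vantHoffEnthalpy <- function(cpMax, tm, dHcal) {
  if (any(dHcal <= 0)) stop("dHcal must be > 0")
  4 * .RGAS_KCAL * tm^2 * cpMax / dHcal
}

#' Cooperative unit size
#'
#' Ratio of the van't Hoff to the calorimetric enthalpy: the average
#' number of molecules melting as one cooperative unit.
#'
#' @param dHvH,dHcal kcal/mol; dHcal > 0.
#' @return unitless count.
#' @examples
#' cooperativeUnit(2930, 8.74)  # ~ 335
#' @export
cooperativeUnit <- function(dHvH, dHcal) {
  if (any(dHcal <= 0)) stop("dHcal must be > 0")
  dHvH / dHcal
}

# Parabolic refinement of a discrete extremum through the 3 points around
# index i; returns c(x, y) of the vertex (falls back to the sample when i
# is at an edge or the curvature vanishes).
.refineExtremum <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(c(x[i], y[i]))
  x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  d2 <- y3[1] - 2 * y3[2] + y3[3]
  if (d2 == 0) return(c(x[i], y[i]))
  # uniform-grid vertex formula is exact enough on DSC grids
  h <- (x3[3] - x3[1]) / 2
  delta <- 0.5 * (y3[1] - y3[3]) / d2
  xv <- x3[2] + delta * h
  yv <- y3[2] - 0.25 * (y3[1] - y3[3]) * delta
  c(xv, yv)
}

# Full width at half maximum by linear interpolation on each flank,
# restricted to the window; NA when a flank never crosses the half height.
.halfWidth <- function(T, cp, ipk, half) {
  lo <- NA_real_; hi <- NA_real_
  i <- ipk
  while (i > 1 && cp[i] > half) i <- i - 1
  if (cp[i] <= half && i < ipk)
    lo <- T[i] + (half - cp[i]) * (T[i + 1] - T[i]) / (cp[i + 1] - cp[i])
  j <- ipk
  while (j < length(T) && cp[j] > half) j <- j + 1
  if (cp[j] <= half && j > ipk)
    hi <- T[j - 1] + (half - cp[j - 1]) * (T[j] - T[j - 1]) /
      (cp[j] - cp[j - 1])
  hi - lo
}

#' Analyze a baseline-subtracted thermogram
#'
#' Extracts the standard single-peak melting metrics: Tm (parabolically
#' refined argmax of Cp inside the main window), peak height Cp,max,
#' calorimetric enthalpy dHcal (trapezoid integral over the main window),
#' full width at half maximum, the optional pretransition temperature Tp,
#' and the derived quantities dS(Tm) = dHcal/Tm, dHvH = 4 R Tm^2 Cp,max /
#' dHcal and the cooperative unit size dHvH/dHcal.
#'
#' @param processed baseline-subtracted [Thermogram-class].
#' @param mainWindow numeric length-2 interval, kelvin, containing the
#'   dominant peak.
#' @param preWindow optional numeric length-2 interval, kelvin, for the
#'   pretransition peak.
#' @return a [DSCTransitionResult-class].
#' @export
analyzeThermogram <- function(processed, mainWindow,
                              preWindow = NULL) {
  stopifnot(is(processed, "Thermogram"), length(mainWindow) == 2)
  T <- processed@temperature
  cp <- processed@cp
  sel <- which(T >= mainWindow[1] & T <= mainWindow[2])
  if (length(sel) < 5) stop("main window contains too few points")
  Tw <- T[sel]; cpw <- cp[sel]
  ipk <- which.max(cpw)
  if (cpw[ipk] <= 0) stop("no positive peak in the main window")
  pk <- .refineExtremum(Tw, cpw, ipk)
  tmK <- pk[1]; cpMax <- pk[2]
  dHcal <- pracma::trapz(Tw, cpw)
  if (dHcal <= 0) stop("non-positive transition area in the main window")
  dTmHalf <- .halfWidth(Tw, cpw, ipk, cpMax / 2)
  tpC <- NA_real_
  if (!is.null(preWindow)) {
    psel <- which(T >= preWindow[1] & T <= preWindow[2])
    if (length(psel) >= 3) {
      pipk <- which.max(cp[psel])
      tpC <- kelvinToCelsius(.refineExtremum(T[psel], cp[psel], pipk)[1])
    }
  }
  dHvH <- vantHoffEnthalpy(cpMax, tmK, dHcal)
  new("DSCTransitionResult",
      tmC = kelvinToCelsius(tmK), tpC = tpC, dHcal = dHcal,
      dTmHalf = dTmHalf, dSAtTm = entropyAtTm(dHcal, tmK),
      cpMax = cpMax, dHvH = dHvH, cus = cooperativeUnit(dHvH, dHcal))
}

#' Fit the gel/fluid ligand-partitioning melting-depression model
#'
#' Fits 1/Tm(x) - 1/Tm0 = (R/dHvH0) ln[(1 + KF x)/(1 + KG x)] over the
#' two affinities by least squares, where x is the drug:lipid mole ratio
#' and KG, KF are per-mole-ratio binding constants to the gel and fluid
#' phase. A ligand preferring the fluid phase (KF > KG) depresses Tm.
#' The reported KF/KG ratio carries a delta-method standard error from the
#' fit covariance (on the log scale). A flat Tm series is degenerate: the
#' ratio is reported as 1 with infinite uncertainty.
#'
#' @param moleRatios drug:lipid mole ratios, including 0.
#' @param tmValues kelvin, melting temperatures at those ratios.
#' @param dHvH0 kcal/mol, transition enthalpy scale of the model.
#' @param tm0 kelvin, drug-free melting temperature.
#' @return a [BindingModelResult-class].
#' @export
fitTmDepression <- function(moleRatios, tmValues, dHvH0, tm0) {
  stopifnot(length(moleRatios) == length(tmValues),
            length(moleRatios) >= 3, any(moleRatios == 0))
  modelId <- "invTm_depression: 1/Tm-1/Tm0 = (R/dHvH0)*log((1+KF*x)/(1+KG*x))"
  y <- 1 / tmValues - 1 / tm0
  x <- moleRatios
  scale <- .RGAS_KCAL / dHvH0
  if (stats::sd(y) == 0 || all(y == 0)) {
    return(new("BindingModelResult", kG = 1, kF = 1, ratio = 1,
               ratioSe = Inf, covariance = matrix(NA_real_, 2, 2),
               modelId = modelId, degenerate = TRUE))
  }
  # start from the dilute-limit slope: y ~ scale*(KF-KG)*x
  slope <- sum(x * y) / sum(x^2)
  dK <- slope / scale
  start <- c(lkG = log(0.5), lkF = log(max(0.5 + dK, 1e-3)))
  resFn <- function(p) {
    kG <- exp(p[1]); kF <- exp(p[2])
    y - scale * log((1 + kF * x) / (1 + kG * x))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resFn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  kG <- exp(fit$par[[1]]); kF <- exp(fit$par[[2]])
  dof <- max(length(x) - 2, 1)
  s2 <- sum(fit$fvec^2) / dof
  V <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e)
    matrix(NA_real_, 2, 2))
  ratio <- kF / kG
  vlr <- V[1, 1] + V[2, 2] - 2 * V[1, 2]   # var of log ratio
  ratioSe <- if (is.finite(vlr) && vlr >= 0) ratio * sqrt(vlr) else NA_real_
  new("BindingModelResult", kG = kG, kF = kF, ratio = ratio,
      ratioSe = ratioSe, covariance = V, modelId = modelId,
      degenerate = FALSE)
}
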