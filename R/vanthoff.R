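#' Equilibrium constant table from a population series
#'
#' ln K = ln(Kp * P_disordered / P_ordered) for every temperature where
#' both fractions are at least `exclusionThreshold` (the logit diverges at
#' the window edges, so near-pure temperatures are excluded before the
#' fit). Excluded rows are attached as the "excluded" attribute.
#'
#' @param series a [PopulationSeries-class].
#' @param kp probe partition coefficient (> 0, default 1).
#' @param exclusionThreshold minimum fraction on both sides (default
#'   0.02).
#' @return data.frame with columns temperatureK, invT, lnK; attribute
#'   "excluded" holds the dropped rows.
#' @export
lnEquilibriumConstant <- function(series, kp = 1,
                                  exclusionThreshold = 0.02) {
  stopifnot(is(series, "PopulationSeries"), kp > 0)
  df <- populations(series)
  keep <- !is.na(df$pOrdered) & !is.na(df$pDisordered) &
    df$pOrdered >= exclusionThreshold &
    df$pDisordered >= exclusionThreshold
  if (!any(keep)) stop("all rows excluded: no coexistence window left")
  out <- data.frame(temperatureK = df$temperatureK[keep],
                    invT = 1 / df$temperatureK[keep],
                    lnK = log(kp * df$pDisordered[keep] /
                                df$pOrdered[keep]))
  attr(out, "excluded") <- df[!keep, , drop = FALSE]
  out
}

# Transform matrix from the centred/scaled basis z = (u - uBar)/s to the
# raw polynomial basis in u (degree deg).
.rawBasisMap <- function(uBar, s, deg) {
  M <- matrix(0, deg + 1, deg + 1)
  for (k in 0:deg)
    for (j in 0:k)
      M[j + 1, k + 1] <- choose(k, j) * (-uBar)^(k - j) / s^k
  M
}

#' Fit the polynomial van't Hoff model
#'
#' Ordinary least squares of ln K on powers of u = 1/T up to `degree`
#' (1-3). The basis is centred on the mean of u and scaled for
#' conditioning (u spans ~1e-4 K^-1 windows, so raw-basis normal equations
#' are hopeless); coefficients and covariance are mapped back to the raw
#' basis ln K = a + b/T + c/T^2 + d/T^3.
#'
#' @param table data.frame with columns invT and lnK (as produced by
#'   [lnEquilibriumConstant()]).
#' @param degree integer 1-3.
#' @param kp partition coefficient stored with the model (default 1).
#' @return a [VantHoffModel-class].
#' @export
fitVantHoff <- function(table, degree, kp = 1) {
  stopifnot(is.data.frame(table), all(c("invT", "lnK") %in% names(table)),
            degree %in% 1:3)
  u <- table$invT; y <- table$lnK
  n <- length(u)
  if (n < degree + 2) stop("need at least degree + 2 points")
  uBar <- mean(u)
  s <- stats::sd(u)
  if (!is.finite(s) || s == 0) stop("degenerate 1/T values")
  z <- (u - uBar) / s
  X <- outer(z, 0:degree, `^`)
  qrX <- qr(X)
  if (qrX$rank < degree + 1) stop("rank-deficient design: cannot fit")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  dof <- n - (degree + 1)
  s2 <- if (dof > 0) rss / dof else 0
  XtXinv <- chol2inv(qr.R(qrX))
  Vbeta <- s2 * XtXinv
  M <- .rawBasisMap(uBar, s, degree)
  raw <- drop(M %*% beta)
  Vraw <- M %*% Vbeta %*% t(M)
  tss <- sum((y - mean(y))^2)
  adjR2 <- if (dof > 0 && tss > 0) 1 - (rss / dof) / (tss / (n - 1)) else
    NA_real_
  coeffs <- c(a = 0, b = 0, c = 0, d = 0)
  coeffs[seq_len(degree + 1)] <- raw
  new("VantHoffModel", kp = kp, degree = as.integer(degree),
      coeffs = coeffs, covariance = Vraw,
      tRange = range(1 / u), adjR2 = adjR2,
      fitTable = data.frame(invT = u, lnK = y))
}

#' Choose the polynomial degree by incremental F-tests
#'
#' Returns the highest candidate degree whose incremental F-test against
#' the next-lower candidate is significant at `alpha`; equal residuals
#' (tie) fall through to the lower degree, and when no step is
#' significant the lowest candidate is returned.
#'
#' @param table data.frame with columns invT and lnK.
#' @param candidateDegrees integer vector, at least 2 candidates
#'   (default 1:3).
#' @param alpha significance level (default 0.01).
#' @return integer degree.
#' @export
selectDegree <- function(table, candidateDegrees = 1:3, alpha = 0.01) {
  stopifnot(length(candidateDegrees) >= 2)
  degs <- sort(unique(as.integer(candidateDegrees)))
  u <- table$invT; y <- table$lnK
  z <- (u - mean(u)) / stats::sd(u)
  rssOf <- function(d) {
    X <- outer(z, 0:d, `^`)
    sum(qr.resid(qr(X), y)^2)
  }
  rss <- vapply(degs, rssOf, numeric(1))
  n <- length(y)
  for (i in rev(seq_along(degs))[-length(degs)]) {
    dHi <- degs[i]; dLo <- degs[i - 1]
    extra <- dHi - dLo
    df2 <- n - (dHi + 1)
    if (df2 <= 0) next
    if (rss[i] >= rss[i - 1]) next     # ties break toward lower degree
    Fstat <- ((rss[i - 1] - rss[i]) / extra) / (rss[i] / df2)
    p <- stats::pf(Fstat, extra, df2, lower.tail = FALSE)
    if (!is.na(p) && p < alpha) return(dHi)
  }
  degs[1]
}

# Polynomial ln K and derived thermodynamic functions of a coefficient
# vector (a, b, c, d); temperatures kelvin, energies cal/mol.
.lnKPoly <- function(co, T) {
  u <- 1 / T
  co[["a"]] + co[["b"]] * u + co[["c"]] * u^2 + co[["d"]] * u^3
}

.thermoFromCoeffs <- function(co, T) {
  u <- 1 / T
  dG <- -.RGAS_CAL * T * (co[["a"]] + co[["b"]] * u + co[["c"]] * u^2 +
                            co[["d"]] * u^3)
  dH <- -.RGAS_CAL * (co[["b"]] + 2 * co[["c"]] * u + 3 * co[["d"]] * u^2)
  dS <- (dH - dG) / T
  dC <- .RGAS_CAL * (2 * co[["c"]] * u^2 + 6 * co[["d"]] * u^3)
  list(dG = dG, dH = dH, dS = dS, dC = dC)
}

# All sign-change roots of f on a fine mesh over [lo, hi], polished by
# uniroot bisection.
.meshRoots <- function(f, lo, hi, by = 0.01) {
  Ts <- seq(lo, hi, by = by)
  if (Ts[length(Ts)] < hi) Ts <- c(Ts, hi)
  v <- f(Ts)
  roots <- Ts[v == 0]
  sgn <- which(v[-1] * v[-length(v)] < 0)
  for (i in sgn)
    roots <- c(roots, stats::uniroot(f, c(Ts[i], Ts[i + 1]),
                                     tol = 1e-10)$root)
  roots <- sort(unique(roots))
  # collapse numerically split double roots (e.g. a dS parabola touching 0)
  if (length(roots) > 1) {
    grp <- cumsum(c(TRUE, diff(roots) > 1e-3))
    roots <- as.numeric(tapply(roots, grp, mean))
  }
  roots
}

#' Temperature-dependent transfer thermodynamics from a fitted model
#'
#' Evaluates, with u = 1/T: dG = -R T (a + b u + c u^2 + d u^3) (i.e.
#' -RT ln K), dH = -R (b + 2c u + 3d u^2) (the van't Hoff derivative
#' -R d lnK/du), dS = (dH - dG)/T, and the analytic heat capacity change
#' dC = d(dH)/dT = R (2c u^2 + 6d u^3), all in cal/mol(/K). Special
#' temperatures inside the grid range are located on a 0.01 K mesh with
#' bisection: every root of dG (ln K = 0; there the transfer is
#' iso-energetic, as at the melting point) and every root of dS
#' (stationary points of dG).
#'
#' @param model a [VantHoffModel-class].
#' @param tGrid kelvin grid inside the model's validity range; default is
#'   512 points spanning it.
#' @return a [ThermoCurves-class].
#' @export
thermodynamicCurves <- function(model, tGrid = NULL) {
  stopifnot(is(model, "VantHoffModel"))
  if (is.null(tGrid))
    tGrid <- seq(model@tRange[1], model@tRange[2], length.out = 512)
  if (min(tGrid) < model@tRange[1] - 1e-9 ||
      max(tGrid) > model@tRange[2] + 1e-9)
    stop("tGrid must lie inside the model temperature range")
  co <- model@coeffs
  th <- .thermoFromCoeffs(co, tGrid)
  lo <- min(tGrid); hi <- max(tGrid)
  gRoots <- .meshRoots(function(T) .lnKPoly(co, T), lo, hi)
  sZero <- .meshRoots(function(T)
    .thermoFromCoeffs(co, T)$dS, lo, hi)
  special <- data.frame(
    kind = c(rep("G_root", length(gRoots)), rep("S_zero", length(sZero))),
    tempK = c(gRoots, sZero))
  special <- special[order(special$tempK), , drop = FALSE]
  rownames(special) <- NULL
  new("ThermoCurves", tGrid = as.numeric(tGrid), dG = th$dG, dH = th$dH,
      dS = th$dS, dC = th$dC, special = special)
}

#' Entropy-enthalpy compensation analysis
#'
#' Regresses dH on dS across the grid: the slope is the compensation
#' temperature (kelvin). Also reports the regression of dH on T dS, whose
#' slope near 1 signals compensation (dG nearly constant relative to the
#' dH, T dS excursions).
#'
#' @param curves a [ThermoCurves-class] with at least 5 grid points and
#'   non-constant dS.
#' @return list with `slope` (= `compensationT`), `intercept`,
#'   `slopeTdS`, `interceptTdS`.
#' @export
compensationAnalysis <- function(curves) {
  stopifnot(is(curves, "ThermoCurves"))
  ok <- curves@dS != 0
  if (sum(ok) < 5) stop("need at least 5 grid points with nonzero dS")
  if (stats::sd(curves@dS) <= 1e-10 * max(abs(curves@dS), 1))
    stop("constant dS: compensation undefined")
  f1 <- stats::lm(curves@dH ~ curves@dS)
  ts <- curves@tGrid * curves@dS
  f2 <- stats::lm(curves@dH ~ ts)
  list(slope = unname(stats::coef(f1)[2]),
       intercept = unname(stats::coef(f1)[1]),
       compensationT = unname(stats::coef(f1)[2]),
       slopeTdS = unname(stats::coef(f2)[2]),
       interceptTdS = unname(stats::coef(f2)[1]))
}

#' Residual-resampling bootstrap bands for the thermodynamic curves
#'
#' Resamples the fit residuals of the van't Hoff polynomial with
#' replacement, refits, and accumulates 2.5/97.5 percentile bands for dG,
#' dH, dS, dC on the grid and for the raw coefficients (a, b, c, d).
#' Bit-reproducible for a fixed seed.
#'
#' @param table data.frame with columns invT and lnK (the fitted data).
#' @param model the fitted [VantHoffModel-class].
#' @param nBoot number of resamples (>= 100, default 1000).
#' @param seed integer RNG seed.
#' @param tGrid kelvin grid (default: the model range, 256 points).
#' @return list with `tGrid`, `bands` (list of 2 x length(tGrid) matrices
#'   "lo"/"hi" for dG, dH, dS, dC), `coefBands` (2 x 4 matrix), `nBoot`,
#'   `seed`.
#' @export
bootstrapUncertainty <- function(table, model, nBoot = 1000, seed = 1L,
                                 tGrid = NULL) {
  stopifnot(is(model, "VantHoffModel"), nBoot >= 100)
  if (is.null(tGrid))
    tGrid <- seq(model@tRange[1], model@tRange[2], length.out = 256)
  u <- table$invT; y <- table$lnK
  deg <- model@degree
  uBar <- mean(u); s <- stats::sd(u)
  z <- (u - uBar) / s
  X <- outer(z, 0:deg, `^`)
  qrX <- qr(X)
  fitted <- drop(X %*% qr.coef(qrX, y))
  resid <- y - fitted
  # variance-corrected residual bootstrap: raw residuals underestimate the
  # error sd by (n - p)/n, so inflate before resampling
  n <- length(y)
  resid <- resid * sqrt(n / max(n - (deg + 1), 1))
  M <- .rawBasisMap(uBar, s, deg)
  set.seed(seed)
  nm <- c("dG", "dH", "dS", "dC")
  curvesB <- lapply(nm, function(x) matrix(0, nBoot, length(tGrid)))
  names(curvesB) <- nm
  coefB <- matrix(0, nBoot, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (b in seq_len(nBoot)) {
    yb <- fitted + sample(resid, replace = TRUE)
    raw <- drop(M %*% qr.coef(qrX, yb))
    co <- c(a = 0, b = 0, c = 0, d = 0)
    co[seq_len(deg + 1)] <- raw
    coefB[b, ] <- co
    th <- .thermoFromCoeffs(as.list(co), tGrid)
    for (x in nm) curvesB[[x]][b, ] <- th[[x]]
  }
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                          names = FALSE)
  bands <- lapply(curvesB, qs)
  for (x in nm) rownames(bands[[x]]) <- c("lo", "hi")
  cb <- qs(coefB)
  rownames(cb) <- c("lo", "hi"); colnames(cb) <- c("a", "b", "c", "d")
  list(tGrid = tGrid, bands = bands, coefBands = cb, nBoot = nBoot,
       seed = seed)
}
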