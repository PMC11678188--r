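# Significant local extrema of a derivative spectrum: indices of interior
# local maxima/minima whose magnitude exceeds `frac` of the global extreme.
.localExtrema <- function(y, frac = 0.1) {
  n <- length(y)
  i <- 2:(n - 1)
  mx <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > frac * max(y)]
  mn <- i[y[i] < y[i - 1] & y[i] <= y[i + 1] & y[i] < frac * min(y)]
  list(maxima = mx, minima = mn)
}

#' Lineshape observables of a first-derivative nitroxide spectrum
#'
#' Computes the classical packing and mobility proxies: `twoAmax`, the
#' outer hyperfine splitting (field of the high-field minimum minus the
#' field of the low-field maximum, both parabolically refined; NA when the
#' outer extrema are not resolved) and `dH0`, the peak-to-peak width of
#' the central derivative line around its zero crossing. The central
#' crossing field is reported as well.
#'
#' @param spec an [EsrSpectrum-class] with a resolvable central line.
#' @return list with elements `twoAmax`, `dH0`, `centralCrossing` (gauss).
#' @export
lineshapeMetrics <- function(spec) {
  stopifnot(is(spec, "EsrSpectrum"))
  B <- spec@field; y <- spec@intensity
  n <- length(B)
  span <- max(B) - min(B)
  # central line: the downward (+ to -) zero crossing nearest the middle
  # of the field range, flanked by its own derivative extrema
  down <- which(y[-n] > 0 & y[-1] <= 0)
  midLo <- min(B) + span / 3
  midHi <- max(B) - span / 3
  down <- down[B[down] >= midLo & B[down] <= midHi]
  if (!length(down))
    stop("no zero crossing in the central third of the field range")
  ic <- down[which.min(abs(B[down] - (min(B) + span / 2)))]
  crossing <- B[ic] + (0 - y[ic]) * (B[ic + 1] - B[ic]) /
    (y[ic + 1] - y[ic])
  i <- 2:(n - 1)
  locMax <- i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
  locMin <- i[y[i] < y[i - 1] & y[i] <= y[i + 1]]
  imax <- locMax[locMax <= ic]
  imin <- locMin[locMin > ic]
  if (!length(imax) || !length(imin))
    stop("central line extrema not resolved")
  imax <- imax[length(imax)]       # nearest max below the crossing
  imin <- imin[1]                  # nearest min above the crossing
  pmax <- .refineExtremum(B, y, imax)
  pmin <- .refineExtremum(B, y, imin)
  dH0 <- pmin[1] - pmax[1]
  ext <- .localExtrema(y)
  twoAmax <- NA_real_
  if (length(ext$maxima) && length(ext$minima)) {
    iLo <- min(ext$maxima)          # low-field maximum
    iHi <- max(ext$minima)          # high-field minimum
    if (B[iHi] > B[iLo])
      twoAmax <- .refineExtremum(B, y, iHi)[1] - .refineExtremum(B, y, iLo)[1]
  }
  list(twoAmax = twoAmax, dH0 = dH0, centralCrossing = crossing)
}

#' Fit a single three-line component to a spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt) over centre field,
#' hyperfine spacing, the three linewidths, amplitude and Gaussian
#' fraction of a [NitroxideComponent-class]. Non-convergence is flagged in
#' the result rather than raised.
#'
#' @param spec an [EsrSpectrum-class].
#' @param init a [NitroxideComponent-class] starting model whose centre
#'   lies within the field range.
#' @return list with elements `model` (the fitted component),
#'   `residualRms`, `converged` (logical) and `info` (solver message).
#' @export
fitSingleComponent <- function(spec, init) {
  stopifnot(is(spec, "EsrSpectrum"), is(init, "NitroxideComponent"))
  B <- spec@field; y <- spec@intensity
  if (init@centerField < min(B) || init@centerField > max(B))
    stop("init centre field outside the spectrum range")
  par0 <- c(center = init@centerField, A = init@hyperfineA,
            w1 = init@widths[1], w2 = init@widths[2], w3 = init@widths[3],
            amp = init@amplitude, gf = init@gaussFraction)
  lower <- c(min(B), 0.5, 0.05, 0.05, 0.05, -Inf, 0)
  upper <- c(max(B), (max(B) - min(B)) / 2, rep(50, 3), Inf, 1)
  modelFn <- function(p) {
    centers <- p[1] + c(-1, 0, 1) * p[2]
    out <- numeric(length(B))
    for (i in 1:3)
      out <- out + .pvDeriv(B - centers[i], p[2 + i], p[7])
    p[6] * out
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = function(p) y - modelFn(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300))
  p <- fit$par
  model <- nitroxideComponent(centerField = p[[1]], hyperfineA = p[[2]],
                              widths = c(p[[3]], p[[4]], p[[5]]),
                              amplitude = p[[6]], gaussFraction = p[[7]])
  list(model = model,
       residualRms = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:4,
       info = fit$message)
}

# Non-negative least squares for two basis columns: try the unconstrained
# 2x2 solution, fall back to the better single-basis solution when a
# weight goes negative.
.nnls2 <- function(y, b1, b2) {
  G <- rbind(c(sum(b1 * b1), sum(b1 * b2)), c(sum(b2 * b1), sum(b2 * b2)))
  rhs <- c(sum(b1 * y), sum(b2 * y))
  w <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
  if (all(w >= 0)) return(w)
  w1 <- max(rhs[1] / G[1, 1], 0)
  w2 <- max(rhs[2] / G[2, 2], 0)
  r1 <- sum((y - w1 * b1)^2)
  r2 <- sum((y - w2 * b2)^2)
  if (r1 <= r2) c(w1, 0) else c(0, w2)
}

.resample <- function(basis, field) {
  stats::approx(basis@field, basis@intensity, xout = field, rule = 2)$y
}

#' Decompose a spectrum into two basis components
#'
#' Solves a non-negative least-squares problem for the weights of two
#' basis spectra after scaling each basis to unit double integral
#' (absorption area), so the normalised weights are spin-count population
#' fractions: P_i = w_i / (w1 + w2). Optionally a rigid field shift of the
#' bases (bounded to +/- 2 G, estimated by cross-correlation with the
#' equal-weight basis sum, ties broken toward the smallest shift) aligns
#' for small field-calibration offsets. Near-collinear bases are rejected
#' as unidentifiable.
#'
#' @param spec target [EsrSpectrum-class].
#' @param basisOrdered,basisDisordered basis [EsrSpectrum-class] objects
#'   (resampled onto the target grid).
#' @param allowShift logical, enable the rigid alignment (default FALSE).
#' @return list with elements `pOrdered`, `pDisordered`, `residualRms`,
#'   `shift` (gauss).
#' @export
decomposeTwoComponents <- function(spec, basisOrdered, basisDisordered,
                                   allowShift = FALSE) {
  stopifnot(is(spec, "EsrSpectrum"))
  B <- spec@field; y <- spec@intensity
  b1 <- .resample(basisOrdered, B)
  b2 <- .resample(basisDisordered, B)
  a1 <- .absorptionArea(B, b1)
  a2 <- .absorptionArea(B, b2)
  if (a1 <= 0 || a2 <= 0) stop("basis spectra must have positive absorption area")
  b1 <- b1 / a1
  b2 <- b2 / a2
  cs <- sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2))
  if (cs > 0.999) stop("basis spectra are collinear (cosine > 0.999): unidentifiable")
  shift <- 0
  if (allowShift) {
    step <- stats::median(diff(B))
    lags <- seq(-2, 2, by = step)
    ref <- (b1 + b2) / 2
    score <- vapply(lags, function(s) {
      rs <- stats::approx(B + s, ref, xout = B, rule = 2)$y
      sum(rs * y) / sqrt(sum(rs^2))
    }, numeric(1))
    best <- max(score)
    cand <- lags[score >= best - 1e-12]
    shift <- cand[which.min(abs(cand))]
    if (shift != 0) {
      b1 <- stats::approx(B + shift, b1, xout = B, rule = 2)$y
      b2 <- stats::approx(B + shift, b2, xout = B, rule = 2)$y
    }
  }
  w <- .nnls2(y, b1, b2)
  if (sum(w) <= 0) stop("degenerate decomposition: zero total weight")
  resid <- y - w[1] * b1 - w[2] * b2
  list(pOrdered = w[1] / sum(w), pDisordered = w[2] / sum(w),
       residualRms = sqrt(mean(resid^2)), shift = shift)
}

#' Nested-model F-test for a second spectral component
#'
#' Formalises "the second component substantially improves the fit": an
#' F-test on the residual sums of squares of the nested one- and
#' two-component fits of the same spectrum. Returns TRUE (prefer two)
#' when p < alpha; a two-component fit that is no better than the
#' one-component fit returns FALSE by construction.
#'
#' @param residual1,residual2 root-mean-square residuals of the one- and
#'   two-component fits.
#' @param nPoints number of spectrum points.
#' @param extraParams numerator degrees of freedom: parameters added by
#'   the second component.
#' @param baseParams parameters of the one-component model (default 7:
#'   centre, hyperfine, three widths, amplitude, Gaussian fraction).
#' @param alpha significance level (default 0.01).
#' @return logical.
#' @export
preferTwoComponents <- function(residual1, residual2, nPoints,
                                extraParams, baseParams = 7,
                                alpha = 0.01) {
  if (residual2 >= residual1) return(FALSE)
  rss1 <- nPoints * residual1^2
  rss2 <- nPoints * residual2^2
  df2 <- nPoints - baseParams - extraParams
  if (df2 <= 0) return(FALSE)
  if (rss2 <= .Machine$double.xmin) return(rss1 > rss2)
  Fstat <- ((rss1 - rss2) / extraParams) / (rss2 / df2)
  stats::pf(Fstat, extraParams, df2, lower.tail = FALSE) < alpha
}

#' Build a population series from a temperature series of spectra
#'
#' Decomposes every spectrum of a temperature series into the ordered and
#' disordered basis components. With the "endpoints" strategy the coldest
#' and hottest spectra serve as the pure ordered and disordered bases
#' (outside the coexistence window the spectra are single-component).
#' Temperatures where the two-component model does not significantly beat
#' the better single-basis fit (nested F-test at `alpha`) are assigned
#' P = 0 or 1. Spectra whose decomposition fails propagate as NA rows.
#'
#' @param spectra list of [EsrSpectrum-class] with temperatures set; at
#'   least 5.
#' @param basisStrategy "endpoints" or "supplied".
#' @param basisOrdered,basisDisordered bases when `basisStrategy =
#'   "supplied"`.
#' @param allowShift passed to [decomposeTwoComponents()].
#' @param alpha significance level of the single-vs-two component test.
#' @return a [PopulationSeries-class] sorted by temperature.
#' @export
buildPopulationSeries <- function(spectra,
                                  basisStrategy = c("endpoints", "supplied"),
                                  basisOrdered = NULL,
                                  basisDisordered = NULL,
                                  allowShift = FALSE, alpha = 0.01) {
  basisStrategy <- match.arg(basisStrategy)
  stopifnot(length(spectra) >= 5)
  Ts <- vapply(spectra, temperature, numeric(1))
  if (anyNA(Ts)) stop("all spectra must carry a temperature")
  o <- order(Ts)
  spectra <- spectra[o]; Ts <- Ts[o]
  if (basisStrategy == "endpoints") {
    basisOrdered <- spectra[[1]]
    basisDisordered <- spectra[[length(spectra)]]
  } else if (is.null(basisOrdered) || is.null(basisDisordered)) {
    stop("supplied strategy needs both basis spectra")
  }
  n <- length(spectra)
  pOrd <- pDis <- rms <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dec <- tryCatch(
      decomposeTwoComponents(spectra[[i]], basisOrdered, basisDisordered,
                             allowShift = allowShift),
      error = function(e) NULL)
    if (is.null(dec)) {
      warning(sprintf("decomposition failed at T = %.2f K", Ts[i]))
      next
    }
    B <- spectra[[i]]@field; y <- spectra[[i]]@intensity
    sing <- function(basis) {
      b <- .resample(basis, B)
      b <- b / .absorptionArea(B, b)
      w <- max(sum(b * y) / sum(b * b), 0)
      sqrt(mean((y - w * b)^2))
    }
    r1 <- min(sing(basisOrdered), sing(basisDisordered))
    if (!preferTwoComponents(r1, dec$residualRms, length(y),
                             extraParams = 1, baseParams = 1,
                             alpha = alpha)) {
      one <- sing(basisOrdered) <= sing(basisDisordered)
      pOrd[i] <- as.numeric(one); pDis[i] <- as.numeric(!one)
      rms[i] <- r1
    } else {
      pOrd[i] <- dec$pOrdered; pDis[i] <- dec$pDisordered
      rms[i] <- dec$residualRms
    }
  }
  populationSeries(Ts, pOrdered = pOrd, pDisordered = pDis,
                   residualRms = rms)
}

#' Order parameter from an orienting potential
#'
#' Evaluates S = <D^2_00> = Int D^2_00 exp(-U/kT) dOmega / Int exp(-U/kT)
#' dOmega for the Wigner-expansion potential of
#' [OrderingPotential-class], with -U/kT = c20 D^2_00 + c22 (D^2_02 +
#' D^2_0-2) + c40 D^4_00 + c42 (D^4_02 + D^4_0-2) + c44 (D^4_04 +
#' D^4_0-4). Quadrature is Gauss-Legendre in cos(theta) crossed with a
#' uniform phi rule; the phi integral is skipped when no phi-dependent
#' coefficient is present. S is bounded in (-0.5, 1).
#'
#' @param pot an [OrderingPotential-class] (or a bare numeric c20 for
#'   convenience).
#' @param nodesTheta Gauss-Legendre nodes in cos(theta) (>= 64,
#'   default 256).
#' @param nodesPhi uniform phi nodes (default 128).
#' @return numeric scalar S.
#' @examples
#' orderParameter(orderingPotential(c20 = 2))  # ~ 0.439
#' @export
orderParameter <- function(pot, nodesTheta = 256, nodesPhi = 128) {
  if (is.numeric(pot)) pot <- orderingPotential(c20 = pot)
  stopifnot(is(pot, "OrderingPotential"), nodesTheta >= 64)
  validObject(pot)
  gl <- pracma::gaussLegendre(nodesTheta, -1, 1)
  x <- gl$x; wx <- gl$w
  d200 <- (3 * x^2 - 1) / 2
  d400 <- (35 * x^4 - 30 * x^2 + 3) / 8
  phiDep <- pot@c22 != 0 || pot@c42 != 0 || pot@c44 != 0
  if (!phiDep) {
    f <- pot@c20 * d200 + pot@c40 * d400
    if (any(!is.finite(f))) stop("non-finite potential values")
    f <- f - max(f)
    w <- wx * exp(f)
    return(sum(w * d200) / sum(w))
  }
  phi <- (seq_len(nodesPhi) - 0.5) * (2 * pi / nodesPhi)
  # real combinations D^L_02 + D^L_0-2 = 2 d^L_02 cos(2 phi), etc.
  d202 <- sqrt(6) / 4 * (1 - x^2)
  d402 <- sqrt(10) / 8 * (1 - x^2) * (7 * x^2 - 1)
  d404 <- sqrt(70) / 16 * (1 - x^2)^2
  f <- outer(pot@c20 * d200 + pot@c40 * d400, rep(1, nodesPhi)) +
    outer(2 * pot@c22 * d202 + 2 * pot@c42 * d402, cos(2 * phi)) +
    outer(2 * pot@c44 * d404, cos(4 * phi))
  if (any(!is.finite(f))) stop("non-finite potential values")
  f <- f - max(f)
  W <- exp(f) * wx            # column-recycled theta weights
  sum(W * d200) / sum(W)
}
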