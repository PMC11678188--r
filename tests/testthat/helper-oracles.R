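# Independent oracles, kept deliberately separate from the package's own
# numerical routes.

# Composite-Simpson quadrature for the uniaxial order parameter
# S = <(3cos^2 t - 1)/2> under weight exp(c20 (3cos^2 t - 1)/2) sin t.
simpsonOrderParameter <- function(c20, n = 20001) {
  th <- seq(0, pi, length.out = n)
  h <- th[2] - th[1]
  d200 <- (3 * cos(th)^2 - 1) / 2
  f1 <- d200 * exp(c20 * d200) * sin(th)
  f2 <- exp(c20 * d200) * sin(th)
  simp <- function(y) {
    m <- length(y)
    (h / 3) * (y[1] + y[m] + 4 * sum(y[seq(2, m - 1, 2)]) +
                 2 * sum(y[seq(3, m - 2, 2)]))
  }
  simp(f1) / simp(f2)
}

# Two-pass least-squares slope/intercept (textbook formulas).
twoPassRegression <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = sl, intercept = mean(y) - sl * mean(x))
}

# ln K polynomial of the van't Hoff law, direct evaluation.
lnKLaw <- function(co, T) co[["a"]] + co[["b"]] / T + co[["c"]] / T^2 +
  co[["d"]] / T^3

# A small noiseless DPPC-like thermogram for reuse in tests.
makeDppcThermogram <- function(noiseSd = 0, seed = 1L,
                               baselineCoeffs = 0, withPre = FALSE,
                               by = 0.005) {
  from <- if (withPre) 300.15 else 306.15   # room for the Tp Gaussian tail
  generateTwoStateThermogram(thermogramSpec(
    tm = 314.15, dHcal = 8.74, dHvH = 2930,
    tp = if (withPre) 307.15 else NA_real_,
    baselineCoeffs = baselineCoeffs, noiseSd = noiseSd,
    tGrid = seq(from, 322.15, by = by), seed = seed))
}
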