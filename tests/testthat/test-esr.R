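test_that("lineshape metrics read splitting and central width off a synthetic spectrum", {
  grid <- seq(3270, 3430, by = 0.05)
  # narrow outer lines: the derivative extrema sit half a linewidth
  # outside the line centres, so the splitting reads 2A + O(width)
  sp <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 17, widths = c(0.3, 1.6, 0.3)), grid)
  m <- lineshapeMetrics(sp)
  expect_lt(abs(m$twoAmax - 34), 0.5)
  expect_lt(abs(m$dH0 - 1.6), 0.05)
  expect_lt(abs(m$centralCrossing - 3350), 0.05)
})

test_that("lineshape metrics are invariant under a field-axis shift", {
  grid <- seq(3270, 3430, length.out = 4096)
  sp <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 17, widths = c(1, 1.6, 1)), grid)
  sh <- esrSpectrum(fieldAxis(sp) + 5, intensities(sp))
  m0 <- lineshapeMetrics(sp)
  m5 <- lineshapeMetrics(sh)
  expect_equal(m5$twoAmax, m0$twoAmax)
  expect_equal(m5$dH0, m0$dH0)
  expect_equal(m5$centralCrossing, m0$centralCrossing + 5)
})

test_that("spectra without a central crossing are rejected", {
  grid <- seq(3300, 3400, length.out = 512)
  expect_error(lineshapeMetrics(esrSpectrum(grid, rep(1, 512))),
               "central")
})

test_that("single-component fit started at the truth is a fixed point", {
  grid <- seq(3300, 3400, length.out = 1024)
  truth <- nitroxideComponent(hyperfineA = 15, widths = c(1.8, 1.6, 2.0),
                              amplitude = 2.5, gaussFraction = 0.4)
  sp <- generateNitroxideSpectrum(truth, grid)
  fit <- fitSingleComponent(sp, truth)
  expect_true(fit$converged)
  expect_lt(fit$residualRms, 1e-10)
  expect_lt(abs(fit$model@hyperfineA - 15) / 15, 1e-6)
  expect_lt(abs(fit$model@amplitude - 2.5) / 2.5, 1e-6)
  expect_lt(max(abs(fit$model@widths - c(1.8, 1.6, 2.0))), 1e-5)
})

test_that("a one-component fit of a mixture is worse than the two-component fit", {
  grid <- seq(3300, 3400, length.out = 1024)
  ord <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 20, widths = c(5, 5, 6),
                       gaussFraction = 0.5), grid)
  dis <- generateNitroxideSpectrum(nitroxideComponent(), grid)
  yo <- intensities(ord); yd <- intensities(dis)
  mix <- esrSpectrum(grid, 0.5 * yo / max(abs(yo)) + 0.5 * yd / max(abs(yd)))
  one <- fitSingleComponent(mix, nitroxideComponent(hyperfineA = 17,
                                                    widths = c(3, 3, 3)))
  two <- decomposeTwoComponents(mix, ord, dis)
  expect_gt(one$residualRms, two$residualRms)
})

test_that("a fit to pure noise is flagged or collapses to zero amplitude", {
  grid <- seq(3300, 3400, length.out = 512)
  set.seed(1)
  sp <- esrSpectrum(grid, rnorm(512, 0, 1))
  fit <- fitSingleComponent(sp, nitroxideComponent())
  expect_true(!fit$converged ||
                abs(fit$model@amplitude) < 0.05 ||
                fit$residualRms > 0.9 * sd(intensities(sp)))
})

test_that("noiseless decomposition of a constructed mixture is exact", {
  grid <- seq(3300, 3400, length.out = 1024)
  ord <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 20, widths = c(5, 5, 6),
                       gaussFraction = 0.5), grid)
  dis <- generateNitroxideSpectrum(nitroxideComponent(), grid)
  # area-normalised mixture at 0.30 / 0.70
  nrm <- function(s) intensities(s) /
    pracma::trapz(grid, as.numeric(pracma::cumtrapz(grid, intensities(s))))
  mix <- esrSpectrum(grid, 0.30 * nrm(ord) + 0.70 * nrm(dis))
  dec <- decomposeTwoComponents(mix, ord, dis)
  expect_lt(abs(dec$pOrdered - 0.30), 1e-6)
  expect_lt(abs(dec$pDisordered - 0.70), 1e-6)
  # pure component maps to (1, 0)
  pure <- decomposeTwoComponents(ord, ord, dis)
  expect_equal(pure$pOrdered, 1)
  expect_equal(pure$pDisordered, 0)
})

test_that("decomposition weights are invariant to basis rescaling", {
  grid <- seq(3300, 3400, length.out = 1024)
  ord <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 20, widths = c(5, 5, 6)), grid)
  dis <- generateNitroxideSpectrum(nitroxideComponent(), grid)
  nrm <- function(s) intensities(s) /
    pracma::trapz(grid, as.numeric(pracma::cumtrapz(grid, intensities(s))))
  mix <- esrSpectrum(grid, 0.4 * nrm(ord) + 0.6 * nrm(dis))
  d1 <- decomposeTwoComponents(mix, ord, dis)
  d2 <- decomposeTwoComponents(
    mix, esrSpectrum(grid, 3.7 * intensities(ord)),
    esrSpectrum(grid, 0.21 * intensities(dis)))
  expect_equal(d1$pOrdered, d2$pOrdered, tolerance = 1e-10)
})

test_that("collinear bases are rejected as unidentifiable", {
  grid <- seq(3300, 3400, length.out = 1024)
  ord <- generateNitroxideSpectrum(nitroxideComponent(), grid)
  near <- esrSpectrum(grid, 1.01 * intensities(ord))
  mix <- esrSpectrum(grid, intensities(ord))
  expect_error(decomposeTwoComponents(mix, ord, near), "collinear")
})

test_that("noisy decomposition recovers fractions within 0.02 at SNR 50", {
  grid <- seq(3300, 3400, length.out = 1024)
  ord <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 20, widths = c(5, 5, 6),
                       gaussFraction = 0.5), grid)
  dis <- generateNitroxideSpectrum(nitroxideComponent(), grid)
  nrm <- function(s) intensities(s) /
    pracma::trapz(grid, as.numeric(pracma::cumtrapz(grid, intensities(s))))
  yo <- nrm(ord); yd <- nrm(dis)
  set.seed(99)
  err <- replicate(60, {
    p <- runif(1, 0.05, 0.95)
    y <- (1 - p) * yo + p * yd
    y <- y + rnorm(length(y), 0, max(abs(y)) / 50)
    dec <- decomposeTwoComponents(esrSpectrum(grid, y), ord, dis)
    abs(dec$pDisordered - p)
  })
  expect_gte(mean(err <= 0.02), 0.95)
})

test_that("shift alignment absorbs a small field-calibration offset", {
  grid <- seq(3300, 3400, length.out = 2048)
  ord <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 20, widths = c(5, 5, 6),
                       gaussFraction = 0.5), grid)
  dis <- generateNitroxideSpectrum(nitroxideComponent(), grid)
  nrm <- function(s) intensities(s) /
    pracma::trapz(grid, as.numeric(pracma::cumtrapz(grid, intensities(s))))
  yMix <- 0.35 * nrm(ord) + 0.65 * nrm(dis)
  # spectrum recorded 0.8 G off the basis calibration
  shifted <- esrSpectrum(grid, approx(grid - 0.8, yMix, xout = grid,
                                      rule = 2)$y)
  d0 <- decomposeTwoComponents(shifted, ord, dis)
  d1 <- decomposeTwoComponents(shifted, ord, dis, allowShift = TRUE)
  expect_lt(abs(d1$pDisordered - 0.65), abs(d0$pDisordered - 0.65))
  expect_lt(abs(abs(d1$shift) - 0.8), 0.15)
})

test_that("the component F-test prefers two only when they genuinely help", {
  expect_false(preferTwoComponents(0.1, 0.1, 1024, 1))
  expect_false(preferTwoComponents(0.1, 0.2, 1024, 1))
  expect_true(preferTwoComponents(0.1, 1e-16, 1024, 1))
  # mixture at SNR 50: second component detected
  grid <- seq(3300, 3400, length.out = 1024)
  ord <- generateNitroxideSpectrum(
    nitroxideComponent(hyperfineA = 20, widths = c(5, 5, 6),
                       gaussFraction = 0.5), grid)
  dis <- generateNitroxideSpectrum(nitroxideComponent(), grid)
  nrm <- function(s) intensities(s) /
    pracma::trapz(grid, as.numeric(pracma::cumtrapz(grid, intensities(s))))
  yo <- nrm(ord); yd <- nrm(dis)
  set.seed(4)
  y <- 0.5 * yo + 0.5 * yd
  y <- y + rnorm(length(y), 0, max(abs(y)) / 50)
  dec <- decomposeTwoComponents(esrSpectrum(grid, y), ord, dis)
  b <- yo / sqrt(sum(yo^2))
  r1 <- sqrt(mean((y - sum(b * y) * b)^2))
  expect_true(preferTwoComponents(r1, dec$residualRms, length(y),
                                  extraParams = 1, baseParams = 1))
  # pure component at SNR 50: mostly not
  set.seed(5)
  falsePos <- replicate(200, {
    y <- yo + rnorm(length(yo), 0, max(abs(yo)) / 50)
    dec <- decomposeTwoComponents(esrSpectrum(grid, y), ord, dis)
    b1 <- yo / sqrt(sum(yo^2))
    r1 <- sqrt(mean((y - sum(b1 * y) * b1)^2))
    preferTwoComponents(r1, dec$residualRms, length(y),
                        extraParams = 1, baseParams = 1)
  })
  expect_gte(mean(!falsePos), 0.95)
})

test_that("population series round-trips the generator and is order-invariant", {
  ser <- generateTwoComponentSeries(seriesSpec())
  ps <- buildPopulationSeries(ser$spectra)
  truth <- populations(ser$populations)
  est <- populations(ps)
  expect_lt(max(abs(est$pDisordered - truth$pDisordered)), 1e-4)
  # shuffled input order gives the identical sorted series
  set.seed(2)
  psShuf <- buildPopulationSeries(sample(ser$spectra))
  expect_identical(populations(psShuf), est)
  # identical spectra give constant populations (with supplied bases)
  n <- length(ser$spectra)
  const <- buildPopulationSeries(lapply(1:6, function(i) {
    s <- ser$spectra[[10]]
    esrSpectrum(fieldAxis(s), intensities(s), temperature = 299 + i)
  }), basisStrategy = "supplied", basisOrdered = ser$spectra[[1]],
    basisDisordered = ser$spectra[[n]])
  expect_equal(length(unique(populations(const)$pDisordered)), 1)
})

test_that("order parameter matches the frozen quadrature oracle and its limits", {
  expect_lt(abs(orderParameter(orderingPotential(c20 = 2)) -
                  0.439278093865), 1e-8)
  expect_lt(abs(orderParameter(orderingPotential(0))), 1e-12)
  # strictly increasing in c20, bounded in (-0.5, 1)
  S <- vapply(c(-10, -4, -1, 0, 1, 4, 10), function(c20)
    orderParameter(orderingPotential(c20)), numeric(1))
  expect_true(all(diff(S) > 0))
  expect_true(all(S > -0.5 & S < 1))
  # node refinement changes nothing at 1e-8 for |c20| <= 10
  for (c20 in c(-10, -3, 3, 10))
    expect_lt(abs(orderParameter(orderingPotential(c20), nodesTheta = 256) -
                    orderParameter(orderingPotential(c20), nodesTheta = 512)),
              1e-8)
})

test_that("rhombic and rank-4 terms enter the potential", {
  s0 <- orderParameter(orderingPotential(c20 = 2))
  s22 <- orderParameter(orderingPotential(c20 = 2, c22 = 0.8))
  s40 <- orderParameter(orderingPotential(c20 = 2, c40 = 0.5))
  expect_false(isTRUE(all.equal(s0, s22)))
  expect_false(isTRUE(all.equal(s0, s40)))
  # a c22-only potential keeps theta ordering symmetric around S = 0
  expect_lt(abs(orderParameter(orderingPotential(c20 = 0, c22 = 1e-8))),
            1e-6)
})
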