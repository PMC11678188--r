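test_that("ln K table follows the population ratio and the Kp shift", {
  ps <- populationSeries(c(300, 305, 310), pOrdered = c(0.5, 0.2, 0.5))
  tbl <- lnEquilibriumConstant(ps)
  expect_equal(tbl$lnK[1], 0)
  expect_equal(tbl$lnK[2], log(4))
  tbl2 <- lnEquilibriumConstant(ps, kp = 2)
  expect_equal(tbl2$lnK - tbl$lnK, rep(log(2), 3))
})

test_that("near-pure temperatures are excluded before the log", {
  ps <- populationSeries(c(300, 302, 304, 306),
                         pOrdered = c(1, 0.99, 0.6, 0.01))
  tbl <- lnEquilibriumConstant(ps, exclusionThreshold = 0.02)
  expect_equal(tbl$temperatureK, 304)
  expect_equal(nrow(attr(tbl, "excluded")), 3)
  expect_error(lnEquilibriumConstant(
    populationSeries(c(300, 305), pOrdered = c(1, 0))), "excluded")
})

test_that("polynomial fit reproduces exact data and degenerates cleanly", {
  Ts <- seq(290, 315, length.out = 20)
  tbl0 <- data.frame(invT = 1 / Ts, lnK = rep(0, 20))
  m0 <- fitVantHoff(tbl0, 3)
  expect_equal(unname(coef(m0)), rep(0, 4))
  co <- c(a = 12.0, b = -7.5e3, c = 1.2e6, d = -6.0e7)
  tbl <- data.frame(invT = 1 / Ts, lnK = lnKLaw(as.list(co), Ts))
  m <- fitVantHoff(tbl, 3)
  expect_lt(max(abs(coef(m) - co) / abs(co)), 1e-6)
  expect_error(fitVantHoff(tbl[1:4, ], 3), "degree \\+ 2")
})

test_that("adjusted R2 of an underfit degree is lower than the true degree's", {
  Ts <- seq(290, 315, length.out = 20)
  co <- list(a = 12.0, b = -7.5e3, c = 1.2e6, d = -6.0e7)
  set.seed(8)
  tbl <- data.frame(invT = 1 / Ts,
                    lnK = lnKLaw(co, Ts) + rnorm(20, 0, 1e-4))
  expect_lt(fitVantHoff(tbl, 1)@adjR2, fitVantHoff(tbl, 3)@adjR2)
})

test_that("degree selection keeps linear data linear and flags real curvature", {
  Ts <- seq(290, 315, length.out = 20)
  set.seed(12)
  lin <- data.frame(invT = 1 / Ts,
                    lnK = 2 - 1500 / Ts + rnorm(20, 0, 0.01))
  expect_equal(selectDegree(lin), 1L)
  flat <- data.frame(invT = 1 / Ts, lnK = rep(1.5, 20))
  expect_equal(selectDegree(flat), 1L)   # exact ties resolve downward
  cub <- data.frame(invT = 1 / Ts,
                    lnK = lnKLaw(as.list(dppcVantHoffCoefficients()), Ts))
  expect_equal(selectDegree(cub), 3L)
})

test_that("thermodynamic curves obey the closed forms of a linear model", {
  Ts <- seq(295, 315, length.out = 10)
  tbl <- data.frame(invT = 1 / Ts, lnK = 3 - 4400 / Ts)
  m <- fitVantHoff(tbl, 1)
  cv <- thermodynamicCurves(m, seq(296, 314, length.out = 101))
  R <- 1.987204
  expect_equal(unique(round(curvesTable(cv)$dH, 6)),
               round(R * 4400, 6))           # -R b = +8.74 kcal/mol
  expect_equal(unique(round(curvesTable(cv)$dS, 8)), round(R * 3, 8))
  expect_equal(unique(curvesTable(cv)$dC), 0)
})

test_that("dG = dH - T dS and the derivative identities hold on a cubic model", {
  ser <- generateTwoComponentSeries(seriesSpec())
  tbl <- lnEquilibriumConstant(ser$populations)
  m <- fitVantHoff(tbl, 3)
  cv <- thermodynamicCurves(m)
  ct <- curvesTable(cv)
  expect_lt(max(abs(ct$dG - (ct$dH - ct$temperatureK * ct$dS))),
            1e-6 * max(abs(ct$dH)))
  # finite differences at 0.01 K vs the analytic dS and dC
  Tm <- seq(min(ct$temperatureK) + 0.5, max(ct$temperatureK) - 0.5,
            length.out = 25)
  h <- 0.01
  up <- curvesTable(thermodynamicCurves(m, Tm + h))
  dn <- curvesTable(thermodynamicCurves(m, Tm - h))
  at <- curvesTable(thermodynamicCurves(m, Tm))
  fdS <- -(up$dG - dn$dG) / (2 * h)
  fdC <- (up$dH - dn$dH) / (2 * h)
  # relative to the curve scale (dS and dC both cross zero on the grid)
  expect_lt(max(abs(fdS - at$dS)) / max(abs(at$dS)), 1e-4)
  expect_lt(max(abs(fdC - at$dC)) / max(abs(at$dC)), 1e-4)
})

test_that("special temperatures are genuine roots", {
  ser <- generateTwoComponentSeries(seriesSpec(
    temperatures = c(296, 298, seq(300, 315.5, length.out = 25), 316.5, 318),
    coexWindow = c(299.5, 315.9)))
  tbl <- lnEquilibriumConstant(ser$populations)
  m <- fitVantHoff(tbl, 3)
  cv <- thermodynamicCurves(m)
  sp <- specialTemperatures(cv)
  gRoots <- sp$tempK[sp$kind == "G_root"]
  expect_gte(length(gRoots), 1)
  for (Tr in gRoots) {
    at <- curvesTable(thermodynamicCurves(m, Tr))
    expect_lt(abs(at$dG), 1e-5)
    # the generator's design melting point sits at 314.15 K
  }
  expect_true(any(abs(gRoots - 314.15) < 0.3))
})

test_that("S-zero temperatures of generic models separate dS signs", {
  # dS = R (a - c u^2 - 2 d u^3): plant a simple root at a random interior
  # temperature by solving for a, then check each reported S_zero is a
  # verified sign change
  set.seed(77)
  found <- 0L
  for (i in 1:10) {
    T0 <- runif(1, 302, 313)
    u0 <- 1 / T0
    cc <- runif(1, 2.5, 4.5) * 1e10
    dd <- runif(1, -4, -2.5) * 1e12
    co <- c(a = cc * u0^2 + 2 * dd * u0^3, b = runif(1, -2, -1) * 1e8,
            c = cc, d = dd)
    Ts <- seq(295, 320, length.out = 30)
    tbl <- data.frame(invT = 1 / Ts, lnK = lnKLaw(as.list(co), Ts))
    m <- fitVantHoff(tbl, 3)
    sp <- specialTemperatures(thermodynamicCurves(m))
    sz <- sp$tempK[sp$kind == "S_zero"]
    expect_true(any(abs(sz - T0) < 0.05))
    for (Tr in sz) {
      if (Tr - 0.05 < min(Ts) || Tr + 0.05 > max(Ts)) next
      lo <- curvesTable(thermodynamicCurves(m, Tr - 0.05))$dS
      hi <- curvesTable(thermodynamicCurves(m, Tr + 0.05))$dS
      expect_lt(lo * hi, 0)
      found <- found + 1L
    }
  }
  expect_gte(found, 10L)
})

test_that("compensation analysis matches an independent regression oracle", {
  ser <- generateTwoComponentSeries(seriesSpec())
  tbl <- lnEquilibriumConstant(ser$populations)
  m <- fitVantHoff(tbl, 3)
  cv <- thermodynamicCurves(m)
  comp <- compensationAnalysis(cv)
  ct <- curvesTable(cv)
  oracle <- twoPassRegression(ct$dS, ct$dH)
  expect_lt(abs(comp$slope - oracle["slope"]) /
              abs(oracle["slope"]), 1e-9)
  expect_lt(abs(comp$intercept - oracle["intercept"]) /
              max(abs(oracle["intercept"]), 1), 1e-9)
})

test_that("dG == 0 curves compensate exactly with slope one in T dS", {
  Ts <- seq(295, 315, length.out = 40)
  expect_error(compensationAnalysis(
    thermodynamicCurves(fitVantHoff(
      data.frame(invT = 1 / Ts, lnK = 3 - 4400 / Ts), 1))),
    "constant dS")
  # synthetic exactly-compensating curves: dG = 0, dH = T dS pointwise
  ser <- generateTwoComponentSeries(seriesSpec())
  m <- fitVantHoff(lnEquilibriumConstant(ser$populations), 3)
  ct <- curvesTable(thermodynamicCurves(m))
  dSsyn <- ct$dS + 0.3 * sin(seq(0, 3, length.out = nrow(ct)))
  dHsyn <- ct$temperatureK * dSsyn
  cvSyn <- new("ThermoCurves", tGrid = ct$temperatureK, dG = dHsyn * 0,
               dH = dHsyn, dS = dSsyn, dC = dHsyn * 0,
               special = data.frame(kind = character(),
                                    tempK = numeric()))
  compSyn <- compensationAnalysis(cvSyn)
  expect_equal(compSyn$slopeTdS, 1, tolerance = 1e-9)
  expect_equal(compSyn$interceptTdS, 0, tolerance = 1e-6)
})

test_that("restricting the grid moves the compensation slope within the dG bound", {
  ser <- generateTwoComponentSeries(seriesSpec())
  tbl <- lnEquilibriumConstant(ser$populations)
  m <- fitVantHoff(tbl, 3)
  full <- thermodynamicCurves(m)
  tr <- model_range <- m@tRange
  half <- thermodynamicCurves(m, seq(tr[1], mean(tr), length.out = 256))
  cF <- compensationAnalysis(full)
  cH <- compensationAnalysis(half)
  ctF <- curvesTable(full)
  bound <- max(abs(ctF$dG)) / min(abs(ctF$dS[ctF$dS != 0]))
  expect_lt(abs(cH$compensationT - cF$compensationT), bound)
})

test_that("bootstrap bands are deterministic, collapse at zero noise, and cover the truth", {
  Ts <- seq(300, 313.2, length.out = 25)
  truth <- dppcVantHoffCoefficients()
  tbl0 <- data.frame(invT = 1 / Ts, lnK = lnKLaw(as.list(truth), Ts))
  m0 <- fitVantHoff(tbl0, 3)
  b0 <- bootstrapUncertainty(tbl0, m0, nBoot = 200, seed = 3L)
  # zero width up to float round-off of the exact fit
  expect_lt(max(b0$bands$dH["hi", ] - b0$bands$dH["lo", ]),
            1e-6 * max(abs(b0$bands$dH)))
  set.seed(21)
  tbl <- data.frame(invT = 1 / Ts,
                    lnK = lnKLaw(as.list(truth), Ts) + rnorm(25, 0, 0.05))
  m <- fitVantHoff(tbl, 3)
  b1 <- bootstrapUncertainty(tbl, m, nBoot = 300, seed = 9L)
  b2 <- bootstrapUncertainty(tbl, m, nBoot = 300, seed = 9L)
  expect_identical(b1, b2)
  expect_true(all(b1$coefBands["lo", ] <= truth &
                    truth <= b1$coefBands["hi", ]))
})

test_that("nominal 95 percent dH bands achieve close-to-nominal pointwise coverage", {
  Ts <- seq(300, 313.2, length.out = 25)
  truth <- dppcVantHoffCoefficients()
  base <- lnKLaw(as.list(truth), Ts)
  probes <- c(302, 306.5, 311)
  trueDH <- curvesTable(thermodynamicCurves(
    fitVantHoff(data.frame(invT = 1 / Ts, lnK = base), 3), probes))$dH
  set.seed(31)
  cover <- matrix(FALSE, 200, length(probes))
  for (r in 1:200) {
    tbl <- data.frame(invT = 1 / Ts, lnK = base + rnorm(25, 0, 0.05))
    m <- fitVantHoff(tbl, 3)
    bb <- bootstrapUncertainty(tbl, m, nBoot = 200, seed = r,
                               tGrid = probes)
    cover[r, ] <- bb$bands$dH["lo", ] <= trueDH &
      trueDH <= bb$bands$dH["hi", ]
  }
  cv <- colMeans(cover)
  expect_true(all(cv >= 0.90 & cv <= 0.99))
})
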