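---
title: "Methods: thermodynamics of gel–fluid coexistence from DSC and spin-label ESR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamics of gel-fluid coexistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoexTherm)
```

# The problem

Phosphatidylcholine bilayers melt from ordered gel phases (the tilted
Lβ′ gel and the rippled Pβ′ phase) to the fluid liquid-crystalline Lα
phase. Between a cold onset temperature and the main melting temperature
Tm, ordered and disordered lipid domains coexist, and a nitroxide
spin-label embedded in the membrane partitions between them, producing
ESR spectra that are superpositions of a broad (ordered) and a narrow
(disordered) component. DSC sees the same transition as an excess heat
capacity endotherm. CoexTherm turns both kinds of measurement into
thermodynamic parameters for the ordered→disordered lipid transfer, and
supplies a synthetic-data generator so every stage can be validated
against known ground truth.

# Models and procedures

## DSC thermogram analysis

After buffer subtraction and removal of a polynomial baseline fitted on
two windows flanking the peak (`subtractBaseline()`, default degree 1),
`analyzeThermogram()` reports, in the units calorimetric tables use
(°C, kcal/mol, cal mol⁻¹ K⁻¹):

* Tm — the Cp maximum in the main window, refined by a parabola through
  the three points around the discrete maximum. DSC grids are coarse
  relative to the ~0.02 °C precision of modern instruments, hence the
  refinement; the same refinement gives Cp,max.
* ΔHcal — composite-trapezoid integral of Cp over the main window (the
  behaviour of standard instrument software).
* ΔTm,½ — full width at half of Cp,max, with linear interpolation
  between the bracketing samples on each flank; reported as missing when
  a flank never crosses the half height rather than guessed.
* ΔS(Tm) = ΔHcal/Tm and ΔHvH = 4RTm²Cp,max/ΔHcal, with
  R = 1.987204 cal mol⁻¹ K⁻¹ everywhere; CUS = ΔHvH/ΔHcal is the
  average number of lipids melting as one cooperative unit.

`fitTmDepression()` fits the two-phase ligand-partitioning
melting-depression law 1/Tm(x) − 1/Tm₀ = (R/ΔH)·ln[(1+K_F x)/(1+K_G x)]
over the gel and fluid affinities by Levenberg–Marquardt on the log
scale. Two design points deserve note. First, the sign convention: a
ligand preferring the fluid phase (K_F > K_G) must depress Tm, which
fixes the fluid constant in the numerator; the functional form is
recorded in the result's `modelId` so alternatives can be added. Second,
the enthalpy scale ΔH is the *per-lipid molar* transition enthalpy
(~8.7 kcal/mol for DPPC): the classical colligative derivation is per
mole of melting lipid. Scaling by the cooperative-unit (van't Hoff)
enthalpy instead makes the prefactor R/ΔH three orders of magnitude
smaller and drives the constants to a degenerate boundary; the function
accepts either, but the molar scale is the physically meaningful choice.
A flat Tm series is reported as ratio 1 with infinite uncertainty rather
than a fit.

## ESR two-component decomposition

The populations of the two spin-label environments are obtained by
linear basis decomposition (`decomposeTwoComponents()`): each basis
spectrum is scaled to unit double integral — the absorption area, i.e.
the spin count — so the non-negative least-squares weights are directly
population fractions, P_i = w_i/(w₁+w₂). Normalising by area rather
than amplitude is what makes a broad and a narrow component comparable.
Weights are therefore invariant under arbitrary rescaling of either
basis. Near-collinear bases (cosine similarity > 0.999) are rejected as
unidentifiable. An optional rigid field shift (±2 G, estimated by
cross-correlation against the equal-weight basis sum, ties broken
toward the smallest shift) absorbs small field-calibration offsets.

`buildPopulationSeries()` applies this across a temperature series. By
default the coldest and hottest spectra serve as the pure ordered and
disordered bases ("endpoints" strategy), which presumes the series
extends beyond the coexistence window on both sides — outside it the
membrane is single-phase and the spectra are single-component. Whether
a second component is genuinely present at each temperature is decided
by a nested F-test on the residual sums of squares
(`preferTwoComponents()`, p < 0.01); temperatures where one basis
suffices are assigned P = 0 or 1. This basis-set decomposition stands
in for full slow-motion spectral simulation: the thermodynamic pipeline
needs only the fractions, and on lineshapes that truly are two-component
mixtures the linear decomposition is exact.

The orientational order parameter is computed from the orienting
pseudopotential U(Ω)/kT = −[c₂₀D²₀₀ + c₂₂(D²₀₂+D²₀₋₂) + rank-4 terms]
as S = ∫D²₀₀ e^(−U/kT) dΩ / ∫e^(−U/kT) dΩ (`orderParameter()`).
Quadrature is Gauss–Legendre in cosθ (default 256 nodes — the integrand
is smooth and even, and doubling the nodes changes S by < 1e-8 for
|c₂₀| ≤ 10) crossed with a uniform midpoint rule in φ (128 nodes),
skipped entirely when no φ-dependent coefficient is present. The
exponent is max-shifted before exponentiation so strongly ordering
potentials do not overflow. Rank-4 coefficients (c₄₀, c₄₂, c₄₄) are
implemented but default to zero, as spin-label fits rarely constrain
them. S is bounded in (−0.5, 1); the limits are approached only as
O(1/c₂₀) — at c₂₀ = ±50 the residual distances are ≈ 0.020 and ≈ 0.010.

## Non-linear van't Hoff analysis

With K = K_p·P_dis/P_ord = exp(−ΔG/RT), the van't Hoff plot ln K vs 1/T
is non-linear for lipid coexistence, and is modelled as a polynomial
ln K = a + b/T + c/T² + d/T³ (degree 1–3). From the fitted coefficients,
with u = 1/T:

* ΔG = −RT·lnK = −RT(a + bu + cu² + du³) (cal/mol),
* ΔH = −R·d(lnK)/du = −R(b + 2cu + 3du²),
* ΔS = (ΔH − ΔG)/T, equivalently R(a − cu² − 2du³),
* ΔC = ∂ΔH/∂T = R(2cu² + 6du³), the analytic derivative.

These satisfy ΔG = ΔH − TΔS identically and ∂ΔG/∂T = −ΔS, which the
test suite verifies by finite differences. Special temperatures — all
roots of ΔG (ln K = 0) and of ΔS (stationary points of ΔG) inside the
grid — are located by scanning a 0.01 K mesh for sign changes and
polishing each bracket by bisection; roots closer than 1e-3 K are
merged, which collapses the numerically split pair a parabola touching
zero produces.

Numerical choices in the fit (`fitVantHoff()`): u spans only ~1e-4 K⁻¹
across a melting window, so the design matrix is built on the centred,
sd-scaled variable z = (u − ū)/s and the coefficients (and covariance)
are mapped back to the raw basis through the binomial expansion. The
raw coefficients are individually huge (1e5–1e12) and cancel to order
unity; they are kept at full double precision throughout, since rounding
them to a few significant digits perturbs ln K by O(1).

Other choices:

* K_p (probe partition coefficient) defaults to 1 — the common
  assumption for chain-labelled phosphatidylcholines — and is exposed
  because deviations only shift ΔG and ΔS by R·ln K_p, not the shapes.
* Fractions below 0.02 on either side are excluded before taking logs
  (`lnEquilibriumConstant()`): the logit diverges at the window edges,
  and the analysis is only meaningful inside the coexistence window.
* Degree selection (`selectDegree()`): the highest candidate whose
  incremental F-test against the next-lower candidate has p < 0.01,
  with ties resolved toward the lower degree. DPPC-like series select
  cubic; a two-root mixture-like law selects quadratic.
* `bootstrapUncertainty()` uses the residual-resampling bootstrap with
  variance correction: raw least-squares residuals underestimate the
  error standard deviation by (n−p)/n, so residuals are inflated by
  √(n/(n−p)) before resampling. Without the correction, nominal 95 %
  bands measurably under-cover at the series lengths typical here
  (n ≈ 25).
* `compensationAnalysis()` regresses ΔH on ΔS (slope = compensation
  temperature, in K) and ΔH on TΔS (slope ≈ 1 signals compensation);
  a constant ΔS is rejected as undefined rather than fitted.

# The synthetic-data generator

`generateTwoStateThermogram()` builds the unique two-state endotherm
consistent with the peak-height relation above:
Cp(T) = ΔHcal·(ΔHvH/RT²)·K/(1+K)², K = exp[−(ΔHvH/R)(1/T − 1/Tm)],
which integrates exactly to ΔHcal and peaks at ΔHcal·ΔHvH/(4RTm²). The
pretransition is a Gaussian of area ΔHpre (the literature gives no
shape); the baseline is a polynomial in (T − Tm); noise is additive
i.i.d. Gaussian with a mandatory seed. Defaults are the DPPC values
(Tm = 314.15 K, ΔHcal = 8.74 kcal/mol, ΔHvH = 2930 kcal/mol,
Tp = 307.15 K, ΔHpre = 1.2 kcal/mol — a typical DPPC pretransition
enthalpy — on a 0.005 K grid over 20–55 °C).

`generateNitroxideSpectrum()` sums three first-derivative pseudo-Voigt
lines at centre ± A and centre, each parameterised by its peak-to-peak
width and derived from a unit-area absorption, so the double integral
of a component is exactly its amplitude (×3). This is deliberately a
*phenomenological* lineshape: it reproduces the feature the pipeline
needs — resolvable broad vs narrow three-line components with known
mixing fractions — not slow-motion lineshape physics.

`generateTwoComponentSeries()` mixes the two area-normalised components
with fractions following the polynomial van't Hoff law inside a declared
coexistence window, and pins P_dis to exactly 0 below it and 1 above it
(outside coexistence the membrane is single-phase). The default
conditions emulate a DPPC series: 25 temperatures across 300–313.2 K
(the ~27–40 °C coexistence window) flanked by three pure-gel and three
pure-fluid temperatures, so the endpoint-basis strategy is exact.

The default cubic coefficients are not arbitrary numbers: they are
solved (at run time, at full precision) from four physical constraints —
ln K = 0 at Tm = 314.15 K; ln K = −3 at the 300 K onset (the disordered
population just emerging, ~5 %); and ΔS = 0 *and* ΔC = 0 at
Tp = 307.15 K, which makes ΔS a parabola touching zero at the
pretransition, keeps ΔH and ΔS positive across the window, and lets ΔC
cross from negative to positive at Tp (`dppcVantHoffCoefficients()`).
A quadratic analogue with two ΔG roots mimics a binary-mixture membrane
(`ternaryVantHoffCoefficients()`). An a priori power analysis guided the
choice of window depth and series length: with 25 points and fraction
noise of 0.02 the cubic term's orthogonal component is detected by the
incremental F-test with power ≈ 0.99, so automatic degree selection is a
meaningful end-to-end check rather than a coin flip.

Two noise channels are provided: spectral noise (i.i.d. Gaussian, as a
fraction of the maximum mixed amplitude) and fraction noise (Gaussian
perturbation of the in-window mixing fractions before mixing), the
latter emulating population-level scatter of the kind spectral fitting
of real data produces.

What the generator does **not** emulate — and what green tests therefore
do not certify on real data: slow-motion/MOMD lineshape distortions,
g- and A-tensor anisotropy, field-modulation artifacts, scan-rate
broadening of thermograms, multi-peak overlapping transitions, or
correlated (non-white) instrument noise. Real gel-phase spectra are not
exact linear mixtures of two fixed basis shapes (component lineshapes
drift with temperature; a linear drift hook is provided but defaults to
off), so real-data population series carry model error the synthetic
round trips cannot show.

## Henderson–Hasselbalch helper

`protonationFraction(pH, pKa)` returns the monoprotic protonated
fraction 1/(1+10^(pH−pKa)). For nicotine's pyrrolidine nitrogen
(pKa ≈ 7.65 at 37 °C) it gives 64.0 % protonated at pH 7.4; reported
speciation values near ~58 % imply a different effective constant, and
both numbers are simply documented here — the helper makes no attempt
to reconcile them.

# Problem sizes and determinism

The test suite and the acceptance script generate everything they use:
thermograms of 3 000–7 000 points, 1 024-point spectra, series of 31
temperatures, 100–200 Monte Carlo replicates, and bootstraps of
200–1 000 resamples. Those sizes were chosen to keep full runs in the
tens of seconds on one core while leaving Monte Carlo rates (recovery
fractions, selection rates, coverage) with standard errors of a few
percent. Every stochastic routine takes an explicit integer seed and is
bit-reproducible; the pipeline writes artifacts with a config hash and
seed in their headers so a run can be reproduced exactly.

# Known limitations

* Populations come from basis decomposition, not spectral simulation;
  ordered/disordered basis choice matters, and an endpoint basis
  contaminated by residual coexistence biases all fractions.
* The Tm-depression model is one standard two-state partitioning form;
  the affinity ratio is only weakly identified from small depressions
  (the dilute-limit data constrain K_F − K_G more strongly than the
  ratio), which the reported uncertainty reflects.
* The polynomial ln K law is an empirical smooth — extrapolation beyond
  the fitted window (e.g. locating the ΔG root just past the warm edge)
  is short-range only.
* ΔC is the analytic derivative of the fitted ΔH; it inherits the
  polynomial's stiffness and should be read as a trend, not a
  point-wise calorimetric measurement.
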