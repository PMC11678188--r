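# CoexTherm

Thermodynamics of gel–fluid phase coexistence in lipid membranes, from
differential scanning calorimetry (DSC) and nitroxide spin-label ESR.

Lipid bilayers such as pulmonary-surfactant models (DPPC, DPPC/POPC/POPG)
melt from ordered gel phases (Lβ′, Pβ′) to the fluid Lα phase through a
temperature window in which ordered and disordered domains coexist. That
coexistence — and how drugs or other amphiphiles shift it — is what this
package quantifies, for membrane biophysicists working with calorimetric
and spin-label data:

* **DSC thermograms** → melting temperature Tm, calorimetric enthalpy
  ΔH<sub>cal</sub> (peak area), transition entropy ΔS = ΔH<sub>cal</sub>/Tm,
  van't Hoff enthalpy ΔH<sub>vH</sub> = 4RTm²Cp<sub>max</sub>/ΔH<sub>cal</sub>,
  cooperative unit size CUS = ΔH<sub>vH</sub>/ΔH<sub>cal</sub>, and a
  gel/fluid ligand-partitioning fit of Tm depression
  (1/Tm − 1/Tm₀ = (R/ΔH)·ln[(1 + K<sub>F</sub>x)/(1 + K<sub>G</sub>x)]).
* **Two-component ESR spectra** → lineshape observables (2A<sub>max</sub>,
  ΔH₀), non-negative least-squares decomposition of each spectrum into
  ordered/disordered basis components (area-normalised, so weights are
  spin populations), and the orientational order parameter
  S = ⟨D²₀₀⟩ computed by quadrature from an orienting potential
  U(Ω)/kT = −[c₂₀D²₀₀ + c₂₂(D²₀₂+D²₀₋₂) + …].
* **Non-linear van't Hoff analysis** → with K = K<sub>p</sub>·P<sub>Lα</sub>/P<sub>Lβ′</sub>
  = exp(−ΔG/RT) and ln K = a + b/T + c/T² + d/T³, temperature-dependent
  ΔG, ΔH = −R·d(lnK)/d(1/T), ΔS = (ΔH − ΔG)/T and ΔC = ∂ΔH/∂T on a grid,
  the special temperatures where ΔG = 0 (melting) and ΔS = 0 (the ΔG
  saddle, empirically near the pretransition), entropy–enthalpy
  compensation regression, automatic polynomial-degree selection by
  incremental F-tests, and residual-bootstrap confidence bands.

A synthetic-data generator produces two-state melting endotherms and
temperature series of three-line nitroxide spectra with known ground
truth, so the whole pipeline is testable without instrument files.

## Worked example

```r
library(CoexTherm)

## DSC: a synthetic DPPC endotherm (Tm = 314.15 K, dHcal = 8.74 kcal/mol,
## dHvH = 2930 kcal/mol) analysed back
tg <- generateTwoStateThermogram(thermogramSpec(tp = NA_real_))
analyzeThermogram(tg, mainWindow = c(310, 318))
#> DSC transition parameters:
#>   Tm      = 41.00 C
#>   dHcal   = 8.74 kcal/mol
#>   dTm,1/2 = 0.24 C
#>   dS(Tm)  = 27.8 cal/mol/K
#>   dHvH    = 2930 kcal/mol
#>   CUS     = 335 molecules

## ESR + van't Hoff: simulate a 16-PCSL-like temperature series across
## the coexistence window, decompose it, fit, and derive the curves
ser <- generateTwoComponentSeries(seriesSpec(seed = 1L))
pops <- buildPopulationSeries(ser$spectra)      # endpoint bases
tbl  <- lnEquilibriumConstant(pops, kp = 1)
fit  <- fitVantHoff(tbl, degree = selectDegree(tbl))
fit
#> VantHoffModel: degree 3, Kp = 1, T range 300.00-313.20 K
#>   ln K = a + b/T + c/T^2 + d/T^3; adj R^2 = 1.0000
#>            a            b            c            d
#>  1.19412e+05 -1.10033e+08  3.37964e+10 -3.46019e+12
thermodynamicCurves(fit)
#> ThermoCurves on 512 points, 300.00-313.20 K
#>   special temperatures:
#>     S_zero at 307.15 K (34.00 C)
```

The transition entropy (27.8 cal mol⁻¹ K⁻¹) and cooperative unit
(~335 lipids) are the standard DPPC melting numbers; the ΔS = 0 point of
the fitted free-energy curve falls at 34 °C, where the DPPC pretransition
sits, and the fitted ln K crosses zero (ΔG = 0) at the melting point just
past the warm edge of the coexistence window.

A config-driven pipeline (`runPipeline()`, or
`Rscript inst/scripts/coextherm.R run --config cfg.yaml`) chains
simulate → decompose → fit and writes CSV/JSON artifacts with provenance
headers.

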