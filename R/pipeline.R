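# md5 of the canonical deparsed config, used as the provenance hash.
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = "exact"), tmp)
  unname(tools::md5sum(tmp))
}

.asWindowK <- function(wC) celsiusToKelvin(sort(as.numeric(wC)))

#' Run the configured analysis pipeline
#'
#' Executes the configured stages end to end and writes every artifact
#' with a provenance header (config hash, seed, package version) so runs
#' are byte-reproducible for a fixed configuration:
#' \describe{
#'   \item{simulate + esr + vanthoff}{generate a two-component spectral
#'     series, decompose it into a population series
#'     (`populations.csv`), fit the van't Hoff polynomial
#'     (`vanthoff_model.json`), and evaluate the thermodynamic curves
#'     (`curves.csv`, `special_temperatures.csv`).}
#'   \item{esr from files}{`esr$input` may instead list spectrum CSV
#'     paths to decompose.}
#'   \item{dsc}{simulate (or read `dsc$input`) a thermogram, subtract the
#'     window baseline and write the transition metrics
#'     (`dsc_result.csv`).}
#' }
#' All referenced input paths are validated before any artifact is
#' written, so a failing configuration leaves no partial outputs.
#'
#' @param config a list, or the path of a YAML file holding one. Top
#'   level: `seed`, `output_dir`, `stages` (subset of "simulate", "esr",
#'   "vanthoff", "dsc") and per-stage sections; see the vignette for the
#'   full schema.
#' @return named character vector of written artifact paths, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages <- config$stages
  if (is.null(stages)) stop("config$stages is required")
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$output_dir %||% "."
  # validate inputs before any output is produced
  for (p in c(config$esr$input, config$dsc$input))
    if (!file.exists(p)) stop("missing input path: ", p)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  prov <- list(config_hash = .configHash(config), seed = seed,
               package_version = as.character(utils::packageVersion(
                 "CoexTherm")))
  artifacts <- character()
  series <- NULL
  popSeries <- NULL

  if ("simulate" %in% stages) {
    sim <- config$simulate %||% list()
    coeffs <- if (!is.null(sim$coeffs)) {
      unlist(sim$coeffs)[c("a", "b", "c", "d")]
    } else if (identical(sim$preset, "ternary")) {
      ternaryVantHoffCoefficients()
    } else dppcVantHoffCoefficients()
    args <- list(vhCoeffs = coeffs,
                 noiseSd = sim$noise_sd %||% 0,
                 fractionNoiseSd = sim$fraction_noise_sd %||% 0,
                 seed = seed)
    if (!is.null(sim$temperatures)) {
      tcfg <- sim$temperatures
      args$temperatures <- seq(tcfg$from, tcfg$to, length.out = tcfg$n)
    }
    if (!is.null(sim$coex_window_K))
      args$coexWindow <- as.numeric(sim$coex_window_K)
    sp <- do.call(seriesSpec, args)
    series <- generateTwoComponentSeries(sp)
  }

  if ("esr" %in% stages) {
    ecfg <- config$esr %||% list()
    spectra <- if (!is.null(ecfg$input)) {
      lapply(ecfg$input, readXYTable, kind = "spectrum")
    } else if (!is.null(series)) series$spectra else
      stop("esr stage needs simulate output or esr$input files")
    popSeries <- buildPopulationSeries(
      spectra,
      basisStrategy = ecfg$basis_strategy %||% "endpoints",
      allowShift = isTRUE(ecfg$allow_shift))
    f <- file.path(outDir, "populations.csv")
    writeXYTable(popSeries, f, extraMeta = prov)
    artifacts["populations"] <- f
  }

  if ("vanthoff" %in% stages) {
    vcfg <- config$vanthoff %||% list()
    if (is.null(popSeries)) {
      if (is.null(vcfg$populations))
        stop("vanthoff stage needs the esr stage or vanthoff$populations")
      popSeries <- readXYTable(vcfg$populations, kind = "populations")
    }
    kp <- vcfg$kp %||% 1
    tbl <- lnEquilibriumConstant(popSeries, kp = kp,
                                 exclusionThreshold =
                                   vcfg$exclusion_threshold %||% 0.02)
    degCfg <- vcfg$degree %||% "auto"
    degree <- if (identical(degCfg, "auto")) selectDegree(tbl) else
      as.integer(degCfg)
    model <- fitVantHoff(tbl, degree, kp = kp)
    curves <- thermodynamicCurves(model)
    fModel <- file.path(outDir, "vanthoff_model.json")
    jsonlite::write_json(c(prov, list(
      degree = model@degree, kp = model@kp,
      coeffs = as.list(model@coeffs),
      covariance = model@covariance,
      t_range_K = model@tRange, adj_r2 = model@adjR2)),
      fModel, auto_unbox = TRUE, digits = NA)
    artifacts["model"] <- fModel
    ct <- curvesTable(curves)
    fCurves <- file.path(outDir, "curves.csv")
    writeLines(c(sprintf("# %s: %s", names(prov), unlist(prov)),
                 "temperature_K,dG_cal_mol,dH_cal_mol,dS_cal_mol_K,dC_cal_mol_K",
                 do.call(paste, c(lapply(ct, .fmtNum), sep = ","))),
               fCurves)
    artifacts["curves"] <- fCurves
    sp <- specialTemperatures(curves)
    fSpec <- file.path(outDir, "special_temperatures.csv")
    writeLines(c(sprintf("# %s: %s", names(prov), unlist(prov)),
                 "kind,temperature_K",
                 if (nrow(sp)) paste(sp$kind, .fmtNum(sp$tempK), sep = ",")),
               fSpec)
    artifacts["special"] <- fSpec
    nBoot <- vcfg$n_boot %||% 0
    if (nBoot >= 100) {
      bb <- bootstrapUncertainty(tbl, model, nBoot = nBoot, seed = seed)
      fB <- file.path(outDir, "coef_bands.json")
      jsonlite::write_json(c(prov, list(coef_bands = bb$coefBands,
                                        n_boot = nBoot)),
                           fB, auto_unbox = TRUE, digits = NA)
      artifacts["coef_bands"] <- fB
    }
  }

  if ("dsc" %in% stages) {
    dcfg <- config$dsc %||% list()
    tg <- if (!is.null(dcfg$input)) {
      readXYTable(dcfg$input, kind = "thermogram")
    } else {
      generateTwoStateThermogram(thermogramSpec(
        tm = celsiusToKelvin(dcfg$tm_C %||% 41),
        dHcal = dcfg$dhcal %||% 8.74,
        dHvH = dcfg$dhvh %||% 2930,
        tp = celsiusToKelvin(dcfg$tp_C %||% 34),
        noiseSd = dcfg$noise_sd %||% 0,
        seed = seed))
    }
    mainW <- .asWindowK(dcfg$main_window_C %||% c(39, 43))
    preW <- if (!is.null(dcfg$pre_window_C)) .asWindowK(dcfg$pre_window_C)
    res <- analyzeThermogram(tg, mainW, preW)
    fD <- file.path(outDir, "dsc_result.csv")
    writeLines(c(sprintf("# %s: %s", names(prov), unlist(prov)),
                 "dHcal_kcal_mol,Tm_C,dTm_half_C,Tp_C,dS_cal_mol_K,dHvH_kcal_mol,CUS",
                 paste(.fmtNum(c(res@dHcal, res@tmC, res@dTmHalf, res@tpC,
                                 res@dSAtTm, res@dHvH, res@cus)),
                       collapse = ",")),
               fD)
    artifacts["dsc"] <- fD
  }
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
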