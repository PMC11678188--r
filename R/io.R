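# Single CSV dialect across the package: optional '#'-prefixed metadata
# lines ("# key: value"), one header row, comma-separated numeric body,
# dot decimal. Temperatures are degrees Celsius at the file boundary for
# thermograms and spectra; the populations/curves files carry kelvin with
# an explicit _K suffix.

.kindColumns <- list(
  thermogram = c("temperature_C", "cp_kcal_mol_K"),
  spectrum = c("field_G", "intensity"),
  populations = c("temperature_K", "P_ordered", "P_disordered",
                  "residual_rms"))

.fmtNum <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a thermogram, spectrum or population series as CSV
#'
#' Emits the package's CSV dialect: '#'-prefixed metadata header lines
#' (kind, temperature_C, seed, ground_truth as JSON, plus any extra
#' provenance), a header row, then numeric rows at full double precision
#' (so a write-read round trip reproduces the arrays exactly).
#'
#' @param object a [Thermogram-class], [EsrSpectrum-class] or
#'   [PopulationSeries-class].
#' @param path output file path.
#' @param extraMeta named list of additional metadata lines.
#' @return `path`, invisibly.
#' @export
writeXYTable <- function(object, path, extraMeta = list()) {
  meta <- list()
  if (is(object, "Thermogram")) {
    kind <- "thermogram"
    body <- data.frame(kelvinToCelsius(object@temperature), object@cp)
    gt <- object@metadata$groundTruth
    if (!is.null(gt))
      meta$ground_truth <- as.character(jsonlite::toJSON(gt,
        auto_unbox = TRUE, digits = NA, na = "null"))
    if (!is.null(object@metadata$seed)) meta$seed <- object@metadata$seed
  } else if (is(object, "EsrSpectrum")) {
    kind <- "spectrum"
    body <- data.frame(object@field, object@intensity)
    if (!is.na(object@temperature))
      meta$temperature_C <- .fmtNum(kelvinToCelsius(object@temperature))
  } else if (is(object, "PopulationSeries")) {
    kind <- "populations"
    body <- data.frame(object@temperature, object@pOrdered,
                       object@pDisordered, object@residualRms)
  } else stop("unsupported object type")
  meta <- c(list(kind = kind), meta, extraMeta)
  lines <- c(sprintf("# %s: %s", names(meta),
                     vapply(meta, as.character, character(1))),
             paste(.kindColumns[[kind]], collapse = ","))
  rows <- do.call(paste, c(lapply(body, .fmtNum), sep = ","))
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read a thermogram, spectrum or population series CSV
#'
#' Parses the package's CSV dialect back into the typed object. Malformed
#' numeric cells are hard errors naming the offending line; a
#' non-monotonic axis is re-sorted ascending with a warning; an empty
#' body or missing required columns is an error.
#'
#' @param path input file path.
#' @param kind "thermogram", "spectrum" or "populations".
#' @return the corresponding S4 object; parsed metadata is attached where
#'   the class carries it.
#' @export
readXYTable <- function(path, kind = c("thermogram", "spectrum",
                                       "populations")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  isMeta <- grepl("^#", raw)
  meta <- list()
  for (ln in raw[isMeta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- m[3]
  }
  bodyIdx <- which(!isMeta & nzchar(trimws(raw)))
  if (length(bodyIdx) < 2) stop("empty body in ", path)
  header <- strsplit(raw[bodyIdx[1]], ",")[[1]]
  need <- .kindColumns[[kind]]
  missing <- setdiff(if (kind == "populations") need[1:3] else need, header)
  if (length(missing))
    stop("missing required columns in ", path, ": ",
         paste(missing, collapse = ", "))
  rowIdx <- bodyIdx[-1]
  cells <- strsplit(raw[rowIdx], ",")
  ncol <- length(header)
  mat <- matrix(NA_real_, length(rowIdx), ncol)
  for (i in seq_along(rowIdx)) {
    v <- cells[[i]]
    if (length(v) != ncol)
      stop(sprintf("line %d of %s: expected %d cells, found %d",
                   rowIdx[i], path, ncol, length(v)))
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !(trimws(v) %in% c("NA", "nan", "NaN", "")))
    if (length(bad))
      stop(sprintf("line %d of %s: malformed numeric cell '%s'",
                   rowIdx[i], path, v[bad[1]]))
    mat[i, ] <- num
  }
  colnames(mat) <- header
  sortBy <- function(axis) {
    if (any(diff(mat[, axis]) <= 0)) {
      warning("axis not strictly increasing in ", path,
              ": re-sorting ascending")
      mat <<- mat[order(mat[, axis]), , drop = FALSE]
    }
  }
  if (kind == "thermogram") {
    sortBy("temperature_C")
    md <- list()
    if (!is.null(meta$ground_truth))
      md$groundTruth <- jsonlite::fromJSON(meta$ground_truth)
    if (!is.null(meta$seed)) md$seed <- as.integer(meta$seed)
    thermogram(celsiusToKelvin(mat[, "temperature_C"]),
               mat[, "cp_kcal_mol_K"], metadata = md)
  } else if (kind == "spectrum") {
    sortBy("field_G")
    tempK <- if (!is.null(meta$temperature_C))
      celsiusToKelvin(as.numeric(meta$temperature_C)) else NA_real_
    esrSpectrum(mat[, "field_G"], mat[, "intensity"], temperature = tempK)
  } else {
    sortBy("temperature_K")
    rms <- if ("residual_rms" %in% header) mat[, "residual_rms"] else
      rep(NA_real_, nrow(mat))
    populationSeries(mat[, "temperature_K"], mat[, "P_ordered"],
                     mat[, "P_disordered"], rms)
  }
}
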