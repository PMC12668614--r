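# File formats and configuration. CSV (RFC 4180, UTF-8, header required)
# is the canonical interchange format; numbers are serialized with 9
# significant digits, densities always in g/mL. A YAML config block
# configures physics constants and per-species analysis options. An
# adapter imports a sheet-per-figure workbook (either a real .xlsx via
# readxl, or a directory of per-sheet CSVs, which is what the package's
# own exporter writes) on a best-effort mapping.

#' Write a tidy measurement table
#'
#' Numbers are formatted with 9 significant digits, which makes
#' write-read round trips idempotent (a value read back and rewritten is
#' preserved exactly).
#'
#' @param measurements validated tidy measurement data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  out <- measurements
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.9g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a tidy measurement table
#'
#' Expects the documented schema (one row per measured cell): columns
#' species, condition, replicate_id, instrument, fluid,
#' fluid_density_g_ml, value, unit. Validation errors name the missing
#' columns or offending row numbers. An empty file with a valid header is
#' an empty table, not an error.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) .psk_error(paste("no such file:", path), "psk_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (!"value" %in% names(df)) {
      .psk_error("missing columns: value", "psk_validation")
    }
    suppressWarnings(df$value <- as.numeric(df$value))
  }
  validate_measurements(df)
  df
}

.CONFIG_KEYS <- list(
  physics = c("fluid_density", "viscosity", "gravity", "water_density",
              "d2o_density", "d2o_water_density", "component_densities"),
  species = c("phi", "peclet_length", "min_particle", "composition"),
  tests = c("alpha", "fdr", "statistic", "influence_on",
            "reference_condition"))

#' Read a study configuration from YAML
#'
#' Recognised blocks: `physics` (fluid_density, viscosity, gravity,
#' water_density, d2o_density, d2o_water_density, component_densities with
#' the five group names), `species` (per species: phi, peclet_length,
#' min_particle, composition), and `tests` (alpha, fdr, statistic,
#' influence_on, reference_condition). Unknown keys are rejected with the
#' offending names.
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) .psk_error(paste("no such file:", path), "psk_io")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("physics", "species", "tests"))
  if (length(unknown)) {
    .psk_error(paste("unknown config blocks:",
                     paste(unknown, collapse = ", ")), "psk_validation")
  }
  ph <- raw$physics %||% list()
  bad <- setdiff(names(ph), .CONFIG_KEYS$physics)
  if (length(bad)) {
    .psk_error(paste("unknown physics keys:", paste(bad, collapse = ", ")),
               "psk_validation")
  }
  cd <- ph$component_densities %||% list()
  dens <- do.call(component_densities, cd)
  fluid <- fluid_environment(
    density = ph$fluid_density %||% 1.026,
    viscosity = ph$viscosity %||% 1.07e-3,
    gravity = ph$gravity %||% 9.81,
    water_density = ph$water_density %||% 0.998)
  fl_d2o <- fluid_d2o(
    density = ph$d2o_density %||% 1.122,
    water_density = ph$d2o_water_density %||% 1.094,
    viscosity = fluid$viscosity, gravity = fluid$gravity)
  tests <- raw$tests %||% list()
  bad <- setdiff(names(tests), .CONFIG_KEYS$tests)
  if (length(bad)) {
    .psk_error(paste("unknown tests keys:", paste(bad, collapse = ", ")),
               "psk_validation")
  }
  shape_phi <- list(); pe_len <- list(); min_part <- list()
  for (sp in names(raw$species %||% list())) {
    entry <- raw$species[[sp]]
    bad <- setdiff(names(entry), .CONFIG_KEYS$species)
    if (length(bad)) {
      .psk_error(sprintf("unknown species keys for '%s': %s", sp,
                         paste(bad, collapse = ", ")), "psk_validation")
    }
    if (!is.null(entry$phi)) shape_phi[[sp]] <- entry$phi
    if (!is.null(entry$peclet_length)) pe_len[[sp]] <- entry$peclet_length
    if (!is.null(entry$min_particle)) min_part[[sp]] <- entry$min_particle
  }
  study_config(fluid = fluid, fluid_d2o = fl_d2o, dens = dens,
               shape_phi = shape_phi, peclet_length = pe_len,
               min_particle = min_part,
               alpha = tests$alpha %||% 0.05,
               statistic = tests$statistic %||% "mean",
               influence_on = tests$influence_on %||% "pairs",
               reference_condition = tests$reference_condition %||% "high",
               fdr = isTRUE(tests$fdr))
}

#' Export tables as a sheet-per-table workbook directory
#'
#' The package's workbook format: a directory with one CSV per sheet,
#' named `<sheet>.csv`. This is the lossless counterpart that
#' [import_s1_workbook()] reads back.
#'
#' @param sheets named list of data.frames.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_workbook <- function(sheets, dir) {
  stopifnot(is.list(sheets), length(names(sheets)) == length(sheets))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sheets)) {
    utils::write.csv(sheets[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Import a sheet-per-figure data workbook (best effort)
#'
#' Accepts either an `.xlsx` workbook (read via the readxl package, one
#' data.frame per sheet) or a directory of per-sheet CSVs as written by
#' [export_workbook()]. Sheets whose columns contain the tidy measurement
#' schema are mapped to measurement tables; all other sheets are kept
#' as-is and listed as unmapped in the manifest -- never a failure.
#'
#' @param path workbook path (.xlsx file or CSV directory).
#' @return list with `sheets` (named list of data.frames), `measurements`
#'   (row-bound mapped tables or NULL) and `manifest` (data.frame: sheet,
#'   rows, cols, mapped).
#' @export
import_s1_workbook <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) .psk_error("workbook directory holds no CSV sheets",
                                   "psk_io")
    sheets <- lapply(files, utils::read.csv, stringsAsFactors = FALSE)
    names(sheets) <- sub("\\.csv$", "", basename(files))
  } else if (file.exists(path) && grepl("\\.xlsx?$", path)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      .psk_error("readxl is required to import .xlsx workbooks", "psk_io")
    }
    sheet_names <- tryCatch(readxl::excel_sheets(path),
                            error = function(e) .psk_error(
                              paste("unreadable workbook:",
                                    conditionMessage(e)), "psk_io"))
    sheets <- lapply(sheet_names, function(s)
      as.data.frame(readxl::read_excel(path, sheet = s)))
    names(sheets) <- sheet_names
  } else {
    .psk_error(paste("not a workbook (.xlsx) or sheet directory:", path),
               "psk_io")
  }
  mapped <- vapply(sheets, function(df) all(.REQUIRED_COLS %in% names(df)),
                   logical(1))
  manifest <- data.frame(sheet = names(sheets),
                         rows = vapply(sheets, nrow, integer(1)),
                         cols = vapply(sheets, ncol, integer(1)),
                         mapped = mapped)
  rownames(manifest) <- NULL
  measurements <- if (any(mapped)) {
    do.call(rbind, lapply(sheets[mapped], function(df) {
      df <- df[.REQUIRED_COLS]
      df$value <- as.numeric(df$value)
      validate_measurements(df)
      df
    }))
  } else NULL
  if (!is.null(measurements)) rownames(measurements) <- NULL
  list(sheets = sheets, measurements = measurements, manifest = manifest)
}
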