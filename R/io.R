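table_schemas <- list(
  voltammogram = c(potential_V = "numeric", current_A = "numeric"),
  cv_manifest = c(file = "character", scan_rate_V_per_s = "numeric",
                  label = "character"),
  metabolic = c(cell_line = "character", diameter_nm = "numeric",
                linker_kda = "numeric", time_h = "numeric",
                activity_fraction = "numeric", replicate = "numeric"),
  spectrum = c(wavelength_nm = "numeric", intensity = "numeric")
)

#' Read a CSV table against a named schema
#'
#' Strict comma-separated, '.'-decimal, header-mandatory reader for the
#' pipeline's tabular formats. Missing columns raise a schema error naming
#' the column; non-numeric cells raise a parse error citing the (data) row
#' number; an empty file is an input error.
#'
#' @param path Path to a CSV file.
#' @param schema_name One of `"voltammogram"`, `"cv_manifest"`,
#'   `"metabolic"`, `"spectrum"`.
#' @return A typed tibble with the schema's columns (extra columns are kept
#'   as character).
#' @export
read_table <- function(path, schema_name) {
  if (!schema_name %in% names(table_schemas)) {
    stop_input(sprintf("Unknown schema `%s`; available: %s.", schema_name,
                       paste(names(table_schemas), collapse = ", ")))
  }
  if (!file.exists(path)) {
    stop_input(sprintf("File not found: %s", path))
  }
  schema <- table_schemas[[schema_name]]
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE),
    error = function(e) stop_input(sprintf("Cannot read %s: %s", path,
                                           conditionMessage(e))))
  if (nrow(raw) == 0L) {
    stop_input(sprintf("Empty table: %s", path))
  }
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Schema `%s`: missing column(s) %s in %s.", schema_name,
                  paste0("`", missing_cols, "`", collapse = ", "), path),
          class = c("qbetr_schema_error", "qbetr_error"))
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      vals <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(vals) & !is.na(raw[[col]]))
      if (length(bad) > 0L) {
        abort(sprintf(
          "Column `%s` of %s: non-numeric value \"%s\" at row %d.",
          col, path, raw[[col]][bad[1L]], bad[1L]),
          class = c("qbetr_parse_error", "qbetr_error"))
      }
      raw[[col]] <- vals
    }
  }
  raw
}

#' Read a voltammogram CSV
#'
#' @param path CSV with header `potential_V,current_A`.
#' @inheritParams voltammogram
#' @return A [voltammogram()].
#' @export
read_voltammogram_csv <- function(path, scan_rate, temperature_K = 298.15,
                                  label = basename(path)) {
  voltammogram(read_table(path, "voltammogram"), scan_rate = scan_rate,
               temperature_K = temperature_K, label = label)
}

#' Read a scan-rate study from a manifest
#'
#' @param manifest_path CSV with header `file,scan_rate_V_per_s,label`, one
#'   row per voltammogram; `file` paths are resolved relative to the
#'   manifest's directory unless absolute.
#' @param temperature_K Temperature applied to all voltammograms.
#' @return A [scan_rate_study()].
#' @export
read_scan_rate_study <- function(manifest_path, temperature_K = 298.15) {
  man <- read_table(manifest_path, "cv_manifest")
  base <- dirname(manifest_path)
  vgrams <- purrr::pmap(man, function(file, scan_rate_V_per_s, label, ...) {
    p <- if (file.exists(file)) file else file.path(base, file)
    read_voltammogram_csv(p, scan_rate = scan_rate_V_per_s,
                          temperature_K = temperature_K, label = label)
  })
  scan_rate_study(vgrams)
}

#' Read a metabolic-activity CSV
#'
#' @param path CSV with header
#'   `cell_line,diameter_nm,linker_kda,time_h,activity_fraction,replicate`.
#' @return A typed tibble (see [aggregate_charging_rates()] for the layout
#'   consumed downstream).
#' @export
read_metabolic_csv <- function(path) {
  read_table(path, "metabolic")
}

#' Read a spectrum CSV, averaging multiple frames if present
#'
#' A single-frame file has header `wavelength_nm,intensity`. A multi-frame
#' acquisition may instead carry one column per frame next to
#' `wavelength_nm`; all non-wavelength columns are then averaged into the
#' mean spectrum.
#'
#' @param path CSV path.
#' @inheritParams spectrum
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, kind = c("scattering", "absorbance"),
                              label = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(raw) == 0L) stop_input(sprintf("Empty table: %s", path))
  if (!"wavelength_nm" %in% names(raw)) {
    abort(sprintf("Schema `spectrum`: missing column `wavelength_nm` in %s.",
                  path),
          class = c("qbetr_schema_error", "qbetr_error"))
  }
  frame_cols <- setdiff(names(raw), "wavelength_nm")
  if (length(frame_cols) == 0L) {
    abort(sprintf("Schema `spectrum`: missing column `intensity` in %s.",
                  path),
          class = c("qbetr_schema_error", "qbetr_error"))
  }
  num <- lapply(raw[c("wavelength_nm", frame_cols)], function(x) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric value \"%s\" at row %d of %s.",
                    x[bad[1L]], bad[1L], path),
            class = c("qbetr_parse_error", "qbetr_error"))
    }
    v
  })
  intensity <- rowMeans(as.data.frame(num[frame_cols]))
  spectrum(num$wavelength_nm, intensity, kind = kind, label = label)
}

#' Write pipeline tables as CSV
#'
#' Writers emitting exactly the CSV schemas the readers consume.
#'
#' @param x The object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_voltammogram_csv <- function(x, path) {
  stopifnot(inherits(x, "voltammogram"))
  readr::write_csv(as_tibble(x)[, c("potential_V", "current_A")], path)
  invisible(path)
}

#' @rdname write_voltammogram_csv
#' @export
write_metabolic_csv <- function(x, path) {
  cols <- c("cell_line", "diameter_nm", "linker_kda", "time_h",
            "activity_fraction", "replicate")
  readr::write_csv(as_tibble(x)[, cols], path)
  invisible(path)
}

#' @rdname write_voltammogram_csv
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  readr::write_csv(as_tibble(x)[, c("wavelength_nm", "intensity")], path)
  invisible(path)
}
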