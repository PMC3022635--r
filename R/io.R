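# Resolve a possibly remapped column, with a clear error naming the file.
.get_col <- function(df, name, mapping, path) {
  col <- if (!is.null(mapping[[name]])) mapping[[name]] else name
  if (!col %in% names(df)) {
    stop("file '", path, "' is missing column '", col, "'")
  }
  df[[col]]
}

.check_numeric <- function(v, col, path) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !is.na(v) & v != "")
  if (length(bad)) {
    stop("file '", path, "': non-numeric values in column '", col,
         "' at rows ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Read the input tables from delimited text
#'
#' Readers for the four input tables (municipalities, facilities, commuting
#' flows, trip lengths), all plain CSV with a header row. Column names can be
#' remapped via `mapping` (a named list, canonical name -> file column name).
#' Distances and coordinates are meters internally; set `units = "km"` to
#' convert kilometre-scaled columns on read.
#'
#' @param path path to a CSV file.
#' @param mapping named list remapping canonical column names (`id`, `x`,
#'   `y`, `population`, `urbanisation_class`; `municipality_id`,
#'   `facility_type`, `count`; `origin_id`, `destination_id`, `commuters`;
#'   `distance_m`, `count`) to the file's column names.
#' @param units `"m"` or `"km"` for coordinate/distance columns.
#' @return the corresponding validated table object.
#' @name readers
NULL

#' @rdname readers
#' @export
read_municipalities <- function(path, mapping = list(), units = c("m", "km")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scale <- if (units == "km") 1000 else 1
  cls <- tryCatch(.get_col(df, "urbanisation_class", mapping, path),
                  error = function(e) "unknown")
  municipality_table(
    id = .get_col(df, "id", mapping, path),
    x = .check_numeric(.get_col(df, "x", mapping, path), "x", path) * scale,
    y = .check_numeric(.get_col(df, "y", mapping, path), "y", path) * scale,
    population = .check_numeric(.get_col(df, "population", mapping, path),
                                "population", path),
    urbanisation_class = cls)
}

#' @rdname readers
#' @param region optional [municipality_table()] to validate ids against.
#' @export
read_facilities <- function(path, mapping = list(), region = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  facility_table(
    municipality_id = .get_col(df, "municipality_id", mapping, path),
    facility_type = .get_col(df, "facility_type", mapping, path),
    count = .check_numeric(.get_col(df, "count", mapping, path), "count",
                           path),
    region = region)
}

#' @rdname readers
#' @export
read_flows <- function(path, mapping = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  flow_table(
    origin_id = .get_col(df, "origin_id", mapping, path),
    destination_id = .get_col(df, "destination_id", mapping, path),
    commuters = .check_numeric(.get_col(df, "commuters", mapping, path),
                               "commuters", path))
}

#' @rdname readers
#' @export
read_trips <- function(path, mapping = list(), units = c("m", "km")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scale <- if (units == "km") 1000 else 1
  trip_length_distribution(
    bin_upper_edges = .check_numeric(.get_col(df, "distance_m", mapping,
                                              path),
                                     "distance_m", path) * scale,
    counts = .check_numeric(.get_col(df, "count", mapping, path), "count",
                            path))
}

#' Write / read a potential surface as an ESRI ASCII grid
#'
#' The ESRI ASCII raster format stores a six-keyword header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, in that
#' order) followed by rows of cell values from the northernmost row down —
#' exactly the storage order of a `potential_surface`.
#'
#' @param surface a `potential_surface`.
#' @param path output (input) file path.
#' @param nodata value standing in for missing cells.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns a `potential_surface` (`NODATA` cells become `NA`).
#' @export
write_esri_ascii <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "potential_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", surface$n_cols),
               sprintf("nrows %d", surface$n_rows),
               sprintf("xllcorner %.10g", surface$origin_x),
               sprintf("yllcorner %.10g", surface$origin_y),
               sprintf("cellsize %.10g", surface$resolution),
               sprintf("NODATA_value %.10g", nodata)), con)
  vals <- surface$values
  vals[is.na(vals)] <- nodata
  for (r in seq_len(surface$n_rows)) {
    writeLines(paste(format(vals[r, ], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
              "nodata_value")
  if (!all(needed %in% names(hdr))) {
    stop("file '", path, "' is not a valid ESRI ASCII grid")
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII grid '", path, "' has ", length(vals),
         " values for ", hdr$nrows, " x ", hdr$ncols, " cells")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  structure(list(values = m, origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner, resolution = hdr$cellsize,
                 n_rows = as.integer(hdr$nrows),
                 n_cols = as.integer(hdr$ncols)),
            class = "potential_surface")
}

#' Run configuration
#'
#' Reads the single YAML configuration file driving the command-line
#' pipeline. Sections mirror the package's modules: `inputs` (file paths and
#' column `mapping`, `units`), `impedance` (a `preset` name *or* explicit
#' `family`/`alpha`/`beta`/`span` — mutually exclusive), `commuter`
#' (`theta`, `max_d`, `external_destinations`, `long_commutes`), `grid`
#' (`resolution`, `margin`), `simulate` (region-spec fields), `outputs`
#' (directory and file names), `seed` and `log_level`. Command-line flags
#' override file values.
#'
#' @param path YAML file path.
#' @return a named list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file '", path, "' does not exist")
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file '", path, "' must be a YAML mapping")
  for (fld in c("resolution", "margin")) {
    v <- cfg$grid[[fld]]
    if (!is.null(v) && (!is.numeric(v) || v < 0)) {
      stop("config grid.", fld, " must be non-negative")
    }
  }
  if (!is.null(cfg$commuter$max_d) && cfg$commuter$max_d <= 0) {
    stop("config commuter.max_d must be positive")
  }
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Write a machine-readable run manifest
#'
#' Every pipeline run writes a JSON manifest capturing the subcommand, the
#' parameters actually used (impedance, grid, commuter settings, seed) and
#' row counts of inputs and outputs, so a run can be reproduced from its
#' manifest alone.
#'
#' @param path output path for the JSON manifest.
#' @param command subcommand name.
#' @param parameters named list of parameters used.
#' @param counts named list of row/cell counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, parameters = list(),
                           counts = list()) {
  manifest <- list(tool = "potaccess",
                   version = as.character(utils::packageVersion("potaccess")),
                   command = command,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   parameters = parameters,
                   counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.log_level <- function() {
  lv <- getOption("potaccess.log_level", "info")
  match(lv, c("debug", "info", "warning", "error"), nomatch = 2L)
}

.log <- function(level, ...) {
  lvl <- match(level, c("debug", "info", "warning", "error"))
  if (lvl >= .log_level()) {
    message(format(Sys.time(), "%H:%M:%S "), "[", level, "] ", ...)
  }
}
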