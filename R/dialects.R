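#' Text dialects of metabolic-cage instrument exports
#'
#' Commercial indirect-calorimetry platforms export delimited text files whose
#' layout differs in header structure, delimiter, decimal mark, timestamp
#' format and gas units. \pkg{calokit} ships a registry of five fully
#' documented dialects that mirror the structure of the common vendors'
#' exports while remaining plain, reproducible text:
#'
#' \describe{
#'   \item{\code{tse_v1}}{TSE LabMaster/PhenoMaster style: semicolon-delimited,
#'     decimal comma, a short key-value header block, separate Date and Time
#'     columns (\code{\%d.\%m.\%Y} / \code{\%H:\%M:\%S}), gases in ml/h.}
#'   \item{\code{clams_v1}}{Columbus CLAMS/Oxymax style: comma-delimited, one
#'     file per animal with the subject id in the header, gases in ml/min.}
#'   \item{\code{sable_v1}}{Sable style: tab-delimited, interleaved event rows
#'     (marker lines) that are skipped on read, gases in l/h.}
#'   \item{\code{cosmed_v1}}{COSMED-style generic table: comma-delimited,
#'     subject/time/VO2/VCO2 (ml/min) plus ambient temperature; no activity or
#'     food/water channels.}
#'   \item{\code{calr_csv}}{CalR-compatible CSV: a single header row
#'     (\code{Animal ID, Date/Time, VO2, VCO2, ...}), ISO timestamps, ml/h.
#'     Also the package's canonical re-ingestable export format.}
#' }
#'
#' A dialect is a plain list; the registry can be extended at runtime with
#' \code{register_dialect()}, subject to the constraint that the first-line
#' signatures of all registered dialects stay pairwise disjoint so that
#' \code{\link{detect_dialect}} is unambiguous.
#'
#' @return \code{list_dialects()} returns the dialect names;
#'   \code{get_dialect()} returns one dialect specification (a list).
#' @name dialects
NULL

# Canonical channel names every dialect maps onto. vo2/vco2 are mandatory.
CK_GAS_CHANNELS <- c("vo2", "vco2")
CK_OPTIONAL_CHANNELS <- c("activity_x", "activity_y", "food", "water",
                          "temp_ambient")

# ml/h is canonical; factors convert file units -> ml/h.
CK_GAS_UNIT_FACTORS <- c("ml/h" = 1, "ml/min" = 60, "l/h" = 1000)

new_dialect <- function(name, signature, header_lines, delimiter, decimal_mark,
                        column_map, timestamp_cols, timestamp_format,
                        gas_units, per_animal_files = FALSE,
                        animal_header_key = NULL, event_col = NULL,
                        event_token = NULL, header_template = character(0)) {
  stopifnot(delimiter != decimal_mark)
  miss <- setdiff(CK_GAS_CHANNELS, names(column_map))
  if (length(miss) && !per_animal_files)
    ck_stop("dialect ", name, " misses mandatory channels: ",
            paste(miss, collapse = ", "))
  structure(list(
    name = name, signature = signature, header_lines = header_lines,
    delimiter = delimiter, decimal_mark = decimal_mark,
    column_map = column_map, timestamp_cols = timestamp_cols,
    timestamp_format = timestamp_format, gas_units = gas_units,
    per_animal_files = per_animal_files,
    animal_header_key = animal_header_key,
    event_col = event_col, event_token = event_token,
    header_template = header_template
  ), class = "calokit_dialect")
}

.dialect_registry <- new.env(parent = emptyenv())

register_dialect_impl <- function(spec) {
  for (nm in ls(.dialect_registry)) {
    other <- get(nm, .dialect_registry)
    if (nm != spec$name && identical(other$signature, spec$signature))
      ck_stop("signature of dialect ", spec$name,
              " collides with registered dialect ", nm)
  }
  assign(spec$name, spec, .dialect_registry)
  invisible(spec)
}

#' @rdname dialects
#' @export
list_dialects <- function() sort(ls(.dialect_registry))

#' @rdname dialects
#' @param name dialect identifier, e.g. \code{"tse_v1"}.
#' @export
get_dialect <- function(name) {
  if (inherits(name, "calokit_dialect")) return(name)
  if (!exists(name, .dialect_registry))
    ck_stop("unknown dialect '", name, "'; registered: ",
            paste(list_dialects(), collapse = ", "))
  get(name, .dialect_registry)
}

#' @rdname dialects
#' @param spec a dialect specification created with the same fields as the
#'   built-in ones (see the registry source for the authoritative field list).
#' @export
register_dialect <- function(spec) register_dialect_impl(spec)

init_dialect_registry <- function() {
  register_dialect_impl(new_dialect(
    name = "tse_v1",
    signature = "TSE LabMaster Export V1",
    header_lines = 3,
    delimiter = ";",
    decimal_mark = ",",
    column_map = c(animal_id = "Animal No.", box = "Box",
                   vo2 = "VO2(3)", vco2 = "VCO2(3)",
                   activity_x = "XT", activity_y = "YT",
                   food = "Feed", water = "Drink", temp_ambient = "TempA"),
    timestamp_cols = c("Date", "Time"),
    timestamp_format = c("%d.%m.%Y", "%H:%M:%S"),
    gas_units = c(vo2 = "ml/h", vco2 = "ml/h"),
    header_template = c("TSE LabMaster Export V1",
                        "Experiment: calokit fixture",
                        "Rack: 1")
  ))
  register_dialect_impl(new_dialect(
    name = "clams_v1",
    signature = "Oxymax CSV File V1",
    header_lines = 2,
    delimiter = ",",
    decimal_mark = ".",
    column_map = c(interval = "Interval",
                   vo2 = "Volume O2", vco2 = "Volume CO2",
                   activity_x = "X Ambulatory", activity_y = "Y Ambulatory",
                   food = "Feed", water = "Drink",
                   temp_ambient = "Cage Temp"),
    timestamp_cols = "Date Time",
    timestamp_format = "%m/%d/%Y %H:%M:%S",
    gas_units = c(vo2 = "ml/min", vco2 = "ml/min"),
    per_animal_files = TRUE,
    animal_header_key = "Subject ID",
    header_template = c("Oxymax CSV File V1")
  ))
  register_dialect_impl(new_dialect(
    name = "sable_v1",
    signature = "SableSystems ExpeData Export",
    header_lines = 1,
    delimiter = "\t",
    decimal_mark = ".",
    column_map = c(animal_id = "Animal",
                   vo2 = "VO2_lh", vco2 = "VCO2_lh",
                   activity_x = "XA", activity_y = "YA",
                   food = "FoodA", water = "WaterA",
                   temp_ambient = "Temp_C"),
    timestamp_cols = "DateTime",
    timestamp_format = "%Y-%m-%d %H:%M:%S",
    gas_units = c(vo2 = "l/h", vco2 = "l/h"),
    event_col = "Animal", event_token = "EVENT",
    header_template = c("SableSystems ExpeData Export")
  ))
  register_dialect_impl(new_dialect(
    name = "cosmed_v1",
    signature = "COSMED Generic Export",
    header_lines = 2,
    delimiter = ",",
    decimal_mark = ".",
    column_map = c(animal_id = "Subject",
                   vo2 = "VO2", vco2 = "VCO2", temp_ambient = "Temp"),
    timestamp_cols = "Time",
    timestamp_format = "%d/%m/%Y %H:%M:%S",
    gas_units = c(vo2 = "ml/min", vco2 = "ml/min"),
    header_template = c("COSMED Generic Export", "Parameters,standard")
  ))
  register_dialect_impl(new_dialect(
    name = "calr_csv",
    signature = "__calr_header__",
    header_lines = 0,
    delimiter = ",",
    decimal_mark = ".",
    column_map = c(animal_id = "Animal ID",
                   vo2 = "VO2", vco2 = "VCO2",
                   activity_x = "X Activity", activity_y = "Y Activity",
                   food = "Food", water = "Water", temp_ambient = "Temp"),
    timestamp_cols = "Date/Time",
    timestamp_format = "%Y-%m-%d %H:%M:%S",
    gas_units = c(vo2 = "ml/h", vco2 = "ml/h")
  ))
}

# Signature match on the first line of a file (token set + delimiter).
dialect_matches_line <- function(spec, line) {
  if (identical(spec$signature, "__calr_header__")) {
    toks <- trimws(strsplit(line, spec$delimiter, fixed = TRUE)[[1]])
    return(all(c("Animal ID", "Date/Time", "VO2", "VCO2") %in% toks))
  }
  identical(trimws(line), spec$signature)
}

#' Identify the instrument dialect of an export file
#'
#' Reads the first line of \code{path} (or, for a directory of per-animal
#' files, of its first file) and matches it against the signatures of all
#' registered dialects. Detection is deterministic; the registry keeps
#' signatures disjoint.
#'
#' @param path a file, or a directory of per-animal files.
#' @return the matching dialect specification.
#' @seealso [read_dataset()], [list_dialects()]
#' @export
detect_dialect <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    if (!length(files)) ck_stop("empty directory: ", path)
    path <- files[1]
  }
  if (!file.exists(path)) ck_stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first)))
    ck_stop("cannot detect dialect: file is empty: ", path)
  hits <- Filter(function(nm) dialect_matches_line(get_dialect(nm), first),
                 list_dialects())
  if (length(hits) == 1L) return(get_dialect(hits[[1]]))
  if (length(hits) > 1L)
    ck_stop("ambiguous dialect signature; matches: ",
            paste(unlist(hits), collapse = ", "))
  # no match: name the closest candidate by shared leading characters
  sigs <- vapply(list_dialects(), function(nm) {
    s <- get_dialect(nm)$signature
    if (identical(s, "__calr_header__")) "Animal ID" else s
  }, character(1))
  shared <- vapply(sigs, function(s) {
    n <- min(nchar(s), nchar(first))
    sum(cumprod(strsplit(substr(s, 1, n), "")[[1]] ==
                  strsplit(substr(first, 1, n), "")[[1]]))
  }, numeric(1))
  ck_stop("unknown dialect for ", path, "; closest candidate: ",
          names(shared)[which.max(shared)])
}
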