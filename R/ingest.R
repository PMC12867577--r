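#' Canonical long-format calorimetry table
#'
#' The \code{calorimetry_frame} is the lingua franca of every stage of the
#' package: one row per (animal, timestamp) sample with the gas-exchange
#' channels normalized to ml/h. Mandatory columns are \code{animal_id},
#' \code{cohort_id}, \code{timestamp} (POSIXct, one local clock, stored as
#' UTC), \code{vo2} and \code{vco2}; optional channels are beam-break activity
#' counts (\code{activity_x}, \code{activity_y}), \code{food} and \code{water}
#' intake per interval (g) and \code{temp_ambient} (degrees C). Provenance
#' (\code{source_file}, \code{dialect_name}) travels in columns; free-form
#' header metadata from the source file travels in the \code{"header_meta"}
#' attribute, and the per-animal experiment span (first/last sample at
#' ingest) in the \code{"span"} attribute.
#'
#' @param df data.frame with at least animal_id, timestamp, vo2, vco2.
#' @param cohort_id default cohort label for rows lacking one.
#' @param source_file,dialect_name provenance, recycled over rows.
#' @param header_meta named list of key-value metadata from file headers.
#' @param validate check invariants (strictly increasing timestamps per
#'   animal, no duplicate samples, numeric gases).
#' @return an object of class \code{calorimetry_frame} (a data.frame).
#' @export
calorimetry_frame <- function(df, cohort_id = "C1", source_file = NA_character_,
                              dialect_name = NA_character_,
                              header_meta = list(), validate = TRUE) {
  req <- c("animal_id", "timestamp", "vo2", "vco2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    ck_stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  df$animal_id <- as.character(df$animal_id)
  if (is.null(df$cohort_id)) df$cohort_id <- cohort_id
  df$cohort_id <- as.character(df$cohort_id)
  if (!inherits(df$timestamp, "POSIXct"))
    df$timestamp <- ck_time(df$timestamp)
  attr(df$timestamp, "tzone") <- CK_TZ
  if (is.null(df$source_file)) df$source_file <- source_file
  if (is.null(df$dialect_name)) df$dialect_name <- dialect_name
  ord <- order(df$animal_id, df$timestamp)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  front <- c("animal_id", "cohort_id", "timestamp", "vo2", "vco2")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  if (validate) {
    for (ch in c("vo2", "vco2"))
      if (!is.numeric(df[[ch]])) ck_stop(ch, " must be numeric")
    key <- paste(df$animal_id, format(df$timestamp, "%Y-%m-%d %H:%M:%OS3"))
    if (anyDuplicated(key))
      ck_stop("duplicate (animal_id, timestamp) sample(s), e.g. ",
              key[duplicated(key)][1])
  }
  attr(df, "header_meta") <- header_meta
  if (is.null(attr(df, "span"))) attr(df, "span") <- frame_span_compute(df)
  class(df) <- c("calorimetry_frame", "data.frame")
  df
}

frame_span_compute <- function(df) {
  if (!nrow(df))
    return(data.frame(animal_id = character(0)))
  sp <- do.call(rbind, lapply(split(df$timestamp, df$animal_id), range))
  data.frame(animal_id = rownames(sp),
             start = as.POSIXct(sp[, 1], origin = "1970-01-01", tz = CK_TZ),
             end = as.POSIXct(sp[, 2], origin = "1970-01-01", tz = CK_TZ),
             row.names = NULL)
}

# Experiment span (used by trim_experiment so trimming is anchored to the
# original recording, not to whatever survives earlier curation steps).
frame_span <- function(frame) {
  attr(frame, "span") %||% frame_span_compute(frame)
}

#' @export
print.calorimetry_frame <- function(x, ...) {
  cat(sprintf("<calorimetry_frame> %d samples, %d animal(s), %d cohort(s)\n",
              nrow(x), length(unique(x$animal_id)),
              length(unique(x$cohort_id))))
  if (nrow(x)) {
    cat(sprintf("  time range: %s .. %s\n",
                format(min(x$timestamp)), format(max(x$timestamp))))
    opt <- intersect(CK_OPTIONAL_CHANNELS, names(x))
    if (length(opt)) cat("  optional channels:", paste(opt, collapse = ", "), "\n")
  }
  invisible(x)
}

read_one_table <- function(path, spec) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) ck_stop("empty file: ", path)
  hdr <- if (spec$header_lines > 0) lines[seq_len(spec$header_lines)] else character(0)
  body <- if (spec$header_lines > 0) lines[-seq_len(spec$header_lines)] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) ck_stop("no data rows in ", path)
  # header block -> key-value metadata (": " or first-delimiter separated)
  meta <- list()
  for (h in hdr[-1]) {
    kv <- regmatches(h, regexec("^([^:,;\t]+)[:,;\t]\\s*(.*)$", h))[[1]]
    if (length(kv) == 3 && nzchar(trimws(kv[2])))
      meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  tab <- utils::read.table(text = body, sep = spec$delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  n_events <- 0L
  if (!is.null(spec$event_col) && spec$event_col %in% names(tab)) {
    ev <- tab[[spec$event_col]] == spec$event_token
    n_events <- sum(ev)
    tab <- tab[!ev, , drop = FALSE]
  }
  list(tab = tab, meta = meta, n_events = n_events)
}

parse_timestamps <- function(tab, spec, path) {
  miss <- setdiff(spec$timestamp_cols, names(tab))
  if (length(miss))
    ck_stop("missing mandatory column(s) in ", path, ": ",
            paste(miss, collapse = ", "))
  if (length(spec$timestamp_cols) == 1) {
    raw <- tab[[spec$timestamp_cols]]
    fmt <- spec$timestamp_format
  } else {
    raw <- do.call(paste, tab[spec$timestamp_cols])
    fmt <- paste(spec$timestamp_format, collapse = " ")
  }
  ts <- as.POSIXct(raw, tz = CK_TZ, format = fmt)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    ck_stop("unparseable timestamp at data row ", bad, " of ", path,
            ": '", raw[bad], "' (expected format ", fmt, ")")
  }
  ts
}

#' Read an instrument export into the canonical frame
#'
#' Parses a delimited-text export in one of the registered dialects, converts
#' gas channels to ml/h, attaches header metadata, and validates structure.
#' For per-animal-file dialects (e.g. \code{clams_v1}) \code{path} may be a
#' directory or a vector of files.
#'
#' Unmapped extra columns are preserved as numeric optional channels and
#' recorded in the frame's \code{"read_log"} attribute rather than dropped.
#'
#' @param path file(s) or directory to read.
#' @param dialect dialect name or specification; \code{"auto"} to detect.
#' @param cohort_id cohort label attached to all rows.
#' @return a [calorimetry_frame()].
#' @examples
#' f <- simulate_animal(animal_sim_params(n_days = 1, seed = 1))$frame
#' d <- file.path(tempdir(), "fixture.csv")
#' write_fixture(f, "calr_csv", d)
#' g <- read_dataset(d, "calr_csv")
#' all.equal(f$vo2, g$vo2, tolerance = 1e-9)
#' @export
read_dataset <- function(path, dialect = "auto", cohort_id = "C1") {
  if (identical(dialect, "auto")) dialect <- detect_dialect(path[1])
  spec <- get_dialect(dialect)
  files <- path
  if (length(path) == 1 && dir.exists(path))
    files <- sort(list.files(path, full.names = TRUE))
  if (!length(files)) ck_stop("no input files under ", path)
  if (!spec$per_animal_files && length(files) > 1)
    ck_stop("dialect ", spec$name, " expects a single file")

  pieces <- list()
  meta_all <- list()
  log <- character(0)
  for (f in files) {
    parsed <- read_one_table(f, spec)
    tab <- parsed$tab
    if (parsed$n_events > 0)
      log <- c(log, sprintf("%s: skipped %d event row(s)", basename(f),
                            parsed$n_events))
    ts <- parse_timestamps(tab, spec, f)
    cmap <- spec$column_map
    known <- c(unname(cmap), spec$timestamp_cols)
    if (!is.null(spec$animal_header_key)) {
      aid <- parsed$meta[[spec$animal_header_key]]
      if (is.null(aid))
        ck_stop("missing mandatory column/header '", spec$animal_header_key,
                "' in ", f)
    } else {
      if (!cmap[["animal_id"]] %in% names(tab))
        ck_stop("missing mandatory column '", cmap[["animal_id"]], "' in ", f)
      aid <- tab[[cmap[["animal_id"]]]]
    }
    out <- data.frame(animal_id = as.character(aid), timestamp = ts)
    for (ch in setdiff(names(cmap), "animal_id")) {
      col <- cmap[[ch]]
      if (!col %in% names(tab)) {
        if (ch %in% CK_GAS_CHANNELS)
          ck_stop("missing mandatory column '", col, "' in ", f)
        next
      }
      v <- parse_num(tab[[col]], spec$decimal_mark)
      if (ch %in% CK_GAS_CHANNELS)
        v <- v * CK_GAS_UNIT_FACTORS[[spec$gas_units[[ch]]]]
      out[[ch]] <- v
    }
    extra <- setdiff(names(tab), known)
    for (col in extra) {
      nm <- tolower(gsub("[^A-Za-z0-9]+", "_", col))
      out[[nm]] <- parse_num(tab[[col]], spec$decimal_mark)
      log <- c(log, sprintf("%s: unmapped column '%s' kept as channel '%s'",
                            basename(f), col, nm))
    }
    out$source_file <- basename(f)
    pieces[[f]] <- out
    meta_all <- utils::modifyList(meta_all, parsed$meta)
  }
  all_cols <- unique(unlist(lapply(pieces, names)))
  pieces <- lapply(pieces, function(p) {
    p[setdiff(all_cols, names(p))] <- NA_real_
    p[all_cols]
  })
  df <- do.call(rbind, c(pieces, make.row.names = FALSE))
  df$dialect_name <- spec$name
  fr <- calorimetry_frame(df, cohort_id = cohort_id, header_meta = meta_all)
  attr(fr, "read_log") <- log
  fr
}

#' Merge calorimetry frames from several cohorts
#'
#' Concatenates frames recorded in different cohorts (possibly at different
#' sampling intervals) for joint analysis. Animals must be identifiable:
#' colliding (cohort_id, animal_id) pairs across frames are an error.
#'
#' @param frames list of [calorimetry_frame()] objects.
#' @return a single combined frame.
#' @export
merge_cohorts <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1)
  keysets <- lapply(frames, function(f) unique(paste(f$cohort_id, f$animal_id)))
  all_keys <- unlist(keysets)
  if (anyDuplicated(all_keys))
    ck_stop("colliding (cohort_id, animal_id) pair(s) across frames: ",
            paste(unique(all_keys[duplicated(all_keys)]), collapse = ", "))
  all_cols <- unique(unlist(lapply(frames, names)))
  parts <- lapply(frames, function(f) {
    df <- as.data.frame(f)
    df[setdiff(all_cols, names(df))] <- NA_real_
    df[all_cols]
  })
  hm <- Reduce(function(a, b) utils::modifyList(a, b %||% list()),
               lapply(frames, attr, "header_meta"), list())
  # animal ids may repeat across cohorts; disambiguate by prefixing with cohort
  df <- do.call(rbind, c(parts, make.row.names = FALSE))
  dup <- tapply(df$cohort_id, df$animal_id, function(x) length(unique(x)) > 1)
  if (any(dup)) {
    sel <- df$animal_id %in% names(dup)[dup]
    df$animal_id[sel] <- paste(df$cohort_id[sel], df$animal_id[sel], sep = ":")
  }
  out <- calorimetry_frame(df, header_meta = hm)
  attr(out, "span") <- frame_span_compute(out)
  out
}
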