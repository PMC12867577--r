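#' Write any tabular artifact as a long-format CSV
#'
#' UTF-8, header row, ISO-8601 timestamps, "." decimal mark; loss-free for
#' all canonical fields (numbers at 15 significant digits). The counterpart
#' [read_long_csv()] restores frames, traces and reports.
#'
#' @param x data.frame (frame, trace, report, ...).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_long_csv <- function(x, path) {
  df <- as.data.frame(x)
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct"))
      df[[col]] <- format(df[[col]], "%Y-%m-%dT%H:%M:%S")
    else if (is.numeric(df[[col]]))
      df[[col]] <- vapply(df[[col]], function(v)
        if (is.na(v)) "" else sprintf("%.15g", v), character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_long_csv
#' @param as_frame re-validate as a [calorimetry_frame()] (requires the
#'   mandatory columns).
#' @export
read_long_csv <- function(path, as_frame = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  for (col in names(df)) {
    if (is.character(df[[col]]) &&
        all(grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$",
                  df[[col]][!is.na(df[[col]]) & nzchar(df[[col]])])) &&
        any(nzchar(df[[col]]), na.rm = TRUE))
      df[[col]] <- ck_time(df[[col]], "%Y-%m-%dT%H:%M:%S")
  }
  if (as_frame) calorimetry_frame(df) else df
}

#' Export a frame in the CalR-compatible CSV dialect
#'
#' Emits the package's documented \code{calr_csv} dialect (single header
#' row: Animal ID, Date/Time, VO2, VCO2 and optional channels, ml/h, ISO
#' timestamps); [read_dataset()] with dialect \code{"calr_csv"} recovers the
#' frame.
#'
#' @param frame a [calorimetry_frame()].
#' @param path output file.
#' @export
write_calr_csv <- function(frame, path) {
  miss <- setdiff(c("animal_id", "timestamp", "vo2", "vco2"), names(frame))
  if (length(miss))
    ck_stop("frame misses mandatory channel(s): ", paste(miss, collapse = ", "))
  write_fixture(frame, "calr_csv", path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

sheet_xml <- function(name, df) {
  df <- as.data.frame(df)
  for (col in names(df))
    if (inherits(df[[col]], "POSIXct"))
      df[[col]] <- format(df[[col]], "%Y-%m-%dT%H:%M:%S")
  cell <- function(v) {
    if (is.na(v)) return("<Cell><Data ss:Type=\"String\"></Data></Cell>")
    if (is.numeric(v))
      sprintf("<Cell><Data ss:Type=\"Number\">%.15g</Data></Cell>", v)
    else
      sprintf("<Cell><Data ss:Type=\"String\">%s</Data></Cell>",
              xml_escape(as.character(v)))
  }
  rows <- c(
    paste0("<Row>", paste0(vapply(names(df), function(n)
      cell(n), character(1)), collapse = ""), "</Row>"),
    vapply(seq_len(nrow(df)), function(i)
      paste0("<Row>", paste0(vapply(seq_along(df), function(j)
        cell(df[i, j]), character(1)), collapse = ""), "</Row>"),
      character(1)))
  c(sprintf("<Worksheet ss:Name=\"%s\"><Table>", xml_escape(name)),
    rows, "</Table></Worksheet>")
}

#' Write the consolidated multi-sheet workbook
#'
#' One workbook with sheets Data, EnergyTrace, RMR, Stats, Curation,
#' Metadata and Config, written as SpreadsheetML 2003 XML — a plain-text
#' multi-sheet format that Excel and LibreOffice open natively.
#'
#' @param bundle a named list of data.frames (and, for Config, a named list
#'   flattened to key/value rows); typically an [cmd_analyze()] export
#'   bundle.
#' @param path output \code{.xml} file.
#' @return invisibly, \code{path}.
#' @export
write_consolidated_workbook <- function(bundle, path) {
  sheets <- list(
    Data = bundle$frame, EnergyTrace = bundle$trace, RMR = bundle$rmr,
    Stats = bundle$stats, Curation = bundle$curation,
    Metadata = bundle$metadata, Config = bundle$config)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             paste0('<Workbook xmlns="urn:schemas-microsoft-com:office:',
                    'spreadsheet" xmlns:ss="urn:schemas-microsoft-com:',
                    'office:spreadsheet">'))
  for (nm in names(sheets)) {
    x <- sheets[[nm]]
    if (is.null(x)) next
    if (!is.data.frame(x))
      x <- data.frame(key = names(unlist(x)),
                      value = as.character(unlist(x)))
    lines <- c(lines, sheet_xml(nm, x))
  }
  lines <- c(lines, "</Workbook>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Render a static figure
#'
#' Deterministic, headless base-graphics figures for the standard views:
#' \code{timeseries} (per-animal EE traces with shaded dark phases),
#' \code{box} and \code{bar} (group summaries, with significance stars when
#' a post-hoc table is supplied), \code{density_map} (locomotion density)
#' and \code{profile} (windowed zeitgeber profiles). Format follows the file
#' extension: .svg, .pdf or .png.
#'
#' @param kind one of timeseries, box, bar, density_map, profile.
#' @param data the stage output matching \code{kind}: an energy trace, an
#'   analysis table (with \code{group}/first-factor column), a
#'   [locomotion_density()] result, or a [windowed_profile()] table.
#' @param path output image file.
#' @param group for box/bar: name of the grouping column in \code{data}.
#' @param value for box/bar/profile: name of the value column.
#' @param stars optional [posthoc()] table whose first row's stars annotate
#'   box/bar figures.
#' @param width,height device size in inches (pixels/96 for png).
#' @return invisibly, \code{path}.
#' @export
render_figure <- function(kind, data, path, group = NULL, value = NULL,
                          stars = NULL, width = 7, height = 5) {
  kinds <- c("timeseries", "box", "bar", "density_map", "profile")
  if (!kind %in% kinds)
    ck_stop("unknown figure kind '", kind, "'; available: ",
            paste(kinds, collapse = ", "))
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                svg = function() grDevices::svg(path, width, height),
                pdf = function() grDevices::pdf(path, width, height),
                png = function() grDevices::png(path, width * 96,
                                                height * 96, res = 96),
                ck_stop("unsupported figure format: .", ext))
  dev()
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)

  if (kind == "timeseries") {
    stopifnot(all(c("animal_id", "timestamp") %in% names(data)))
    v <- value %||% "ee"
    animals <- unique(data$animal_id)
    graphics::par(mfrow = c(length(animals), 1), mar = c(2, 4, 1, 1))
    for (a in animals) {
      d <- data[data$animal_id == a, ]
      graphics::plot(d$timestamp, d[[v]], type = "l", col = "grey20",
                     xlab = "", ylab = paste(a, v))
      if ("phase" %in% names(d)) {
        dark <- d$phase == "dark"
        r <- rle(dark)
        ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
        for (k in which(r$values))
          graphics::rect(d$timestamp[starts[k]], graphics::par("usr")[3],
                         d$timestamp[ends[k]], graphics::par("usr")[4],
                         col = grDevices::adjustcolor("grey", 0.3),
                         border = NA)
      }
    }
  } else if (kind %in% c("box", "bar")) {
    g <- group %||% names(data)[vapply(data, is.character,
                                       logical(1))][1]
    v <- value %||% names(data)[vapply(data, is.numeric, logical(1))][1]
    gf <- factor(data[[g]])
    if (kind == "box") {
      graphics::boxplot(data[[v]] ~ gf, xlab = g, ylab = v, col = "grey85")
    } else {
      m <- tapply(data[[v]], gf, mean)
      s <- tapply(data[[v]], gf, stats::sd)
      bp <- graphics::barplot(m, ylim = c(0, max(m + s, na.rm = TRUE) * 1.2),
                              xlab = g, ylab = v, col = "grey75")
      graphics::arrows(bp, m - s, bp, m + s, angle = 90, code = 3,
                       length = 0.05)
    }
    if (!is.null(stars) && nrow(stars))
      graphics::mtext(stars$stars[1], side = 3, line = -1.5, cex = 1.4)
  } else if (kind == "density_map") {
    h <- if (is.list(data) && !is.data.frame(data)) data[[1]] else data
    graphics::image(seq_len(nrow(h)), seq_len(ncol(h)), h,
                    col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE),
                    xlab = "x bin", ylab = "y bin")
  } else { # profile
    v <- value %||% "value"
    animals <- unique(data$animal_id)
    cols <- grDevices::hcl.colors(max(2, length(animals)), "Dark 3")
    graphics::plot(NULL, xlim = range(data$window_start),
                   ylim = range(data[[v]], na.rm = TRUE),
                   xlab = "zeitgeber time [h]", ylab = v)
    for (i in seq_along(animals)) {
      d <- data[data$animal_id == animals[i], ]
      graphics::lines(d$window_start, d[[v]], col = cols[i])
    }
  }
  invisible(path)
}
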