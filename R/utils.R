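# Internal helpers shared across modules.

# All timestamps in the package are POSIXct pinned to UTC: experiments run on
# one local clock and no timezone arithmetic is ever wanted (a DST jump inside
# a 3-day trace would corrupt interval logic).
CK_TZ <- "UTC"

ck_time <- function(x, format = "%Y-%m-%d %H:%M:%S") {
  as.POSIXct(x, tz = CK_TZ, format = format)
}

# Parse numbers written with either decimal mark. Empty strings -> NA.
parse_num <- function(x, decimal_mark = ".") {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  if (decimal_mark == ",") x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

# Format numbers for fixture files: 12 significant digits guarantees
# round-trips well inside 1e-9 relative tolerance without bloating files.
format_num <- function(x, decimal_mark = ".") {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.12g", v)
  }, character(1))
  if (decimal_mark == ",") out <- gsub(".", ",", out, fixed = TRUE)
  out
}

# Parse "HH:MM" clock strings to fractional hours.
clock_hours <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    h <- as.numeric(p[1])
    m <- if (length(p) >= 2) as.numeric(p[2]) else 0
    s <- if (length(p) >= 3) as.numeric(p[3]) else 0
    (h + m / 60 + s / 3600) %% 24
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ck_stop <- function(...) stop(paste0(...), call. = FALSE)
ck_warn <- function(...) warning(paste0(...), call. = FALSE)

# data.frame row-subset that keeps calokit attributes (base `[` drops them).
subset_keep_attrs <- function(df, keep) {
  at <- attributes(df)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (nm in setdiff(names(at), c("names", "row.names", "class")))
    attr(out, nm) <- at[[nm]]
  class(out) <- class(df)
  out
}
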