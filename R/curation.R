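#' Curation configuration
#'
#' Bundles all tunables of the curation stage. Consistency checks only flag
#' problems; removal happens through the explicit corrective actions
#' (z-score outlier removal, trimming, day selection, exclusions,
#' resampling), so the audit report can always reconcile row counts.
#'
#' @param check_negative_gas flag samples with vo2 < 0 or vco2 < 0.
#' @param remove_negative_gas corrective action: actually drop flagged
#'   negative-gas samples (off by default; flagging alone never removes).
#' @param min_sample_interval seconds; animals whose median sampling interval
#'   is below this are flagged as high-frequency.
#' @param enforce_complete_days keep only days passing the completeness rule.
#' @param complete_day_min_fraction a day is complete iff observed samples >=
#'   this fraction of the expected 24 h / nominal-interval count.
#' @param temp_range plausible ambient-temperature range in degrees C.
#' @param z_threshold z-score magnitude above which a sample is an outlier.
#' @param z_scope \code{"per_animal"} (each animal scored against its own
#'   mean/sd) or \code{"pooled"}.
#' @param z_channels channels to outlier-filter in the full pipeline.
#' @param trim_start,trim_end hours trimmed from each animal's experiment
#'   start/end (habituation and handling artifacts).
#' @param day_selection \code{"zeitgeber"} (days start at ZT0) or
#'   \code{"calendar"} (midnight).
#' @param excluded_animals,excluded_days animal ids / "YYYY-MM-DD" dates
#'   dropped outright.
#' @param target_interval optional resampling interval in minutes.
#' @return a \code{curation_config} list.
#' @export
curation_config <- function(check_negative_gas = TRUE,
                            remove_negative_gas = FALSE,
                            min_sample_interval = 60,
                            enforce_complete_days = FALSE,
                            complete_day_min_fraction = 0.95,
                            temp_range = c(20, 26),
                            z_threshold = 3,
                            z_scope = c("per_animal", "pooled"),
                            z_channels = character(0),
                            trim_start = 0, trim_end = 0,
                            day_selection = c("zeitgeber", "calendar"),
                            excluded_animals = character(0),
                            excluded_days = character(0),
                            target_interval = NULL) {
  stopifnot(z_threshold > 0,
            complete_day_min_fraction > 0, complete_day_min_fraction <= 1,
            trim_start >= 0, trim_end >= 0)
  structure(list(
    check_negative_gas = isTRUE(check_negative_gas),
    remove_negative_gas = isTRUE(remove_negative_gas),
    min_sample_interval = min_sample_interval,
    enforce_complete_days = isTRUE(enforce_complete_days),
    complete_day_min_fraction = complete_day_min_fraction,
    temp_range = temp_range,
    z_threshold = z_threshold,
    z_scope = match.arg(z_scope),
    z_channels = z_channels,
    trim_start = trim_start, trim_end = trim_end,
    day_selection = match.arg(day_selection),
    excluded_animals = excluded_animals,
    excluded_days = excluded_days,
    target_interval = target_interval
  ), class = "curation_config")
}

report_row <- function(name, n_flagged, n_removed, affected = character(0),
                       params = "") {
  data.frame(check = name, n_flagged = n_flagged, n_removed = n_removed,
             affected = paste(affected, collapse = "|"), params = params,
             stringsAsFactors = FALSE)
}

median_interval <- function(ts) {
  if (length(ts) < 2) return(NA_real_)
  stats::median(as.numeric(diff(ts), units = "secs"))
}

#' Run the pre-defined consistency checks
#'
#' Flags (never removes): negative respiratory gas values, animals sampled
#' faster than \code{min_sample_interval}, incomplete days, and ambient
#' temperatures outside \code{temp_range}. Users decide on corrective
#' actions; see [curate()].
#'
#' @param frame a [calorimetry_frame()].
#' @param config a [curation_config()].
#' @param pp photoperiod (needed for zeitgeber day completeness); optional.
#' @return a \code{curation_report} data.frame: one row per enabled check
#'   with flagged/removed counts and affected animals or days.
#' @export
run_consistency_checks <- function(frame, config = curation_config(),
                                   pp = NULL) {
  stopifnot(nrow(frame) > 0)
  rep <- list()
  if (config$check_negative_gas) {
    bad <- frame$vo2 < 0 | frame$vco2 < 0
    bad[is.na(bad)] <- FALSE
    rep$neg <- report_row("negative_gas", sum(bad), 0L,
                          unique(frame$animal_id[bad]))
  }
  med <- vapply(split(frame$timestamp, frame$animal_id), median_interval,
                numeric(1))
  fast <- names(med)[!is.na(med) & med < config$min_sample_interval]
  n_fast <- sum(frame$animal_id %in% fast)
  rep$hf <- report_row("high_frequency", n_fast, 0L, fast,
                       sprintf("min_sample_interval=%gs",
                               config$min_sample_interval))
  cd <- day_completeness(frame, config, pp)
  incomplete <- cd[!cd$complete, , drop = FALSE]
  rep$days <- report_row("complete_days", sum(incomplete$n_obs), 0L,
                         unique(paste0(incomplete$animal_id, "@day",
                                       incomplete$day)),
                         sprintf("min_fraction=%g, mode=%s",
                                 config$complete_day_min_fraction,
                                 config$day_selection))
  if ("temp_ambient" %in% names(frame)) {
    oob <- frame$temp_ambient < config$temp_range[1] |
      frame$temp_ambient > config$temp_range[2]
    oob[is.na(oob)] <- FALSE
    rep$temp <- report_row("temperature_range", sum(oob), 0L,
                           unique(frame$animal_id[oob]),
                           sprintf("range=[%g,%g]C", config$temp_range[1],
                                   config$temp_range[2]))
  }
  out <- do.call(rbind, rep)
  rownames(out) <- NULL
  class(out) <- c("curation_report", "data.frame")
  out
}

# Day index of each sample: zeitgeber days are anchored at the lights-on
# immediately preceding each animal's first sample; calendar days at midnight.
day_index <- function(frame, mode, pp = NULL) {
  secs <- as.numeric(frame$timestamp)
  if (mode == "calendar")
    return(floor(secs / 86400))
  if (is.null(pp)) pp <- default_photoperiod()
  # shift clock so that lights-on aligns with 00:00, then take calendar days
  floor((secs - pp$lights_on * 3600) / 86400)
}

day_completeness <- function(frame, config, pp = NULL) {
  mode <- config$day_selection
  if (mode == "zeitgeber" && is.null(pp))
    pp <- attr(frame, "photoperiod")
  di <- day_index(frame, mode, pp)
  parts <- split(seq_len(nrow(frame)), frame$animal_id)
  out <- lapply(names(parts), function(a) {
    idx <- parts[[a]]
    nominal <- median_interval(frame$timestamp[idx])
    expected <- if (is.na(nominal) || nominal <= 0) NA_real_ else
      86400 / nominal
    tab <- table(di[idx])
    data.frame(animal_id = a, day = as.numeric(names(tab)),
               n_obs = as.integer(tab), n_expected = expected,
               complete = as.integer(tab) >=
                 config$complete_day_min_fraction * expected)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Remove outliers by z-score thresholding
#'
#' Single-pass scoring: within each scope group (per animal, or pooled across
#' animals), \eqn{z_i = (x_i - \bar x)/s} with mean and sd computed once on
#' the pre-removal data — no iterative re-scoring. Samples with |z| above the
#' threshold are removed. Groups with zero variance are left untouched with
#' a warning.
#'
#' @param frame a [calorimetry_frame()].
#' @param channel channel name to score (e.g. "vo2").
#' @param config a [curation_config()] (uses z_threshold and z_scope).
#' @return list with \code{frame} (filtered) and \code{removed} (data.frame:
#'   animal_id, timestamp, value, z).
#' @export
remove_outliers_zscore <- function(frame, channel, config = curation_config()) {
  if (!channel %in% names(frame)) ck_stop("unknown channel: ", channel)
  x <- frame[[channel]]
  if (!is.numeric(x)) ck_stop("channel ", channel, " is not numeric")
  groups <- if (config$z_scope == "per_animal") frame$animal_id
            else rep("all", nrow(frame))
  z <- rep(NA_real_, nrow(frame))
  for (g in unique(groups)) {
    idx <- which(groups == g & !is.na(x))
    if (length(idx) < 3) next
    mu <- mean(x[idx]); s <- stats::sd(x[idx])
    if (!is.finite(s) || s == 0) {
      ck_warn("zero variance in ", channel, " for group '", g,
              "': no outliers removed there")
      next
    }
    z[idx] <- (x[idx] - mu) / s
  }
  drop <- !is.na(z) & abs(z) > config$z_threshold
  removed <- data.frame(animal_id = frame$animal_id[drop],
                        timestamp = frame$timestamp[drop],
                        channel = rep(channel, sum(drop)),
                        value = x[drop], z = z[drop])
  list(frame = subset_keep_attrs(frame, !drop), removed = removed)
}

#' Remove samples inside a time/value rectangle
#'
#' Programmatic equivalent of a graphical rectangular selection: removes
#' samples whose timestamp lies in \code{time_window} and whose
#' \code{channel} value lies in \code{value_window} (both closed intervals).
#'
#' @param frame a [calorimetry_frame()].
#' @param channel channel name.
#' @param time_window length-2 POSIXct (or parseable strings).
#' @param value_window length-2 numeric.
#' @return list with \code{frame} and \code{removed}.
#' @export
remove_region <- function(frame, channel, time_window, value_window) {
  if (!channel %in% names(frame)) ck_stop("unknown channel: ", channel)
  tw <- sort(if (inherits(time_window, "POSIXct")) time_window
             else ck_time(time_window))
  vw <- sort(value_window)
  x <- frame[[channel]]
  inside <- frame$timestamp >= tw[1] & frame$timestamp <= tw[2] &
    !is.na(x) & x >= vw[1] & x <= vw[2]
  removed <- data.frame(animal_id = frame$animal_id[inside],
                        timestamp = frame$timestamp[inside],
                        channel = rep(channel, sum(inside)),
                        value = x[inside], z = rep(NA_real_, sum(inside)))
  list(frame = subset_keep_attrs(frame, !inside), removed = removed)
}

#' Trim habituation/handling segments
#'
#' Drops, per animal, all samples within \code{trim_start} hours of that
#' animal's experiment start and within \code{trim_end} hours of its end.
#' Trims are anchored to the experiment span recorded at ingest, so applying
#' the same trim twice changes nothing.
#'
#' @param frame a [calorimetry_frame()].
#' @param trim_start,trim_end hours.
#' @return the trimmed frame.
#' @export
trim_experiment <- function(frame, trim_start = 0, trim_end = 0) {
  stopifnot(trim_start >= 0, trim_end >= 0)
  if (trim_start == 0 && trim_end == 0) return(frame)
  sp <- frame_span(frame)
  i0 <- match(frame$animal_id, sp$animal_id)
  keep <- frame$timestamp >= sp$start[i0] + trim_start * 3600 &
    frame$timestamp <= sp$end[i0] - trim_end * 3600
  emptied <- setdiff(unique(frame$animal_id),
                     unique(frame$animal_id[keep]))
  if (length(emptied))
    ck_warn("trim removed every sample of animal(s): ",
            paste(emptied, collapse = ", "))
  subset_keep_attrs(frame, keep)
}

#' Keep complete (and requested) days
#'
#' Partitions each animal's trace into days — zeitgeber days starting at ZT0
#' or calendar days starting at midnight — and keeps only days whose observed
#' sample count reaches \code{complete_day_min_fraction} of the expected
#' count (24 h divided by the animal's median sampling interval).
#'
#' @param frame a [calorimetry_frame()].
#' @param config a [curation_config()].
#' @param pp photoperiod; required for zeitgeber day selection.
#' @return the day-filtered frame.
#' @export
select_days <- function(frame, config = curation_config(), pp = NULL) {
  if (config$day_selection == "zeitgeber" && is.null(pp)) {
    pp <- attr(frame, "photoperiod")
    if (is.null(pp)) pp <- default_photoperiod()
  }
  cd <- day_completeness(frame, config, pp)
  keep_days <- cd[cd$complete, c("animal_id", "day")]
  if (!nrow(keep_days))
    ck_stop("no complete day in any animal at min_fraction = ",
            config$complete_day_min_fraction)
  di <- day_index(frame, config$day_selection, pp)
  keep <- paste(frame$animal_id, di) %in%
    paste(keep_days$animal_id, keep_days$day)
  subset_keep_attrs(frame, keep)
}

#' Exclude whole animals and whole days
#'
#' @param frame a [calorimetry_frame()].
#' @param excluded_animals animal ids to drop.
#' @param excluded_days "YYYY-MM-DD" calendar dates to drop (all animals).
#' @return the filtered frame.
#' @export
exclude_records <- function(frame, excluded_animals = character(0),
                            excluded_days = character(0)) {
  keep <- !(frame$animal_id %in% excluded_animals)
  if (length(excluded_days)) {
    d <- format(frame$timestamp, "%Y-%m-%d")
    keep <- keep & !(d %in% excluded_days)
  }
  if (!any(keep)) ck_stop("exclusions removed every sample")
  subset_keep_attrs(frame, keep)
}

#' Resample to a uniform (coarser) interval
#'
#' Aggregates each animal's trace into non-overlapping windows of
#' \code{target_interval} minutes aligned to the animal's first sample.
#' Intensive channels (gases, temperature) are averaged; count-like channels
#' (activity, food, water) are summed. The window start becomes the sample
#' timestamp.
#'
#' @param frame a [calorimetry_frame()].
#' @param target_interval minutes; must not undercut the native median
#'   interval.
#' @return the resampled frame.
#' @export
resample_uniform <- function(frame, target_interval) {
  tgt <- target_interval * 60
  sum_ch <- intersect(c("activity_x", "activity_y", "food", "water"),
                      names(frame))
  mean_ch <- intersect(c("vo2", "vco2", "temp_ambient"), names(frame))
  extra_num <- setdiff(names(frame)[vapply(frame, is.numeric, logical(1))],
                       c(sum_ch, mean_ch))
  parts <- split(seq_len(nrow(frame)), frame$animal_id)
  out <- lapply(names(parts), function(a) {
    idx <- parts[[a]]
    native <- median_interval(frame$timestamp[idx])
    if (!is.na(native) && tgt < native)
      ck_stop("target_interval (", target_interval, " min) is finer than ",
              "animal ", a, "'s native interval (", native / 60, " min)")
    t0 <- min(frame$timestamp[idx])
    bin <- floor(as.numeric(frame$timestamp[idx] - t0, units = "secs") / tgt)
    agg <- function(ch, f) tapply(frame[[ch]][idx], bin, f, simplify = TRUE)
    bins <- sort(unique(bin))
    res <- data.frame(animal_id = a,
                      cohort_id = frame$cohort_id[idx][1],
                      timestamp = t0 + bins * tgt)
    for (ch in mean_ch) res[[ch]] <-
      as.numeric(agg(ch, function(v) mean(v, na.rm = TRUE))[as.character(bins)])
    for (ch in sum_ch) res[[ch]] <-
      as.numeric(agg(ch, function(v) sum(v, na.rm = TRUE))[as.character(bins)])
    for (ch in c("source_file", "dialect_name"))
      if (ch %in% names(frame)) res[[ch]] <- frame[[ch]][idx][1]
    res
  })
  df <- do.call(rbind, c(out, make.row.names = FALSE))
  fr <- calorimetry_frame(df, header_meta = attr(frame, "header_meta") %||% list())
  attr(fr, "photoperiod") <- attr(frame, "photoperiod")
  attr(fr, "span") <- frame_span(frame)
  fr
}

#' Run the full curation chain with an audit report
#'
#' Fixed order: consistency checks (flags) — exclusions — z-score outlier
#' removal — trimming — day selection — resampling. Each step appends a row
#' to the audit report; input rows minus output rows always equals the sum of
#' the report's \code{n_removed} column (resampling books its aggregation
#' row-count reduction there).
#'
#' @param frame a [calorimetry_frame()].
#' @param config a [curation_config()].
#' @param pp photoperiod (falls back to the frame's, then to a 12:12 default
#'   with a prominent warning).
#' @return list of class \code{curation_result}: \code{frame},
#'   \code{report}, \code{removed} (row-level log of removed samples).
#' @export
curate <- function(frame, config = curation_config(), pp = NULL) {
  if (is.null(pp)) pp <- attr(frame, "photoperiod")
  if (is.null(pp) && config$day_selection == "zeitgeber")
    pp <- default_photoperiod()
  n_in <- nrow(frame)
  report <- run_consistency_checks(frame, config, pp)
  removed_log <- list()

  if (config$remove_negative_gas) {
    bad <- frame$vo2 < 0 | frame$vco2 < 0
    bad[is.na(bad)] <- FALSE
    removed_log$neg <- data.frame(animal_id = frame$animal_id[bad],
                                  timestamp = frame$timestamp[bad],
                                  channel = rep("vo2/vco2", sum(bad)),
                                  value = frame$vo2[bad],
                                  z = rep(NA_real_, sum(bad)))
    frame <- subset_keep_attrs(frame, !bad)
    report <- rbind(report, report_row("remove_negative_gas", sum(bad),
                                       sum(bad)))
  }
  if (length(config$excluded_animals) || length(config$excluded_days)) {
    n0 <- nrow(frame)
    frame <- exclude_records(frame, config$excluded_animals,
                             config$excluded_days)
    report <- rbind(report, report_row(
      "exclusions", n0 - nrow(frame), n0 - nrow(frame),
      c(config$excluded_animals, config$excluded_days)))
  }
  for (ch in config$z_channels) {
    res <- remove_outliers_zscore(frame, ch, config)
    removed_log[[paste0("z_", ch)]] <- res$removed
    report <- rbind(report, report_row(
      paste0("zscore_", ch), nrow(res$removed), nrow(res$removed),
      unique(res$removed$animal_id),
      sprintf("threshold=%g, scope=%s", config$z_threshold, config$z_scope)))
    frame <- res$frame
  }
  if (config$trim_start > 0 || config$trim_end > 0) {
    n0 <- nrow(frame)
    frame <- trim_experiment(frame, config$trim_start, config$trim_end)
    report <- rbind(report, report_row(
      "trim", n0 - nrow(frame), n0 - nrow(frame), character(0),
      sprintf("start=%gh, end=%gh", config$trim_start, config$trim_end)))
  }
  if (config$enforce_complete_days) {
    n0 <- nrow(frame)
    frame <- select_days(frame, config, pp)
    report <- rbind(report, report_row(
      "day_selection", n0 - nrow(frame), n0 - nrow(frame), character(0),
      sprintf("mode=%s, min_fraction=%g", config$day_selection,
              config$complete_day_min_fraction)))
  }
  if (!is.null(config$target_interval)) {
    n0 <- nrow(frame)
    frame <- resample_uniform(frame, config$target_interval)
    report <- rbind(report, report_row(
      "resample_aggregation", 0L, n0 - nrow(frame), character(0),
      sprintf("target=%gmin", config$target_interval)))
  }
  stopifnot(n_in - nrow(frame) == sum(report$n_removed))
  class(report) <- c("curation_report", "data.frame")
  structure(list(frame = frame, report = report,
                 removed = do.call(rbind, c(removed_log,
                                            make.row.names = FALSE))),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("<curation_result> %d samples retained\n", nrow(x$frame)))
  print(as.data.frame(x$report))
  invisible(x)
}
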