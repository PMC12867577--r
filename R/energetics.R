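#' Respiratory exchange ratio
#'
#' RER = V̇CO2 / V̇O2 (both in ml/h). Values outside the physiological band
#' [0.5, 1.3] are flagged, never filtered; non-positive V̇O2 yields a missing
#' value with a flag (curation should have caught it).
#'
#' @param vo2,vco2 numeric vectors, ml/h.
#' @return numeric vector of RER values with attribute \code{"flag"}
#'   (logical: TRUE where the value is missing or out of the physiological
#'   band).
#' @export
compute_rer <- function(vo2, vco2) {
  rer <- ifelse(vo2 > 0, vco2 / vo2, NA_real_)
  flag <- is.na(rer) | rer < 0.5 | rer > 1.3
  structure(rer, flag = flag)
}

# Caloric-equivalent equation registry. Each entry maps (vo2 [ml/h], rer) to
# EE [kJ/h]. The caloric equivalent a + b*RER is in mW per (ml O2/h); the
# factor 3.6/1000 converts mW to kJ/h.
.ee_equations <- new.env(parent = emptyenv())

init_ee_registry <- function() {
  # Heldmaier: caloric equivalent 4.44 + 1.43*RER mW/(ml O2/h)
  assign("heldmaier", list(
    fn = function(vo2, rer) (4.44 + 1.43 * rer) * vo2 * 3.6 / 1000,
    description = "EE = (4.44 + 1.43 RER) * VO2 * 3.6/1000 [kJ/h]"
  ), .ee_equations)
  # Weir (abbreviated, no urinary nitrogen): 3.941 kcal/L O2 + 1.106 kcal/L
  # CO2; converted to kJ/h with VO2 in ml/h and VCO2 = RER*VO2.
  assign("weir", list(
    fn = function(vo2, rer) (3.941 + 1.106 * rer) * vo2 / 1000 * 4.184,
    description = "EE = (3.941 + 1.106 RER) * VO2/1000 * 4.184 [kJ/h]"
  ), .ee_equations)
}

#' List available energy-expenditure equations
#' @return data.frame of equation ids and formulas.
#' @export
list_equations <- function() {
  ids <- sort(ls(.ee_equations))
  data.frame(equation = ids,
             formula = vapply(ids, function(i)
               get(i, .ee_equations)$description, character(1)),
             row.names = NULL)
}

#' Energy expenditure from oxygen consumption
#'
#' Reconstructs EE (kJ/h) from V̇O2 and RER via a caloric-equivalent
#' equation. The default is the Heldmaier equation,
#' EE = (4.44 + 1.43·RER)·V̇O2·3.6/1000, with V̇O2 in ml/h; a Weir-type
#' alternative is registered as \code{"weir"}.
#'
#' @param vo2 ml/h (>= 0).
#' @param rer dimensionless respiratory exchange ratio.
#' @param equation equation id; see [list_equations()].
#' @return EE in kJ/h (linear in vo2, and in rer at fixed vo2).
#' @export
compute_ee <- function(vo2, rer, equation = "heldmaier") {
  if (!exists(equation, .ee_equations))
    ck_stop("unknown equation '", equation, "'; available: ",
            paste(sort(ls(.ee_equations)), collapse = ", "))
  get(equation, .ee_equations)$fn(vo2, rer)
}

# Frayn-type non-protein stoichiometry, g/L of gas exchanged; and energy
# densities used for the closure consistency check (kJ/g).
CK_FRAYN <- c(fat_vo2 = 1.67, fat_vco2 = 1.67, cho_vco2 = 4.55,
              cho_vo2 = 3.21)
CK_ENERGY_DENSITY <- c(fat = 39.6, cho = 16.7)

#' Substrate oxidation rates
#'
#' Non-protein fat and carbohydrate oxidation from gas exchange
#' (Frayn-type stoichiometry): fat_ox = 1.67·(V̇O2 − V̇CO2)/1000,
#' cho_ox = (4.55·V̇CO2 − 3.21·V̇O2)/1000, both g/h with gases in ml/h.
#' Negative rates (RER outside the non-protein band) are flagged, never
#' clamped.
#'
#' @param vo2,vco2 ml/h.
#' @return data.frame with \code{fat_ox}, \code{cho_ox} (g/h) and
#'   \code{ox_flag} (TRUE where either rate is negative).
#' @export
substrate_oxidation <- function(vo2, vco2) {
  fat <- CK_FRAYN[["fat_vo2"]] * (vo2 - vco2) / 1000
  cho <- (CK_FRAYN[["cho_vco2"]] * vco2 - CK_FRAYN[["cho_vo2"]] * vo2) / 1000
  data.frame(fat_ox = fat, cho_ox = cho,
             ox_flag = !is.na(fat) & !is.na(cho) & (fat < 0 | cho < 0))
}

#' Derive the per-sample energy trace
#'
#' Computes RER, EE, substrate oxidation, zeitgeber time and light/dark phase
#' for every sample of a (curated) frame; optional channels are carried
#' along so downstream aggregation has them.
#'
#' @param frame a [calorimetry_frame()].
#' @param pp a [photoperiod()]; defaults to the frame's.
#' @param equation EE equation id.
#' @return an \code{energy_trace} data.frame: animal_id, timestamp, zt,
#'   phase, rer, rer_flag, ee, fat_ox, cho_ox, ox_flag, plus any optional
#'   channels of the frame.
#' @export
energy_trace <- function(frame, pp = NULL, equation = "heldmaier") {
  if (is.null(pp)) pp <- attr(frame, "photoperiod")
  if (is.null(pp)) pp <- default_photoperiod()
  rer <- compute_rer(frame$vo2, frame$vco2)
  zt <- zeitgeber_time(frame$timestamp, pp)
  ox <- substrate_oxidation(frame$vo2, frame$vco2)
  out <- data.frame(animal_id = frame$animal_id,
                    cohort_id = frame$cohort_id,
                    timestamp = frame$timestamp,
                    zt = zt, phase = zt_phase(zt, pp),
                    rer = as.numeric(rer), rer_flag = attr(rer, "flag"),
                    ee = compute_ee(frame$vo2, as.numeric(rer), equation))
  out <- cbind(out, ox)
  for (ch in intersect(CK_OPTIONAL_CHANNELS, names(frame)))
    out[[ch]] <- frame[[ch]]
  attr(out, "photoperiod") <- pp
  attr(out, "equation") <- equation
  class(out) <- c("energy_trace", "data.frame")
  out
}

#' RMR estimation configuration
#'
#' @param window_length minutes; sliding-window length for the
#'   coefficient-of-variation scan (must cover >= 3 samples).
#' @param cov_threshold maximal within-window CoV (sd/mean) for a window to
#'   qualify as resting.
#' @param fallback_percentile fraction of lowest-EE samples averaged when no
#'   window qualifies.
#' @param restrict_phase restrict the scan to one photoperiod phase
#'   (\code{"light"}, \code{"dark"}) or use the whole trace (\code{"none"}).
#' @return an \code{rmr_config} list.
#' @export
rmr_config <- function(window_length = 30, cov_threshold = 0.05,
                       fallback_percentile = 0.05,
                       restrict_phase = c("none", "light", "dark")) {
  stopifnot(window_length > 0, cov_threshold > 0,
            fallback_percentile > 0, fallback_percentile <= 1)
  structure(list(window_length = window_length,
                 cov_threshold = cov_threshold,
                 fallback_percentile = fallback_percentile,
                 restrict_phase = match.arg(restrict_phase)),
            class = "rmr_config")
}

#' Resting metabolic rate from signal variability
#'
#' Slides a window of \code{window_length} minutes over each animal's EE
#' series at single-sample steps (optionally restricted to one photoperiod
#' phase) and computes the coefficient of variation (sd/mean) per window.
#' RMR is the minimum window mean among windows whose CoV stays below
#' \code{cov_threshold}; if no window is quiet enough, RMR falls back to the
#' mean of the lowest \code{fallback_percentile} of EE samples. Total energy
#' expenditure is TEE = 24·mean(EE) over the (curated, complete-day) trace,
#' and activity-related energy expenditure AEE = TEE − 24·RMR; a negative
#' AEE is flagged, never clamped.
#'
#' @param trace an [energy_trace()].
#' @param config an [rmr_config()].
#' @return an \code{rmr_result} data.frame, one row per animal: rmr (kJ/h),
#'   window_start, method_used, tee (kJ/day), aee (kJ/day), aee_flag.
#' @export
estimate_rmr <- function(trace, config = rmr_config()) {
  parts <- split(seq_len(nrow(trace)), trace$animal_id)
  rows <- lapply(names(parts), function(a) {
    idx <- parts[[a]]
    tee <- 24 * mean(trace$ee[idx], na.rm = TRUE)
    sel <- idx
    if (config$restrict_phase != "none")
      sel <- idx[trace$phase[idx] == config$restrict_phase]
    ee <- trace$ee[sel]
    ts <- trace$timestamp[sel]
    keep <- !is.na(ee)
    ee <- ee[keep]; ts <- ts[keep]
    interval <- median_interval(ts)
    if (!length(ee) || is.na(interval))
      ck_stop("animal ", a, ": trace too short for RMR estimation")
    w <- max(3L, round(config$window_length * 60 / interval))
    span_len <- as.numeric(max(ts) - min(ts), units = "mins")
    if (span_len < 2 * config$window_length)
      ck_stop("animal ", a, ": trace spans ", round(span_len), " min, ",
              "need >= 2 x window_length (", 2 * config$window_length, " min)")
    n <- length(ee)
    if (n <= w)
      ck_stop("animal ", a, ": too few samples (", n, ") for a ",
              config$window_length, "-min window")
    starts <- seq_len(n - w + 1L)
    # windowed mean/sd via cumulative sums (single pass, O(n))
    cs <- c(0, cumsum(ee)); cs2 <- c(0, cumsum(ee^2))
    m <- (cs[starts + w] - cs[starts]) / w
    v <- pmax((cs2[starts + w] - cs2[starts]) - w * m^2, 0) / (w - 1)
    cov <- sqrt(v) / m
    ok <- is.finite(cov) & cov <= config$cov_threshold & m > 0
    if (any(ok)) {
      j <- starts[ok][which.min(m[ok])]
      rmr <- min(m[ok])
      method <- "cov_window"
      wstart <- ts[j]
    } else {
      k <- max(1L, ceiling(config$fallback_percentile * n))
      rmr <- mean(sort(ee)[seq_len(k)])
      method <- "percentile_fallback"
      wstart <- as.POSIXct(NA)
    }
    aee <- tee - 24 * rmr
    data.frame(animal_id = a, rmr = rmr, window_start = wstart,
               method_used = method, tee = tee, aee = aee,
               aee_flag = aee < 0)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("rmr_result", "data.frame")
  out
}

#' @export
print.rmr_result <- function(x, ...) {
  cat(sprintf("<rmr_result> %d animal(s)\n", nrow(x)))
  print(as.data.frame(x), digits = 4)
  if (any(x$aee_flag))
    cat("note: negative AEE flagged for",
        paste(x$animal_id[x$aee_flag], collapse = ", "), "\n")
  invisible(x)
}

#' Windowed zeitgeber-time profile
#'
#' Aggregates a channel of the energy trace into tumbling windows of
#' zeitgeber time (e.g. hourly EE profiles). Windows with no samples are
#' omitted.
#'
#' @param trace an [energy_trace()].
#' @param window window length in ZT hours.
#' @param statistic \code{"mean"} or \code{"min"}.
#' @param channel trace channel to aggregate (default \code{"ee"}).
#' @return data.frame: animal_id, window_start (ZT hours), value.
#' @export
windowed_profile <- function(trace, window = 1, statistic = c("mean", "min"),
                             channel = "ee") {
  statistic <- match.arg(statistic)
  if (!channel %in% names(trace)) ck_stop("unknown channel: ", channel)
  f <- if (statistic == "mean") function(v) mean(v, na.rm = TRUE)
       else function(v) min(v, na.rm = TRUE)
  bin <- floor(trace$zt / window) * window
  agg <- stats::aggregate(trace[[channel]],
                          by = list(animal_id = trace$animal_id,
                                    window_start = bin), FUN = f)
  names(agg)[3] <- "value"
  agg[order(agg$animal_id, agg$window_start), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Light/dark phase aggregates
#'
#' Per animal and photoperiod phase: mean EE and RER (intensities), summed
#' food/water intake and activity counts (per-interval quantities).
#'
#' @param trace an [energy_trace()].
#' @return data.frame with one light and one dark row per animal.
#' @export
aggregate_photoperiod <- function(trace) {
  stopifnot("phase" %in% names(trace))
  key <- list(animal_id = trace$animal_id, phase = trace$phase)
  out <- stats::aggregate(trace$ee, by = key,
                          FUN = function(v) mean(v, na.rm = TRUE))
  names(out)[3] <- "mean_ee"
  if ("rer" %in% names(trace))
    out$mean_rer <- stats::aggregate(trace$rer, by = key, FUN = function(v)
      mean(v, na.rm = TRUE))$x
  for (ch in intersect(c("food", "water", "activity_x", "activity_y"),
                       names(trace)))
    out[[paste0(ch, "_sum")]] <- stats::aggregate(trace[[ch]], by = key,
                                                  FUN = function(v)
                                                    sum(v, na.rm = TRUE))$x
  out[order(out$animal_id, out$phase), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Locomotion density map
#'
#' Joint 2-D histogram of the per-sample beam-break coordinates
#' (activity_x, activity_y), each sample weighted by its total count, and
#' normalized to unit mass. Bin edges span the observed coordinate range.
#'
#' @param frame a frame or trace with activity_x/activity_y channels.
#' @param bins integer vector (nx, ny).
#' @return list per animal of nx-by-ny matrices summing to 1 (all-zero when
#'   the animal shows no activity).
#' @export
locomotion_density <- function(frame, bins = c(10, 10)) {
  if (!all(c("activity_x", "activity_y") %in% names(frame)))
    ck_stop("activity_x/activity_y channels are required for a density map")
  nx <- bins[1]; ny <- bins[2]
  lapply(split(seq_len(nrow(frame)), frame$animal_id), function(idx) {
    x <- frame$activity_x[idx]; y <- frame$activity_y[idx]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    w <- x + y
    h <- matrix(0, nx, ny)
    if (!length(x) || sum(w) == 0) return(h)
    ex <- seq(min(x), max(x), length.out = nx + 1)
    ey <- seq(min(y), max(y), length.out = ny + 1)
    ix <- pmin(findInterval(x, ex, rightmost.closed = TRUE), nx)
    iy <- pmin(findInterval(y, ey, rightmost.closed = TRUE), ny)
    for (k in seq_along(x)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + w[k]
    h / sum(h)
  })
}
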