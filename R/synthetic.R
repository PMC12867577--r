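#' Parameters of a simulated animal
#'
#' The generator emulates what a metabolic cage records from a mouse-sized
#' animal: a resting-plateau energy expenditure, a smoothed dark-phase
#' increment (nocturnal animals are active after lights-off), exponentially
#' decaying activity bursts concentrated in the dark phase, Gaussian
#' measurement noise, and an RER that drifts between a light-phase
#' (fat-leaning) and a dark-phase (carbohydrate-leaning) value. Gas traces
#' are obtained by inverting the Heldmaier equation, so recomputing EE from
#' the generated gases reproduces the ground truth exactly.
#'
#' @param rmr resting metabolic rate, kJ/h.
#' @param dark_increment EE added during the dark phase, kJ/h (ramped over
#'   \code{transition_minutes}).
#' @param burst_rate activity bursts per hour (80\% of the rate falls in the
#'   dark phase, 20\% in the light phase).
#' @param burst_amplitude peak EE of a burst, kJ/h.
#' @param burst_decay exponential decay constant of a burst, minutes.
#' @param rer_light,rer_dark phase RER targets.
#' @param noise_sd Gaussian measurement noise on EE, kJ/h.
#' @param sampling_interval minutes between samples.
#' @param n_days experiment length, days.
#' @param body_mass g.
#' @param transition_minutes light/dark transition ramp.
#' @param start first sample timestamp (at lights-on by default).
#' @param seed integer RNG seed.
#' @return an \code{animal_sim_params} list.
#' @export
animal_sim_params <- function(rmr = 8, dark_increment = 6, burst_rate = 2,
                              burst_amplitude = 4, burst_decay = 10,
                              rer_light = 0.75, rer_dark = 0.95,
                              noise_sd = 0.16, sampling_interval = 5,
                              n_days = 3, body_mass = 25,
                              transition_minutes = 30,
                              start = "2024-03-04 07:00:00", seed = 1L) {
  stopifnot(rmr > 0, noise_sd >= 0, sampling_interval > 0, n_days >= 1,
            rer_light >= 0.5, rer_light <= 1.3,
            rer_dark >= 0.5, rer_dark <= 1.3)
  structure(as.list(environment()), class = "animal_sim_params")
}

# Smoothed dark indicator in [0,1]: linear ramps of `ramp` hours at the
# light->dark and dark->light transitions, evaluated in zeitgeber time.
smoothed_dark <- function(zt, pp, ramp_h) {
  d0 <- pp$dark_onset
  up <- pmin(pmax((zt - d0) / ramp_h, 0), 1)        # after dark onset
  down <- pmin(pmax((24 - zt) / ramp_h, 0), 1)      # before next lights-on
  pmin(up, down)
}

#' Simulate a single animal's calorimetry trace
#'
#' @param params an [animal_sim_params()].
#' @param pp a [photoperiod()] (12:12, lights on 07:00 by default).
#' @param animal_id,cohort_id identifiers.
#' @return list with \code{frame} (a [calorimetry_frame()]) and
#'   \code{truth} (the generating parameters plus the noiseless EE series).
#' @export
simulate_animal <- function(params = animal_sim_params(),
                            pp = photoperiod(),
                            animal_id = "A1", cohort_id = "C1") {
  stopifnot(inherits(params, "animal_sim_params"))
  p <- params
  set.seed(p$seed %% .Machine$integer.max)
  dt_min <- p$sampling_interval
  n <- round(p$n_days * 24 * 60 / dt_min)
  t0 <- ck_time(p$start)
  ts <- t0 + seq(0, by = dt_min * 60, length.out = n)
  zt <- zeitgeber_time(ts, pp)
  s <- smoothed_dark(zt, pp, p$transition_minutes / 60)

  # activity bursts: Poisson events, 80/20 dark/light split of the rate
  hours <- p$n_days * 24
  dark_frac <- ((pp$lights_on - pp$lights_off) %% 24) / 24
  n_dark <- stats::rpois(1, 0.8 * p$burst_rate * hours)
  n_light <- stats::rpois(1, 0.2 * p$burst_rate * hours)
  t_rel <- as.numeric(ts - t0, units = "hours")
  is_dark <- s > 0.5
  draw_times <- function(k, pool) {
    if (k == 0 || !any(pool)) return(numeric(0))
    sample(t_rel[pool], k, replace = TRUE) + stats::runif(k, 0, dt_min / 60)
  }
  ev <- c(draw_times(n_dark, is_dark), draw_times(n_light, !is_dark))
  burst <- numeric(n)
  for (e in ev) {
    after <- t_rel >= e
    burst[after] <- burst[after] +
      p$burst_amplitude * exp(-(t_rel[after] - e) * 60 / p$burst_decay)
  }

  eps <- stats::rnorm(n, 0, p$noise_sd)
  ee <- p$rmr + p$dark_increment * s + burst + eps
  rer <- p$rer_light + (p$rer_dark - p$rer_light) * s
  vo2 <- ee * 1000 / 3.6 / (4.44 + 1.43 * rer)
  vco2 <- rer * vo2

  act_total <- stats::rpois(n, 0.5) + round(4 * burst)
  ax <- stats::rbinom(n, act_total, 0.5)
  frame <- data.frame(
    animal_id = animal_id, cohort_id = cohort_id, timestamp = ts,
    vo2 = vo2, vco2 = vco2,
    activity_x = as.numeric(ax), activity_y = as.numeric(act_total - ax),
    food = ifelse(is_dark, stats::rbinom(n, 1, 0.15) * 0.12, 0),
    water = ifelse(is_dark, stats::rbinom(n, 1, 0.2) * 0.1, 0),
    temp_ambient = 23 + stats::rnorm(n, 0, 0.2),
    source_file = NA_character_, dialect_name = "synthetic")
  fr <- calorimetry_frame(frame)
  attr(fr, "photoperiod") <- pp
  truth <- list(params = p, ee_true = ee, ee_noiseless = ee - eps,
                rer_true = rer, burst = burst, dark_frac = dark_frac)
  list(frame = fr, truth = truth)
}

#' Parameters of a simulated two-group cohort
#'
#' Animal-level model: group A/B with a fixed additive \code{group_effect}
#' on group B's RMR, a linear body-mass slope around the cohort mean mass,
#' and animal-level Gaussian jitter. Hierarchical seeding (cohort seed ->
#' per-animal seeds) means adding an animal never perturbs the others.
#'
#' @param n_per_group animals per group (>= 2).
#' @param group_effect kJ/h added to group B's RMR.
#' @param mass_slope kJ/h per g of body mass (around the mean).
#' @param mass_mean,mass_sd body-mass distribution, g.
#' @param animal_sd animal-level RMR jitter, kJ/h.
#' @param template shared [animal_sim_params()] template.
#' @param pp photoperiod.
#' @param seed cohort seed.
#' @return a \code{cohort_sim_params} list.
#' @export
cohort_sim_params <- function(n_per_group = 8, group_effect = 2,
                              mass_slope = 0.25, mass_mean = 25, mass_sd = 2,
                              animal_sd = 1,
                              template = animal_sim_params(),
                              pp = photoperiod(), seed = 20240304L) {
  stopifnot(n_per_group >= 2, mass_sd >= 0, animal_sd >= 0)
  structure(as.list(environment()), class = "cohort_sim_params")
}

#' Simulate a two-group cohort with known ground truth
#'
#' @param params a [cohort_sim_params()].
#' @param timeseries generate full gas time series (TRUE) or only the
#'   animal-level summaries and metadata (FALSE; orders of magnitude faster
#'   for calibration studies on the statistics stage, and distributionally
#'   identical at the animal level by construction).
#' @return list with \code{frame} (NULL when \code{timeseries = FALSE}),
#'   \code{metadata} (a \code{metadata_table} with group + body_mass) and
#'   \code{truth} (per-animal true RMR etc.).
#' @export
simulate_cohort <- function(params = cohort_sim_params(), timeseries = TRUE) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  n <- 2L * p$n_per_group
  ids <- sprintf("A%02d", seq_len(n))
  group <- rep(c("A", "B"), each = p$n_per_group)
  # hierarchical seeding: one derived seed per animal, all below 2^31
  animal_seeds <- (p$seed + 7919L * seq_len(n)) %% .Machine$integer.max
  mass <- numeric(n); jitter <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(animal_seeds[i])
    mass[i] <- stats::rnorm(1, p$mass_mean, p$mass_sd)
    jitter[i] <- stats::rnorm(1, 0, p$animal_sd)
  }
  rmr_i <- p$template$rmr + p$group_effect * (group == "B") +
    p$mass_slope * (mass - p$mass_mean) + jitter
  rmr_i <- pmax(rmr_i, 0.5)  # keep physically positive

  frames <- NULL
  if (timeseries) {
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      ap <- p$template
      ap$rmr <- rmr_i[i]
      ap$body_mass <- mass[i]
      ap$seed <- animal_seeds[i] + 1L
      frames[[i]] <- simulate_animal(ap, p$pp, animal_id = ids[i],
                                     cohort_id = "C1")$frame
    }
    frame <- do.call(rbind, lapply(frames, as.data.frame))
    frame <- calorimetry_frame(frame)
    attr(frame, "photoperiod") <- p$pp
  } else frame <- NULL

  meta <- data.frame(animal_id = ids, cohort_id = "C1", genotype = group,
                     body_mass = mass)
  class(meta) <- c("metadata_table", "data.frame")
  attr(meta, "photoperiod") <- p$pp
  truth <- data.frame(animal_id = ids, group = group, body_mass = mass,
                      rmr_true = rmr_i,
                      dark_increment = p$template$dark_increment)
  list(frame = frame, metadata = meta, truth = truth)
}

#' Write a frame as an instrument-dialect fixture
#'
#' Emits files conforming exactly to a registered dialect (header block,
#' delimiter, decimal mark, gas units, per-animal file splitting where the
#' dialect demands it), the counterpart of [read_dataset()]. Channels the
#' dialect cannot represent are dropped from the file with a warning.
#'
#' @param frame a [calorimetry_frame()].
#' @param dialect dialect name or spec.
#' @param path output file; for per-animal-file dialects, a directory.
#' @return invisibly, the file(s) written.
#' @export
write_fixture <- function(frame, dialect, path) {
  spec <- get_dialect(dialect)
  cmap <- spec$column_map
  present <- intersect(c(CK_GAS_CHANNELS, CK_OPTIONAL_CHANNELS), names(frame))
  unrepresentable <- setdiff(present, names(cmap))
  if (length(unrepresentable))
    ck_warn("dialect ", spec$name, " cannot represent channel(s), dropped: ",
            paste(unrepresentable, collapse = ", "))
  chans <- intersect(names(cmap), c(present, "animal_id"))

  body_for <- function(df) {
    tab <- list()
    if (length(spec$timestamp_cols) == 1) {
      tab[[spec$timestamp_cols]] <- format(df$timestamp,
                                           spec$timestamp_format)
    } else {
      for (k in seq_along(spec$timestamp_cols))
        tab[[spec$timestamp_cols[k]]] <- format(df$timestamp,
                                                spec$timestamp_format[k])
    }
    for (ch in chans) {
      col <- cmap[[ch]]
      if (ch == "animal_id") { tab[[col]] <- df$animal_id; next }
      v <- df[[ch]]
      if (ch %in% CK_GAS_CHANNELS)
        v <- v / CK_GAS_UNIT_FACTORS[[spec$gas_units[[ch]]]]
      tab[[col]] <- format_num(v, spec$decimal_mark)
    }
    tab <- as.data.frame(tab, check.names = FALSE, optional = TRUE)
    c(paste(names(tab), collapse = spec$delimiter),
      apply(tab, 1, paste, collapse = spec$delimiter))
  }

  if (spec$per_animal_files) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    written <- character(0)
    for (a in unique(frame$animal_id)) {
      df <- frame[frame$animal_id == a, , drop = FALSE]
      hdr <- c(spec$header_template,
               paste(spec$animal_header_key, a, sep = spec$delimiter))
      hdr <- hdr[seq_len(spec$header_lines)]
      f <- file.path(path, paste0(gsub("[^A-Za-z0-9_-]", "_", a), ".csv"))
      writeLines(c(hdr, body_for(df)), f)
      written <- c(written, f)
    }
    return(invisible(written))
  }
  hdr <- spec$header_template
  writeLines(c(hdr, body_for(frame)), path)
  invisible(path)
}
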