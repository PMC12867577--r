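# Shared fixture builders. Everything is generated in code at test time;
# nothing binary is stored in the repository.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal hand-built frame: regular sampling, constant or supplied gases.
make_frame <- function(animals = "A1", n = 24, interval_min = 60,
                       vo2 = 1000, vco2 = 750,
                       start = "2024-03-04 07:00:00", ...) {
  extra <- list(...)
  rows <- lapply(animals, function(a) {
    df <- data.frame(
      animal_id = a,
      timestamp = calokit:::ck_time(start) +
        seq(0, by = interval_min * 60, length.out = n),
      vo2 = rep_len(vo2, n), vco2 = rep_len(vco2, n))
    for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
    df
  })
  calorimetry_frame(do.call(rbind, rows))
}

# Energy trace built directly (for RMR unit tests), bypassing gas inversion.
make_trace <- function(ee, interval_min = 5, start = "2024-03-04 07:00:00",
                       animal_id = "A1", pp = photoperiod()) {
  ts <- calokit:::ck_time(start) +
    seq(0, by = interval_min * 60, length.out = length(ee))
  zt <- zeitgeber_time(ts, pp)
  structure(data.frame(animal_id = animal_id, timestamp = ts, zt = zt,
                       phase = zt_phase(zt, pp), ee = ee),
            class = c("energy_trace", "data.frame"))
}

write_lines_tmp <- function(lines, ext = ".csv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
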