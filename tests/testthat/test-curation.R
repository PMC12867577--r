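test_that("consistency checks flag but never remove", {
  fr <- make_frame("A1", n = 10, vo2 = c(rep(1000, 9), -5),
                   temp_ambient = c(rep(23, 9), 31))
  rep <- run_consistency_checks(fr, curation_config(day_selection = "calendar"))
  expect_s3_class(rep, "curation_report")
  expect_equal(rep$n_flagged[rep$check == "negative_gas"], 1)
  expect_equal(rep$n_flagged[rep$check == "temperature_range"], 1)
  expect_true(all(rep$n_removed == 0))

  clean <- simulate_animal(animal_sim_params(n_days = 1, seed = 5))$frame
  rep2 <- run_consistency_checks(clean, curation_config())
  expect_equal(rep2$n_flagged[rep2$check %in%
                                c("negative_gas", "high_frequency")],
               c(0, 0))

  fast <- make_frame("F1", n = 20, interval_min = 0.5)  # 30 s sampling
  rep3 <- run_consistency_checks(fast,
                                 curation_config(min_sample_interval = 60,
                                                 day_selection = "calendar"))
  expect_equal(rep3$n_flagged[rep3$check == "high_frequency"], 20)
  expect_match(rep3$affected[rep3$check == "high_frequency"], "F1")
})

test_that("z-score outlier removal is single-pass and matches the spec example", {
  x <- c(rep(10, 9), 100)
  fr <- make_frame("A1", n = 10, vo2 = x)
  res <- remove_outliers_zscore(fr, "vo2", curation_config(z_threshold = 2))
  expect_equal(nrow(res$removed), 1L)
  expect_equal(res$removed$value, 100)
  expect_equal(res$removed$z, (100 - mean(x)) / sd(x))  # ~2.846
  expect_equal(round(res$removed$z, 3), 2.846)
  expect_equal(nrow(res$frame), 9L)

  inf <- remove_outliers_zscore(fr, "vo2", curation_config(z_threshold = 1e12))
  expect_equal(nrow(inf$removed), 0L)

  const <- make_frame("A1", n = 10, vo2 = 10)
  expect_warning(r0 <- remove_outliers_zscore(const, "vo2",
                                              curation_config(z_threshold = 2)),
                 "zero variance")
  expect_equal(nrow(r0$removed), 0L)
})

test_that("z-score filter agrees with a brute-force oracle on random frames", {
  # oracle: explicit per-group loop, no shared code with the implementation
  oracle_keep <- function(fr, channel, thr, scope) {
    keep <- rep(TRUE, nrow(fr))
    groups <- if (scope == "per_animal") unique(fr$animal_id) else "all"
    for (g in groups) {
      idx <- if (scope == "per_animal") which(fr$animal_id == g)
             else seq_len(nrow(fr))
      v <- fr[[channel]][idx]
      if (length(v) < 3) next
      mu <- sum(v) / length(v)
      s <- sqrt(sum((v - mu)^2) / (length(v) - 1))
      if (s == 0) next
      for (k in seq_along(idx))
        if (abs((v[k] - mu) / s) > thr) keep[idx[k]] <- FALSE
    }
    keep
  }
  set.seed(99)
  for (rep_i in 1:20) {
    na <- sample(1:4, 1)
    n <- sample(10:120, 1)
    fr <- make_frame(paste0("A", seq_len(na)), n = n,
                     vo2 = 1000, vco2 = 700)
    fr$vo2 <- fr$vo2 + rnorm(nrow(fr), 0, 50) +
      ifelse(runif(nrow(fr)) < 0.05, 500, 0)
    thr <- runif(1, 1.5, 3.5)
    scope <- sample(c("per_animal", "pooled"), 1)
    res <- remove_outliers_zscore(fr, "vo2",
                                  curation_config(z_threshold = thr,
                                                  z_scope = scope))
    keep <- oracle_keep(fr, "vo2", thr, scope)
    expect_equal(nrow(res$frame), sum(keep))
    expect_equal(res$frame$vo2, fr$vo2[keep])
  }
})

test_that("rectangular region removal hits exactly the selected samples", {
  fr <- make_frame("A1", n = 10, vo2 = 1:10 * 100)
  tw <- c(fr$timestamp[3], fr$timestamp[4])
  res <- remove_region(fr, "vo2", tw, c(250, 450))
  expect_equal(nrow(res$removed), 2L)
  expect_equal(res$removed$value, c(300, 400))

  degenerate <- remove_region(fr, "vo2", c(fr$timestamp[3], fr$timestamp[3]),
                              c(0, 0))
  expect_equal(nrow(degenerate$removed), 0L)
  allrm <- remove_region(fr, "vo2", range(fr$timestamp), c(-Inf, Inf))
  expect_equal(nrow(allrm$frame), 0L)
})

test_that("trimming is anchored to the experiment span and idempotent", {
  fr <- make_frame("A1", n = 72, interval_min = 60)  # 72 h at 1/h
  tr <- trim_experiment(fr, 12, 12)
  expect_equal(nrow(tr), 48L)  # 48 h retained
  expect_equal(as.data.frame(trim_experiment(tr, 12, 12)),
               as.data.frame(tr))  # anchored: re-trim changes nothing
  expect_equal(as.data.frame(trim_experiment(fr, 0, 0)), as.data.frame(fr))
  expect_warning(empty <- trim_experiment(fr, 100, 0), "every sample")
  expect_equal(nrow(empty), 0L)
})

test_that("day selection keeps exactly the complete middle day", {
  # half day / full day / half day at 1-h sampling, calendar days
  ts <- c(calokit:::ck_time("2024-03-04 12:00:00") + 3600 * (0:11),
          calokit:::ck_time("2024-03-05 00:00:00") + 3600 * (0:23),
          calokit:::ck_time("2024-03-06 00:00:00") + 3600 * (0:11))
  fr <- calorimetry_frame(data.frame(animal_id = "A1", timestamp = ts,
                                     vo2 = 1000, vco2 = 700))
  cfg <- curation_config(day_selection = "calendar",
                         complete_day_min_fraction = 0.95)
  kept <- select_days(fr, cfg)
  expect_equal(nrow(kept), 24L)
  expect_true(all(format(kept$timestamp, "%Y-%m-%d") == "2024-03-05"))

  # min_fraction -> 0+ retains all days
  all_kept <- select_days(fr, curation_config(day_selection = "calendar",
                                              complete_day_min_fraction = 1e-9))
  expect_equal(nrow(all_kept), nrow(fr))

  expect_error(select_days(make_frame("A1", n = 4),
                           curation_config(day_selection = "calendar",
                                           complete_day_min_fraction = 0.95)),
               "no complete day")
})

test_that("zeitgeber days split at lights-on, not midnight", {
  pp <- photoperiod("07:00", "19:00")
  ts <- calokit:::ck_time("2024-03-04 06:00:00") + 3600 * (0:2)  # 06,07,08h
  fr <- calorimetry_frame(data.frame(animal_id = "A1", timestamp = ts,
                                     vo2 = 1, vco2 = 1))
  di <- calokit:::day_index(fr, "zeitgeber", pp)
  expect_equal(di[2] - di[1], 1)          # 06:00 belongs to the previous ZT day
  expect_equal(di[3], di[2])              # 07:00 and 08:00 share a ZT day
  dc <- calokit:::day_index(fr, "calendar")
  expect_true(all(dc == dc[1]))           # same calendar day throughout
})

test_that("exclusions drop whole animals and days, but never everything", {
  fr <- make_frame(c("A1", "A2", "A3"), n = 48, interval_min = 60)
  ex <- exclude_records(fr, excluded_animals = "A2")
  expect_setequal(unique(ex$animal_id), c("A1", "A3"))
  expect_equal(nrow(ex), 96L)
  exd <- exclude_records(fr, excluded_days = "2024-03-04")
  expect_true(all(format(exd$timestamp, "%Y-%m-%d") != "2024-03-04"))
  expect_equal(nrow(exd), 3 * sum(format(fr$timestamp[fr$animal_id == "A1"],
                                         "%Y-%m-%d") != "2024-03-04"))
  expect_error(exclude_records(fr, excluded_animals = c("A1", "A2", "A3")),
               "every sample")
})

test_that("uniform resampling averages gases and sums counts", {
  fr <- make_frame("A1", n = 60, interval_min = 1, vo2 = 1, vco2 = 1,
                   activity_x = 1)
  fr$vo2 <- 1:60  # ramp
  rs <- resample_uniform(fr, 10)
  expect_equal(nrow(rs), 6L)
  expect_equal(rs$vo2, c(5.5, 15.5, 25.5, 35.5, 45.5, 55.5))
  expect_equal(rs$activity_x, rep(10, 6))  # counts summed
  expect_equal(as.numeric(diff(rs$timestamp), units = "mins"), rep(10, 5))

  ident <- resample_uniform(fr, 1)
  expect_equal(ident$vo2, fr$vo2)
  expect_true(all(ident$timestamp == fr$timestamp))

  expect_error(resample_uniform(fr, 0.5), "finer")
})

test_that("the curation chain reconciles row counts and is idempotent", {
  co <- simulate_cohort(cohort_sim_params(
    n_per_group = 2, seed = 31,
    template = animal_sim_params(n_days = 2, noise_sd = 0.3)))
  fr <- co$frame
  fr$vo2[10] <- -2  # plant a negative gas sample
  cfg <- curation_config(remove_negative_gas = TRUE,
                         trim_start = 2, trim_end = 2,
                         enforce_complete_days = FALSE,
                         target_interval = 10)
  res <- curate(fr, cfg, photoperiod())
  expect_equal(nrow(fr) - nrow(res$frame), sum(res$report$n_removed))
  expect_gte(res$report$n_flagged[res$report$check == "negative_gas"], 1)

  # re-running the same chain on its own output changes nothing
  res2 <- curate(res$frame, cfg, photoperiod())
  expect_equal(as.data.frame(res2$frame), as.data.frame(res$frame),
               tolerance = 1e-12)

  # reconciliation also holds with day selection + z-score removal enabled
  cfg2 <- curation_config(z_channels = c("vo2", "vco2"), z_threshold = 3,
                          enforce_complete_days = TRUE,
                          day_selection = "zeitgeber")
  res3 <- curate(co$frame, cfg2, photoperiod())
  expect_equal(nrow(co$frame) - nrow(res3$frame), sum(res3$report$n_removed))
})
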