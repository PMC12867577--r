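test_that("RER is VCO2/VO2 with a physiological flagging band", {
  r <- compute_rer(c(1000, 1000, 0, 1000), c(700, 1000, 700, 1400))
  expect_equal(as.numeric(r), c(0.7, 1.0, NA, 1.4))
  expect_equal(attr(r, "flag"), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("the Heldmaier equation gives hand-computed EE values and is linear", {
  expect_equal(compute_ee(1000, 0), 15.984)            # 4.44*1000*3.6/1000
  expect_equal(compute_ee(1000, 1), 21.132)            # (4.44+1.43)*3.6
  expect_equal(compute_ee(0, 0.8), 0)
  expect_error(compute_ee(1000, 0.8, "nonsense"), "heldmaier")
  expect_true("weir" %in% list_equations()$equation)

  # linearity in vo2 at fixed RER, for both registered equations
  for (eq in list_equations()$equation) {
    v <- c(100, 500, 2000); a <- 3.7
    expect_equal(compute_ee(a * v, 0.85, eq), a * compute_ee(v, 0.85, eq))
  }
})

test_that("substrate oxidation uses the documented stoichiometry and flags negatives", {
  s <- substrate_oxidation(1000, 700)
  expect_equal(s$fat_ox, 0.501)        # 1.67 * 300 / 1000
  expect_equal(s$cho_ox, -0.025)       # (4.55*700 - 3.21*1000)/1000
  expect_true(s$ox_flag)
  expect_equal(substrate_oxidation(1000, 1000)$fat_ox, 0)
  expect_equal(unlist(substrate_oxidation(0, 0)[c("fat_ox", "cho_ox")]),
               c(fat_ox = 0, cho_ox = 0))
})

test_that("substrate energy approximately closes against EE on synthetic traces", {
  sa <- simulate_animal(animal_sim_params(seed = 8, n_days = 2))
  tr <- energy_trace(sa$frame)
  in_band <- !is.na(tr$rer) & tr$rer >= 0.71 & tr$rer <= 1.0
  closure <- (tr$fat_ox * 39.6 + tr$cho_ox * 16.7)[in_band] / tr$ee[in_band]
  expect_true(all(abs(closure - 1) < 0.05))
})

test_that("RMR equals the plateau on a noiseless constant trace", {
  tr <- make_trace(rep(10, 24 * 12))  # one day at 5-min sampling
  r <- estimate_rmr(tr, rmr_config(window_length = 30))
  expect_equal(r$rmr, 10)
  expect_equal(r$tee, 240)
  expect_equal(r$aee, 0)
  expect_equal(r$method_used, "cov_window")
  expect_false(r$aee_flag)
})

test_that("RMR falls back to the low percentile on relentless sawtooth traces", {
  ee <- rep(c(5, 15), 144)
  tr <- make_trace(ee)
  r <- estimate_rmr(tr, rmr_config(window_length = 30, cov_threshold = 0.05))
  expect_equal(r$method_used, "percentile_fallback")
  expect_equal(r$rmr, 5)  # mean of the lowest 5% of samples
  expect_error(estimate_rmr(make_trace(rep(10, 5)),
                            rmr_config(window_length = 30)),
               "too|spans")
})

test_that("RMR recovers the generator plateau within 5% (and exactly without noise)", {
  errs <- vapply(1:3, function(s) {
    sa <- simulate_animal(animal_sim_params(seed = 100 + s))  # rmr 8, 2% noise
    r <- estimate_rmr(energy_trace(sa$frame), rmr_config())
    abs(r$rmr - 8) / 8
  }, numeric(1))
  expect_true(all(errs <= 0.05))

  exact <- simulate_animal(animal_sim_params(noise_sd = 0, burst_rate = 0,
                                             seed = 1))
  r0 <- estimate_rmr(energy_trace(exact$frame), rmr_config())
  expect_equal(r0$rmr, 8, tolerance = 1e-9)
  # cov-window RMR never exceeds any qualifying window's mean by construction
  expect_lte(r0$rmr, mean(energy_trace(exact$frame)$ee))
})

test_that("windowed profiles aggregate in zeitgeber time", {
  tr <- make_trace(rep(10, 288))
  pr <- windowed_profile(tr, 1, "mean")
  expect_equal(nrow(pr), 24L)
  expect_true(all(pr$value == 10))

  # light/dark step: 5 in light, 10 in dark under 12:12
  ee <- ifelse(make_trace(numeric(288))$phase == "light", 5, 10)
  pr2 <- windowed_profile(make_trace(ee), 1, "mean")
  expect_equal(pr2$value, rep(c(5, 10), each = 12))

  # min statistic against a brute-force per-window oracle on a V-shaped day
  v <- abs(seq(-1, 1, length.out = 288)) * 6 + 4
  trv <- make_trace(v)
  got <- windowed_profile(trv, 1, "min")
  want <- vapply(0:23, function(h)
    min(v[floor(trv$zt) == h]), numeric(1))
  expect_equal(got$value, want)
})

test_that("photoperiod aggregates use means for intensities and sums for intakes", {
  ee <- ifelse(make_trace(numeric(48), interval_min = 30)$phase == "light",
               6, 12)
  tr <- make_trace(ee, interval_min = 30)
  tr$food <- rep(0.1, 48)
  tr$activity_x <- rep(2, 48)
  ag <- aggregate_photoperiod(tr)
  expect_equal(nrow(ag), 2L)
  expect_equal(ag$mean_ee[ag$phase == "light"], 6)
  expect_equal(ag$mean_ee[ag$phase == "dark"], 12)
  expect_equal(ag$food_sum, c(2.4, 2.4))       # 24 samples x 0.1 g per phase
  expect_equal(ag$activity_x_sum, c(48, 48))
})

test_that("locomotion density is a unit-mass histogram matching a brute-force oracle", {
  one <- make_frame("A1", n = 6, activity_x = 3, activity_y = 2)
  h1 <- locomotion_density(one, c(5, 5))$A1
  expect_equal(sum(h1), 1)
  expect_equal(sum(h1 > 0), 1L)  # all mass in a single bin
  expect_equal(max(h1), 1)

  # equal total counts over 4 distinct positions, 2x2 bins -> 0.25 each
  # (1,1) x6, (1,3) x3, (3,1) x3, (3,3) x2: every position carries mass 12
  un <- make_frame("A1", n = 14,
                   activity_x = c(rep(1, 9), rep(3, 5)),
                   activity_y = c(rep(1, 6), rep(3, 3), rep(1, 3), rep(3, 2)))
  h2 <- locomotion_density(un, c(2, 2))$A1
  expect_equal(h2, matrix(0.25, 2, 2))

  # brute-force oracle on random data
  set.seed(4)
  rnd <- make_frame("A1", n = 200,
                    activity_x = sample(0:9, 200, TRUE),
                    activity_y = sample(0:9, 200, TRUE))
  bins <- c(4, 3)
  got <- locomotion_density(rnd, bins)$A1
  ex <- seq(min(rnd$activity_x), max(rnd$activity_x), length.out = bins[1] + 1)
  ey <- seq(min(rnd$activity_y), max(rnd$activity_y), length.out = bins[2] + 1)
  want <- matrix(0, bins[1], bins[2])
  for (k in seq_len(nrow(rnd))) {
    ix <- min(max(findInterval(rnd$activity_x[k], ex, rightmost.closed = TRUE),
                  1), bins[1])
    iy <- min(max(findInterval(rnd$activity_y[k], ey, rightmost.closed = TRUE),
                  1), bins[2])
    want[ix, iy] <- want[ix, iy] + rnd$activity_x[k] + rnd$activity_y[k]
  }
  want <- want / sum(want)
  expect_equal(got, want)
  expect_equal(sum(got), 1, tolerance = 1e-12)

  expect_error(locomotion_density(make_frame("A1", n = 5), c(2, 2)),
               "activity")
})

test_that("the energy trace carries phase labels and flags through", {
  sa <- simulate_animal(animal_sim_params(n_days = 1, seed = 2))
  tr <- energy_trace(sa$frame)
  expect_setequal(unique(tr$phase), c("light", "dark"))
  expect_equal(tr$ee, sa$truth$ee_true, tolerance = 1e-9)
  expect_type(tr$rer_flag, "logical")
  expect_true(all(c("activity_x", "food", "temp_ambient") %in% names(tr)))
})
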