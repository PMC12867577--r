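make_table <- function(n = 10, delta = 0, seed = 1, two_factor = FALSE,
                       mass_slope = 0) {
  set.seed(seed)
  g <- rep(c("A", "B"), each = n)
  mass <- rnorm(2 * n, 25, 2)
  tab <- data.frame(animal_id = sprintf("A%02d", seq_len(2 * n)),
                    rmr = 8 + delta * (g == "B") +
                      mass_slope * (mass - 25) + rnorm(2 * n),
                    genotype = g, body_mass = mass)
  if (two_factor) tab$sex <- rep(c("m", "f"), n)
  tab
}

test_that("analysis tables bridge RMR results and metadata", {
  co <- simulate_cohort(cohort_sim_params(n_per_group = 3, seed = 17),
                        timeseries = FALSE)
  fake_rmr <- data.frame(animal_id = co$truth$animal_id,
                         rmr = co$truth$rmr_true, tee = 1, aee = 1)
  tab <- build_analysis_table(fake_rmr, co$metadata, "rmr")
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("rmr", "genotype", "body_mass") %in% names(tab)))
  expect_error(build_analysis_table(fake_rmr, co$metadata, "vo2max"),
               "not available")
})

test_that("assumption checks pass on normal data and catch heavy tails", {
  set.seed(42)
  tab <- make_table(n = 20)
  spec <- model_spec("rmr", "genotype")
  rep <- check_assumptions(tab, spec)
  expect_true(rep$shapiro_passed)
  expect_true(rep$levene_passed)
  # p-values agree with the reference tests applied to the same residuals
  fit <- lm(rmr ~ genotype, data = tab)
  expect_equal(rep$shapiro_p, shapiro.test(residuals(fit))$p.value,
               tolerance = 1e-6)
  lev <- car::leveneTest(tab$rmr, factor(tab$genotype), center = median)
  expect_equal(rep$levene_p, lev[["Pr(>F)"]][1], tolerance = 1e-6)

  set.seed(7)
  heavy <- make_table(n = 25)
  heavy$rmr <- rcauchy(50)
  expect_false(check_assumptions(heavy, spec)$shapiro_passed)

  # n = 1 per group: both tests are reported as not computable, not failed
  tiny1 <- make_table(n = 2)[c(1, 3), ]
  rep3 <- check_assumptions(tiny1, spec)
  expect_true(is.na(rep3$shapiro_p))
  expect_true(is.na(rep3$levene_p))
  expect_true(is.na(rep3$shapiro_passed))
})

test_that("a known group shift is detected and matches the reference fit", {
  tab <- make_table(n = 10, delta = 2, seed = 5)  # delta = 2 sigma
  res <- fit_model(tab, model_spec("rmr", "genotype"))
  p_geno <- res$model_table$p[res$model_table$term == "genotype"]
  expect_lt(p_geno, 0.05)
  ref <- anova(lm(rmr ~ genotype, data = tab))
  expect_equal(p_geno, ref[["Pr(>F)"]][1], tolerance = 1e-8)
  expect_equal(res$model_table$statistic[1], ref[["F value"]][1],
               tolerance = 1e-8)

  flat <- tab; flat$rmr <- 5
  resf <- fit_model(flat, model_spec("rmr", "genotype"))
  expect_equal(resf$model_table$statistic[1], 0, tolerance = 1e-12)
})

test_that("Type-II tests match car::Anova on random (unbalanced) designs", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(14:40, 1)
    dat <- data.frame(
      y = rnorm(n),
      f1 = sample(c("a", "b", if (runif(1) < 0.5) "c"), n, TRUE),
      f2 = sample(c("u", "v"), n, TRUE),
      x = rnorm(n))
    while (min(table(dat$f1, dat$f2)) < 2) {
      dat$f1 <- sample(unique(dat$f1), n, TRUE)
      dat$f2 <- sample(c("u", "v"), n, TRUE)
    }
    dat$y <- dat$y + 0.5 * (dat$f1 == "b") + 0.3 * dat$x
    with_int <- runif(1) < 0.5
    spec <- model_spec("y", c("f1", "f2"), covariates = "x",
                       interaction = with_int)
    got <- fit_model(dat, spec)$model_table
    ref <- car::Anova(lm(calokit:::spec_formula(spec), data = dat), type = 2)
    ref <- ref[got$term, ]
    expect_equal(got$p, ref[["Pr(>F)"]], tolerance = 1e-6)
    expect_equal(got$statistic, ref[["F value"]], tolerance = 1e-6)
  }
})

test_that("poisson GLMs use likelihood-ratio tests matching car::Anova", {
  set.seed(3)
  dat <- data.frame(counts = rpois(40, 6), genotype = rep(c("A", "B"), 20))
  dat$counts[dat$genotype == "B"] <- rpois(20, 9)
  spec <- model_spec("counts", "genotype", family = "poisson")
  got <- fit_model(dat, spec)$model_table
  ref <- car::Anova(glm(counts ~ genotype, dat, family = poisson()), type = 2)
  expect_equal(got$p, ref[["Pr(>Chisq)"]], tolerance = 1e-6)
  expect_lt(got$p[1], 0.05)
})

test_that("ANCOVA recovers the generating group effect with ~95% CI coverage", {
  hits <- 0; nsim <- 200; beta_g <- 1.5
  for (s in seq_len(nsim)) {
    tab <- make_table(n = 8, delta = beta_g, seed = 4000 + s,
                      mass_slope = 0.25)
    res <- fit_model(tab, model_spec("rmr", "genotype",
                                     covariates = "body_mass"))
    ci <- confint(res$fit)["genotypeB", ]
    if (ci[1] <= beta_g && beta_g <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / nsim, 0.90)
  expect_lte(hits / nsim, 0.99)
})

test_that("rank-deficient designs fail with the aliased term named", {
  tab <- make_table(n = 6)
  tab$dup <- tab$genotype  # perfectly confounded factor
  expect_error(fit_model(tab, model_spec("rmr", c("genotype", "dup"))),
               "aliased|rank")
})

test_that("post-hoc corrections reproduce hand-computed adjustments", {
  # Holm on raw {0.01, 0.04, 0.03} -> {0.03, 0.06, 0.06}
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))

  set.seed(21)
  tab <- data.frame(animal_id = 1:30,
                    rmr = rnorm(30),
                    diet = rep(c("chow", "hfd", "west"), each = 10))
  res <- fit_model(tab, model_spec("rmr", "diet"))
  ph_t <- posthoc(res, "pairwise_t", "holm")
  expect_equal(nrow(ph_t), 3L)
  expect_equal(ph_t$p_adj, p.adjust(ph_t$p_raw, "holm"))
  expect_true(all(ph_t$p_adj >= ph_t$p_raw))

  # identical value composition in all groups: all adjusted p near 1
  tab$rmr <- rep(seq(5, 9.5, by = 0.5), 3)
  req <- fit_model(tab, model_spec("rmr", "diet"))
  expect_true(all(posthoc(req, "tukey")$p_adj > 0.9))

  # monotonicity: bonferroni >= holm >= raw, elementwise, on random p-vectors
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    expect_true(all(p.adjust(p, "bonferroni") >= p.adjust(p, "holm") - 1e-15))
    expect_true(all(p.adjust(p, "holm") >= p - 1e-15))
  }

  # tukey p-values agree with the TukeyHSD reference on the same fit
  ph_tk <- posthoc(res, "tukey")
  ref <- TukeyHSD(aov(rmr ~ diet, data = tab_for <- res$data))$diet
  expect_equal(sort(ph_tk$p_adj),
               sort(unname(ref[, "p adj"])), tolerance = 1e-8)
})

test_that("single-level factors yield an empty post-hoc table", {
  tab <- make_table(n = 5)
  res <- fit_model(tab, model_spec("rmr", "genotype"))
  res$data$genotype <- factor("A")
  expect_equal(nrow(posthoc(res)), 0L)
})

test_that("asterisk codes follow the conventional thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.04, 0.5, 0.05)),
               c("***", "**", "*", "ns", "ns"))
  expect_error(significance_stars(1.2), "outside")
  expect_error(significance_stars(-0.1), "outside")
  expect_true(is.na(significance_stars(NA_real_)))
})

test_that("the plain-text report contains model, check-marks and stars", {
  tab <- make_table(n = 10, delta = 3, seed = 2)
  res <- fit_model(tab, model_spec("rmr", "genotype"))
  ph <- posthoc(res, "pairwise_t")
  txt <- paste(render_stat_report(res, ph), collapse = "\n")
  expect_match(txt, "genotype")
  expect_match(txt, "Shapiro")
  expect_match(txt, "Post-hoc")
})
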