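#' Model specification for group statistics
#'
#' @param response per-animal metric name (e.g. \code{"rmr"}, \code{"tee"},
#'   \code{"mean_ee"}).
#' @param factors harmonized factor names (categorical).
#' @param covariates numeric covariates (e.g. \code{"body_mass"} for
#'   mass-adjusted ANCOVA).
#' @param family \code{"gaussian"} (least squares) or \code{"poisson"}
#'   (ML GLM, for count responses).
#' @param interaction include all factor-by-factor interactions.
#' @param ss_type sums-of-squares type for factorial terms: 2 (default) or 3
#'   (with sum-to-zero contrasts).
#' @return a \code{model_spec} list.
#' @export
model_spec <- function(response, factors, covariates = character(0),
                       family = c("gaussian", "poisson"),
                       interaction = FALSE, ss_type = 2) {
  stopifnot(length(response) == 1, length(factors) >= 1, ss_type %in% c(2, 3))
  structure(list(response = response, factors = factors,
                 covariates = covariates, family = match.arg(family),
                 interaction = isTRUE(interaction), ss_type = ss_type),
            class = "model_spec")
}

spec_formula <- function(spec) {
  fac <- paste(spec$factors,
               collapse = if (spec$interaction) " * " else " + ")
  rhs <- paste(c(spec$covariates, fac), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Build the per-animal analysis table
#'
#' Bridges the energetics outputs to the statistics stage: one row per
#' animal, carrying the requested summary metric plus the harmonized factors
#' and covariates from the metadata.
#'
#' @param rmr an [estimate_rmr()] result (for metrics rmr/tee/aee), or any
#'   data.frame with animal_id + metric columns (e.g. phase aggregates).
#' @param meta a harmonized \code{metadata_table}.
#' @param metric column of \code{rmr} to analyse.
#' @return data.frame: animal_id, metric column, factor and covariate
#'   columns.
#' @export
build_analysis_table <- function(rmr, meta, metric = "rmr") {
  if (!metric %in% names(rmr))
    ck_stop("metric '", metric, "' not available; have: ",
            paste(setdiff(names(rmr), "animal_id"), collapse = ", "))
  tab <- data.frame(animal_id = rmr$animal_id)
  tab[[metric]] <- rmr[[metric]]
  idx <- match(tab$animal_id, meta$animal_id)
  for (col in setdiff(names(meta), c("animal_id", "cohort_id")))
    tab[[col]] <- meta[[col]][idx]
  tab
}

#' Check parametric-test assumptions
#'
#' Shapiro–Wilk normality on the residuals of the specified model and
#' median-centered Levene variance homogeneity across the factor-level
#' groups; each is summarized as a pass/fail check-mark at alpha = 0.05.
#' A test whose requirements are not met (fewer than 3 residuals, or
#' fewer than 2 observations in some group) is reported as not computable
#' (NA), not as failed.
#'
#' @param table analysis table from [build_analysis_table()].
#' @param spec a [model_spec()].
#' @return an \code{assumption_report}: shapiro_p, shapiro_passed, levene_p,
#'   levene_passed, alpha.
#' @export
check_assumptions <- function(table, spec) {
  dat <- prepare_model_data(table, spec)
  alpha <- 0.05
  shapiro_p <- NA_real_
  fit <- stats::lm(spec_formula(spec), data = dat)
  res <- stats::residuals(fit)
  if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    shapiro_p <- stats::shapiro.test(res)$p.value
  grp <- interaction(dat[spec$factors], drop = TRUE)
  levene_p <- NA_real_
  if (nlevels(grp) >= 2 && all(table(grp) >= 2)) {
    lev <- car::leveneTest(dat[[spec$response]], grp, center = stats::median)
    levene_p <- lev[["Pr(>F)"]][1]
  }
  structure(list(shapiro_p = shapiro_p,
                 shapiro_passed = if (is.na(shapiro_p)) NA else
                   shapiro_p >= alpha,
                 levene_p = levene_p,
                 levene_passed = if (is.na(levene_p)) NA else
                   levene_p >= alpha,
                 alpha = alpha),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  mark <- function(p, ok) {
    if (is.na(p)) return("not computable")
    sprintf("p = %.4g %s", p, if (isTRUE(ok)) "✓" else "✗")
  }
  cat("Assumption checks (alpha = ", x$alpha, "):\n", sep = "")
  cat("  Shapiro-Wilk (residual normality): ",
      mark(x$shapiro_p, x$shapiro_passed), "\n", sep = "")
  cat("  Levene (variance homogeneity):     ",
      mark(x$levene_p, x$levene_passed), "\n", sep = "")
  invisible(x)
}

prepare_model_data <- function(table, spec) {
  terms_needed <- c(spec$response, spec$factors, spec$covariates)
  miss <- setdiff(terms_needed, names(table))
  if (length(miss))
    ck_stop("missing column(s) in analysis table: ",
            paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[terms_needed]), , drop = FALSE]
  for (f in spec$factors) dat[[f]] <- factor(dat[[f]])
  for (v in spec$covariates)
    if (!is.numeric(dat[[v]])) ck_stop("covariate ", v, " must be numeric")
  dat
}

# Type-II tests by nested model comparison: for each term t, compare the
# model with all terms that neither equal nor contain t against that model
# plus t. Gaussian: F against the full-model residual MS; Poisson: LR chisq.
type2_table <- function(full_fit, dat, spec) {
  tl <- attr(stats::terms(full_fit), "term.labels")
  fac <- attr(stats::terms(full_fit), "factors")
  contains <- function(a, b) {  # does term a contain term b?
    va <- rownames(fac)[fac[, a] > 0]
    vb <- rownames(fac)[fac[, b] > 0]
    all(vb %in% va) && !setequal(va, vb)
  }
  gaussian <- spec$family == "gaussian"
  rss_full <- if (gaussian) sum(stats::residuals(full_fit)^2) else NA
  df_full <- stats::df.residual(full_fit)
  refit <- function(terms_in) {
    f <- if (length(terms_in))
      stats::reformulate(terms_in, response = spec$response)
    else stats::as.formula(paste(spec$response, "~ 1"))
    if (gaussian) stats::lm(f, data = dat)
    else stats::glm(f, data = dat, family = stats::poisson())
  }
  rows <- lapply(tl, function(t) {
    others <- tl[vapply(tl, function(o)
      o != t && !contains(o, t), logical(1))]
    m0 <- refit(others)
    m1 <- refit(c(others, t))
    if (gaussian) {
      ss <- sum(stats::residuals(m0)^2) - sum(stats::residuals(m1)^2)
      df <- stats::df.residual(m0) - stats::df.residual(m1)
      # degenerate constant response: no variance anywhere -> statistic 0
      tot <- sum((dat[[spec$response]] - mean(dat[[spec$response]]))^2)
      if (rss_full <= 1e-12 * max(tot, 1) && ss <= 1e-12 * max(tot, 1)) {
        stat <- 0; p <- 1
      } else {
        stat <- (ss / df) / (rss_full / df_full)
        p <- stats::pf(stat, df, df_full, lower.tail = FALSE)
      }
      data.frame(term = t, df = df, sumsq = ss, statistic = stat, p = p)
    } else {
      dev <- stats::deviance(m0) - stats::deviance(m1)
      df <- stats::df.residual(m0) - stats::df.residual(m1)
      data.frame(term = t, df = df, sumsq = NA_real_, statistic = dev,
                 p = stats::pchisq(dev, df, lower.tail = FALSE))
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fit the group-comparison model
#'
#' Multi-way ANOVA / ANCOVA (gaussian, least squares) or Poisson GLM
#' (maximum likelihood) on the per-animal analysis table, with Type-II
#' sums of squares for the factorial terms by default (Type-III with
#' sum-to-zero contrasts via \code{ss_type = 3} in the spec). When a
#' covariate is present, covariate-adjusted group means (predictions at the
#' grand covariate mean) are reported for the first factor.
#'
#' @param table analysis table.
#' @param spec a [model_spec()].
#' @return a \code{stat_result}: \code{model_table} (term, df, statistic,
#'   p), \code{adjusted_means}, \code{assumptions}, the underlying
#'   \code{fit}, and the data used.
#' @export
fit_model <- function(table, spec) {
  dat <- prepare_model_data(table, spec)
  for (f in spec$factors)
    if (nlevels(dat[[f]]) < 2)
      ck_stop("factor ", f, " has a single level")
  contr <- if (spec$ss_type == 3)
    lapply(stats::setNames(spec$factors, spec$factors),
           function(.) "contr.sum")
  fml <- spec_formula(spec)
  fit <- if (spec$family == "gaussian")
    stats::lm(fml, data = dat, contrasts = contr)
  else stats::glm(fml, data = dat, family = stats::poisson(),
                  contrasts = contr)
  # rank deficiency -> aliased terms
  if (any(is.na(stats::coef(fit))))
    ck_stop("rank-deficient design; aliased coefficient(s): ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  model_table <- if (spec$ss_type == 2) type2_table(fit, dat, spec)
  else {
    a3 <- car::Anova(fit, type = 3)
    keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
    if (spec$family == "gaussian")
      data.frame(term = rownames(a3)[keep], df = a3$Df[keep],
                 sumsq = a3[["Sum Sq"]][keep],
                 statistic = a3[["F value"]][keep], p = a3[["Pr(>F)"]][keep])
    else
      data.frame(term = rownames(a3)[keep], df = a3$Df[keep],
                 sumsq = NA_real_, statistic = a3[["LR Chisq"]][keep],
                 p = a3[["Pr(>Chisq)"]][keep])
  }
  adj <- NULL
  if (length(spec$covariates)) {
    f1 <- spec$factors[1]
    grid <- dat[!duplicated(dat[[f1]]), , drop = FALSE]
    grid <- grid[order(grid[[f1]]), , drop = FALSE]
    for (v in spec$covariates) grid[[v]] <- mean(dat[[v]])
    for (f in setdiff(spec$factors, f1))
      grid[[f]] <- factor(levels(dat[[f]])[1], levels = levels(dat[[f]]))
    pr <- stats::predict(fit, newdata = grid, type = "response")
    adj <- data.frame(level = as.character(grid[[f1]]), adjusted_mean = pr)
    rownames(adj) <- NULL
  }
  structure(list(model_table = model_table, adjusted_means = adj,
                 assumptions = check_assumptions(table, spec),
                 fit = fit, data = dat, spec = spec),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s model, Type-%s tests\n", x$spec$family,
              x$spec$ss_type))
  mt <- x$model_table
  mt$stars <- significance_stars(mt$p)
  print(mt, digits = 4)
  print(x$assumptions)
  if (!is.null(x$adjusted_means)) {
    cat("Covariate-adjusted means (", x$spec$factors[1], "):\n", sep = "")
    print(x$adjusted_means, digits = 4)
  }
  invisible(x)
}

#' @export
summary.stat_result <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Post-hoc pairwise comparisons
#'
#' All pairwise contrasts of one factor's levels, either Tukey HSD
#' (family-wise adjusted by the studentized range) or pairwise t tests with
#' a monotone p-value correction (Holm, Bonferroni or Benjamini–Hochberg).
#' Stars follow the conventional asterisk notation.
#'
#' @param result a [fit_model()] result.
#' @param method \code{"tukey"} or \code{"pairwise_t"}.
#' @param correction correction for pairwise t p-values.
#' @param factor factor to compare; default the spec's first factor.
#' @return data.frame: pair, estimate, p_raw, p_adj, stars; empty when the
#'   factor has a single level.
#' @export
posthoc <- function(result, method = c("tukey", "pairwise_t"),
                    correction = c("holm", "bonferroni", "BH"),
                    factor = NULL) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  spec <- result$spec
  f <- factor %||% spec$factors[1]
  dat <- result$data
  lv <- levels(dat[[f]])
  empty <- data.frame(pair = character(0), estimate = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      stars = character(0))
  if (length(lv) < 2) return(empty)
  # raw p from pooled-sd pairwise t tests (no correction)
  raw <- stats::pairwise.t.test(dat[[spec$response]], dat[[f]],
                                p.adjust.method = "none")$p.value
  pairs <- list(); praw <- c(); est <- c()
  gm <- tapply(dat[[spec$response]], dat[[f]], mean)
  for (i in seq_len(nrow(raw))) for (j in seq_len(ncol(raw)))
    if (!is.na(raw[i, j])) {
      a <- rownames(raw)[i]; b <- colnames(raw)[j]
      pairs[[length(pairs) + 1L]] <- paste(a, b, sep = " - ")
      praw <- c(praw, raw[i, j])
      est <- c(est, unname(gm[a] - gm[b]))
    }
  if (method == "tukey") {
    af <- stats::aov(spec_formula(spec), data = dat)
    # aov warns about the (intended) continuous covariate in the model
    tk <- suppressWarnings(stats::TukeyHSD(af, which = f))[[f]]
    key <- rownames(tk)
    ours <- vapply(pairs, function(p) {
      ab <- strsplit(p, " - ", fixed = TRUE)[[1]]
      m <- match(paste(ab[1], ab[2], sep = "-"), key)
      if (is.na(m)) match(paste(ab[2], ab[1], sep = "-"), key) else m
    }, numeric(1))
    padj <- tk[ours, "p adj"]
    correction <- "tukey"
  } else {
    padj <- stats::p.adjust(praw, method = correction)
  }
  out <- data.frame(pair = unlist(pairs), estimate = est, p_raw = praw,
                    p_adj = pmin(padj, 1),
                    stars = significance_stars(pmin(padj, 1)))
  attr(out, "correction") <- correction
  rownames(out) <- NULL
  out
}

#' Conventional asterisk notation for adjusted p-values
#'
#' \code{p < 0.001} gives \code{"***"}, \code{< 0.01} \code{"**"},
#' \code{< 0.05} \code{"*"}, otherwise \code{"ns"}.
#'
#' @param p_adj numeric vector in [0, 1] (NA allowed).
#' @return character vector of codes.
#' @export
significance_stars <- function(p_adj) {
  bad <- !is.na(p_adj) & (p_adj < 0 | p_adj > 1)
  if (any(bad)) ck_stop("p-value(s) outside [0, 1]: ",
                        paste(p_adj[bad], collapse = ", "))
  out <- ifelse(p_adj < 0.001, "***",
                ifelse(p_adj < 0.01, "**",
                       ifelse(p_adj < 0.05, "*", "ns")))
  out[is.na(p_adj)] <- NA_character_
  out
}

#' Plain-text statistical report
#'
#' Renders the fitted model table, the assumption check-marks and a starred
#' post-hoc table the way the results are meant to be read.
#'
#' @param result a [fit_model()] result.
#' @param posthoc_table optional [posthoc()] table.
#' @return character vector of report lines (also printed).
#' @export
render_stat_report <- function(result, posthoc_table = NULL) {
  lines <- utils::capture.output({
    print(result)
    if (!is.null(posthoc_table) && nrow(posthoc_table)) {
      cat("Post-hoc comparisons (correction: ",
          attr(posthoc_table, "correction") %||% "none", "):\n", sep = "")
      print(posthoc_table, digits = 4)
    }
  })
  lines
}
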