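# Nonparametric statistics battery relating QC metrics to acquisition
# details and subject phenotypes: Anderson-Darling normality screening,
# Wilcoxon rank-sum tests with Hodges-Lehmann 95% confidence intervals of
# the difference between medians, Kendall tau-b rank correlation, linear
# regression, quintile contrasts, and family-wise Bonferroni correction
# (applied to the motion family only).

#' Mosteller body surface area
#'
#' Height is recovered from weight and BMI (`height_m = sqrt(weight/bmi)`),
#' then `BSA = sqrt(height_cm * weight / 3600)` in m^2.
#'
#' @param weight kg.
#' @param bmi kg/m^2.
#' @return body surface area, m^2 (vectorised).
#' @export
mosteller_bsa <- function(weight, bmi) {
  if (any(weight <= 0) || any(bmi <= 0))
    stop("weight and bmi must be positive")
  height_cm <- 100 * sqrt(weight / bmi)
  sqrt(height_cm * weight / 3600)
}

#' Anderson-Darling normality test (estimated parameters)
#'
#' The case with both mean and variance estimated from the sample, using
#' the small-sample-corrected statistic and its p-value approximation.
#'
#' @param x numeric sample, n >= 8.
#' @return `list(A2 = statistic, p = p.value)`.
#' @export
anderson_darling_normal <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 8) stop("Anderson-Darling test needs n >= 8")
  if (stats::sd(x) == 0) stop("zero-variance sample")
  res <- nortest::ad.test(x)
  list(A2 = unname(res$statistic), p = res$p.value)
}

#' Wilcoxon rank-sum test with Hodges-Lehmann confidence interval
#'
#' Two-sided rank-sum test between independent samples, with the
#' Hodges-Lehmann estimate and confidence interval of the location
#' difference (the standard rank-sum-associated interval for the
#' difference between medians): the point estimate is the median of all
#' pairwise differences `x_i - y_j` and the interval inverts the
#' Mann-Whitney statistic over them. Exact for small tie-free samples,
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alpha two-sided significance level.
#' @param test_id label carried into the result.
#' @return one-row `data.frame`: `test_id`, `type`, `n1`, `n2`,
#'   `statistic` (rank-sum W), `estimate` (HL difference x - y), `p`,
#'   `ci_low`, `ci_high`.
#' @export
ranksum_with_ci <- function(x, y, alpha = 0.05, test_id = "ranksum") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("empty sample")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, conf.int = TRUE, conf.level = 1 - alpha))
  data.frame(test_id = test_id, type = "ranksum",
             n1 = length(x), n2 = length(y),
             statistic = unname(wt$statistic),
             estimate = unname(wt$estimate),
             p = wt$p.value,
             ci_low = wt$conf.int[1], ci_high = wt$conf.int[2],
             stringsAsFactors = FALSE)
}

#' Kendall tau-b rank correlation
#'
#' Tie-corrected tau; exact p-value for small tie-free samples, normal
#' approximation with tie correction otherwise.
#'
#' @param x,y paired numeric samples.
#' @param test_id label carried into the result.
#' @return one-row `data.frame`: `test_id`, `type`, `n1` (pairs),
#'   `statistic` (tau-b), `p`; CI columns are `NA`.
#' @export
kendall_tau_b <- function(x, y, test_id = "tau") {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  if (length(x) < 2) stop("tau-b needs at least two pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("tau-b undefined for an all-tied sample")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  data.frame(test_id = test_id, type = "tau",
             n1 = length(x), n2 = NA_integer_,
             statistic = unname(ct$estimate),
             estimate = unname(ct$estimate),
             p = ct$p.value,
             ci_low = NA_real_, ci_high = NA_real_,
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression line
#'
#' @param x,y paired numeric samples, n >= 3.
#' @return `list(slope, intercept, r)` with `r` the Pearson correlation.
#' @export
linear_regression <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("regression needs n >= 3")
  if (stats::var(x) == 0) stop("regression undefined for constant x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tests in the family.
#' @return `alpha / n_tests` (exact value; round for display only).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' First- and last-quintile membership
#'
#' Strict-inequality membership below the 20th and above the 80th
#' empirical percentile (linear-interpolation percentile definition).
#'
#' @param values numeric vector, n >= 5.
#' @param probs the two percentile cut levels.
#' @return `list(low, high, cutpoints)`: logical masks and the two cut
#'   values.
#' @export
quintile_groups <- function(values, probs = c(0.2, 0.8)) {
  if (length(values) < 5) stop("quintile groups need n >= 5")
  cuts <- qc_quantile(values, probs)
  list(low = values < cuts[1], high = values > cuts[2], cutpoints = cuts)
}

#' Default association-test plan
#'
#' Enumerates the cohort comparisons per metric family. The motion family
#' carries the Bonferroni correction over its 19 tests (11 covariate tests
#' plus 8 condition-versus-healthy contrasts); the regional and quintile
#' contrasts are descriptive companions exempt from correction, and the
#' coverage and contrast families are small enough that no correction is
#' applied.
#'
#' @param date_windows `list(first = c(from, to), last = c(from, to))`
#'   acquisition-period windows for the first-versus-last-period contrast.
#' @return a `data.frame` plan consumed by [run_association_battery()],
#'   with the date windows attached as an attribute.
#' @export
default_association_plan <- function(date_windows = list(
  first = c("2014-04-01", "2015-09-30"),
  last = c("2017-08-01", "2018-02-28"))) {
  row <- function(family, id, type, metric, covariate = NA, metric2 = NA,
                  corrected = FALSE)
    data.frame(family = family, test_id = id, type = type, metric = metric,
               covariate = covariate, metric2 = metric2,
               corrected = corrected, stringsAsFactors = FALSE)
  conds <- c("angina", "infarction", "arrhythmia", "cardiomyopathy",
             "asthma", "copd", "emphysema", "bronchiectasis")
  plan <- rbind(
    row("coverage", "site", "ranksum_site", "coverage"),
    row("coverage", "first_vs_last_period", "ranksum_period", "coverage"),
    row("coverage", "weight", "tau", "coverage", "weight"),
    row("coverage", "bsa", "tau", "coverage", "bsa"),

    row("motion", "site", "ranksum_site", "average_misalignment",
        corrected = TRUE),
    row("motion", "first_vs_last_period", "ranksum_period",
        "average_misalignment", corrected = TRUE),
    row("motion", "weight", "tau", "average_misalignment", "weight",
        corrected = TRUE),
    row("motion", "bsa", "tau", "average_misalignment", "bsa",
        corrected = TRUE),
    row("motion", "age", "tau", "average_misalignment", "age",
        corrected = TRUE),
    row("motion", "systolic_bp", "tau", "average_misalignment",
        "systolic_bp", corrected = TRUE),
    row("motion", "diastolic_bp", "tau", "average_misalignment",
        "diastolic_bp", corrected = TRUE),
    row("motion", "walking_days", "tau", "average_misalignment",
        "walking_days", corrected = TRUE),
    row("motion", "vigorous_days", "tau", "average_misalignment",
        "vigorous_days", corrected = TRUE),
    row("motion", "alcohol_freq", "tau", "average_misalignment",
        "alcohol_freq", corrected = TRUE),
    row("motion", "never_vs_current_smoking", "ranksum_smoking",
        "average_misalignment", corrected = TRUE),
    do.call(rbind, lapply(conds, function(cc)
      row("motion", paste0(cc, "_vs_healthy"), "ranksum_condition",
          "average_misalignment", paste0("cond_", cc), corrected = TRUE))),
    row("motion", "mid_vs_apical", "ranksum_cols", "mid_misalignment",
        metric2 = "apical_misalignment"),
    row("motion", "mid_vs_basal", "ranksum_cols", "mid_misalignment",
        metric2 = "basal_misalignment"),
    row("motion", "low_vs_high_weight", "ranksum_quintile",
        "average_misalignment", "weight"),

    row("contrast", "mid_vs_apical", "ranksum_cols", "mid_contrast",
        metric2 = "apical_contrast"),
    row("contrast", "mid_vs_basal", "ranksum_cols", "mid_contrast",
        metric2 = "basal_contrast"),
    row("contrast", "site", "ranksum_site", "average_contrast"),
    row("contrast", "first_vs_last_period", "ranksum_period",
        "average_contrast"))
  attr(plan, "date_windows") <- lapply(date_windows, as.Date)
  plan
}

#' Run the cohort association battery
#'
#' Executes every planned test with pairwise deletion of missing values,
#' then applies per-family multiple-testing control: within each family
#' the Bonferroni threshold is `alpha` divided by the number of
#' correction-eligible tests in the plan (1 for families where no
#' correction is deemed necessary); correction-exempt tests are judged at
#' `alpha`. Planned tests with an empty group are recorded as skipped.
#'
#' @param cohort a cohort `data.frame` (see [generate_cohort()]).
#' @param plan a plan from [default_association_plan()].
#' @param alpha family-wise significance level.
#' @return a `data.frame` with one row per planned test: identifiers,
#'   group sizes, statistic, Hodges-Lehmann estimate, p, 95% CI, the
#'   per-family threshold and `significant_after_correction`.
#' @export
run_association_battery <- function(cohort, plan = default_association_plan(),
                                    alpha = 0.05) {
  dw <- attr(plan, "date_windows")
  pull2 <- function(i) {
    r <- plan[i, ]
    met <- cohort[[r$metric]]
    switch(r$type,
      ranksum_site = {
        lv <- levels(factor(cohort$site))
        list(x = met[cohort$site == lv[1]], y = met[cohort$site == lv[2]])
      },
      ranksum_period = {
        d <- as.Date(cohort$acq_date)
        list(x = met[d >= dw$first[1] & d <= dw$first[2]],
             y = met[d >= dw$last[1] & d <= dw$last[2]])
      },
      ranksum_smoking = list(x = met[cohort$smoking == "never"],
                             y = met[cohort$smoking == "current"]),
      ranksum_condition = list(x = met[cohort[[r$covariate]]],
                               y = met[cohort$healthy_control &
                                         !cohort[[r$covariate]]]),
      ranksum_cols = list(x = met, y = cohort[[r$metric2]]),
      ranksum_quintile = {
        g <- quintile_groups(cohort[[r$covariate]])
        list(x = met[g$low], y = met[g$high])
      },
      tau = list(x = cohort[[r$covariate]], y = met),
      stop("unknown test type: ", r$type))
  }

  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    r <- plan[i, ]
    smp <- pull2(i)
    res <- if (r$type == "tau") {
      if (sum(!is.na(smp$x) & !is.na(smp$y)) < 2) NULL else
        kendall_tau_b(smp$x, smp$y, test_id = r$test_id)
    } else {
      x <- smp$x[!is.na(smp$x)]; y <- smp$y[!is.na(smp$y)]
      if (length(x) < 1 || length(y) < 1) NULL else
        ranksum_with_ci(x, y, alpha = alpha, test_id = r$test_id)
    }
    if (is.null(res)) {
      res <- data.frame(test_id = r$test_id, type = r$type, n1 = 0L, n2 = 0L,
                        statistic = NA_real_, estimate = NA_real_,
                        p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE)
      res$status <- "skipped"
    } else res$status <- "ok"
    res$family <- r$family
    res$corrected <- r$corrected
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)

  n_corr <- stats::aggregate(corrected ~ family, data = plan, FUN = sum)
  thr <- stats::setNames(
    bonferroni_threshold(alpha, pmax(1, n_corr$corrected)), n_corr$family)
  out$p_threshold <- ifelse(out$corrected, thr[out$family], alpha)
  out$significant_after_correction <- !is.na(out$p) & out$p < out$p_threshold
  out[c("family", "test_id", "type", "n1", "n2", "statistic", "estimate",
        "p", "ci_low", "ci_high", "corrected", "p_threshold",
        "significant_after_correction", "status")]
}
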