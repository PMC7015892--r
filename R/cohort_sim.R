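# Synthetic cohort generator: per-subject covariates and QC metrics with
# controllable covariate-metric associations, standing in for a large
# population imaging study. The weight-misalignment association is
# injected through a Gaussian copula so that the population Kendall tau-b
# can be dialled exactly; misalignment is log-normal (right-skewed,
# strictly positive — the paper-scale cohort medians/IQRs are the default
# calibration), coverage and contrast are location-family draws with a
# site shift on coverage.

#' Cohort specification
#'
#' Defaults emulate the population-study conditions this package targets:
#' two acquisition sites with unequal throughput, acquisition dates over
#' 2014-2018, adult weight/BMI/age distributions, a weight-misalignment
#' Kendall tau-b of 0.21, misalignment median 2.29 mm (IQR 1.17 mm),
#' contrast median 39% (IQR 6%), and most stacks at or above full
#' coverage.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param weight_mean,weight_sd weight distribution, kg.
#' @param bmi_mean,bmi_sd body-mass-index distribution, kg/m^2.
#' @param age_mean,age_sd,age_range age distribution, years (truncated).
#' @param site_levels,site_proportions acquisition sites and their mix.
#' @param date_range acquisition date window (`Date` or parseable strings).
#' @param smoking_probs P(never, previous, current).
#' @param alcohol_probs probabilities of the 6 intake-frequency codes
#'   (1 = daily ... 6 = never).
#' @param walking_probs,vigorous_probs probabilities for 0-7 days/week.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd blood pressure, mmHg.
#' @param condition_prevalence named prevalences of the self-reported
#'   cardiovascular/respiratory conditions.
#' @param condition_misalignment_shift named additive misalignment shifts
#'   (mm) for subjects reporting each condition.
#' @param healthy_control_rate P(healthy control | no listed condition).
#' @param target_tau_weight_misalignment population Kendall tau-b between
#'   weight and average misalignment, in (-1, 1).
#' @param misalignment_median,misalignment_iqr log-normal calibration, mm.
#' @param smoking_misalignment_shift additive shift (mm) for current
#'   smokers (half of it for previous smokers).
#' @param coverage_mean,coverage_sd coverage distribution, percent.
#' @param site_coverage_shift coverage location shift (percentage points)
#'   subtracted at the first-listed (high-throughput) site.
#' @param contrast_median,contrast_iqr contrast distribution, percent.
#' @param seed RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1000,
                        weight_mean = 76, weight_sd = 15,
                        bmi_mean = 27, bmi_sd = 4,
                        age_mean = 61.7, age_sd = 7.0, age_range = c(45, 82),
                        site_levels = c("Cheadle", "Newcastle"),
                        site_proportions = c(0.85, 0.15),
                        date_range = c("2014-04-01", "2018-02-28"),
                        smoking_probs = c(never = 0.55, previous = 0.35,
                                          current = 0.10),
                        alcohol_probs = c(0.20, 0.25, 0.12, 0.20, 0.15, 0.08),
                        walking_probs = rep(1 / 8, 8),
                        vigorous_probs = c(0.30, 0.14, 0.14, 0.12, 0.10,
                                           0.08, 0.06, 0.06),
                        sbp_mean = 138, sbp_sd = 18,
                        dbp_mean = 82, dbp_sd = 10,
                        condition_prevalence = c(angina = 0.030,
                                                 infarction = 0.025,
                                                 arrhythmia = 0.040,
                                                 cardiomyopathy = 0.003,
                                                 asthma = 0.110, copd = 0.015,
                                                 emphysema = 0.005,
                                                 bronchiectasis = 0.004),
                        condition_misalignment_shift = c(angina = 0.25,
                                                         infarction = 0.30,
                                                         arrhythmia = 0.10,
                                                         cardiomyopathy = 0.20,
                                                         asthma = 0.05,
                                                         copd = 0.30,
                                                         emphysema = 0.20,
                                                         bronchiectasis = 0.10),
                        healthy_control_rate = 0.70,
                        target_tau_weight_misalignment = 0.21,
                        misalignment_median = 2.29, misalignment_iqr = 1.17,
                        smoking_misalignment_shift = 0.22,
                        coverage_mean = 104, coverage_sd = 5,
                        site_coverage_shift = 3,
                        contrast_median = 39, contrast_iqr = 6,
                        seed = 1L) {
  stopifnot(n_subjects >= 2)
  if (abs(target_tau_weight_misalignment) > 0.999)
    stop("target tau is infeasible for a Gaussian copula link")
  for (p in list(site_proportions, smoking_probs, alcohol_probs,
                 walking_probs, vigorous_probs)) {
    if (abs(sum(p) - 1) > 1e-6) stop("category probabilities must sum to 1")
  }
  structure(as.list(environment())[setdiff(names(formals(cohort_spec)), "p")],
            class = "cohort_spec")
}

#' Kendall tau to Gaussian-copula correlation
#'
#' Inverts the Gaussian-copula relation `tau = (2/pi) * asin(rho)`:
#' `rho = sin(pi * tau / 2)`.
#'
#' @param tau Kendall tau-b in `[-1, 1]`.
#' @return the latent normal correlation.
#' @export
copula_tau_to_rho <- function(tau) {
  stopifnot(all(abs(tau) <= 1))
  sin(pi * tau / 2)
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` with one row per subject: identifiers, site,
#'   acquisition date, anthropometrics (weight, BMI, Mosteller BSA), age,
#'   blood pressure, lifestyle, smoking, condition indicators
#'   (`cond_*`), `healthy_control`, and the QC metrics
#'   (`coverage`, `average_misalignment` + regional, `average_contrast`
#'   + regional).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  rho <- copula_tau_to_rho(spec$target_tau_weight_misalignment)
  meanlog <- log(spec$misalignment_median)
  sdlog <- asinh(spec$misalignment_iqr / (2 * spec$misalignment_median)) /
    stats::qnorm(0.75)

  with_seed(spec$seed, {
    z_w <- stats::rnorm(n)
    weight <- spec$weight_mean + spec$weight_sd * z_w
    bmi <- pmax(16, stats::rnorm(n, spec$bmi_mean, spec$bmi_sd))
    bsa <- mosteller_bsa(weight, bmi)
    age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                     spec$age_range[1]), spec$age_range[2])
    site <- factor(sample(spec$site_levels, n, replace = TRUE,
                          prob = spec$site_proportions),
                   levels = spec$site_levels)
    dr <- as.Date(spec$date_range)
    acq_date <- dr[1] + sample.int(as.integer(dr[2] - dr[1]) + 1L, n,
                                   replace = TRUE) - 1L
    smoking <- factor(sample(names(spec$smoking_probs), n, replace = TRUE,
                             prob = spec$smoking_probs),
                      levels = names(spec$smoking_probs))
    alcohol_freq <- sample.int(length(spec$alcohol_probs), n, replace = TRUE,
                               prob = spec$alcohol_probs)
    walking_days <- sample(0:7, n, replace = TRUE, prob = spec$walking_probs)
    vigorous_days <- sample(0:7, n, replace = TRUE, prob = spec$vigorous_probs)
    systolic_bp <- stats::rnorm(n, spec$sbp_mean, spec$sbp_sd)
    diastolic_bp <- stats::rnorm(n, spec$dbp_mean, spec$dbp_sd)

    conds <- vapply(names(spec$condition_prevalence), function(cc)
      stats::runif(n) < spec$condition_prevalence[[cc]], logical(n))
    any_cond <- rowSums(conds) > 0
    healthy_control <- !any_cond & stats::runif(n) < spec$healthy_control_rate

    # Gaussian-copula link: tau(weight, misalignment) = (2/pi) asin(rho)
    z_m <- rho * z_w + sqrt(1 - rho^2) * stats::rnorm(n)
    mis <- stats::qlnorm(stats::pnorm(z_m), meanlog, sdlog)
    mis <- mis + spec$smoking_misalignment_shift *
      (smoking == "current") + 0.5 * spec$smoking_misalignment_shift *
      (smoking == "previous")
    shifts <- spec$condition_misalignment_shift
    for (cc in names(shifts)) mis <- mis + shifts[[cc]] * conds[, cc]

    # paper-scale regional ratios around the overall average
    reg_noise <- function(sd) exp(stats::rnorm(n, 0, sd))
    apical_mis <- mis * (2.48 / 2.29) * reg_noise(0.10)
    mid_mis <- mis * (1.86 / 2.29) * reg_noise(0.10)
    basal_mis <- mis * (2.56 / 2.29) * reg_noise(0.10)

    coverage <- stats::rnorm(n, spec$coverage_mean, spec$coverage_sd) -
      spec$site_coverage_shift * (site == spec$site_levels[1])
    csd <- spec$contrast_iqr / (2 * stats::qnorm(0.75))
    contrast <- stats::rnorm(n, spec$contrast_median, csd)
    apical_con <- contrast - 2 + stats::rnorm(n, 0, 2)
    mid_con <- contrast + 2 + stats::rnorm(n, 0, 2)
    basal_con <- contrast - 3 + stats::rnorm(n, 0, 2)

    out <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n)),
      site = site, acq_date = acq_date,
      weight = weight, bmi = bmi, bsa = bsa, age = age,
      systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
      walking_days = walking_days, vigorous_days = vigorous_days,
      alcohol_freq = alcohol_freq, smoking = smoking,
      healthy_control = healthy_control,
      coverage = coverage,
      average_misalignment = mis,
      apical_misalignment = apical_mis, mid_misalignment = mid_mis,
      basal_misalignment = basal_mis,
      average_contrast = contrast,
      apical_contrast = apical_con, mid_contrast = mid_con,
      basal_contrast = basal_con,
      stringsAsFactors = FALSE)
    for (cc in colnames(conds)) out[[paste0("cond_", cc)]] <- conds[, cc]
    out
  })
}
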