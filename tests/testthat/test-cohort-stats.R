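# Brute-force oracles for the rank statistics, kept independent of the
# implementation path they check.

# exact two-sided rank-sum p by enumerating all group labelings
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# tau-b by direct summation over all pairs, with tie terms
brute_tau_b <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

test_that("Mosteller BSA follows the two-step formula", {
  # constructed unit case: weight 36, bmi 36 -> height 1 m, bsa 1
  expect_equal(mosteller_bsa(36, 36), 1)
  # direct evaluation: height = sqrt(80/25) m, bsa = sqrt(h_cm * 80 / 3600)
  h_cm <- 100 * sqrt(80 / 25)
  expect_equal(mosteller_bsa(80, 25), sqrt(h_cm * 80 / 3600))
  expect_equal(round(mosteller_bsa(80, 25), 4), 1.9938)
  # scaling identity at fixed bmi: height grows as sqrt(w), so
  # bsa = w^(3/4) * bmi^(-1/4) / 6 and bsa(4w) = 4^(3/4) bsa(w)
  expect_equal(mosteller_bsa(4 * 70, 27), 4^0.75 * mosteller_bsa(70, 27))
  expect_equal(mosteller_bsa(70, 27), 70^0.75 * 27^-0.25 / 6)
  expect_error(mosteller_bsa(-1, 25), "positive")
})

test_that("Anderson-Darling statistic equals the textbook summation", {
  set.seed(601)
  x <- round(rnorm(10, 5, 2), 3)
  res <- anderson_darling_normal(x)
  xs <- sort(x)
  z <- (xs - mean(x)) / sd(x)
  n <- length(x)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(pnorm(z)) + log(1 - pnorm(rev(z)))))
  expect_equal(res$A2, a2, tolerance = 1e-12)
  expect_error(anderson_darling_normal(rep(1, 20)), "variance")
  expect_error(anderson_darling_normal(rnorm(5)), "n >= 8")
})

test_that("Anderson-Darling rejects heavy skew and respects the null", {
  set.seed(602)
  expect_lt(anderson_darling_normal(rexp(500))$p, 0.001)
  # a single well-behaved normal sample should not reject strongly
  expect_gt(anderson_darling_normal(rnorm(500))$p, 0.001)
})

test_that("rank-sum p and Hodges-Lehmann estimate match brute force", {
  r <- ranksum_with_ci(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                     # 2/20 labelings as extreme
  expect_equal(r$estimate, -3)               # median of all 9 pairwise diffs
  expect_equal(enum_ranksum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(603)
  for (rep in 1:5) {
    x <- rnorm(7); y <- rnorm(6, 0.8)
    r <- ranksum_with_ci(x, y)
    expect_equal(r$p, enum_ranksum_p(x, y), tolerance = 1e-12)
    diffs <- sort(as.vector(outer(x, y, "-")))
    expect_equal(r$estimate, median(diffs), tolerance = 1e-9)
  }
  # identical multisets: zero location difference
  expect_equal(ranksum_with_ci(c(2, 4, 9), c(9, 2, 4))$estimate, 0)
  expect_error(ranksum_with_ci(numeric(0), 1:3), "empty")
})

test_that("HL confidence interval endpoints invert the exact rank-sum test", {
  set.seed(604)
  for (rep in 1:4) {
    x <- rnorm(6); y <- rnorm(6, 1)
    r <- ranksum_with_ci(x, y, alpha = 0.05)
    diffs <- sort(as.vector(outer(x, y, "-")))
    # scan shifts between consecutive pairwise differences: the CI is the
    # closure of the shifts whose exact test is not rejected
    mids <- (head(diffs, -1) + tail(diffs, -1)) / 2
    acc <- vapply(mids, function(d) enum_ranksum_p(x, y + d) > 0.05, TRUE)
    expect_equal(r$ci_low, diffs[min(which(acc))], tolerance = 1e-9)
    expect_equal(r$ci_high, diffs[max(which(acc)) + 1], tolerance = 1e-9)
  }
})

test_that("exact and normal-approximation rank-sum p agree for n = 8 + 8", {
  set.seed(605)
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_norm <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("Kendall tau-b matches all-pairs brute force, with and without ties", {
  r <- kendall_tau_b(1:5, c(1, 2, 3, 5, 4))
  expect_equal(r$statistic, 0.8)             # C = 9, D = 1 over 10 pairs
  expect_equal(kendall_tau_b(1:6, (1:6)^3)$statistic, 1)
  set.seed(606)
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    x <- sample(1:8, n, replace = TRUE)      # heavy ties
    y <- x + sample(0:4, n, replace = TRUE)
    expect_equal(kendall_tau_b(x, y)$statistic, brute_tau_b(x, y),
                 tolerance = 1e-12)
  }
  # antisymmetry for tie-free y
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(kendall_tau_b(x, y)$statistic, -kendall_tau_b(x, -y)$statistic)
  expect_error(kendall_tau_b(rep(1, 10), 1:10), "all-tied")
})

test_that("exact small-sample tau p-value matches permutation enumeration", {
  set.seed(607)
  x <- rnorm(6); y <- rnorm(6)
  r <- kendall_tau_b(x, y)
  perms <- combinat_perms <- NULL
  # enumerate all 720 permutations of y
  idx <- expand.grid(rep(list(1:6), 6))
  idx <- idx[apply(idx, 1, function(v) length(unique(v)) == 6), ]
  taus <- apply(idx, 1, function(v) brute_tau_b(x, y[as.integer(v)]))
  p_enum <- mean(abs(taus) >= abs(r$statistic) - 1e-12)
  expect_equal(r$p, p_enum, tolerance = 1e-9)
})

test_that("tau-b estimator is nearly unbiased on copula data", {
  set.seed(608)
  rho <- copula_tau_to_rho(0.2)
  taus <- replicate(300, {
    z1 <- rnorm(500); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(500)
    unname(cor(z1, z2, method = "kendall"))
  })
  expect_lt(abs(mean(taus) - 0.2), 0.01)
})

test_that("linear regression matches its closed-form oracle", {
  x <- 1:20
  f <- linear_regression(x, 2 * x + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1); expect_equal(f$r, 1)
  set.seed(609)
  x <- rnorm(100); y <- 0.6 * x + rnorm(100)
  f2 <- linear_regression(x, y)
  expect_equal(f2$slope, cov(x, y) / var(x), tolerance = 1e-9)
  # independence null: negligible correlation at large n
  xn <- rnorm(10000); yn <- rnorm(10000)
  expect_lt(abs(linear_regression(xn, yn)$r), 0.05)
  expect_error(linear_regression(rep(1, 10), rnorm(10)), "constant")
})

test_that("Bonferroni threshold is exact, monotone, and prints as 0.0026", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(round_half_up(bonferroni_threshold(0.05, 19), 4), 0.0026)
  thr <- vapply(1:30, function(n) bonferroni_threshold(0.05, n), 0)
  expect_true(all(diff(thr) < 0))
})

test_that("quintile groups use strict linear-interpolation percentiles", {
  g <- quintile_groups(1:100)
  # order-statistic oracle: q20 = 20.8, q80 = 80.2 under type-7
  expect_equal(unname(g$cutpoints), c(20.8, 80.2))
  expect_equal(which(g$low), 1:20)
  expect_equal(which(g$high), 81:100)
  all_equal <- quintile_groups(rep(5, 50))
  expect_false(any(all_equal$low)); expect_false(any(all_equal$high))
  # continuous data: each group close to n/5
  set.seed(610)
  gc <- quintile_groups(rnorm(10000))
  expect_lt(abs(mean(gc$low) - 0.2), 0.02)
  expect_lt(abs(mean(gc$high) - 0.2), 0.02)
})

test_that("the association battery applies per-family correction and skips", {
  coh <- generate_cohort(cohort_spec(n_subjects = 600, seed = 77))
  res <- run_association_battery(coh)
  expect_equal(sum(res$family == "motion" & res$corrected), 19)
  expect_equal(unique(res$p_threshold[res$corrected]), 0.05 / 19)
  expect_equal(unique(res$p_threshold[!res$corrected]), 0.05)
  # uncorrected families decide at alpha
  un <- res[!res$corrected & res$status == "ok", ]
  expect_equal(un$significant_after_correction, un$p < 0.05)
  # empty group is skipped, not failed
  coh2 <- coh
  coh2$cond_cardiomyopathy <- FALSE
  res2 <- run_association_battery(coh2)
  expect_equal(res2$status[res2$test_id == "cardiomyopathy_vs_healthy"],
               "skipped")
  expect_false(any(is.na(res2$status)))
})
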