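test_that("coverage matches closed-form gap/overhang arithmetic", {
  # exact span: centres 0..90 over L = 90
  ph <- generate_phantom(phantom_spec())
  cov <- compute_coverage(ph$stack, ph$landmarks)
  expect_equal(cov$coverage, 100)
  expect_equal(cov$basal_gap + cov$apical_gap +
                 cov$basal_overhang + cov$apical_overhang, 0)

  # centres -5..95: overhangs 5 and 5, coverage 100 * 100 / 90
  ph2 <- generate_phantom(phantom_spec(apical_truncation = -5,
                                       basal_truncation = -5))
  cov2 <- compute_coverage(ph2$stack, ph2$landmarks)
  expect_equal(cov2$coverage, 100 * 100 / 90)
  expect_equal(cov2$apical_overhang, 5)
  expect_equal(cov2$basal_overhang, 5)
  expect_equal(cov2$basal_gap, 0)

  # centres 10..90: apical gap 10, coverage 100 * 80 / 90, below the
  # severe threshold
  ph3 <- generate_phantom(phantom_spec(apical_truncation = 10))
  cov3 <- compute_coverage(ph3$stack, ph3$landmarks)
  expect_equal(cov3$coverage, 100 * 80 / 90)
  expect_equal(cov3$apical_gap, 10)
  cls <- classify_stack(cov3, NULL, NULL)
  expect_true(cls$flags[["coverage_severe"]])
})

test_that("coverage agrees with a 0.01 mm axis-sampling oracle", {
  set.seed(501)
  for (rep in 1:8) {
    at <- runif(1, -10, 20); bt <- runif(1, -10, 20)
    ph <- generate_phantom(phantom_spec(apical_truncation = at,
                                        basal_truncation = bt))
    cov <- compute_coverage(ph$stack, ph$landmarks)
    s <- ph$truth$slice_axis_coords
    grid <- seq(0.005, 89.995, by = 0.01)          # midpoints of 0.01 mm cells
    covered_inside <- 100 * mean(grid >= min(s) & grid <= max(s))
    overhang <- 100 * (max(0, -min(s)) + max(0, max(s) - 90)) / 90
    expect_lt(abs(cov$coverage - (covered_inside + overhang)), 0.05)
  }
})

test_that("coverage sanity and error contracts hold", {
  ph <- generate_phantom(phantom_spec())
  bad_lm <- structure(list(mv = NULL, apex = NULL, per_view = list(),
                           fused_from = character(0), sanity_ok = FALSE),
                      class = "landmark_set")
  cov <- compute_coverage(ph$stack, bad_lm)
  expect_false(cov$sanity_ok)
  expect_true(is.na(cov$coverage))
  one <- stack_volume(ph$stack$slices[1])
  expect_error(compute_coverage(one, ph$landmarks), "two slices")
})

test_that("misalignment recovers injected shifts and regional averages", {
  # one slice among the assessed shifted by (3, 4)-ish grid multiples
  sh <- matrix(0, 10, 2); sh[6, ] <- c(3, 4) * 1.8
  ph <- generate_phantom(phantom_spec(per_slice_shift = sh))
  qc <- truth_qc(ph)
  mot <- qc$motion
  expect_true(mot$sanity_ok)
  truth <- ph$truth$applied_shift_magnitudes[mot$slice_indices]
  expect_equal(mot$per_slice_mm, truth, tolerance = 1e-9)
  expect_equal(mot$average_mm, mean(truth))
  # count-weighted regional identity
  n_ap <- 2; n_ba <- 2; n_mid <- length(mot$per_slice_mm) - 4
  expect_equal(mot$average_mm,
               (n_ap * mot$apical_mm + n_mid * mot$mid_mm +
                  n_ba * mot$basal_mm) / length(mot$per_slice_mm),
               tolerance = 1e-9)
})

test_that("regional split follows the first-2/last-2/mid convention", {
  reg <- saqc:::regional_split(8)
  expect_equal(reg$apical, 1:2)
  expect_equal(reg$mid, 3:6)
  expect_equal(reg$basal, 7:8)
  vals <- c(4, 4, 1, 1, 1, 1, 2, 2)      # apex -> base
  expect_equal(mean(vals[reg$apical]), 4)
  expect_equal(mean(vals[reg$mid]), 1)
  expect_equal(mean(vals[reg$basal]), 2)
  expect_equal(mean(vals), (2 * 4 + 4 * 1 + 2 * 2) / 8)
})

test_that("misalignment scales exactly with the shift vectors", {
  base <- matrix(0, 10, 2); base[4, ] <- c(1.8, 0); base[8, ] <- c(0, -1.8)
  m_at <- function(k) {
    ph <- generate_phantom(phantom_spec(per_slice_shift = base * k))
    truth_qc(ph)$motion$per_slice_mm
  }
  m1 <- m_at(1); m2 <- m_at(2); m0 <- m_at(0)
  expect_equal(m2, 2 * m1, tolerance = 1e-9)
  expect_equal(m0, 0 * m1)
})

test_that("increasing basal truncation never increases coverage", {
  covs <- vapply(c(-5, 0, 5, 12, 20), function(bt) {
    ph <- generate_phantom(phantom_spec(basal_truncation = bt))
    compute_coverage(ph$stack, ph$landmarks)$coverage
  }, 0)
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("contrast follows the per-slice dynamic-range formula", {
  ph <- generate_phantom(phantom_spec(intensity_blood = 200,
                                      intensity_myo = 80, intensity_bg = 0))
  con <- truth_qc(ph)$contrast
  expect_true(con$sanity_ok)
  expect_equal(unique(con$per_slice_pct), 60)
  # equal means give zero contrast
  ph0 <- generate_phantom(phantom_spec(intensity_blood = 120,
                                       intensity_myo = 120, intensity_bg = 0))
  con0 <- truth_qc(ph0)$contrast
  expect_equal(unique(con0$per_slice_pct), 0)
  # count-weighted regional identity
  n <- length(con$per_slice_pct)
  expect_equal(con$average_pct,
               (2 * con$apical_pct + (n - 4) * con$mid_pct +
                  2 * con$basal_pct) / n, tolerance = 1e-9)
})

test_that("reference centres match the analytic axis-plane intersections", {
  ph <- generate_phantom(phantom_spec(seed = 31))
  centers <- compute_reference_centers(ph$la_views, ph$la_segs, ph$stack)
  ax <- lv_axis(ph$truth$apex, ph$truth$mv)
  for (k in seq_along(ph$stack$slices)) {
    expected <- slice_plane_intersection(ax$apex_point, ax$direction,
                                         ph$stack$slices[[k]]$geometry)
    expect_lt(max(abs(centers[[k]] - expected)), 1e-6)
  }
  # single LA view still defines the line
  c1 <- compute_reference_centers(ph$la_views[1], ph$la_segs[1], ph$stack)
  expect_lt(max(abs(c1[[5]] - centers[[5]])), 1e-6)
  # empty LA masks: no reference at all
  empty <- list(seg_map(labels = matrix(0L, 96, 96)))
  c0 <- compute_reference_centers(ph$la_views[1], empty, ph$stack)
  expect_true(all(vapply(c0, is.null, TRUE)))
})

test_that("all three metrics are invariant under rigid scene motion", {
  set.seed(502)
  sh <- matrix(0, 10, 2); sh[5, ] <- c(-1.8, 3.6)
  ph <- generate_phantom(phantom_spec(per_slice_shift = sh,
                                      basal_truncation = 6))
  qc1 <- truth_qc(ph)
  R <- random_rotation(); tr <- rnorm(3, 0, 80)
  ph$stack <- rigid_transform(ph$stack, R, tr)
  ph$la_views <- lapply(ph$la_views, rigid_transform, R = R, t = tr)
  ph$landmarks <- rigid_transform(ph$landmarks, R, tr)
  qc2 <- truth_qc(ph)
  expect_equal(qc2$coverage$coverage, qc1$coverage$coverage, tolerance = 1e-9)
  expect_equal(qc2$coverage$basal_gap, qc1$coverage$basal_gap, tolerance = 1e-9)
  expect_lt(max(abs(qc2$motion$per_slice_mm - qc1$motion$per_slice_mm)), 1e-6)
  expect_lt(max(abs(qc2$contrast$per_slice_pct - qc1$contrast$per_slice_pct)),
            1e-6)
})

test_that("classification uses strict boundaries and exclusion semantics", {
  thr <- qc_thresholds()
  mk_cov <- function(v) structure(list(coverage = v, sanity_ok = TRUE),
                                  class = "coverage_result")
  mk_mot <- function(v) structure(list(average_mm = v, sanity_ok = TRUE),
                                  class = "motion_result")
  mk_con <- function(v) structure(list(average_pct = v, sanity_ok = TRUE),
                                  class = "contrast_result")
  # coverage exactly 100 counts as full
  cls <- classify_stack(mk_cov(100), mk_mot(3.4), mk_con(30), thr)
  expect_false(cls$flags[["coverage_suboptimal"]])
  # misalignment exactly 3.4 mm is corrupt (boundary included)
  expect_true(cls$flags[["motion_corrupt"]])
  # contrast exactly 30 is not low
  expect_false(cls$flags[["contrast_low"]])
  cls2 <- classify_stack(mk_cov(99.999), mk_mot(3.399), mk_con(19.9), thr)
  expect_true(cls2$flags[["coverage_suboptimal"]])
  expect_false(cls2$flags[["motion_corrupt"]])
  expect_true(cls2$flags[["contrast_very_low"]])
  # sanity-failed checks are excluded, never flagged
  failed <- list(sanity_ok = FALSE)
  cls3 <- classify_stack(failed, failed, failed, thr)
  expect_length(cls3$flags, 0)
  expect_setequal(cls3$excluded, c("coverage", "motion", "contrast"))
})

test_that("threshold container enforces its orderings", {
  expect_error(qc_thresholds(coverage_suboptimal = 90, coverage_severe = 95))
  expect_error(qc_thresholds(contrast_low = 10, contrast_very_low = 20))
})
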