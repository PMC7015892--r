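test_that("binarize takes the per-pixel argmax with ties to background", {
  onehot <- array(0, c(2, 2, 3))
  onehot[, , 2] <- c(1, 0, 0, 1); onehot[, , 1] <- c(0, 1, 0, 0)
  onehot[, , 3] <- c(0, 0, 1, 0)
  b <- binarize(seg_map(probs = onehot))
  expect_equal(b$labels, matrix(c(1L, 0L, 2L, 1L), 2, 2))

  unif <- array(1 / 3, c(3, 3, 3))
  expect_true(all(binarize(seg_map(probs = unif))$labels == 0L))

  p <- array(0, c(1, 1, 3)); p[1, 1, ] <- c(0.2, 0.5, 0.3)
  expect_equal(as.integer(binarize(seg_map(probs = p))$labels), 1L)
})

test_that("seg_map validates probability normalisation and label values", {
  bad <- array(0.5, c(2, 2, 3))
  expect_error(seg_map(probs = bad), "sum to 1")
  expect_error(seg_map(labels = matrix(3L, 2, 2)), "labels")
})

test_that("extract_masks recovers phantom tissue on a clean mid-slice", {
  ph <- generate_phantom(phantom_spec())
  seg <- extract_masks(ph$stack$slices[[6]]$image)
  truth <- ph$sa_segs[[6]]$labels
  expect_gte(dice_coef(seg$labels == 1L, truth == 1L), 0.95)
  expect_gte(dice_coef(seg$labels == 2L, truth == 2L), 0.95)
})

test_that("extract_masks handles degenerate and cavity-free images", {
  flat <- matrix(7, 32, 32)
  seg <- extract_masks(flat)
  expect_true(seg$degenerate)
  expect_true(all(seg$labels == 0L))
  # apical slice: myocardium only, no false cavity
  ph <- generate_phantom(phantom_spec())
  seg1 <- extract_masks(ph$stack$slices[[1]]$image)
  expect_equal(sum(seg1$labels == 1L), 0)
  expect_gt(sum(seg1$labels == 2L), 0)
})

test_that("extract_masks is invariant to affine intensity rescaling", {
  ph <- generate_phantom(phantom_spec(noise_sd = 5, seed = 17))
  img <- ph$stack$slices[[6]]$image
  s1 <- extract_masks(img)
  s2 <- extract_masks(3.7 * img + 250)
  expect_identical(s1$labels, s2$labels)
})

test_that("detected landmarks agree with phantom truth", {
  ph <- generate_phantom(phantom_spec())
  for (q in 1:3) {
    # ground-truth masks: sub-voxel agreement
    lm_t <- detect_landmarks(ph$la_views[[q]], ph$la_segs[[q]])
    expect_lt(sqrt(sum((lm_t$mv - ph$truth$mv)^2)), 1.8)
    expect_lt(sqrt(sum((lm_t$apex - ph$truth$apex)^2)), 1.8)
    # extracted masks: within two in-plane voxels
    lm_e <- detect_landmarks(ph$la_views[[q]], extract_masks(ph$la_views[[q]]$image))
    expect_lt(sqrt(sum((lm_e$mv - ph$truth$mv)^2)), 2 * 1.8)
    expect_lt(sqrt(sum((lm_e$apex - ph$truth$apex)^2)), 2 * 1.8)
  }
  empty <- seg_map(labels = matrix(0L, 96, 96))
  expect_null(detect_landmarks(ph$la_views[[1]], empty))
})

test_that("sanity check passes clean stacks and catches defects", {
  ph <- generate_phantom(phantom_spec())
  san <- sanity_check_seg(ph$stack, ph$sa_segs, ph$landmarks)
  expect_true(san$passed)
  expect_length(san$reasons, 0)

  # truncated so only 5 slices lie between apex and mitral valve
  ph5 <- generate_phantom(phantom_spec(apical_truncation = 30,
                                       basal_truncation = 20))
  expect_length(ph5$stack$slices, 5)
  san5 <- sanity_check_seg(ph5$stack, ph5$sa_segs, ph5$landmarks)
  expect_false(san5$passed)
  expect_true("lt6_slices" %in% san5$reasons)

  # interior slice with a zeroed cavity mask
  segs <- ph$sa_segs
  lab <- segs[[6]]$labels
  lab[lab == 1L] <- 0L
  segs[[6]] <- seg_map(labels = lab, source = "ground_truth")
  san_h <- sanity_check_seg(ph$stack, segs, ph$landmarks)
  expect_false(san_h$passed)
  expect_true("empty_cavity" %in% san_h$reasons)

  # implausible cavity area jump between adjacent well-sized slices
  segs2 <- ph$sa_segs
  lab2 <- segs2[[7]]$labels
  cav <- which(lab2 == 1L, arr.ind = TRUE)
  ctr <- colMeans(cav)
  keep <- sqrt((cav[, 1] - ctr[1])^2 + (cav[, 2] - ctr[2])^2) <= 4
  lab2[lab2 == 1L] <- 0L
  lab2[cav[keep, , drop = FALSE]] <- 1L
  segs2[[7]] <- seg_map(labels = lab2, source = "ground_truth")
  san_j <- sanity_check_seg(ph$stack, segs2, ph$landmarks)
  expect_false(san_j$passed)
  expect_true("area_jump" %in% san_j$reasons)

  # broken myocardial ring on most slices
  segs3 <- lapply(ph$sa_segs, function(sg) {
    lab <- sg$labels
    lab[lab == 2L] <- 0L
    seg_map(labels = lab, source = "ground_truth")
  })
  san_r <- sanity_check_seg(ph$stack, segs3, ph$landmarks)
  expect_false(san_r$passed)
  expect_true("broken_ring" %in% san_r$reasons)

  # failed landmark fusion propagates
  bad_lm <- structure(list(mv = NULL, apex = NULL, per_view = list(),
                           fused_from = character(0), sanity_ok = FALSE),
                      class = "landmark_set")
  san_l <- sanity_check_seg(ph$stack, ph$sa_segs, bad_lm)
  expect_false(san_l$passed)
})

test_that("ground-truth labels and their one-hot encoding give identical metrics", {
  sh <- matrix(0, 10, 2); sh[5, ] <- c(1.8, -3.6)
  ph <- generate_phantom(phantom_spec(per_slice_shift = sh, seed = 23))
  as_onehot <- function(sg) {
    p <- array(0, c(dim(sg$labels), 3))
    for (k in 0:2) p[, , k + 1][sg$labels == k] <- 1
    seg_map(probs = p, source = "ground_truth")
  }
  sa_oh <- lapply(ph$sa_segs, as_onehot)
  la_oh <- lapply(ph$la_segs, as_onehot)
  r1 <- qc_subject(ph$stack, ph$la_views, ph$sa_segs, ph$la_segs, ph$landmarks)
  r2 <- qc_subject(ph$stack, ph$la_views, sa_oh, la_oh, ph$landmarks)
  expect_equal(r1$coverage$coverage, r2$coverage$coverage)
  expect_equal(r1$motion$per_slice_mm, r2$motion$per_slice_mm)
  expect_equal(r1$contrast$per_slice_pct, r2$contrast$per_slice_pct)
})
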