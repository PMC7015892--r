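# The three stack-level quality checks: heart coverage of the LV long
# axis, inter-slice in-plane misalignment against the long-axis-derived
# reference, and blood-pool/myocardium contrast normalised by the dynamic
# range — each with regional (apical / mid / basal) breakdowns and
# threshold classification.

#' Classification thresholds
#'
#' Defaults follow the validated operating points: coverage below 100% is
#' sub-optimal and below 90% severe; an average misalignment of 3.4 mm or
#' more marks noticeable motion corruption; average contrast below 30% of
#' the dynamic range is low, below 20% very low.
#'
#' @param coverage_suboptimal,coverage_severe percent coverage cut-offs.
#' @param motion_corrupt average misalignment cut-off, mm (inclusive).
#' @param contrast_low,contrast_very_low percent contrast cut-offs.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(coverage_suboptimal = 100, coverage_severe = 90,
                          motion_corrupt = 3.4, contrast_low = 30,
                          contrast_very_low = 20) {
  stopifnot(coverage_severe <= coverage_suboptimal,
            contrast_very_low <= contrast_low, motion_corrupt > 0)
  structure(list(coverage_suboptimal = coverage_suboptimal,
                 coverage_severe = coverage_severe,
                 motion_corrupt = motion_corrupt,
                 contrast_low = contrast_low,
                 contrast_very_low = contrast_very_low),
            class = "qc_thresholds")
}

# Axis coordinates of all slice centres, plus the slices lying between the
# landmarks (inclusive), ordered apex -> base.
stack_axis_coords <- function(stack, axis) {
  s <- vapply(stack$slices, function(sl)
    project_onto_axis(slice_center(sl), axis), 0)
  between <- which(s >= -1e-9 & s <= axis$length + 1e-9)
  list(s = s, between = between[order(s[between])])
}

#' Heart coverage of the LV long axis
#'
#' The covered portion of the apex-to-mitral-valve segment, in percent,
#' using the span of slice centres as the stack extent (an
#' exactly-spanning defect-free stack scores 100%; edge-based extent is
#' available via `use_edges`). Coverage above 100% indicates an
#' over-abundant stack. Gaps (landmark outside the stack) and overhangs
#' (stack past the landmark) are always reported:
#' `coverage = 100 * (L - gaps + overhangs) / L`.
#'
#' @param stack a [stack_volume()].
#' @param landmarks a [fuse_landmarks()] result.
#' @param use_edges measure the stack extent at slice edges (centre
#'   +/- thickness/2) instead of slice centres.
#' @return `list(coverage, basal_gap, apical_gap, basal_overhang,
#'   apical_overhang, sanity_ok)` of class `coverage_result`; all metric
#'   fields are `NA` when the landmark sanity check failed.
#' @export
compute_coverage <- function(stack, landmarks, use_edges = FALSE) {
  if (length(stack$slices) < 2) stop("coverage needs at least two slices")
  if (!isTRUE(landmarks$sanity_ok)) {
    return(structure(list(coverage = NA_real_, basal_gap = NA_real_,
                          apical_gap = NA_real_, basal_overhang = NA_real_,
                          apical_overhang = NA_real_, sanity_ok = FALSE),
                     class = "coverage_result"))
  }
  axis <- lv_axis(landmarks$apex, landmarks$mv)
  s <- stack_axis_coords(stack, axis)$s
  half <- if (use_edges) stack$slices[[1]]$geometry$thickness / 2 else 0
  s_min <- min(s) - half
  s_max <- max(s) + half
  L <- axis$length
  apical_gap <- max(0, s_min)
  basal_gap <- max(0, L - s_max)
  apical_overhang <- max(0, -s_min)
  basal_overhang <- max(0, s_max - L)
  coverage <- 100 * (L - basal_gap - apical_gap +
                       basal_overhang + apical_overhang) / L
  structure(list(coverage = coverage, basal_gap = basal_gap,
                 apical_gap = apical_gap, basal_overhang = basal_overhang,
                 apical_overhang = apical_overhang, sanity_ok = TRUE),
            class = "coverage_result")
}

#' Reference in-plane centres from the long-axis views
#'
#' Pools cavity centroids sampled along the cavity's long dimension in
#' each usable long-axis view, maps them to world space, fits a 3-D
#' total-least-squares line through them (the breath-hold-consistent LV
#' axis), and intersects that line with every SA slice plane.
#'
#' @param la_views list of [la_view()].
#' @param la_segs list of `seg_map`, one per view.
#' @param stack the SA [stack_volume()].
#' @param n_samples centroid samples per view along the long dimension.
#' @return list with one entry per SA slice: in-plane mm coordinates
#'   `(row_mm, col_mm)` of the expected LV centre, or `NULL` when the
#'   reference cannot be constructed (empty masks or line parallel to the
#'   slice plane).
#' @export
compute_reference_centers <- function(la_views, la_segs, stack,
                                      n_samples = 10) {
  pts <- list()
  for (q in seq_along(la_views)) {
    lab <- seg_labels(la_segs[[q]])
    cav <- which(lab == 1L, arr.ind = TRUE)
    if (nrow(cav) < 2) next
    geom <- la_views[[q]]$geometry
    sp <- geom$spacing
    P <- cbind((cav[, 1] - 1) * sp[1], (cav[, 2] - 1) * sp[2])
    ctr <- colMeans(P)
    Pc <- sweep(P, 2, ctr)
    pc1 <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)$vectors[, 1]
    t_val <- as.vector(Pc %*% pc1)
    breaks <- seq(min(t_val), max(t_val), length.out = n_samples + 1)
    bin <- pmin(pmax(findInterval(t_val, breaks, rightmost.closed = TRUE), 1),
                n_samples)
    for (b in unique(bin)) {
      uv <- colMeans(P[bin == b, , drop = FALSE])
      pts[[length(pts) + 1]] <- plane_to_world(uv, geom)
    }
  }
  n_sa <- length(stack$slices)
  if (length(pts) < 2) return(rep(list(NULL), n_sa))
  M <- do.call(rbind, pts)
  ctr <- colMeans(M)
  dir <- svd(sweep(M, 2, ctr))$v[, 1]
  lapply(stack$slices, function(sl)
    slice_plane_intersection(ctr, dir, sl$geometry))
}

#' Inter-slice misalignment
#'
#' Per assessed slice, the magnitude in mm of the in-plane translation
#' separating the observed LV position (sub-voxel centre of mass of the
#' cavity mask) from the reference position implied by the long-axis
#' views. Assessment is restricted to slices between the apex and the
#' mitral valve that have a cavity; regional averages follow the
#' apex-to-base order: apical = first 2, basal = last 2, mid = remainder.
#'
#' @param stack a [stack_volume()].
#' @param sa_segs list of `seg_map` per SA slice.
#' @param expected_centers output of [compute_reference_centers()].
#' @param landmarks a [fuse_landmarks()] result.
#' @param sanity a precomputed `sanity_report`, or `NULL` to run
#'   [sanity_check_seg()] here.
#' @return `list(per_slice_mm, slice_indices, average_mm, apical_mm,
#'   mid_mm, basal_mm, sanity_ok, reasons)` of class `motion_result`.
#' @export
compute_misalignment <- function(stack, sa_segs, expected_centers, landmarks,
                                 sanity = NULL) {
  if (is.null(sanity))
    sanity <- sanity_check_seg(stack, sa_segs, landmarks, check_id = "motion")
  fail <- function(reasons) {
    structure(list(per_slice_mm = numeric(0), slice_indices = integer(0),
                   average_mm = NA_real_, apical_mm = NA_real_,
                   mid_mm = NA_real_, basal_mm = NA_real_,
                   sanity_ok = FALSE, reasons = reasons),
              class = "motion_result")
  }
  if (!isTRUE(sanity$passed)) return(fail(sanity$reasons))
  axis <- lv_axis(landmarks$apex, landmarks$mv)
  ax <- stack_axis_coords(stack, axis)

  idx <- integer(0); m <- numeric(0)
  for (k in ax$between) {
    lab <- seg_labels(sa_segs[[k]])
    cav <- which(lab == 1L, arr.ind = TRUE)
    if (nrow(cav) == 0 || is.null(expected_centers[[k]])) next
    sp <- stack$slices[[k]]$geometry$spacing
    obs <- c(mean(cav[, 1] - 1) * sp[1], mean(cav[, 2] - 1) * sp[2])
    m <- c(m, vnorm(obs - expected_centers[[k]]))
    idx <- c(idx, k)
  }
  if (length(m) == 0) return(fail("no_assessable_slices"))
  reg <- regional_split(length(m))
  structure(list(per_slice_mm = m, slice_indices = idx,
                 average_mm = mean(m),
                 apical_mm = mean(m[reg$apical]),
                 mid_mm = if (length(reg$mid)) mean(m[reg$mid]) else NA_real_,
                 basal_mm = if (length(reg$basal)) mean(m[reg$basal]) else NA_real_,
                 sanity_ok = TRUE, reasons = character(0)),
            class = "motion_result")
}

# apical = first 2, basal = last 2, mid = remainder (apex -> base order)
regional_split <- function(n) {
  apical <- seq_len(min(2, n))
  basal <- if (n > 2) setdiff(seq(max(1, n - 1), n), apical) else integer(0)
  list(apical = apical, basal = basal,
       mid = setdiff(seq_len(n), c(apical, basal)))
}

#' Cardiac image contrast
#'
#' Per assessed slice, `100 * (mean blood-pool intensity - mean myocardium
#' intensity) / dynamic range`, the dynamic range being that slice's
#' max - min intensity (per-stack range via `per_stack_dr`), averaged over
#' the slices between apex and mitral valve; regional averages as in
#' [compute_misalignment()].
#'
#' @inheritParams compute_misalignment
#' @param per_stack_dr normalise by the whole stack's dynamic range
#'   instead of each slice's.
#' @return `list(per_slice_pct, slice_indices, average_pct, apical_pct,
#'   mid_pct, basal_pct, sanity_ok, reasons, excluded_slices)` of class
#'   `contrast_result`.
#' @export
compute_contrast <- function(stack, sa_segs, landmarks, sanity = NULL,
                             per_stack_dr = FALSE) {
  if (is.null(sanity))
    sanity <- sanity_check_seg(stack, sa_segs, landmarks, check_id = "contrast")
  fail <- function(reasons) {
    structure(list(per_slice_pct = numeric(0), slice_indices = integer(0),
                   average_pct = NA_real_, apical_pct = NA_real_,
                   mid_pct = NA_real_, basal_pct = NA_real_,
                   sanity_ok = FALSE, reasons = reasons,
                   excluded_slices = integer(0)),
              class = "contrast_result")
  }
  if (!isTRUE(sanity$passed)) return(fail(sanity$reasons))
  axis <- lv_axis(landmarks$apex, landmarks$mv)
  ax <- stack_axis_coords(stack, axis)
  stack_dr <- diff(range(unlist(lapply(stack$slices, function(sl) range(sl$image)))))

  idx <- integer(0); cvals <- numeric(0); dropped <- integer(0)
  for (k in ax$between) {
    lab <- seg_labels(sa_segs[[k]])
    img <- stack$slices[[k]]$image
    cav <- lab == 1L; myo <- lab == 2L
    if (!any(cav) || !any(myo)) next
    dr <- if (per_stack_dr) stack_dr else diff(range(img))
    if (dr <= 0) { dropped <- c(dropped, k); next }
    cvals <- c(cvals, 100 * (mean(img[cav]) - mean(img[myo])) / dr)
    idx <- c(idx, k)
  }
  if (length(cvals) == 0) return(fail("no_assessable_slices"))
  reg <- regional_split(length(cvals))
  structure(list(per_slice_pct = cvals, slice_indices = idx,
                 average_pct = mean(cvals),
                 apical_pct = mean(cvals[reg$apical]),
                 mid_pct = if (length(reg$mid)) mean(cvals[reg$mid]) else NA_real_,
                 basal_pct = if (length(reg$basal)) mean(cvals[reg$basal]) else NA_real_,
                 sanity_ok = TRUE, reasons = character(0),
                 excluded_slices = dropped),
            class = "contrast_result")
}

#' Classify a stack against the quality thresholds
#'
#' Strict comparisons throughout: coverage exactly 100% is full,
#' misalignment exactly at the motion threshold is corrupt, contrast
#' exactly at a cut-off is not flagged. Checks whose sanity gate failed
#' are reported as excluded and never flagged.
#'
#' @param cov,mot,con results of the three checks (any may be `NULL` or
#'   sanity-failed).
#' @param thresholds a [qc_thresholds()].
#' @return `list(flags, excluded)`: named logical vector of the five
#'   classification flags (only for non-excluded checks) and the names of
#'   excluded checks.
#' @export
classify_stack <- function(cov, mot, con, thresholds = qc_thresholds()) {
  flags <- logical(0)
  excluded <- character(0)
  if (!is.null(cov) && isTRUE(cov$sanity_ok)) {
    flags["coverage_suboptimal"] <- cov$coverage < thresholds$coverage_suboptimal
    flags["coverage_severe"] <- cov$coverage < thresholds$coverage_severe
  } else excluded <- c(excluded, "coverage")
  if (!is.null(mot) && isTRUE(mot$sanity_ok)) {
    flags["motion_corrupt"] <- mot$average_mm >= thresholds$motion_corrupt
  } else excluded <- c(excluded, "motion")
  if (!is.null(con) && isTRUE(con$sanity_ok)) {
    flags["contrast_low"] <- con$average_pct < thresholds$contrast_low
    flags["contrast_very_low"] <- con$average_pct < thresholds$contrast_very_low
  } else excluded <- c(excluded, "contrast")
  list(flags = flags, excluded = excluded)
}

#' Run all three quality checks on one subject
#'
#' End-to-end per-subject pipeline: landmark detection and fusion (unless
#' landmarks are supplied), segmentation (unless masks are supplied),
#' sanity checks, the three metrics, and threshold classification.
#'
#' @param stack SA [stack_volume()].
#' @param la_views list of [la_view()].
#' @param sa_segs,la_segs lists of `seg_map`, or `NULL` to run
#'   [extract_masks()].
#' @param landmarks a [fuse_landmarks()] result, or `NULL` to detect and
#'   fuse from the long-axis views.
#' @param thresholds a [qc_thresholds()].
#' @param max_pairwise_dist landmark-fusion agreement threshold, mm.
#' @return a `qc_report` list: `subject_id`, `coverage`, `motion`,
#'   `contrast`, `flags`, `excluded`, `landmarks`.
#' @export
qc_subject <- function(stack, la_views, sa_segs = NULL, la_segs = NULL,
                       landmarks = NULL, thresholds = qc_thresholds(),
                       max_pairwise_dist = 20) {
  if (is.null(sa_segs))
    sa_segs <- lapply(stack$slices, function(sl) extract_masks(sl$image))
  if (is.null(la_segs))
    la_segs <- lapply(la_views, function(v) extract_masks(v$image))
  if (is.null(landmarks)) {
    cand <- list()
    for (q in seq_along(la_views)) {
      lm <- detect_landmarks(la_views[[q]], la_segs[[q]])
      if (!is.null(lm)) cand[[la_views[[q]]$view_label]] <- lm
    }
    if (length(cand) == 0) {
      landmarks <- structure(list(mv = NULL, apex = NULL, per_view = list(),
                                  fused_from = character(0), sanity_ok = FALSE),
                             class = "landmark_set")
    } else landmarks <- fuse_landmarks(cand, max_pairwise_dist)
  }
  cov <- compute_coverage(stack, landmarks)
  sanity <- sanity_check_seg(stack, sa_segs, landmarks, check_id = "motion")
  centers <- if (isTRUE(landmarks$sanity_ok))
    compute_reference_centers(la_views, la_segs, stack) else
      rep(list(NULL), length(stack$slices))
  mot <- compute_misalignment(stack, sa_segs, centers, landmarks, sanity)
  con <- compute_contrast(stack, sa_segs, landmarks, sanity)
  cls <- classify_stack(cov, mot, con, thresholds)
  structure(list(subject_id = stack$subject_id, complete = TRUE,
                 coverage = cov, motion = mot, contrast = con,
                 flags = cls$flags, excluded = cls$excluded,
                 landmarks = landmarks),
            class = "qc_report")
}
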