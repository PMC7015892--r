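# Classical mask and landmark extraction for phantom images, plus the
# segmentation-level sanity checks that gate the motion and contrast
# metrics. The learned landmark/segmentation model used on real scans is
# deliberately not part of this package; this intensity-based extractor
# keeps the pipeline runnable end-to-end, and every downstream function
# also accepts ground-truth masks directly (source = "ground_truth") or
# externally computed ones (source = "external").

#' Segmentation map
#'
#' Either a hard label image (0 = background, 1 = LV cavity / blood pool,
#' 2 = LV myocardium) or per-label probability maps that sum to one per
#' pixel.
#'
#' @param labels integer matrix with values in `{0, 1, 2}`, or `NULL`.
#' @param probs `nrow x ncol x 3` array of per-label probabilities
#'   (background, cavity, myocardium), or `NULL`.
#' @param source provenance: `"extracted"`, `"ground_truth"` or
#'   `"external"`.
#' @param degenerate flag set by the extractor when the input image was
#'   unusable (e.g. constant).
#' @return an object of class `seg_map`.
#' @export
seg_map <- function(labels = NULL, probs = NULL, source = "extracted",
                    degenerate = FALSE) {
  source <- match.arg(source, c("extracted", "ground_truth", "external"))
  if (is.null(labels) && is.null(probs))
    stop("seg_map needs labels or probability maps")
  if (!is.null(labels)) {
    if (!all(labels %in% 0:2)) stop("labels must be 0, 1 or 2")
    storage.mode(labels) <- "integer"
  }
  if (!is.null(probs)) {
    stopifnot(length(dim(probs)) == 3, dim(probs)[3] == 3)
    sums <- probs[, , 1] + probs[, , 2] + probs[, , 3]
    if (max(abs(sums - 1)) > 1e-6)
      stop("probability maps must sum to 1 per pixel")
  }
  structure(list(labels = labels, probs = probs, source = source,
                 degenerate = degenerate),
            class = "seg_map")
}

#' Collapse probability maps to hard labels
#'
#' Per-pixel argmax over (background, cavity, myocardium); any tie for the
#' maximum falls back to background, so an uninformative map segments
#' nothing.
#'
#' @param seg a `seg_map` with probability maps.
#' @return a `seg_map` with hard labels (probabilities retained).
#' @export
binarize <- function(seg) {
  stopifnot(inherits(seg, "seg_map"))
  if (is.null(seg$probs)) {
    if (!is.null(seg$labels)) return(seg)
    stop("no probability maps to binarize")
  }
  p <- seg$probs
  d <- dim(p)
  p1 <- matrix(p[, , 1], d[1], d[2])
  p2 <- matrix(p[, , 2], d[1], d[2])
  p3 <- matrix(p[, , 3], d[1], d[2])
  mx <- pmax(p1, p2, p3)
  n_at_max <- (abs(p1 - mx) < 1e-12) + (abs(p2 - mx) < 1e-12) +
    (abs(p3 - mx) < 1e-12)
  lab <- matrix(0L, d[1], d[2])
  lab[abs(p2 - mx) < 1e-12] <- 1L
  lab[abs(p3 - mx) < 1e-12] <- 2L
  lab[n_at_max > 1] <- 0L
  seg_map(labels = lab, probs = p, source = seg$source)
}

# Hard labels from any seg_map.
seg_labels <- function(seg) {
  if (!is.null(seg$labels)) return(seg$labels)
  binarize(seg)$labels
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

# Two-threshold (three-class) Otsu: maximises the between-class variance
# over all threshold pairs on a binned histogram. Returns the two cut
# values and the three class means. (Single-threshold Otsu comes from
# EBImage; the multi-level variant is not provided there.)
otsu3 <- function(x, levels = 256) {
  b <- pmin(floor(x * levels), levels - 1)          # x in [0, 1]
  h <- tabulate(b + 1L, nbins = levels) / length(x)
  mids <- (seq_len(levels) - 0.5) / levels
  W <- cumsum(h); M <- cumsum(h * mids)
  best <- -Inf; t_best <- c(1L, 2L)
  for (i in 1:(levels - 2)) {
    w1 <- W[i]; if (w1 == 0) next
    m1 <- M[i] / w1
    j <- (i + 1):(levels - 1)
    w2 <- W[j] - W[i]; w3 <- 1 - W[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (M[j] - M[i]) / w2
    m3 <- (M[levels] - M[j]) / w3
    v <- w1 * m1^2 + w2 * m2^2 + w3 * m3^2        # total mean is constant
    v[!ok] <- -Inf
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; t_best <- c(i, j[k]) }
  }
  cls <- findInterval(b, t_best)                   # 0, 1, 2
  list(t_lo = t_best[1] / levels, t_hi = t_best[2] / levels,
       means = vapply(0:2, function(k)
         if (any(cls == k)) mean(x[cls == k]) else NA_real_, 0))
}

#' Extract cavity and myocardium masks from an intensity image
#'
#' Three-class (background / myocardium / blood pool) Otsu thresholding:
#' the two thresholds are estimated on a Gaussian-smoothed copy of the
#' image (stable under noise) and applied to the original pixels (no
#' boundary bias on clean images). The cavity is the largest bright
#' connected component; the myocardium is a morphological ring around it
#' intersected with the mid-intensity band. When the upper two class
#' means nearly coincide the image holds only one tissue class above
#' background — the normal situation near the apex — and no cavity is
#' reported.
#'
#' @param image 2-D intensity matrix.
#' @param min_cavity_px smallest credible cavity component, pixels.
#' @param ring_width_px width of the myocardial search ring, pixels.
#' @param smooth_sigma Gaussian pre-smoothing in pixels (stabilises the
#'   thresholds under noise; 0 disables).
#' @return a `seg_map` with `source = "extracted"`; a constant image gives
#'   empty masks flagged `degenerate`.
#' @export
extract_masks <- function(image, min_cavity_px = 9, ring_width_px = 9,
                          smooth_sigma = 1) {
  rng <- range(image)
  empty <- matrix(0L, nrow(image), ncol(image))
  if (diff(rng) == 0)
    return(seg_map(labels = empty, source = "extracted", degenerate = TRUE))

  x <- (image - rng[1]) / diff(rng)           # Otsu invariance to affine rescale
  xs <- if (smooth_sigma > 0)
    pmin(pmax(EBImage::gblur(x, sigma = smooth_sigma), 0), 1) else x

  lab <- empty
  th <- otsu3(xs)
  myo_only <- function() {
    t1 <- EBImage::otsu(xs, range = c(0, 1))
    if (any(x > t1)) lab[largest_component(x > t1)] <- 2L
    seg_map(labels = lab, source = "extracted")
  }
  if (is.na(th$means[3]) || is.na(th$means[2]) ||
      th$means[3] - th$means[2] < 0.15)
    return(myo_only())
  mid_lo <- th$t_lo; mid_hi <- th$t_hi
  bright <- x > mid_hi
  cavity <- largest_component(bright)
  if (sum(cavity) < min_cavity_px) return(myo_only())
  brush <- EBImage::makeBrush(2 * ring_width_px + 1, shape = "disc")
  ring <- EBImage::dilate(cavity * 1, brush) > 0 & !cavity
  myo <- ring & (x > mid_lo) & !bright
  lab[myo] <- 2L
  lab[cavity] <- 1L
  seg_map(labels = lab, source = "extracted")
}

#' Detect mitral-valve and apex landmarks in a long-axis view
#'
#' The cavity's principal axis is the LV long axis in a long-axis plane.
#' The basal end is identified as the wide end of the cavity; the mitral
#' valve is the centroid of the cavity's open (basal) edge, and the apex
#' is the point of the full LV mask (cavity plus myocardium, so the
#' estimate reaches the epicardial tip rather than stopping at the
#' endocardium) farthest from the valve along the principal axis.
#'
#' @param la an [la_view()].
#' @param seg a `seg_map` for that view.
#' @return `list(mv =, apex =)` world 3-vectors, or `NULL` when the cavity
#'   mask is empty (the view is then excluded from landmark fusion).
#' @export
detect_landmarks <- function(la, seg) {
  lab <- seg_labels(seg)
  cav <- which(lab == 1L, arr.ind = TRUE)
  if (nrow(cav) == 0) return(NULL)
  sp <- la$geometry$spacing
  # 0-based pixel coordinates in mm
  P <- cbind((cav[, 1] - 1) * sp[1], (cav[, 2] - 1) * sp[2])
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  pc1 <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)$vectors[, 1]
  t_cav <- Pc %*% pc1
  t_rng <- range(t_cav)
  band <- 0.1 * diff(t_rng)
  # the basal (open) end of the cavity is its wide end
  w_hi <- sum(t_cav >= t_rng[2] - band)
  w_lo <- sum(t_cav <= t_rng[1] + band)
  if (w_lo > w_hi) { pc1 <- -pc1; t_cav <- -t_cav; t_rng <- rev(-t_rng) }

  edge <- t_cav >= max(t_cav) - max(sp)       # within one pixel of the open edge
  mv_mm <- colMeans(P[edge, , drop = FALSE])

  lv <- which(lab > 0L, arr.ind = TRUE)
  Q <- cbind((lv[, 1] - 1) * sp[1], (lv[, 2] - 1) * sp[2])
  t_lv <- sweep(Q, 2, ctr) %*% pc1
  tip <- t_lv <= min(t_lv) + 1e-9
  apex_mm <- colMeans(Q[tip, , drop = FALSE])

  list(mv = plane_to_world(mv_mm, la$geometry),
       apex = plane_to_world(apex_mm, la$geometry))
}

#' Sanity-check segmentations for the motion and contrast metrics
#'
#' A stack fails when (a) fewer than `min_slices` slice centres fall
#' between the apex and the mitral valve, or (b) the masks look
#' unreliable: a cavity-free slice sandwiched between slices with cavity
#' (a hole in the stack), a cavity area jump above `max_area_jump`
#' (relative change, 3 = 300%) between adjacent slices that both have a
#' substantial cavity (at least `min_area_mm2`), or a myocardium that
#' fails to enclose the cavity on more than half of the slices with
#' cavity.
#'
#' @param stack a [stack_volume()].
#' @param segs list of `seg_map`, one per slice.
#' @param landmarks a [fuse_landmarks()] result.
#' @param check_id which metric this gate protects.
#' @param min_slices,max_area_jump,min_area_mm2 rule thresholds.
#' @return `list(check_id, passed, reasons)` of class `sanity_report`;
#'   `passed` is `TRUE` iff `reasons` is empty.
#' @export
sanity_check_seg <- function(stack, segs, landmarks,
                             check_id = c("motion", "contrast", "coverage"),
                             min_slices = 6, max_area_jump = 3,
                             min_area_mm2 = 150) {
  check_id <- match.arg(check_id)
  reasons <- character(0)
  if (!isTRUE(landmarks$sanity_ok)) {
    return(structure(list(check_id = check_id, passed = FALSE,
                          reasons = "landmark_sanity"),
                     class = "sanity_report"))
  }
  axis <- lv_axis(landmarks$apex, landmarks$mv)
  s <- vapply(stack$slices, function(sl)
    project_onto_axis(slice_center(sl), axis), 0)
  between <- which(s >= -1e-9 & s <= axis$length + 1e-9)
  between <- between[order(s[between])]

  if (length(between) < min_slices) reasons <- c(reasons, "lt6_slices")

  if (length(between)) {
    px_area <- vapply(between, function(k) {
      sp <- stack$slices[[k]]$geometry$spacing
      sum(seg_labels(segs[[k]]) == 1L) * sp[1] * sp[2]
    }, 0)
    nonempty <- which(px_area > 0)
    if (length(nonempty)) {
      inner <- seq(min(nonempty), max(nonempty))
      if (any(px_area[inner] == 0)) reasons <- c(reasons, "empty_cavity")
    }
    if (length(px_area) > 1) {
      for (i in seq_len(length(px_area) - 1)) {
        a <- px_area[i]; b <- px_area[i + 1]
        if (min(a, b) >= min_area_mm2 && max(a, b) / min(a, b) > 1 + max_area_jump) {
          reasons <- c(reasons, "area_jump"); break
        }
      }
    }
    if (length(nonempty)) {
      broken <- vapply(between[nonempty], function(k) {
        lab <- seg_labels(segs[[k]])
        !ring_encloses(lab)
      }, TRUE)
      if (mean(broken) > 0.5) reasons <- c(reasons, "broken_ring")
    }
  }
  structure(list(check_id = check_id, passed = length(reasons) == 0,
                 reasons = reasons),
            class = "sanity_report")
}

# TRUE when the myocardium separates the cavity from the image border:
# no connected component of non-myocardium contains both a border pixel
# and a cavity pixel.
ring_encloses <- function(lab) {
  notmyo <- lab != 2L
  comp <- EBImage::bwlabel(notmyo)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  cav_comp <- unique(comp[lab == 1L])
  length(intersect(border[border > 0], cav_comp[cav_comp > 0])) == 0
}
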