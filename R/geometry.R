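# World-space geometry of cine MR slices, landmarks and the LV long axis.
#
# Conventions (shared by every module):
#   * world coordinates follow the NIfTI affine: RAS+, millimetres;
#   * voxel-to-world uses the voxel-centre convention with 0-based indices,
#     i.e. world = origin + i*spacing[1]*row_dir + j*spacing[2]*col_dir for
#     pixel (i, j) of a slice;
#   * the LV long axis points from the apex towards the mitral valve, so
#     basal structures sit at high axis coordinates.

#' Slice geometry
#'
#' World-space placement of a single 2-D slice: origin (world position of
#' the centre of the first voxel), orthonormal in-plane axes, through-plane
#' normal (right-handed with the in-plane axes), pixel spacing and slice
#' thickness.
#'
#' @param origin numeric 3-vector, mm.
#' @param row_dir,col_dir unit 3-vectors along increasing first/second
#'   pixel index.
#' @param spacing numeric 2-vector, mm per pixel.
#' @param thickness slice thickness, mm.
#' @param index integer acquisition index.
#' @return an object of class `slice_geometry`.
#' @export
slice_geometry <- function(origin, row_dir, col_dir, spacing,
                           thickness = 8, index = 1L) {
  origin <- as.numeric(origin); row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir); spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3, length(row_dir) == 3, length(col_dir) == 3,
            length(spacing) == 2)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (thickness <= 0) stop("thickness must be positive")
  if (abs(vnorm(row_dir) - 1) > 1e-6 || abs(vnorm(col_dir) - 1) > 1e-6)
    stop("row_dir and col_dir must be unit vectors")
  if (abs(sum(row_dir * col_dir)) > 1e-6)
    stop("row_dir and col_dir must be orthogonal")
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  structure(list(origin = origin, row_dir = row_dir, col_dir = col_dir,
                 normal = normal, spacing = spacing, thickness = thickness,
                 index = as.integer(index)),
            class = "slice_geometry")
}

#' Short-axis stack volume
#'
#' An ordered list of parallel slices with their pixel data, for one
#' subject at one cardiac phase (end-diastole).
#'
#' @param slices list of `list(geometry = slice_geometry, image = matrix)`.
#' @param subject_id subject identifier.
#' @param frame_label cardiac phase label.
#' @return an object of class `stack_volume`.
#' @export
stack_volume <- function(slices, subject_id = "subject",
                         frame_label = "end_diastole") {
  if (length(slices) < 1) stop("a stack needs at least one slice")
  dims <- lapply(slices, function(s) dim(s$image))
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
    stop("all slices must share the same image size")
  n0 <- slices[[1]]$geometry$normal
  for (s in slices) {
    if (vnorm(s$geometry$normal - n0) > 1e-3)
      stop("slices are not parallel: stack is not a valid SA acquisition")
  }
  structure(list(slices = slices, subject_id = subject_id,
                 frame_label = frame_label),
            class = "stack_volume")
}

#' Long-axis view
#'
#' @param geometry a `slice_geometry`.
#' @param image 2-D intensity matrix.
#' @param view_label one of `"2ch"`, `"3ch"`, `"4ch"`.
#' @return an object of class `la_view`.
#' @export
la_view <- function(geometry, image, view_label) {
  view_label <- match.arg(view_label, c("2ch", "3ch", "4ch"))
  structure(list(geometry = geometry, image = image, view_label = view_label),
            class = "la_view")
}

#' LV long axis from apex and mitral-valve landmarks
#'
#' Direction points apex -> mitral valve; the apex projects to axis
#' coordinate 0 and the mitral valve to `L = |mv - apex|`.
#'
#' @param apex,mv world landmark positions, mm.
#' @return an object of class `lv_axis` with fields `apex_point`,
#'   `direction`, `length`.
#' @export
lv_axis <- function(apex, mv) {
  apex <- as.numeric(apex); mv <- as.numeric(mv)
  L <- vnorm(mv - apex)
  if (L == 0) stop("apex and mitral valve coincide: no axis")
  structure(list(apex_point = apex, direction = (mv - apex) / L, length = L),
            class = "lv_axis")
}

#' Fuse per-view landmark candidates with a sanity check
#'
#' Each long-axis view proposes a (mitral valve, apex) pair. Views are
#' retained greedily so that within the retained set every pairwise
#' same-landmark distance is at most `max_pairwise_dist`; the fused
#' landmark is the component-wise median over retained views (the midpoint
#' when two views survive). The sanity check fails when no pair of views
#' agrees — landmarks from the views are at unrealistic distances from
#' each other — or, trivially, never for a single-view input.
#'
#' @param per_view named list `view -> list(mv =, apex =)` of world-mm
#'   candidates (1 to 3 views).
#' @param max_pairwise_dist agreement threshold in mm.
#' @return an object of class `landmark_set` with fields `mv`, `apex`,
#'   `per_view`, `fused_from`, `sanity_ok`.
#' @export
fuse_landmarks <- function(per_view, max_pairwise_dist = 20) {
  if (length(per_view) < 1) stop("no landmark candidates supplied")
  views <- names(per_view)
  if (is.null(views)) views <- paste0("view", seq_along(per_view))

  ok_subset <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    for (a in utils::combn(idx, 2, simplify = FALSE)) {
      d_mv <- vnorm(per_view[[a[1]]]$mv - per_view[[a[2]]]$mv)
      d_ap <- vnorm(per_view[[a[1]]]$apex - per_view[[a[2]]]$apex)
      if (d_mv > max_pairwise_dist || d_ap > max_pairwise_dist) return(FALSE)
    }
    TRUE
  }

  n <- length(per_view)
  retained <- integer(0)
  # largest agreeing subset; ties broken towards the tightest subset
  for (k in seq(n, 1)) {
    cands <- utils::combn(seq_len(n), k, simplify = FALSE)
    good <- Filter(ok_subset, cands)
    if (length(good)) {
      spread <- vapply(good, function(idx) {
        if (length(idx) < 2) return(0)
        max(vapply(utils::combn(idx, 2, simplify = FALSE), function(a)
          max(vnorm(per_view[[a[1]]]$mv - per_view[[a[2]]]$mv),
              vnorm(per_view[[a[1]]]$apex - per_view[[a[2]]]$apex)), 0))
      }, 0)
      retained <- good[[which.min(spread)]]
      break
    }
  }

  sanity_ok <- (n == 1 && length(retained) == 1) || length(retained) >= 2
  if (!sanity_ok) {
    return(structure(list(mv = NULL, apex = NULL, per_view = per_view,
                          fused_from = character(0), sanity_ok = FALSE),
                     class = "landmark_set"))
  }
  comp_median <- function(field) {
    m <- do.call(rbind, lapply(retained, function(i) per_view[[i]][[field]]))
    apply(m, 2, stats::median)
  }
  structure(list(mv = comp_median("mv"), apex = comp_median("apex"),
                 per_view = per_view, fused_from = views[retained],
                 sanity_ok = TRUE),
            class = "landmark_set")
}

#' Signed axis coordinate of a world point
#'
#' @param point world 3-vector, mm.
#' @param axis an `lv_axis`.
#' @return `(point - apex) . direction`: 0 at the apex, `L` at the mitral
#'   valve. Components orthogonal to the axis are ignored.
#' @export
project_onto_axis <- function(point, axis) {
  sum((as.numeric(point) - axis$apex_point) * axis$direction)
}

#' Intersect a line with a slice plane
#'
#' @param point,direction a world-space line (point on line, direction).
#' @param slice a `slice_geometry`.
#' @return in-plane coordinates `(row_mm, col_mm)` of the intersection
#'   relative to the slice origin, or `NULL` when the line is parallel to
#'   the plane (within 1e-6): the slice cannot be assessed against that
#'   reference.
#' @export
slice_plane_intersection <- function(point, direction, slice) {
  direction <- as.numeric(direction); point <- as.numeric(point)
  denom <- sum(direction * slice$normal)
  if (abs(denom) < 1e-6 * vnorm(direction)) return(NULL)
  t <- sum((slice$origin - point) * slice$normal) / denom
  p <- point + t * direction
  c(sum((p - slice$origin) * slice$row_dir),
    sum((p - slice$origin) * slice$col_dir))
}

# Map in-plane mm coordinates back to a world point.
plane_to_world <- function(uv, slice) {
  slice$origin + uv[1] * slice$row_dir + uv[2] * slice$col_dir
}

# World position of 0-based pixel (i, j).
pixel_to_world <- function(i, j, slice) {
  slice$origin + i * slice$spacing[1] * slice$row_dir +
    j * slice$spacing[2] * slice$col_dir
}

# World position of the geometric centre of a slice's image.
slice_center <- function(sl) {
  d <- dim(sl$image)
  pixel_to_world((d[1] - 1) / 2, (d[2] - 1) / 2, sl$geometry)
}

#' Apply a rigid transform to geometry objects
#'
#' Utility for invariance checks: rotates/translates slice geometries,
#' stacks, views and landmark sets as one rigid scene motion (pixel data is
#' untouched — it travels with its slice).
#'
#' @param x a `slice_geometry`, `stack_volume`, `la_view` or
#'   `landmark_set`.
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector, mm.
#' @return the transformed object.
#' @export
rigid_transform <- function(x, R, t = c(0, 0, 0)) {
  R <- as.matrix(R); t <- as.numeric(t)
  tp <- function(p) as.numeric(R %*% p + t)
  td <- function(d) as.numeric(R %*% d)
  if (inherits(x, "slice_geometry")) {
    return(slice_geometry(tp(x$origin), td(x$row_dir), td(x$col_dir),
                          x$spacing, x$thickness, x$index))
  }
  if (inherits(x, "stack_volume")) {
    x$slices <- lapply(x$slices, function(s) {
      s$geometry <- rigid_transform(s$geometry, R, t); s
    })
    return(x)
  }
  if (inherits(x, "la_view")) {
    x$geometry <- rigid_transform(x$geometry, R, t)
    return(x)
  }
  if (inherits(x, "landmark_set")) {
    if (!is.null(x$mv)) x$mv <- tp(x$mv)
    if (!is.null(x$apex)) x$apex <- tp(x$apex)
    x$per_view <- lapply(x$per_view, function(v)
      list(mv = tp(v$mv), apex = tp(v$apex)))
    return(x)
  }
  stop("unsupported object for rigid_transform")
}
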