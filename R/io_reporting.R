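# NIfTI readers/writers, percentage arithmetic with the display rounding
# used in reports, per-subject JSON reports and the cohort-level summary
# with its exclusion accounting.

# 4x4 voxel(0-based)->world affine of a slice-stack geometry.
stack_affine <- function(geom, step_dir, step_mm) {
  A <- diag(4)
  A[1:3, 1] <- geom$row_dir * geom$spacing[1]
  A[1:3, 2] <- geom$col_dir * geom$spacing[2]
  A[1:3, 3] <- step_dir * step_mm
  A[1:3, 4] <- geom$origin
  A
}

write_nifti_volume <- function(arr, affine, path) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::qform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write a phantom subject as NIfTI files plus a truth sidecar
#'
#' The SA stack becomes one 3-D volume (slices along the third axis, the
#' through-plane step being thickness + gap); each LA view becomes a
#' single-slice volume. Ground truth goes to a JSON sidecar.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- phantom$stack
  g1 <- st$slices[[1]]$geometry
  m <- length(st$slices)
  step <- if (m > 1)
    vnorm(st$slices[[2]]$geometry$origin - g1$origin) else g1$thickness
  arr <- array(0, c(dim(st$slices[[1]]$image), m))
  for (k in seq_len(m)) arr[, , k] <- st$slices[[k]]$image
  paths <- c(sa = file.path(dir, "sa.nii"))
  write_nifti_volume(arr, stack_affine(g1, g1$normal, step), paths["sa"])
  for (v in phantom$la_views) {
    p <- file.path(dir, sprintf("la_%s.nii", v$view_label))
    write_nifti_volume(array(v$image, c(dim(v$image), 1)),
                       stack_affine(v$geometry, v$geometry$normal,
                                    v$geometry$thickness), p)
    paths[paste0("la_", v$view_label)] <- p
  }
  truth_path <- file.path(dir, "truth.json")
  tr <- phantom$truth
  tr$applied_shifts <- unname(split(tr$applied_shifts,
                                    seq_len(nrow(tr$applied_shifts))))
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  paths["truth"] <- truth_path
  paths
}

# slice geometries from a NIfTI affine (voxel-centre, 0-based convention)
affine_to_geometries <- function(A, dims, thickness) {
  sp <- c(vnorm(A[1:3, 1]), vnorm(A[1:3, 2]))
  step <- A[1:3, 3]
  lapply(seq_len(dims[3]), function(k)
    slice_geometry(origin = A[1:3, 4] + (k - 1) * step,
                   row_dir = A[1:3, 1] / sp[1], col_dir = A[1:3, 2] / sp[2],
                   spacing = sp, thickness = thickness, index = k))
}

#' Read one subject's images
#'
#' Reads the SA stack and up to three LA views from NIfTI files; geometry
#' comes from the sform/qform affine. A missing file marks the subject
#' incomplete instead of raising an error. 4-D cines are reduced to the
#' requested temporal frame (frame 1 = end-diastole by convention).
#'
#' @param paths named list/vector with entries `sa`, `la_2ch`, `la_3ch`,
#'   `la_4ch` (file paths).
#' @param subject_id identifier attached to the stack.
#' @param frame 1-based temporal frame for 4-D inputs.
#' @param thickness slice thickness, mm (NIfTI stores only the
#'   through-plane step, which includes the gap).
#' @return `list(complete, missing, stack, la_views)`; `stack`/`la_views`
#'   are `NULL` when incomplete.
#' @export
read_subject <- function(paths, subject_id = "subject", frame = 1L,
                         thickness = 8) {
  wanted <- c("sa", "la_2ch", "la_3ch", "la_4ch")
  paths <- as.list(paths)
  missing <- wanted[!vapply(wanted, function(w)
    !is.null(paths[[w]]) && file.exists(paths[[w]]), TRUE)]
  if (length(missing))
    return(list(complete = FALSE, missing = missing,
                stack = NULL, la_views = NULL))

  read_one <- function(path) {
    im <- RNifti::readNifti(path)
    A <- RNifti::xform(im, useQuaternionFirst = FALSE)
    arr <- as.array(im)
    if (length(dim(arr)) == 4) arr <- arr[, , , frame, drop = TRUE]
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
    list(A = A, arr = arr)
  }

  sa <- read_one(paths$sa)
  geoms <- affine_to_geometries(sa$A, dim(sa$arr), thickness)
  slices <- lapply(seq_len(dim(sa$arr)[3]), function(k)
    list(geometry = geoms[[k]], image = sa$arr[, , k]))
  stack <- stack_volume(slices, subject_id = subject_id)

  la_views <- list()
  for (lbl in c("2ch", "3ch", "4ch")) {
    one <- read_one(paths[[paste0("la_", lbl)]])
    g <- affine_to_geometries(one$A, dim(one$arr), thickness)[[1]]
    la_views[[lbl]] <- la_view(g, one$arr[, , 1], lbl)
  }
  list(complete = TRUE, missing = character(0),
       stack = stack, la_views = la_views)
}

#' Count-to-percentage arithmetic used in all reports
#'
#' @param count,denominator non-negative count and positive denominator.
#' @return `list(raw, value, label)`: the exact percentage, its display
#'   value rounded half-up to one decimal, and the printed string.
#' @export
percentage <- function(count, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (count < 0 || count > denominator)
    stop("count must lie in [0, denominator]")
  raw <- 100 * count / denominator
  value <- round_half_up(raw, 1)
  list(raw = raw, value = value, label = sprintf("%.1f%%", value))
}

#' Write a per-subject QC report as deterministic JSON
#'
#' @param report a `qc_report` from [qc_subject()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  strip <- function(x) x[!vapply(x, is.null, TRUE)]
  out <- list(
    subject_id = report$subject_id,
    coverage = strip(report$coverage[c("coverage", "basal_gap", "apical_gap",
                                       "basal_overhang", "apical_overhang",
                                       "sanity_ok")]),
    motion = strip(report$motion[c("average_mm", "apical_mm", "mid_mm",
                                   "basal_mm", "per_slice_mm", "sanity_ok",
                                   "reasons")]),
    contrast = strip(report$contrast[c("average_pct", "apical_pct", "mid_pct",
                                       "basal_pct", "per_slice_pct",
                                       "sanity_ok", "reasons")]),
    flags = as.list(report$flags),
    excluded = report$excluded)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Summarise QC reports over a cohort
#'
#' Exclusion accounting and headline statistics: per check, the number of
#' analysed versus sanity-excluded subjects (exclusion percentages over
#' the complete scans, as in the printed reports), threshold-flag counts
#' with percentages over the analysed subjects, and median/IQR of each
#' metric (overall and regional) over analysed subjects only.
#'
#' @param reports list of `qc_report`s (entries may be
#'   `list(complete = FALSE)` for incomplete scans).
#' @param thresholds a [qc_thresholds()].
#' @return a `cohort_summary` list; see Details in the README.
#' @export
summarize_cohort <- function(reports, thresholds = qc_thresholds()) {
  if (length(reports) < 1) stop("no reports to summarise")
  complete <- vapply(reports, function(r) isTRUE(r$complete), TRUE)
  reps <- reports[complete]
  n_total <- length(reports)
  n_complete <- length(reps)

  get_metric <- function(check, field) {
    vapply(reps, function(r) {
      res <- r[[check]]
      if (!is.null(res) && isTRUE(res$sanity_ok)) res[[field]] else NA_real_
    }, 0)
  }
  med_iqr <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(list(median = NA_real_, iqr = NA_real_))
    list(median = stats::median(v), iqr = qc_iqr(v))
  }
  check_block <- function(check, fields) {
    analysed <- vapply(reps, function(r) isTRUE(r[[check]]$sanity_ok), TRUE)
    n_analysed <- sum(analysed)
    n_excluded <- n_complete - n_analysed
    stats <- lapply(fields, function(f) med_iqr(get_metric(check, f)))
    names(stats) <- fields
    list(n_analysed = n_analysed, n_excluded = n_excluded,
         exclusion_pct = percentage(n_excluded, n_complete)$value,
         stats = stats)
  }

  cov_v <- get_metric("coverage", "coverage")
  mot_v <- get_metric("motion", "average_mm")
  con_v <- get_metric("contrast", "average_pct")

  flag_block <- function(values, cmp, cut, n_analysed) {
    cnt <- sum(cmp(values[!is.na(values)], cut))
    list(count = cnt,
         pct = if (n_analysed > 0) percentage(cnt, n_analysed)$value else NA_real_)
  }

  cov <- check_block("coverage", "coverage")
  mot <- check_block("motion", c("average_mm", "apical_mm", "mid_mm", "basal_mm"))
  con <- check_block("contrast", c("average_pct", "apical_pct", "mid_pct",
                                   "basal_pct"))

  cov$flags <- list(
    below_100 = flag_block(cov_v, `<`, thresholds$coverage_suboptimal, cov$n_analysed),
    below_90 = flag_block(cov_v, `<`, thresholds$coverage_severe, cov$n_analysed),
    full_or_more = flag_block(cov_v, `>=`, thresholds$coverage_suboptimal, cov$n_analysed))
  mot$flags <- list(
    motion_corrupt = flag_block(mot_v, `>=`, thresholds$motion_corrupt, mot$n_analysed))
  con$flags <- list(
    below_30 = flag_block(con_v, `<`, thresholds$contrast_low, con$n_analysed),
    below_20 = flag_block(con_v, `<`, thresholds$contrast_very_low, con$n_analysed))

  structure(list(n_total = n_total, n_complete = n_complete,
                 coverage = cov, motion = mot, contrast = con),
            class = "cohort_summary")
}
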