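# Shared fixtures, all generated in code.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Per-slice shifts on the acquisition pixel grid (integer multiples of the
# in-plane spacing), magnitudes capped at max_mag mm. On-grid shifts keep
# the discretised cavity masks exact translates of each other, so mask
# centroids are analytically exact and recovery can be tested to 1e-6.
grid_shifts <- function(n_slices, spacing = 1.8, max_mag = 6) {
  cand <- expand.grid(i = -3:3, j = -3:3)
  cand <- cand[sqrt(cand$i^2 + cand$j^2) * spacing <= max_mag, ]
  idx <- sample.int(nrow(cand), n_slices, replace = TRUE)
  cbind(cand$i[idx], cand$j[idx]) * spacing
}

# random rigid rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# truth-mask QC run on a phantom, returning the three results
truth_qc <- function(ph) {
  centers <- compute_reference_centers(ph$la_views, ph$la_segs, ph$stack)
  san <- sanity_check_seg(ph$stack, ph$sa_segs, ph$landmarks)
  list(coverage = compute_coverage(ph$stack, ph$landmarks),
       motion = compute_misalignment(ph$stack, ph$sa_segs, centers,
                                     ph$landmarks, san),
       contrast = compute_contrast(ph$stack, ph$sa_segs, ph$landmarks, san),
       sanity = san)
}
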