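# Small numeric helpers shared across modules.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise the zero vector")
  v / n
}

#' Round half away from zero
#'
#' Display rounding used in all reports: ties go up (`0.05 -> 0.1`),
#' matching the convention of the printed percentages this package
#' reproduces. Base [round()] rounds half to even and is not used for
#' display.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Quantile convention used everywhere (quintile cuts, medians, IQRs):
# linear interpolation between order statistics (type 7, the R default).
qc_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

qc_iqr <- function(x) {
  q <- qc_quantile(x, c(0.25, 0.75))
  q[2] - q[1]
}

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring
# the caller's RNG state afterwards so generators are deterministic
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
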