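# internal helpers shared across modules

vec_norm <- function(v) sqrt(sum(v^2))

# unit vector; zero vectors return c(0, 0)
unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) return(c(0, 0))
  v / n
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

# 2x2 rotation matrix, angle in radians
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# derive a reproducible child seed (kept well below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

# column-wise Pearson correlations between two matrices with matched columns
col_cor <- function(a, b) {
  vapply(seq_len(ncol(a)), function(j) stats::cor(a[, j], b[, j]), numeric(1))
}
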