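#' Causal exponential smoothing kernel
#'
#' Unit-sum decaying-exponential kernel truncated at `tau` seconds with
#' decay constant `tau / 3`, sampled at `dt`. This is the smoother applied
#' to binned spike counts before decoding.
#'
#' @param tau Kernel support, seconds.
#' @param dt Bin width, seconds.
#' @return Numeric vector of kernel weights (most recent bin first).
#' @export
smoothing_kernel <- function(tau, dt) {
  stopifnot_scalar(tau, "tau", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n <- max(1L, floor(tau / dt))
  w <- exp(-(seq_len(n) - 1) * dt / (tau / 3))
  w / sum(w)
}

#' Smooth binned counts into firing-rate estimates
#'
#' Causal convolution of each channel's count series with the unit-sum
#' truncated exponential kernel of [smoothing_kernel()], expressed in Hz
#' (counts per bin divided by `dt`). A constant input of `r` counts/bin
#' converges to `r / dt` Hz after the kernel transient.
#'
#' @param counts Non-negative count matrix, time x channels (a vector is
#'   treated as a single channel).
#' @param dt Bin width, seconds.
#' @param tau Kernel support, seconds.
#' @return Rate matrix (Hz), same shape as `counts`.
#' @examples
#' r <- smooth_rates(matrix(1, 100, 1), dt = 0.02, tau = 0.44)
#' tail(r, 1)  # ~50 Hz
#' @export
smooth_rates <- function(counts, dt, tau) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  k <- smoothing_kernel(tau, dt)
  n <- nrow(counts)
  out <- matrix(0, n, ncol(counts))
  # convolve causally: out[t] = sum_j k[j] * counts[t - j + 1]
  for (j in seq_len(min(length(k), n))) {
    idx <- seq_len(n - j + 1L)
    out[idx + j - 1L, ] <- out[idx + j - 1L, ] + k[j] * counts[idx, , drop = FALSE]
  }
  dimnames(out) <- dimnames(counts)
  out / dt
}
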