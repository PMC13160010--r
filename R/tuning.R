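#' Draw a population tuning model
#'
#' Samples the per-channel encoding parameters used by the spike generator:
#' baseline rates, cosine-tuning preferred directions (uniform on the
#' circle), tuning depths, and a rank-2 error-latent loading built from two
#' random unit patterns scaled by `config$error_gain`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `bci_tuning` with elements `baseline` (Hz),
#'   `preferred_direction` (n x 2, unit rows), `depth` (Hz per unit speed)
#'   and `error_loading` (n x 2, Hz at full latent).
#' @examples
#' tun <- generate_tuning(sim_config(n_channels = 16), seed = 1)
#' rowSums(tun$preferred_direction^2)
#' @export
generate_tuning <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_channels
  baseline <- pmax(0.5, rnorm(n, config$baseline_rate, config$baseline_rate / 4))
  theta <- runif(n, 0, 2 * pi)
  pd <- cbind(cos(theta), sin(theta))
  depth <- pmax(0, rnorm(n, config$tuning_depth, config$tuning_depth / 3))
  # rank-2 loading: two random patterns, the second weaker
  u1 <- rnorm(n); u1 <- u1 / sqrt(mean(u1^2))
  u2 <- rnorm(n); u2 <- u2 - u1 * sum(u2 * u1) / sum(u1 * u1)
  u2 <- u2 / sqrt(mean(u2^2))
  loading <- config$error_gain * cbind(u1, 0.4 * u2)
  structure(
    list(baseline = baseline, preferred_direction = pd, depth = depth,
         error_loading = loading, n_channels = n),
    class = "bci_tuning"
  )
}

# rotate the preferred directions by `angle` radians (recording drift)
rotate_tuning <- function(tuning, angle) {
  tuning$preferred_direction <- tuning$preferred_direction %*% t(rot2(angle))
  tuning
}

# per-channel Poisson rates (Hz) for one bin
tuning_rates <- function(tuning, commanded_velocity, error_latent) {
  e <- if (length(error_latent) == 1L) c(error_latent, 0) else error_latent
  lam <- tuning$baseline +
    tuning$depth * as.vector(tuning$preferred_direction %*% commanded_velocity) +
    as.vector(tuning$error_loading %*% e)
  pmax(0, lam)
}

#' Emit one bin of Poisson threshold-crossing counts
#'
#' Draws independent Poisson counts per channel with rate
#' `max(0, baseline + depth * (pd . v) + error_loading %*% e)` for bin
#' width `dt`. The first component of `error_latent` is the error latent in
#' \[0, 1\]; an optional second component drives the second loading pattern.
#'
#' @param tuning A [generate_tuning()] model.
#' @param commanded_velocity Length-2 commanded velocity (screen units/s).
#' @param error_latent Scalar in \[0, 1\] (or length-2 vector) error latent.
#' @param dt Bin width, seconds.
#' @param seed Optional seed for a reproducible draw.
#' @return Integer vector of counts, one per channel.
#' @examples
#' tun <- generate_tuning(sim_config(n_channels = 8), seed = 1)
#' emit_counts(tun, c(0.5, 0), 0, dt = 0.02, seed = 1)
#' @export
emit_counts <- function(tuning, commanded_velocity, error_latent, dt,
                        seed = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a positive scalar.")
  }
  e1 <- error_latent[1]
  if (is.na(e1) || e1 < 0 || e1 > 1) {
    abort("`error_latent[1]` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  lam <- tuning_rates(tuning, commanded_velocity, error_latent)
  rpois(length(lam), lam * dt)
}
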