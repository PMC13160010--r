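#' Simulation configuration for a synthetic closed-loop BCI session
#'
#' Bundles every tunable parameter of the synthetic center-out BCI
#' generator: the recorded population (channel count, baseline and tuning
#' rates, the error-related latent), the task geometry (workspace, target
#' ring, success radius), the 50 Hz binning and exponential rate smoothing,
#' and the perturbation process that produces epochs of erroneous control.
#'
#' The generator emulates threshold-crossing counts from a motor-cortex
#' array: each channel fires as an inhomogeneous Poisson process whose rate
#' is a baseline plus a cosine-tuned velocity term plus a low-rank
#' error-latent term. Control errors are produced by a decoder-side
#' disturbance: at Poisson-distributed event times a velocity offset in a
#' per-session bias direction is added to the decoded cursor velocity for
#' `perturb_duration` seconds, while an error-related latent in the
#' population rises `error_lead` seconds *before* the disturbance manifests
#' kinematically. While the latent is high the user's command is degraded in
#' a direction-neutral way (gain drop plus isotropic noise), emulating the
#' loss of intent information during faulty control.
#'
#' @param n_channels Number of recorded channels (default 176).
#' @param bin_dt Bin width in seconds (default 0.02, i.e. 50 Hz).
#' @param smoothing_tau Support of the causal decaying-exponential rate
#'   smoother, seconds (default 0.44). The kernel is truncated at
#'   `smoothing_tau` with decay constant `smoothing_tau / 3` and normalized
#'   to unit sum.
#' @param n_targets Number of radial targets (default 8).
#' @param target_radius Success radius around a target, screen units.
#' @param target_ring Distance of reach targets from the center, screen
#'   units (workspace is the \[-1, 1\]^2 box).
#' @param trial_timeout Per-phase timeout, seconds.
#' @param baseline_rate Mean baseline firing rate, Hz per channel.
#' @param tuning_depth Scale of directional tuning, Hz per (screen unit/s).
#' @param error_gain Per-channel scale of the error-latent loading, Hz.
#'   Setting 0 removes all error information from the population.
#' @param error_lead Lead of the neural error latent over the kinematic
#'   error, seconds (default 0.2).
#' @param bias_direction Session bias direction of the disturbance, degrees;
#'   `NULL` draws one uniformly per session.
#' @param bias_jitter Angular jitter (sd, degrees) of individual disturbance
#'   events around `bias_direction`.
#' @param perturb_rate Rate of disturbance events, events/s.
#' @param perturb_duration Duration of one disturbance event, seconds.
#' @param perturb_speed Speed of the disturbance velocity, screen units/s.
#' @param nominal_speed Commanded cursor speed, screen units/s.
#' @param command_noise Isotropic sd of the user command, screen units/s.
#' @param command_degrade Fractional loss of command gain at full error
#'   latent (direction-neutral).
#' @param command_noise_boost Multiplicative increase of command noise at
#'   full error latent.
#' @param slow_radius Distance at which the commanded speed starts scaling
#'   down linearly towards the target (proportional-control zone).
#' @param latent_baseline Mean of the sub-threshold baseline fluctuation of
#'   the error latent during correct control (error-monitoring activity is
#'   never exactly silent); present only while the perturbation process is
#'   active.
#' @param latent_baseline_sd Sd of that baseline fluctuation.
#' @param latent_decay Post-event decay constant of the error latent, s.
#' @param set_drift Sd (degrees) of the per-set random rotation drift of
#'   preferred directions, emulating across-set recording instability.
#' @param seed Default seed used when a generator function is called without
#'   one.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_channels = 32, perturb_rate = 0)
#' cfg$bin_dt
#' @export
sim_config <- function(n_channels = 176,
                       bin_dt = 0.02,
                       smoothing_tau = 0.44,
                       n_targets = 8,
                       target_radius = 0.12,
                       target_ring = 0.8,
                       trial_timeout = 8,
                       baseline_rate = 10,
                       tuning_depth = 15,
                       error_gain = 40,
                       error_lead = 0.2,
                       bias_direction = NULL,
                       bias_jitter = 30,
                       perturb_rate = 0.6,
                       perturb_duration = 0.9,
                       perturb_speed = 1.2,
                       nominal_speed = 0.8,
                       command_noise = 0.1,
                       command_degrade = 0.8,
                       command_noise_boost = 0,
                       slow_radius = 0.15,
                       latent_baseline = 0.15,
                       latent_baseline_sd = 0.12,
                       latent_decay = 0.1,
                       set_drift = 3,
                       seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels), bin_dt = bin_dt,
    smoothing_tau = smoothing_tau, n_targets = as.integer(n_targets),
    target_radius = target_radius, target_ring = target_ring,
    trial_timeout = trial_timeout, baseline_rate = baseline_rate,
    tuning_depth = tuning_depth, error_gain = error_gain,
    error_lead = error_lead, bias_direction = bias_direction,
    bias_jitter = bias_jitter, perturb_rate = perturb_rate,
    perturb_duration = perturb_duration, perturb_speed = perturb_speed,
    nominal_speed = nominal_speed, command_noise = command_noise,
    command_degrade = command_degrade,
    command_noise_boost = command_noise_boost,
    slow_radius = slow_radius, latent_baseline = latent_baseline,
    latent_baseline_sd = latent_baseline_sd, latent_decay = latent_decay,
    set_drift = set_drift, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar(cfg$bin_dt, "bin_dt", positive = TRUE)
  stopifnot_scalar(cfg$smoothing_tau, "smoothing_tau", positive = TRUE)
  if (cfg$n_channels < 2L) abort("`n_channels` must be >= 2.")
  stopifnot_scalar(cfg$error_lead, "error_lead", nonneg = TRUE)
  for (nm in c("baseline_rate", "tuning_depth", "error_gain", "perturb_rate",
               "perturb_duration", "perturb_speed", "nominal_speed",
               "command_noise", "set_drift",
               "latent_baseline", "latent_baseline_sd")) {
    stopifnot_scalar(cfg[[nm]], nm, nonneg = TRUE)
  }
  stopifnot_scalar(cfg$trial_timeout, "trial_timeout", positive = TRUE)
  stopifnot_scalar(cfg$target_radius, "target_radius", positive = TRUE)
  if (cfg$target_ring <= 0 || cfg$target_ring > sqrt(2)) {
    abort("`target_ring` must lie inside the [-1, 1]^2 workspace.")
  }
  if (cfg$n_targets < 1L) abort("`n_targets` must be >= 1.")
  if (!is.null(cfg$bias_direction)) {
    stopifnot_scalar(cfg$bias_direction, "bias_direction")
  }
  if (cfg$command_degrade < 0 || cfg$command_degrade > 1) {
    abort("`command_degrade` must be in [0, 1].")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d channels @ %g Hz bins, smoothing %g ms\n",
              x$n_channels, 1 / x$bin_dt, 1000 * x$smoothing_tau))
  cat(sprintf("  %d targets on ring %.2f, success radius %.2f, timeout %g s\n",
              x$n_targets, x$target_ring, x$target_radius, x$trial_timeout))
  cat(sprintf("  baseline %g Hz, depth %g Hz/(u/s), error gain %g Hz, lead %g ms\n",
              x$baseline_rate, x$tuning_depth, x$error_gain,
              1000 * x$error_lead))
  cat(sprintf("  perturbations: %g /s x %g s @ speed %g\n",
              x$perturb_rate, x$perturb_duration, x$perturb_speed))
  invisible(x)
}
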