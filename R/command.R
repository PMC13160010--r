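# User-command and perturbation process.
#
# Disturbance events arrive as a renewal process (Exp(perturb_rate) gaps
# after each event); during an event a velocity offset in the session bias
# direction is added to the *decoded* cursor velocity. The error latent
# turns on `error_lead` s before the event manifests and decays with
# `latent_decay` after it ends; while high, the user's command loses gain
# and gains isotropic noise (direction-neutral degradation). All draws come
# from the caller's RNG stream.

new_perturb_state <- function(config, bias_direction_rad) {
  rate <- config$perturb_rate
  start <- if (rate > 0) rexp(1, rate) else Inf
  list(
    t = 0,
    ev_start = start,
    ev_end = start + config$perturb_duration,
    ev_end_prev = -Inf,
    a_at_end = 0,
    e_at_end = 0,
    ev_dir = c(1, 0),
    ev_dir_set = FALSE,
    ev_amp = 1, # per-event strength of the latent expression
    u = 0.72,   # in-event latent amplitude (slow AR(1))
    w = 0,      # secondary-pattern amplitude AR(1)
    eta = 0,    # sub-threshold baseline latent AR(1)
    eta2 = 0,   # baseline fluctuation along the secondary pattern
    bias_dir = bias_direction_rad
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Error latent at time t for the current event. The *state* latent e1
# (reported per bin) ramps deterministically 0.55 -> 1 across the lead
# window -- it exceeds 0.5 as soon as the lead starts -- fluctuates high
# (AR(1) around 0.72) during the event, decays exponentially after it, and
# sits at a sub-threshold baseline fluctuation between events.
#
# Its population *expression* is split over the two loading patterns: the
# anticipation pattern (a2, second loading column) carries the latent
# during the lead window and persists at half strength through the event;
# the execution pattern (a1, first column) expresses it only once the
# error manifests. This is what makes pre-error activity detectable yet
# distinguishable from error activity, so that training on pre-error
# windows genuinely buys earlier detection.
latent_value <- function(state, config) {
  t <- state$t
  lead <- config$error_lead
  phase <- "baseline"
  frac <- 0; dec <- 0
  if (t >= state$ev_start - lead && t < state$ev_start && lead > 0) {
    phase <- "lead"
    frac <- (t - (state$ev_start - lead)) / lead
  } else if (t >= state$ev_start && t <= state$ev_end) {
    phase <- "event"
  } else if (is.finite(state$ev_end_prev) && t > state$ev_end_prev) {
    phase <- "decay"
    dec <- exp(-(t - state$ev_end_prev) / max(config$latent_decay, 1e-9))
  }
  e_task <- switch(phase,
                   lead = 0.55 + 0.45 * frac,
                   event = min(1, state$u),
                   decay = state$e_at_end * dec,
                   0)
  e1 <- min(1, max(state$eta, e_task))
  a1 <- switch(phase,
               lead = state$eta,
               event = state$u * state$ev_amp,
               decay = state$a_at_end * dec,
               state$eta)
  a2 <- switch(phase,
               lead = e_task * (1.0 + 0.3 * state$w),
               event = (0.1 + 0.08 * state$w) * state$u * state$ev_amp,
               decay = 0.1 * state$a_at_end * dec,
               state$eta2)
  list(e1 = e1, a1 = a1, a2 = a2)
}

advance_perturbation <- function(state, config, dt) {
  state$t <- state$t + dt
  t <- state$t
  # entering an event: freeze its direction and strength
  if (t >= state$ev_start && t <= state$ev_end && !state$ev_dir_set) {
    ang <- state$bias_dir + deg2rad(rnorm(1, 0, config$bias_jitter))
    state$ev_dir <- c(cos(ang), sin(ang))
    state$ev_amp <- runif(1, 0.55, 1.35)
    state$ev_dir_set <- TRUE
  }
  # leaving an event: schedule the next one in full
  if (t > state$ev_end) {
    state$ev_end_prev <- state$ev_end
    state$e_at_end <- min(1, state$u)
    state$a_at_end <- state$u * state$ev_amp
    gap <- if (config$perturb_rate > 0) rexp(1, config$perturb_rate) else Inf
    state$ev_start <- state$ev_end + gap
    state$ev_end <- state$ev_start + config$perturb_duration
    state$ev_dir_set <- FALSE
  }
  # amplitude fluctuations (clipped AR(1) processes); the in-event
  # amplitude drifts slowly (~0.5 s) so its variance survives the rate
  # smoothing
  state$u <- min(1.3, max(0.35, 0.72 + 0.96 * (state$u - 0.72) + rnorm(1, 0, 0.084)))
  state$w <- min(1, max(-1, 0.85 * state$w + rnorm(1, 0, 0.16)))
  if (config$perturb_rate > 0) {
    m <- config$latent_baseline
    s <- config$latent_baseline_sd
    state$eta <- min(1, max(0, m + 0.875 * (state$eta - m) +
                              rnorm(1, 0, s * sqrt(1 - 0.875^2))))
    state$eta2 <- min(1, max(-1, 0.875 * state$eta2 + rnorm(1, 0, 0.145)))
  }
  state
}

#' One step of the simulated user command
#'
#' Advances the perturbation process by one bin and returns the user's
#' commanded velocity, the error latent, and the decoder-side disturbance
#' velocity for this bin. The command is the intent direction scaled by
#' `speed` plus isotropic noise; while the error latent is high the command
#' gain drops by `config$command_degrade * e` and the noise is inflated,
#' both direction-neutral. The latent envelope reaches 1 `config$error_lead`
#' seconds before the disturbance starts to act on the cursor.
#'
#' @param intent_direction Unit vector towards the target.
#' @param bias_state Perturbation state from a previous call, or `NULL` to
#'   start a fresh process (bias direction then taken from `config`, or
#'   drawn uniformly).
#' @param config A [sim_config()].
#' @param speed Desired command speed for this bin (defaults to
#'   `config$nominal_speed`).
#' @return List with `command` (length-2 velocity), `error_latent` (the
#'   latent state, scalar in \[0, 1\]), `expression` (length-2 amplitudes of
#'   the two loading patterns expressing the latent in the population),
#'   `perturb_on` (logical), `perturb_velocity` (length-2 disturbance
#'   velocity to add to the decoded cursor velocity), and `state` (to pass
#'   back in).
#' @examples
#' cfg <- sim_config(n_channels = 8, perturb_rate = 0)
#' set.seed(1)
#' step <- simulate_user_command(c(1, 0), NULL, cfg)
#' step$error_latent
#' @export
simulate_user_command <- function(intent_direction, bias_state, config,
                                  speed = config$nominal_speed) {
  if (abs(vec_norm(intent_direction) - 1) > 1e-6 &&
      vec_norm(intent_direction) > 0) {
    intent_direction <- unit_vec(intent_direction)
  }
  if (is.null(bias_state)) {
    bias <- if (is.null(config$bias_direction)) runif(1, 0, 2 * pi) else
      deg2rad(config$bias_direction)
    bias_state <- new_perturb_state(config, bias)
  }
  state <- advance_perturbation(bias_state, config, config$bin_dt)
  lat <- latent_value(state, config)
  e1 <- lat$e1
  noise_sd <- config$command_noise * (1 + config$command_noise_boost * e1)
  gain <- 1 - config$command_degrade * e1
  command <- intent_direction * speed * gain + rnorm(2, 0, noise_sd)
  on <- state$t >= state$ev_start && state$t <= state$ev_end
  list(
    command = command,
    error_latent = e1,
    expression = c(lat$a1, lat$a2),
    perturb_on = on,
    perturb_velocity = if (on) config$perturb_speed * state$ev_dir else c(0, 0),
    state = state
  )
}
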