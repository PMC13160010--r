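#' Error-modulation policy
#'
#' @param mode `"off"` (no modulation) or `"damp"` (velocity damping).
#' @param damp_gain Speed multiplier applied while an error is flagged
#'   (default 0.30: the cursor speed is reduced to 30% of its computed
#'   value).
#' @param tau Error-probability threshold (default 0.85), applied
#'   inclusively.
#' @return An object of class `modulation_policy`.
#' @export
modulation_policy <- function(mode = c("off", "damp"), damp_gain = 0.30,
                              tau = 0.85) {
  mode <- match.arg(mode)
  if (damp_gain < 0 || damp_gain > 1) abort("`damp_gain` must be in [0, 1].")
  if (tau <= 0 || tau > 1) abort("`tau` must be in (0, 1].")
  structure(list(mode = mode, damp_gain = damp_gain, tau = tau),
            class = "modulation_policy")
}

#' Modulate a decoded velocity by the error probability
#'
#' If the policy is damping and the error probability reaches the
#' threshold (`probability >= tau`, inclusive), the velocity is scaled by
#' `damp_gain`; direction is always preserved. Otherwise the velocity is
#' returned unchanged.
#'
#' @param velocity Length-2 decoded velocity.
#' @param error_probability Scalar error probability in \[0, 1\].
#' @param policy A [modulation_policy()].
#' @return Length-2 velocity.
#' @examples
#' modulate_velocity(c(1, 2), 0.9, modulation_policy("damp"))
#' @export
modulate_velocity <- function(velocity, error_probability, policy) {
  if (!inherits(policy, "modulation_policy")) abort("Invalid policy.")
  if (policy$mode == "damp" && error_probability >= policy$tau) {
    return(policy$damp_gain * velocity)
  }
  velocity
}

#' Run an alternating modulation ON/OFF experiment
#'
#' Runs `n_sets` sets of the center-out task with one calibrated decoder
#' and one trained classifier. The first set is always without error
#' modulation, then conditions alternate (OFF, ON, OFF, ...), which
#' controls for slow recording drift. Each set draws its own reproducible
#' generator substream from `seed`, and tuning keeps drifting from set to
#' set (`config$set_drift`).
#'
#' @param config A [sim_config()].
#' @param decoder Calibrated decoder (see [calibrate_decoder()]).
#' @param classifier Trained [train_error_classifier()].
#' @param n_sets Number of sets (>= 2 for a paired comparison).
#' @param trials_per_set Full (reach + center) trials per set (default 40,
#'   i.e. 80 phase records).
#' @param seed Integer seed.
#' @param damp_gain,tau Policy parameters for the ON sets.
#' @param tuning Tuning model at the start of the experiment (defaults to a
#'   fresh draw; pass `calibrate_decoder()$tuning` to continue a session).
#' @param drift_bias Session-level mean drift increment (radians); pass
#'   `calibrate_decoder()$drift_bias` to continue the same instability
#'   trajectory, `NULL` draws a fresh one.
#' @param keep_sessions Keep the full per-set sessions (default TRUE); with
#'   `FALSE` only the per-set metric summary is returned.
#' @return An object of class `bci_experiment`: `summary` (one row per set
#'   with the performance metrics) and optionally `sets`.
#' @export
run_experiment <- function(config, decoder, classifier, n_sets,
                           trials_per_set = 40, seed = config$seed,
                           damp_gain = 0.30, tau = 0.85, tuning = NULL,
                           drift_bias = NULL, keep_sessions = TRUE) {
  if (n_sets < 2L) warn("Fewer than 2 sets: no paired ON/OFF comparison.")
  if (is.null(tuning)) tuning <- generate_tuning(config, seed)
  set.seed(child_seed(seed, 31L))
  if (is.null(drift_bias)) drift_bias <- rnorm(1, 0, deg2rad(config$set_drift))
  drift <- cumsum(rnorm(n_sets, drift_bias, deg2rad(config$set_drift) / 3))
  sets <- vector("list", n_sets)
  rows <- vector("list", n_sets)
  for (k in seq_len(n_sets)) {
    pol <- if (k %% 2L == 1L) modulation_policy("off") else
      modulation_policy("damp", damp_gain = damp_gain, tau = tau)
    s <- generate_session(config, 2L * trials_per_set,
                          seed = child_seed(seed, 100L + k),
                          decoder = decoder, classifier = classifier,
                          policy = pol, tuning = rotate_tuning(tuning, drift[k]))
    m <- session_metrics(s)
    m$set <- k
    m$policy <- pol$mode
    rows[[k]] <- m
    sets[[k]] <- if (keep_sessions) s else NULL
  }
  summary <- dplyr::relocate(dplyr::bind_rows(rows), "set", "policy")
  structure(list(summary = summary,
                 sets = if (keep_sessions) sets else NULL,
                 n_sets = n_sets, seed = seed),
            class = "bci_experiment")
}

#' @export
print.bci_experiment <- function(x, ...) {
  cat(sprintf("<bci_experiment> %d sets (policies: %s)\n", x$n_sets,
              paste(x$summary$policy, collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' @rdname glance.error_classifier
#' @export
glance.bci_experiment <- function(x, ...) {
  x$summary |>
    dplyr::group_by(.data$policy) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop") |>
    dplyr::select(-"set")
}

#' Run a hold (station-keeping) task
#'
#' Generalization task: the cursor starts on the target ring and must be
#' brought within `hold_radius` of the central hold point and kept there
#' continuously for `hold_duration` seconds before `timeout`. The error
#' classifier is reused unchanged from center-out training (no
#' task-specific calibration). Disturbances, latent and modulation work
#' exactly as in [generate_session()].
#'
#' @param config A [sim_config()].
#' @param decoder Calibrated decoder.
#' @param classifier Trained classifier (required for damping).
#' @param policy A [modulation_policy()].
#' @param hold_radius Hold zone radius, screen units (default 0.15).
#' @param hold_duration Required continuous time in the zone, seconds.
#' @param n_trials Number of hold trials.
#' @param seed Integer seed.
#' @param timeout Per-trial timeout, seconds.
#' @param tuning Optional tuning model.
#' @return Tibble with one row per trial: `success`, `completion_time`
#'   (s; `NA` when timed out), start position and policy.
#' @export
run_hold_task <- function(config, decoder, classifier = NULL,
                          policy = modulation_policy("off"),
                          hold_radius = 0.15, hold_duration = 1,
                          n_trials = 10, seed = config$seed, timeout = 12,
                          tuning = NULL) {
  validate_sim_config(config)
  if (hold_duration > timeout) {
    abort("`hold_duration` cannot exceed `timeout`.")
  }
  if (policy$mode == "damp" && is.null(classifier)) {
    abort("Damping policy requires a trained classifier.")
  }
  if (is.null(tuning)) tuning <- generate_tuning(config, seed)
  set.seed(child_seed(seed, 47L))
  dt <- config$bin_dt
  nch <- config$n_channels
  hold_bins <- ceiling(hold_duration / dt)
  max_bins <- ceiling(timeout / dt)
  bias_rad <- if (is.null(config$bias_direction)) runif(1, 0, 2 * pi) else
    deg2rad(config$bias_direction)
  pstate <- new_perturb_state(config, bias_rad)
  kern <- smoothing_kernel(config$smoothing_tau, dt)
  K <- length(kern)
  damp_on <- policy$mode == "damp" && !is.null(classifier)
  if (damp_on) {
    cw <- classifier$w; cb <- classifier$b; ctau <- policy$tau
    win_bins <- max(1L, round(0.08 / dt))
  }
  hold <- c(0, 0)
  out <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    ang <- 2 * pi * ((tr - 1L) %% config$n_targets) / config$n_targets
    cursor <- config$target_ring * c(cos(ang), sin(ang))
    start <- cursor
    ring <- matrix(0, K, nch); ring_pos <- 0L
    kst <- NULL; flag <- FALSE; wsum <- numeric(nch)
    in_zone <- 0L; done_bin <- NA_integer_
    for (b in seq_len(max_bins)) {
      intent <- hold - cursor
      dist <- sqrt(sum(intent^2))
      dir <- if (dist > 0) intent / dist else c(0, 0)
      sp <- config$nominal_speed * min(1, dist / max(config$slow_radius, 1e-9))
      uc <- simulate_user_command(dir, pstate, config, speed = sp)
      pstate <- uc$state
      lam <- tuning_rates(tuning, uc$command, uc$expression)
      cnt <- rpois(nch, lam * dt)
      ring_pos <- (ring_pos %% K) + 1L
      ring[ring_pos, ] <- cnt
      rate <- as.vector(crossprod(ring[((ring_pos - seq_len(K)) %% K) + 1L, ,
                                       drop = FALSE], kern)) / dt
      ks <- decode_step(decoder, rate, kst)
      kst <- ks$state
      vtot <- ks$velocity + uc$perturb_velocity
      if (damp_on) {
        if (flag) vtot <- policy$damp_gain * vtot
        wsum <- wsum + rate
        if (b %% win_bins == 0L) {
          flag <- plogis(sum(cw * (wsum / win_bins)) + cb) >= ctau
          wsum <- numeric(nch)
        }
      }
      cursor <- pmin(1, pmax(-1, cursor + vtot * dt))
      in_zone <- if (sqrt(sum((hold - cursor)^2)) <= hold_radius)
        in_zone + 1L else 0L
      if (in_zone >= hold_bins) { done_bin <- b; break }
    }
    out[[tr]] <- tibble(
      trial_id = tr, start_x = start[1], start_y = start[2],
      success = !is.na(done_bin),
      completion_time = if (is.na(done_bin)) NA_real_ else done_bin * dt,
      policy = policy$mode
    )
  }
  dplyr::bind_rows(out)
}
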