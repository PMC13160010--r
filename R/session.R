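#' Generate a synthetic closed-loop BCI session
#'
#' Runs the 50 Hz closed loop of the center-out task: on every bin the
#' user's intent (the vector from cursor to target) is turned into a noisy
#' commanded velocity, the population emits Poisson counts, counts are
#' smoothed into rates, the decoder (or a scripted auto-cursor) produces a
#' velocity, optional error modulation damps it, the decoder-side
#' disturbance is added, and the cursor is integrated and clamped to the
#' \[-1, 1\]^2 workspace. Trial records alternate *reach* phases (cursor
#' reset to the center, target on the ring) and *center* phases (return to
#' the center); a phase ends on target acquisition or timeout. The whole
#' session is reproducible from `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param n_trials Number of trial records (phases) to run.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param decoder A calibrated [calibrate_velocity_kalman()] decoder with an
#'   attached factor model, or `NULL` for auto-cursor (observation) mode.
#' @param classifier Optional trained [train_error_classifier()] model used
#'   for online error modulation.
#' @param policy A [modulation_policy()]; damping requires a classifier.
#' @param cursor_mode `"decoder"` or `"auto"`. In auto mode the cursor
#'   moves straight to the target at the nominal speed (used for
#'   observation calibration) and no disturbances are scheduled.
#' @param attenuation Orthogonal attenuation factor in \[0, 1\] applied to
#'   the decoded velocity (0 during closed-loop calibration, 1 otherwise).
#' @param tuning Optional [generate_tuning()] model (e.g. a drifted one);
#'   defaults to `generate_tuning(config, seed)`.
#' @return An object of class `bci_session`: `config`, `tuning`, `trials`
#'   (one row per phase record), `bins` (one row per 20 ms bin), `counts`
#'   (integer matrix, time x channels), `rates` (Hz matrix),
#'   `bias_direction` (degrees), plus the run settings.
#' @examples
#' cfg <- sim_config(n_channels = 12, perturb_rate = 0)
#' s <- generate_session(cfg, n_trials = 2, seed = 1, cursor_mode = "auto")
#' s$trials
#' @export
generate_session <- function(config, n_trials, seed = config$seed,
                             decoder = NULL, classifier = NULL,
                             policy = modulation_policy("off"),
                             cursor_mode = if (is.null(decoder)) "auto" else "decoder",
                             attenuation = 1, tuning = NULL) {
  validate_sim_config(config)
  cursor_mode <- match.arg(cursor_mode, c("decoder", "auto"))
  if (cursor_mode == "decoder" && is.null(decoder)) {
    abort("Decoder mode requires a calibrated decoder.")
  }
  if (policy$mode == "damp" && is.null(classifier) && cursor_mode == "decoder") {
    abort("Damping policy requires a trained classifier.")
  }
  if (n_trials < 1L) abort("`n_trials` must be >= 1.")
  if (is.null(tuning)) tuning <- generate_tuning(config, seed)

  set.seed(child_seed(seed, 11L))
  dt <- config$bin_dt
  nch <- config$n_channels
  max_phase_bins <- ceiling(config$trial_timeout / dt)
  cap <- n_trials * max_phase_bins

  bias_rad <- if (is.null(config$bias_direction)) runif(1, 0, 2 * pi) else
    deg2rad(config$bias_direction)
  pcfg <- config
  if (cursor_mode == "auto") pcfg$perturb_rate <- 0
  pstate <- new_perturb_state(pcfg, bias_rad)

  # smoothing ring buffer
  kern <- smoothing_kernel(config$smoothing_tau, dt)
  K <- length(kern)
  ring <- matrix(0, K, nch)
  ring_pos <- 0L
  # kernel aligned so that kern[1] weights the most recent bin
  kern_idx <- function(pos) ((pos - seq_len(K)) %% K) + 1L

  counts <- matrix(0L, cap, nch)
  rates <- matrix(0, cap, nch)
  b_trial <- integer(cap); b_bin <- integer(cap)
  b_cx <- numeric(cap); b_cy <- numeric(cap)
  b_tx <- numeric(cap); b_ty <- numeric(cap)
  b_cmdx <- numeric(cap); b_cmdy <- numeric(cap)
  b_decx <- numeric(cap); b_decy <- numeric(cap)
  b_vx <- numeric(cap); b_vy <- numeric(cap)
  b_lat <- numeric(cap); b_pert <- logical(cap); b_flag <- logical(cap)

  tr_phase <- character(n_trials); tr_tx <- numeric(n_trials)
  tr_ty <- numeric(n_trials); tr_ti <- integer(n_trials)
  tr_sx <- numeric(n_trials); tr_sy <- numeric(n_trials)
  tr_nb <- integer(n_trials); tr_ok <- logical(n_trials)

  # classifier fast path
  damp_on <- policy$mode == "damp" && !is.null(classifier)
  if (damp_on) {
    cw <- classifier$w; cb <- classifier$b; ctau <- policy$tau
    win_bins <- max(1L, round(0.08 / dt))
  }

  row <- 0L
  cursor <- c(0, 0)
  kst <- NULL
  for (tr in seq_len(n_trials)) {
    is_reach <- (tr %% 2L) == 1L
    if (is_reach) {
      cursor <- c(0, 0)
      ti <- sample.int(config$n_targets, 1L)
      ang <- 2 * pi * (ti - 1L) / config$n_targets
      target <- config$target_ring * c(cos(ang), sin(ang))
    } else {
      ti <- 0L
      target <- c(0, 0)
    }
    tr_phase[tr] <- if (is_reach) "reach" else "center"
    tr_tx[tr] <- target[1]; tr_ty[tr] <- target[2]; tr_ti[tr] <- ti
    tr_sx[tr] <- cursor[1]; tr_sy[tr] <- cursor[2]
    kst <- NULL                       # decoder state reset at trial start
    flag <- FALSE
    wsum <- numeric(nch)              # running window rate sum for the flag
    success <- FALSE
    nb <- 0L
    for (b in seq_len(max_phase_bins)) {
      intent <- target - cursor
      dist <- sqrt(sum(intent^2))
      dir <- if (dist > 0) intent / dist else c(0, 0)
      sp <- config$nominal_speed * min(1, dist / max(config$slow_radius, 1e-9))
      uc <- simulate_user_command(dir, pstate, pcfg, speed = sp)
      pstate <- uc$state
      lam <- tuning_rates(tuning, uc$command, uc$expression)
      cnt <- rpois(nch, lam * dt)
      ring_pos <- (ring_pos %% K) + 1L
      ring[ring_pos, ] <- cnt
      rate <- as.vector(crossprod(ring[kern_idx(ring_pos), , drop = FALSE], kern)) / dt

      flag_applied <- FALSE
      if (cursor_mode == "auto") {
        vdec <- dir * config$nominal_speed
        vapp <- vdec
      } else {
        ks <- decode_step(decoder, rate, kst)
        kst <- ks$state
        vdec <- ks$velocity
        vtot <- vdec + uc$perturb_velocity
        if (attenuation < 1 && dist > 0) {
          vtot <- orthogonal_attenuation(vtot, dir, attenuation)
        }
        if (damp_on) {
          # the flag computed from the last completed 80 ms window damps
          # every bin of the current window (causal update cadence)
          if (flag) {
            vtot <- policy$damp_gain * vtot
            flag_applied <- TRUE
          }
          wsum <- wsum + rate
          if (b %% win_bins == 0L) {
            p <- plogis(sum(cw * (wsum / win_bins)) + cb)
            flag <- p >= ctau
            wsum <- numeric(nch)
          }
        }
        vapp <- vtot
      }
      cursor <- pmin(1, pmax(-1, cursor + vapp * dt))
      row <- row + 1L; nb <- nb + 1L
      counts[row, ] <- cnt; rates[row, ] <- rate
      b_trial[row] <- tr; b_bin[row] <- b
      b_cx[row] <- cursor[1]; b_cy[row] <- cursor[2]
      b_tx[row] <- target[1]; b_ty[row] <- target[2]
      b_cmdx[row] <- uc$command[1]; b_cmdy[row] <- uc$command[2]
      b_decx[row] <- vdec[1]; b_decy[row] <- vdec[2]
      b_vx[row] <- vapp[1]; b_vy[row] <- vapp[2]
      b_lat[row] <- uc$error_latent
      b_pert[row] <- uc$perturb_on
      b_flag[row] <- flag_applied
      if (sqrt(sum((target - cursor)^2)) <= config$target_radius) {
        success <- TRUE
        break
      }
    }
    tr_nb[tr] <- nb; tr_ok[tr] <- success
  }

  keep <- seq_len(row)
  trials <- tibble(
    trial_id = seq_len(n_trials), phase = tr_phase,
    target_x = tr_tx, target_y = tr_ty, target_index = tr_ti,
    start_x = tr_sx, start_y = tr_sy,
    n_bins = tr_nb, duration = tr_nb * dt, success = tr_ok,
    modulation_on = policy$mode == "damp"
  )
  bins <- tibble(
    trial_id = b_trial[keep], bin = b_bin[keep],
    cursor_x = b_cx[keep], cursor_y = b_cy[keep],
    target_x = b_tx[keep], target_y = b_ty[keep],
    command_vx = b_cmdx[keep], command_vy = b_cmdy[keep],
    decoded_vx = b_decx[keep], decoded_vy = b_decy[keep],
    vx = b_vx[keep], vy = b_vy[keep],
    error_latent = b_lat[keep], perturb_on = b_pert[keep],
    flagged = b_flag[keep]
  )
  structure(
    list(config = config, tuning = tuning, trials = trials, bins = bins,
         counts = counts[keep, , drop = FALSE],
         rates = rates[keep, , drop = FALSE],
         bias_direction = rad2deg(bias_rad) %% 360,
         policy = policy, seed = seed, cursor_mode = cursor_mode,
         attenuation = attenuation),
    class = "bci_session"
  )
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf("<bci_session> %d phase records (%d bins, %d channels), %s cursor, policy %s\n",
              nrow(x$trials), nrow(x$bins), ncol(x$counts),
              x$cursor_mode, x$policy$mode))
  cat(sprintf("  success %d/%d phases, bias direction %.0f deg\n",
              sum(x$trials$success), nrow(x$trials), x$bias_direction))
  invisible(x)
}

#' Two-step decoder calibration
#'
#' Reproduces the standard calibration sequence: an *observation* set in
#' which the cursor moves itself to each target and the decoder is fit to
#' the recorded rates against the cursor velocity, followed by a
#' *closed-loop* set in which the participant drives the cursor through the
#' observation decoder with all velocity orthogonal to the target direction
#' attenuated, and the final decoder is refit on that data against the
#' intended (towards-target) velocity. Preferred directions drift by a
#' random rotation between sets (`config$set_drift`), which is what makes
#' the refit worthwhile.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_trials Trial records per calibration set (default 40).
#' @param n_factors Factor-analysis dimensionality (default 20).
#' @param attenuation Orthogonal attenuation during closed-loop calibration
#'   (default 0, movement confined to the target line).
#' @return List with `observation` and `final` decoders, the drifted
#'   `tuning` after calibration, the cumulative `drift` angles and the
#'   session-level `drift_bias` (radians), and the two calibration
#'   sessions.
#' @export
calibrate_decoder <- function(config, seed = config$seed, n_trials = 40,
                              n_factors = 20, attenuation = 0) {
  tuning0 <- generate_tuning(config, seed)
  set.seed(child_seed(seed, 23L))
  # within-session instability drifts in a consistent direction
  drift_bias <- rnorm(1, 0, deg2rad(config$set_drift))
  drift <- cumsum(rnorm(2, drift_bias, deg2rad(config$set_drift) / 3))
  s_obs <- generate_session(config, n_trials, seed = child_seed(seed, 1L),
                            cursor_mode = "auto", tuning = tuning0)
  v_obs <- cbind(s_obs$bins$vx, s_obs$bins$vy)
  fa1 <- fit_factor_analysis(s_obs$rates, n_factors = n_factors)
  dec1 <- calibrate_velocity_kalman(fa_project(fa1, s_obs$rates), v_obs, fa = fa1)
  tun1 <- rotate_tuning(tuning0, drift[1])
  s_cl <- generate_session(config, n_trials, seed = child_seed(seed, 2L),
                           decoder = dec1, attenuation = attenuation,
                           tuning = tun1)
  intent <- cbind(s_cl$bins$target_x - s_cl$bins$cursor_x,
                  s_cl$bins$target_y - s_cl$bins$cursor_y)
  d <- sqrt(rowSums(intent^2))
  ok <- d > 0
  vint <- intent
  vint[ok, ] <- intent[ok, ] / d[ok] * config$nominal_speed *
    pmin(1, d[ok] / max(config$slow_radius, 1e-9))
  vint[!ok, ] <- 0
  fa2 <- fit_factor_analysis(s_cl$rates, n_factors = n_factors)
  dec2 <- calibrate_velocity_kalman(fa_project(fa2, s_cl$rates), vint, fa = fa2)
  tun2 <- rotate_tuning(tuning0, drift[2])
  list(observation = dec1, final = dec2, tuning = tun2, drift = drift,
       drift_bias = drift_bias,
       sessions = list(observation = s_obs, closed_loop = s_cl))
}
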