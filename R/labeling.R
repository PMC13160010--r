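#' Motor intent vector
#'
#' The vector from the current cursor position to the current target,
#' `target - cursor`, and its magnitude. The zero vector (zero magnitude)
#' occurs exactly when the cursor sits on the target.
#'
#' @param cursor Length-2 cursor position.
#' @param target Length-2 target position.
#' @return List with `vx`, `vy` and `magnitude`.
#' @examples
#' motor_intent(c(0.2, 0.1), c(0.5, 0.5))
#' @export
motor_intent <- function(cursor, target) {
  v <- c(target[1] - cursor[1], target[2] - cursor[2])
  list(vx = v[1], vy = v[2], magnitude = sqrt(sum(v^2)))
}

#' Label control bins from cursor-to-target distances
#'
#' Bin `t` is *error* iff the distance increased from the previous bin
#' (`d(t) > d(t-1)`), otherwise *correct*. The first bin (no predecessor)
#' and ties (a stationary cursor) are labeled correct.
#'
#' @param distances Numeric vector of cursor-to-target distances.
#' @return Character vector of labels (`"correct"` / `"error"`), same
#'   length as `distances`.
#' @examples
#' label_bins(c(1.0, 0.9, 0.95, 0.8))
#' @export
label_bins <- function(distances) {
  if (length(distances) < 2L) return(rep("correct", length(distances)))
  lab <- rep("correct", length(distances))
  lab[which(diff(distances) > 0) + 1L] <- "error"
  lab
}

#' Mark the pre-error window before each error onset
#'
#' For every correct-to-error transition, relabels the correct bins within
#' the preceding `window` seconds as `pre_error`. The window is truncated
#' at the sequence start and at an earlier error bout; error bins are never
#' relabeled.
#'
#' @param labels Per-bin labels from [label_bins()].
#' @param window Pre-error window length, seconds (default 0.2).
#' @param bin_dt Bin width, seconds (default 0.02).
#' @return Labels with `pre_error` inserted.
#' @examples
#' mark_pre_error(c(rep("correct", 12), "error"), window = 0.2)
#' @export
mark_pre_error <- function(labels, window = 0.2, bin_dt = 0.02) {
  n_pre <- floor(window / bin_dt)
  if (n_pre < 1L || length(labels) == 0L) return(labels)
  is_err <- labels == "error"
  onsets <- which(is_err & !c(FALSE, is_err[-length(is_err)]))
  out <- labels
  for (o in onsets) {
    lo <- max(1L, o - n_pre)
    idx <- seq(lo, o - 1L)
    idx <- idx[idx >= 1L & out[idx] == "correct"]
    # truncate at an earlier error bout: only bins after the last error bin
    if (length(idx) > 0) {
      prior_err <- which(is_err[seq_len(o - 1L)])
      if (length(prior_err) > 0) idx <- idx[idx > max(prior_err)]
      out[idx] <- "pre_error"
    }
  }
  out
}

#' Label non-overlapping feature windows
#'
#' Cuts a per-bin distance series into non-overlapping windows of
#' `window_len` seconds (4 bins at 50 Hz for the default 80 ms) and labels
#' each window *error* iff the distance at its last bin exceeds the
#' distance at the bin before its first (the distance increased while the
#' features were recorded). Windows whose bins are majority `pre_error`
#' (from [mark_pre_error()]) and are not error are labeled `pre_error`.
#'
#' @param distances Per-bin distance series for one trial. The first
#'   element is taken as the distance *before* the first feature bin, so a
#'   series of `4k + 1` distances yields `k` windows.
#' @param window_len Window length, seconds (default 0.08).
#' @param bin_dt Bin width, seconds (default 0.02).
#' @param pre_error_window Pre-error window passed to [mark_pre_error()],
#'   seconds; `0` disables pre-error marking.
#' @return Character vector of window labels.
#' @examples
#' window_labels(seq(1, 0.4, by = -0.05))  # strictly decreasing: all correct
#' @export
window_labels <- function(distances, window_len = 0.08, bin_dt = 0.02,
                          pre_error_window = 0.2) {
  w <- round(window_len / bin_dt)
  if (abs(w - window_len / bin_dt) > 1e-8 || w < 1L) {
    abort("`window_len` must be a positive multiple of `bin_dt`.")
  }
  d0 <- distances[1]
  d <- distances[-1]
  n <- length(d)
  n_win <- floor(n / w)
  if (n_win < 1L) {
    warn("Trial shorter than one window; skipped.")
    return(character(0))
  }
  bin_lab <- label_bins(c(d0, d))[-1]
  if (pre_error_window > 0) {
    bin_lab <- mark_pre_error(bin_lab, pre_error_window, bin_dt)
  }
  refs <- c(d0, d)[(seq_len(n_win) - 1L) * w + 1L]  # distance before first bin
  ends <- d[seq_len(n_win) * w]
  out <- ifelse(ends > refs, "error", "correct")
  for (i in seq_len(n_win)) {
    if (out[i] == "error") next
    bl <- bin_lab[((i - 1L) * w + 1L):(i * w)]
    if (sum(bl == "pre_error") > w / 2) out[i] <- "pre_error"
  }
  out
}

# per-bin distance series for one trial, including the start distance
trial_distances <- function(trial_bins, start_x, start_y) {
  d <- sqrt((trial_bins$target_x - trial_bins$cursor_x)^2 +
              (trial_bins$target_y - trial_bins$cursor_y)^2)
  d0 <- sqrt((trial_bins$target_x[1] - start_x)^2 +
               (trial_bins$target_y[1] - start_y)^2)
  c(d0, d)
}

#' Label every bin of a session
#'
#' Applies the kinematic error definition ([label_bins()] plus
#' [mark_pre_error()]) per trial record and returns the session with a
#' `label` column added to `session$bins`.
#'
#' @param session A [generate_session()] session.
#' @param pre_error_window Pre-error window, seconds (default 0.2).
#' @return The session, with `bins$label` in
#'   `c("correct", "pre_error", "error")`.
#' @export
label_session <- function(session, pre_error_window = 0.2) {
  dt <- session$config$bin_dt
  labs <- character(nrow(session$bins))
  for (tr in session$trials$trial_id) {
    idx <- which(session$bins$trial_id == tr)
    if (length(idx) == 0L) next
    d <- trial_distances(session$bins[idx, ],
                         session$trials$start_x[tr], session$trials$start_y[tr])
    bl <- label_bins(d)[-1]
    labs[idx] <- mark_pre_error(bl, pre_error_window, dt)
  }
  session$bins$label <- labs
  session
}

#' Extract labeled 80 ms feature windows from a session
#'
#' Cuts each trial record into non-overlapping windows of `window_len`
#' seconds, labels them from the endpoint distances (see
#' [window_labels()]), and attaches per-window features: the per-channel
#' mean smoothed rate, the mean motor-intent vector, and the mean applied
#' cursor velocity.
#'
#' @param session A [generate_session()] session.
#' @param window_len Window length, seconds (default 0.08).
#' @param pre_error_window Pre-error window, seconds (default 0.2).
#' @param phases Which trial phases to keep (default both).
#' @return A tibble with one row per window: `trial_id`, `phase`,
#'   `target_index`, `window`, `t_start`, `label`, intent (`intent_x`,
#'   `intent_y`), mean applied velocity (`vx`, `vy`), `flagged` (any bin
#'   damped online) and a `features` matrix column (n_windows x
#'   n_channels).
#' @export
window_features <- function(session, window_len = 0.08,
                            pre_error_window = 0.2,
                            phases = c("reach", "center")) {
  dt <- session$config$bin_dt
  w <- round(window_len / dt)
  rows <- list()
  feats <- list()
  for (tr in session$trials$trial_id) {
    if (!(session$trials$phase[tr] %in% phases)) next
    idx <- which(session$bins$trial_id == tr)
    n_win <- floor(length(idx) / w)
    if (n_win < 1L) next
    tb <- session$bins[idx, ]
    d <- trial_distances(tb, session$trials$start_x[tr],
                         session$trials$start_y[tr])
    wl <- window_labels(d, window_len, dt, pre_error_window)
    R <- session$rates[idx, , drop = FALSE]
    for (i in seq_len(n_win)) {
      bi <- ((i - 1L) * w + 1L):(i * w)
      feats[[length(feats) + 1L]] <- colMeans(R[bi, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble(
        trial_id = tr, phase = session$trials$phase[tr],
        target_index = session$trials$target_index[tr],
        window = i, t_start = (idx[bi[1]] - 1L) * dt,
        label = wl[i],
        intent_x = mean(tb$target_x[bi] - tb$cursor_x[bi]),
        intent_y = mean(tb$target_y[bi] - tb$cursor_y[bi]),
        vx = mean(tb$vx[bi]), vy = mean(tb$vy[bi]),
        flagged = any(tb$flagged[bi])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$features <- do.call(rbind, feats)
  out
}

#' Fraction of error-labeled windows in a window set
#'
#' @param windows A [window_features()] tibble.
#' @return Scalar fraction of windows labeled `error`.
#' @export
error_fraction <- function(windows) {
  if (nrow(windows) == 0L) return(NA_real_)
  mean(windows$label == "error")
}

#' Filter window sets by their erroneous-control fraction
#'
#' Keeps the sets in which at least `min_error_fraction` of the windows are
#' labeled erroneous control (boundary inclusive), the screening applied
#' before training the error classifier so that training data are not
#' dominated by correct control. The threshold is a parameter (0.30 by
#' default; e.g. 0.25 for a well-performing participant).
#'
#' @param sets A list of [window_features()] tibbles.
#' @param min_error_fraction Retention threshold (default 0.30).
#' @return The retained sets, with an attribute `fractions` giving the
#'   error fraction of every input set.
#' @export
filter_sets <- function(sets, min_error_fraction = 0.30) {
  if (length(sets) == 0L) {
    warn("No sets supplied.")
    return(structure(list(), fractions = numeric(0)))
  }
  fr <- vapply(sets, error_fraction, numeric(1))
  keep <- !is.na(fr) & fr >= min_error_fraction
  structure(sets[keep], fractions = fr)
}
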