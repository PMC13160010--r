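#' Success rate of a session
#'
#' A trial is a consecutive reach + center pair of phase records; it is
#' successful only when both phases succeeded (a reach followed by a timed
#' out center phase counts as failed). The rate is successes over trials.
#'
#' @param session A [generate_session()] session (or its `trials` tibble).
#' @return Scalar fraction in \[0, 1\].
#' @export
success_rate <- function(session) {
  tr <- if (is.data.frame(session)) session else session$trials
  pairs <- paired_trials(tr)
  if (nrow(pairs) == 0L) return(mean(tr$success))
  mean(pairs$success)
}

paired_trials <- function(trials) {
  reach <- which(trials$phase == "reach")
  reach <- reach[reach + 1L <= nrow(trials)]
  reach <- reach[trials$phase[reach + 1L] == "center"]
  tibble(
    reach_id = trials$trial_id[reach],
    success = trials$success[reach] & trials$success[reach + 1L],
    duration = trials$duration[reach] + trials$duration[reach + 1L]
  )
}

#' Target acquisition rate
#'
#' Successful trials per second of total set duration.
#'
#' @param session A session or `trials` tibble.
#' @return Rate in 1/s.
#' @export
acquisition_rate <- function(session) {
  tr <- if (is.data.frame(session)) session else session$trials
  total <- sum(tr$duration)
  if (total <= 0) abort("Set duration must be positive.")
  pairs <- paired_trials(tr)
  succ <- if (nrow(pairs) > 0L) sum(pairs$success) else sum(tr$success)
  succ / total
}

#' Normalized path length of one trial phase
#'
#' Arc length of the cursor polyline divided by the straight start-target
#' distance; 1 is the ideal straight reach. Defined for successful phases.
#'
#' @param trajectory Matrix (time x 2) of cursor positions, excluding the
#'   start point.
#' @param start Length-2 start position.
#' @param target Length-2 target position.
#' @return Scalar ratio (>= 1 up to discretization).
#' @examples
#' normalized_path_length(cbind(c(.5, 1), c(0, 0)), c(0, 0), c(1, 0))
#' @export
normalized_path_length <- function(trajectory, start, target) {
  pts <- rbind(start, as.matrix(trajectory))
  seg <- sqrt(rowSums(diff(pts)^2))
  ideal <- sqrt(sum((target - start)^2))
  if (ideal <= 0) abort("Start and target coincide.")
  sum(seg) / ideal
}

#' Mean angular error of a trial phase
#'
#' Per-bin angle (degrees, in \[0, 180\]) between the decoded velocity and
#' the ideal velocity (towards the target from the *current* cursor
#' position), averaged over the phase. Bins with speed below `speed_floor`
#' are skipped.
#'
#' @param velocities Matrix (time x 2) of decoded velocities.
#' @param cursor_positions Matrix (time x 2) of cursor positions at the
#'   start of each bin.
#' @param target Length-2 target position.
#' @param speed_floor Minimum speed for a bin to count (default 1e-6).
#' @return Mean angle in degrees, or `NA` if no bin qualifies.
#' @export
angular_error <- function(velocities, cursor_positions, target,
                          speed_floor = 1e-6) {
  v <- as.matrix(velocities)
  p <- as.matrix(cursor_positions)
  ideal <- cbind(target[1] - p[, 1], target[2] - p[, 2])
  sp <- sqrt(rowSums(v^2))
  isp <- sqrt(rowSums(ideal^2))
  ok <- sp > speed_floor & isp > speed_floor
  if (!any(ok)) return(NA_real_)
  cosang <- rowSums(v[ok, , drop = FALSE] * ideal[ok, , drop = FALSE]) /
    (sp[ok] * isp[ok])
  mean(rad2deg(acos(pmin(1, pmax(-1, cosang)))))
}

#' Mean path deviation of a trial phase
#'
#' Mean perpendicular distance of the cursor from the straight line through
#' start and target. Defined for successful phases.
#'
#' @inheritParams normalized_path_length
#' @return Mean normal distance, screen units.
#' @examples
#' path_deviation(cbind(c(.5, 1), c(.1, .1)), c(0, 0), c(1, 0))
#' @export
path_deviation <- function(trajectory, start, target) {
  u <- target - start
  nu <- sqrt(sum(u^2))
  if (nu <= 0) abort("Start and target coincide.")
  pts <- as.matrix(trajectory)
  rel <- cbind(pts[, 1] - start[1], pts[, 2] - start[2])
  mean(abs(rel[, 1] * u[2] - rel[, 2] * u[1]) / nu)
}

#' Per-set performance metrics of a session
#'
#' One-row tibble with the closed-loop performance metrics: success rate,
#' acquisition rate (per second), and the per-phase means of normalized
#' path length, angular error (degrees) and path deviation. Path metrics
#' are computed on successful phases only; angular error over all phases.
#'
#' @param session A labeled or unlabeled [generate_session()] session.
#' @return A one-row tibble.
#' @export
session_metrics <- function(session) {
  tr <- session$trials
  npl <- numeric(0); pdev <- numeric(0); aerr <- numeric(0)
  for (i in tr$trial_id) {
    idx <- which(session$bins$trial_id == i)
    if (length(idx) < 2L) next
    b <- session$bins[idx, ]
    traj <- cbind(b$cursor_x, b$cursor_y)
    start <- c(tr$start_x[i], tr$start_y[i])
    target <- c(tr$target_x[i], tr$target_y[i])
    pos_prev <- rbind(start, traj[-nrow(traj), , drop = FALSE])
    aerr <- c(aerr, angular_error(cbind(b$vx, b$vy), pos_prev, target))
    if (tr$success[i]) {
      npl <- c(npl, normalized_path_length(traj, start, target))
      pdev <- c(pdev, path_deviation(traj, start, target))
    }
  }
  tibble(
    success_rate = success_rate(session),
    acquisition_rate = acquisition_rate(session),
    normalized_path_length = if (length(npl)) mean(npl) else NA_real_,
    angular_error = if (length(aerr)) mean(aerr, na.rm = TRUE) else NA_real_,
    path_deviation = if (length(pdev)) mean(pdev) else NA_real_
  )
}

#' Normalized error-distance histogram
#'
#' Cursor-to-target distances at error-labeled bins, normalized per trial
#' by the start-of-trial cursor-to-target distance, as a histogram. A mass
#' near 0 reflects small corrective movements close to the target; mass
#' near 1 and above reflects errors that pushed the cursor farther away
#' than where the trial started.
#'
#' @param session A [label_session()]-labeled session.
#' @param breaks Histogram breaks (default `seq(0, ceiling(max), 0.1)`).
#' @return Tibble with `mid`, `count` and `density`; the raw normalized
#'   distances are in attribute `values`.
#' @export
error_distance_histogram <- function(session, breaks = NULL) {
  if (!("label" %in% names(session$bins))) abort("Label the session first.")
  vals <- numeric(0)
  for (i in session$trials$trial_id) {
    idx <- which(session$bins$trial_id == i)
    b <- session$bins[idx, ]
    err <- b$label == "error"
    if (!any(err)) next
    d0 <- sqrt((session$trials$target_x[i] - session$trials$start_x[i])^2 +
                 (session$trials$target_y[i] - session$trials$start_y[i])^2)
    if (d0 <= 0) next
    d <- sqrt((b$target_x - b$cursor_x)^2 + (b$target_y - b$cursor_y)^2)
    vals <- c(vals, d[err] / d0)
  }
  if (length(vals) == 0L) {
    warn("No error-labeled bins.")
    return(structure(tibble(mid = numeric(0), count = integer(0),
                            density = numeric(0)), values = numeric(0)))
  }
  if (is.null(breaks)) breaks <- seq(0, ceiling(max(vals) * 10) / 10, by = 0.1)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  structure(tibble(mid = h$mids, count = h$counts, density = h$density),
            values = vals)
}

#' Entropy of the cursor direction distribution
#'
#' Shannon entropy (nats) of the histogram of movement directions over
#' `n_bins` equal angular bins; the uniform distribution attains
#' `log(n_bins)`. Zero-velocity bins are excluded. Lower values indicate a
#' directional bias of the control signal.
#'
#' @param velocities Matrix (time x 2) of velocities.
#' @param n_bins Number of angular bins (default 16).
#' @param speed_floor Minimum speed for inclusion.
#' @return Entropy in nats.
#' @examples
#' a <- seq(0, 2 * pi, length.out = 1601)[-1]
#' direction_entropy(cbind(cos(a), sin(a)))  # ~log(16)
#' @export
direction_entropy <- function(velocities, n_bins = 16, speed_floor = 1e-9) {
  v <- as.matrix(velocities)
  sp <- sqrt(rowSums(v^2))
  v <- v[sp > speed_floor, , drop = FALSE]
  if (nrow(v) == 0L) abort("No nonzero velocities.")
  ang <- atan2(v[, 2], v[, 1])
  bin <- floor((ang + pi) / (2 * pi) * n_bins) %% n_bins
  p <- tabulate(bin + 1L, n_bins) / length(bin)
  p <- p[p > 0]
  -sum(p * log(p))
}
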