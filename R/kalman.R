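#' Calibrate a velocity Kalman filter on factor scores
#'
#' Linear-Gaussian model with 2-D velocity state `v_t`:
#' `v_t = A v_{t-1} + w`, `z_t = d + H v_t + r`, where `z_t` are the
#' factor-analysis scores for one bin. The observation map `(H, d)` is fit
#' by least squares of the factors on the intent velocity (ridge fallback
#' for rank-deficient designs), the state transition as a damped identity
#' from the velocity autoregression, and the noise covariances from the
#' residuals. An output `gain` is calibrated so the decoded speed on the
#' training data matches the intent speed.
#'
#' @param factors Matrix, time x n_factors.
#' @param intent_velocity Matrix, time x 2, the intended cursor velocity.
#' @param fa Optional [fit_factor_analysis()] model to attach, so the
#'   decoder can consume raw rate bins.
#' @param gain Output speed multiplier; `"auto"` (default) matches mean
#'   decoded speed to mean intent speed on the training data.
#' @return An object of class `kalman_decoder`.
#' @export
calibrate_velocity_kalman <- function(factors, intent_velocity, fa = NULL,
                                      gain = "auto") {
  Z <- as.matrix(factors); V <- as.matrix(intent_velocity)
  if (nrow(Z) != nrow(V)) abort("`factors` and `intent_velocity` lengths differ.")
  if (ncol(V) != 2L) abort("`intent_velocity` must have 2 columns.")
  if (all(abs(V) < .Machine$double.eps)) {
    abort("`intent_velocity` is identically zero; nothing to regress on.")
  }
  n <- nrow(Z); k <- ncol(Z)
  vm <- colMeans(V); zm <- colMeans(Z)
  Vc <- sweep(V, 2, vm); Zc <- sweep(Z, 2, zm)
  G <- crossprod(Vc)
  ridge <- 0
  if (rcond_2x2(G) < 1e-10) {
    ridge <- 1e-6 * mean(diag(G))
    warn(sprintf("Rank-deficient velocity design; ridge %.3g applied.", ridge))
  }
  B <- solve(G + diag(ridge, 2), crossprod(Vc, Zc))  # 2 x k
  H <- t(B)                                          # k x 2
  d <- zm - as.vector(H %*% vm)
  obs_resid <- Zc - Vc %*% B
  R <- crossprod(obs_resid) / max(1, n - 1)
  R <- R + diag(1e-8 * mean(diag(R)), k)
  # damped-identity transition from the velocity AR(1)
  v0 <- V[-n, , drop = FALSE]; v1 <- V[-1, , drop = FALSE]
  a <- sum(v1 * v0) / max(sum(v0 * v0), .Machine$double.eps)
  a <- min(max(a, 0), 0.999)
  A <- diag(a, 2)
  st_resid <- v1 - a * v0
  Q <- crossprod(st_resid) / max(1, n - 2)
  Q <- Q + diag(1e-10 * mean(diag(Q)), 2)
  dec <- structure(
    list(fa = fa, H = H, d = d, A = A, Q = Q, R = R, gain = 1,
         n_factors = k,
         HtRi = t(solve(R, H)),        # 2 x k
         HtRiH = crossprod(H, solve(R, H))),
    class = "kalman_decoder"
  )
  if (identical(gain, "auto")) {
    dv <- decode_sequence(dec, Z, raw = FALSE)
    sp <- sqrt(rowSums(dv^2))
    target <- mean(sqrt(rowSums(V^2)))
    dec$gain <- if (mean(sp) > 0) target / mean(sp) else 1
  } else {
    dec$gain <- gain
  }
  dec
}

rcond_2x2 <- function(m) {
  e <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) return(0)
  max(min(e), 0) / max(e)
}

#' Initialize Kalman decoder state
#'
#' Fresh filter state (zero velocity, broad covariance); the decoder state
#' is reset at the start of every trial.
#'
#' @param decoder A [calibrate_velocity_kalman()] decoder.
#' @return A list with elements `v` (state mean) and `P` (covariance).
#' @export
kalman_state <- function(decoder) {
  list(v = c(0, 0), P = decoder$Q * 10 + diag(1e-4, 2))
}

#' One Kalman predict/update step
#'
#' Consumes one bin of observations (a raw rate bin if the decoder carries
#' a factor model, otherwise a factor-score vector) and returns the decoded
#' velocity and the updated filter state.
#'
#' @param decoder A `kalman_decoder`.
#' @param observation Numeric vector: rate bin (length n_channels, when the
#'   decoder has an attached factor model and `raw = TRUE`) or factor
#'   scores (length n_factors).
#' @param state Filter state from the previous call, or `NULL` to start a
#'   trial (see [kalman_state()]).
#' @param raw Whether `observation` is a raw rate bin to be projected
#'   through the attached factor model first.
#' @return List with `velocity` (length 2, after the output gain) and
#'   `state`.
#' @export
decode_step <- function(decoder, observation, state = NULL, raw = !is.null(decoder$fa)) {
  if (is.null(state)) state <- kalman_state(decoder)
  z <- if (raw) {
    if (is.null(decoder$fa)) abort("Decoder has no factor model attached.")
    as.vector(fa_project(decoder$fa, observation))
  } else as.numeric(observation)
  if (length(z) != decoder$n_factors) {
    abort(sprintf("Observation has length %d; decoder expects %d factors.",
                  length(z), decoder$n_factors))
  }
  # predict
  v_pr <- decoder$A %*% state$v
  P_pr <- decoder$A %*% state$P %*% t(decoder$A) + decoder$Q
  # update (information form; only 2x2 inversions)
  Pi_pr <- solve(P_pr)
  P_po <- solve(Pi_pr + decoder$HtRiH)
  v_po <- P_po %*% (Pi_pr %*% v_pr + decoder$HtRi %*% (z - decoder$d))
  list(velocity = decoder$gain * as.vector(v_po),
       state = list(v = as.vector(v_po), P = P_po))
}

#' Decode a whole observation sequence from a reset state
#'
#' Convenience wrapper running [decode_step()] over the rows of an
#' observation matrix, starting from a fresh trial state.
#'
#' @param decoder A `kalman_decoder`.
#' @param factors Matrix of observations (time x n_factors, or time x
#'   n_channels with `raw = TRUE`).
#' @param raw Project raw rate bins through the attached factor model.
#' @return Matrix (time x 2) of decoded velocities.
#' @export
decode_sequence <- function(decoder, factors, raw = FALSE) {
  st <- NULL
  out <- matrix(0, nrow(factors), 2)
  for (i in seq_len(nrow(factors))) {
    r <- decode_step(decoder, factors[i, ], st, raw = raw)
    out[i, ] <- r$velocity
    st <- r$state
  }
  out
}

#' Attenuate the velocity component orthogonal to an ideal direction
#'
#' Preserves the component of `velocity` parallel to `ideal_direction` and
#' multiplies the orthogonal component by `attenuation`. With
#' `attenuation = 0` movement is confined to the line through the ideal
#' direction, as used during closed-loop decoder calibration.
#'
#' @param velocity Length-2 velocity vector.
#' @param ideal_direction Unit vector towards the target.
#' @param attenuation Scalar in \[0, 1\].
#' @return Length-2 velocity vector.
#' @examples
#' orthogonal_attenuation(c(1, 1), c(1, 0), 0)
#' @export
orthogonal_attenuation <- function(velocity, ideal_direction, attenuation) {
  nd <- vec_norm(ideal_direction)
  if (nd < .Machine$double.eps) abort("`ideal_direction` must be non-zero.")
  if (attenuation < 0 || attenuation > 1) abort("`attenuation` must be in [0, 1].")
  u <- ideal_direction / nd
  par <- sum(velocity * u) * u
  par + attenuation * (velocity - par)
}

#' @export
print.kalman_decoder <- function(x, ...) {
  cat(sprintf("<kalman_decoder> %d factors%s, gain %.3f, A = %.3f I\n",
              x$n_factors,
              if (is.null(x$fa)) "" else sprintf(" (FA on %d channels)",
                                                 x$fa$n_channels),
              x$gain, x$A[1, 1]))
  invisible(x)
}

#' @rdname glance.error_classifier
#' @export
glance.kalman_decoder <- function(x, ...) {
  tibble(n_factors = x$n_factors, gain = x$gain, transition = x$A[1, 1],
         has_factor_model = !is.null(x$fa))
}
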