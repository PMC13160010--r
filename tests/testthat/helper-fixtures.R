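# Shared fixtures and independent oracles for the test suite.

# small, fast config for unit tests (not the study-scale defaults)
tiny_config <- function(...) {
  sim_config(n_channels = 24, ...)
}

# one cached small decoded session + derived objects, shared across tests
.fixture_env <- new.env(parent = emptyenv())

small_session <- function() {
  if (is.null(.fixture_env$session)) {
    cfg <- sim_config(n_channels = 48, seed = 7)
    cal <- calibrate_decoder(cfg, seed = 7, n_trials = 30, n_factors = 10)
    s <- generate_session(cfg, 60, seed = 107, decoder = cal$final,
                          tuning = cal$tuning)
    .fixture_env$session <- label_session(s)
    .fixture_env$cal <- cal
  }
  .fixture_env$session
}

small_calibration <- function() {
  small_session()
  .fixture_env$cal
}

small_windows <- function() {
  if (is.null(.fixture_env$windows)) {
    .fixture_env$windows <- window_features(small_session(), phases = "reach")
  }
  .fixture_env$windows
}

# independent alignment-index oracle: SVD route, no shared code with the
# implementation (which goes through cov/eigen)
alignment_oracle <- function(A, B, M) {
  one <- function(X, Y) {
    Xc <- sweep(X, 2, colMeans(X))
    Yc <- sweep(Y, 2, colMeans(Y))
    V <- svd(Xc)$v[, seq_len(M), drop = FALSE]
    sv <- svd(Yc)$d^2 / (nrow(Y) - 1)
    C <- crossprod(Yc) / (nrow(Y) - 1)
    sum(diag(t(V) %*% C %*% V)) / sum(sort(sv, decreasing = TRUE)[seq_len(M)])
  }
  (one(A, B) + one(B, A)) / 2
}

# data matrix whose sample covariance is exactly diag(ev): scaled
# orthonormal design columns
exact_cov_data <- function(ev, n = length(ev) * 4) {
  p <- length(ev)
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  q <- sweep(q, 2, colMeans(q))          # center
  q <- qr.Q(qr(q))                       # re-orthonormalize centered cols
  sweep(q, 2, sqrt(ev * (n - 1)), "*")
}

# windows tibble with controllable class structure for classifier tests
make_windows <- function(n_per_class, mu_correct, mu_error, sd = 1,
                         n_pre = 0, mu_pre = mu_error, seed = 1) {
  set.seed(seed)
  p <- length(mu_correct)
  lab <- c(rep("correct", n_per_class), rep("error", n_per_class),
           rep("pre_error", n_pre))
  mus <- rbind(matrix(mu_correct, n_per_class, p, byrow = TRUE),
               matrix(mu_error, n_per_class, p, byrow = TRUE))
  if (n_pre > 0) mus <- rbind(mus, matrix(mu_pre, n_pre, p, byrow = TRUE))
  f <- mus + matrix(rnorm(length(lab) * p, sd = sd), length(lab), p)
  ord <- sample(seq_along(lab))
  out <- tibble::tibble(
    trial_id = rep(seq_len(max(1, length(lab) %/% 10)), length.out = length(lab)),
    phase = "reach",
    target_index = rep(1:8, length.out = length(lab)),
    window = seq_along(lab), t_start = seq_along(lab) * 0.08,
    label = lab[ord],
    intent_x = 0, intent_y = 0, vx = 0, vy = 0, flagged = FALSE
  )
  out$features <- f[ord, , drop = FALSE]
  out
}
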