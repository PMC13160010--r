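test_that("factor analysis recovers a planted factor subspace", {
  set.seed(11)
  n <- 5000; p <- 40; k <- 5
  L <- matrix(rnorm(p * k), p, k)
  z <- matrix(rnorm(n * k), n, k)
  x <- z %*% t(L) + matrix(rnorm(n * p, sd = 0.5), n, p)
  fit <- fit_factor_analysis(x, n_factors = k)
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(fit$loglik) > -1e-6 * abs(fit$loglik[1])))
  # recovered loading spans the planted subspace (principal angles)
  q1 <- qr.Q(qr(L)); q2 <- qr.Q(qr(fit$loading))
  expect_gt(min(svd(crossprod(q1, q2))$d), 0.95)
  expect_error(fit_factor_analysis(x, n_factors = p + 1), "channel")
})

test_that("constant channels are excluded with a warning", {
  set.seed(2)
  x <- cbind(matrix(rnorm(600), 200, 3), 5)
  expect_warning(fit <- fit_factor_analysis(x, n_factors = 2), "constant")
  expect_equal(fit$excluded, 4L)
  expect_equal(ncol(fa_project(fit, x)), 2L)
})

test_that("noise-free linear observations decode almost perfectly", {
  set.seed(3)
  n <- 2000
  v <- matrix(rnorm(n * 2, sd = 0.5), n, 2)
  # smooth the velocity so it has AR structure
  v <- apply(v, 2, function(col) as.numeric(stats::filter(col, 0.9,
                                                          "recursive")))
  H <- matrix(rnorm(12 * 2), 12, 2)
  z <- v %*% t(H) + matrix(rnorm(n * 12, sd = 1e-4), n, 12)
  dec <- calibrate_velocity_kalman(z, v)
  vd <- decode_sequence(dec, z)
  expect_gt(cor(vd[, 1], v[, 1]), 0.99)
  expect_gt(cor(vd[, 2], v[, 2]), 0.99)
  expect_error(calibrate_velocity_kalman(z, matrix(0, n, 2)), "zero")
})

test_that("decode_step is stateful, resettable and deterministic", {
  set.seed(4)
  z <- matrix(rnorm(50 * 6), 50, 6)
  v <- matrix(rnorm(50 * 2), 50, 2)
  dec <- calibrate_velocity_kalman(z, v)
  run <- function() {
    st <- NULL
    out <- matrix(0, 10, 2)
    for (i in 1:10) {
      r <- decode_step(dec, z[i, ], st)
      out[i, ] <- r$velocity
      st <- r$state
    }
    out
  }
  expect_identical(run(), run())
  # constant observations converge to a fixed point
  st <- NULL
  vs <- matrix(0, 200, 2)
  for (i in 1:200) {
    r <- decode_step(dec, z[1, ], st)
    vs[i, ] <- r$velocity
    st <- r$state
  }
  expect_lt(sum(abs(vs[200, ] - vs[199, ])), 1e-8)
  expect_error(decode_step(dec, z[1, 1:3]), "factors")
})

test_that("orthogonal attenuation preserves the parallel component", {
  expect_equal(orthogonal_attenuation(c(1, 1), c(1, 0), 0), c(1, 0))
  expect_equal(orthogonal_attenuation(c(1, 1), c(1, 0), 1), c(1, 1))
  expect_equal(orthogonal_attenuation(c(3, 0), c(1, 0), 0.2), c(3, 0))
  v <- c(0.3, -0.7); d <- c(1, 2) / sqrt(5)
  out <- orthogonal_attenuation(v, d, 0.5)
  expect_equal(sum(out * d), sum(v * d))
  expect_error(orthogonal_attenuation(c(1, 1), c(0, 0), 0.5), "non-zero")
})

test_that("factor model agrees with the reference ML fit on easy data", {
  skip_if_not_installed("stats")
  set.seed(5)
  n <- 3000; p <- 12; k <- 2
  L <- matrix(rnorm(p * k), p, k)
  x <- matrix(rnorm(n * k), n, k) %*% t(L) +
    matrix(rnorm(n * p, sd = 1), n, p)
  fit <- fit_factor_analysis(x, n_factors = k)
  ref <- stats::factanal(covmat = stats::cov(x), factors = k)
  # compare loading subspaces (factanal works on the correlation scale)
  ref_load <- diag(apply(x, 2, stats::sd)) %*% ref$loadings
  q1 <- qr.Q(qr(fit$loading)); q2 <- qr.Q(qr(matrix(ref_load, p, k)))
  expect_gt(min(svd(crossprod(q1, q2))$d), 0.95)
})

test_that("closed-loop recalibration beats the observation-only decoder", {
  # probed under strong within-session drift and a tight timeout, where
  # decoder staleness matters; the advantage should be paired-consistent
  diffs_succ <- numeric(0); diffs_npl <- numeric(0)
  for (sd in 1:10) {
    cfg <- sim_config(n_channels = 48, seed = sd, perturb_rate = 0,
                      set_drift = 20, trial_timeout = 1.6,
                      target_radius = 0.1)
    cal <- calibrate_decoder(cfg, seed = sd, n_trials = 30, n_factors = 10)
    s_obs <- generate_session(cfg, 30, seed = sd + 300,
                              decoder = cal$observation, tuning = cal$tuning)
    s_fin <- generate_session(cfg, 30, seed = sd + 300,
                              decoder = cal$final, tuning = cal$tuning)
    diffs_succ <- c(diffs_succ,
                    mean(s_fin$trials$success) - mean(s_obs$trials$success))
    npl_o <- session_metrics(s_obs)$normalized_path_length
    npl_f <- session_metrics(s_fin)$normalized_path_length
    if (is.finite(npl_o) && is.finite(npl_f)) {
      diffs_npl <- c(diffs_npl, npl_f - npl_o)
    }
  }
  # the refit decoder is never substantially worse and is better on average
  expect_gt(mean(diffs_succ), 0)
  expect_true(all(diffs_succ >= -0.05))
  expect_lt(mean(diffs_npl), 0)
})
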