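test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(n_channels = 8), "sim_config")
  expect_error(sim_config(bin_dt = 0), "bin_dt")
  expect_error(sim_config(smoothing_tau = -1), "smoothing_tau")
  expect_error(sim_config(n_channels = 1), "n_channels")
  expect_error(sim_config(error_lead = -0.1), "error_lead")
  expect_error(sim_config(baseline_rate = -5), "baseline_rate")
  expect_error(sim_config(target_ring = 2), "target_ring")
})

test_that("generate_tuning is deterministic with uniform preferred directions", {
  cfg <- sim_config(n_channels = 176)
  t1 <- generate_tuning(cfg, seed = 3)
  t2 <- generate_tuning(cfg, seed = 3)
  expect_identical(t1, t2)
  expect_equal(rowSums(t1$preferred_direction^2), rep(1, 176))
  # zero amplitude kills the loading
  t0 <- generate_tuning(sim_config(n_channels = 32, error_gain = 0), seed = 1)
  expect_true(all(t0$error_loading == 0))
  # mean resultant of uniform directions is ~0 (Monte Carlo over seeds)
  res <- vapply(1:20, function(s) {
    pd <- generate_tuning(cfg, seed = s)$preferred_direction
    sqrt(sum(colMeans(pd)^2))
  }, numeric(1))
  expect_lt(mean(res), 3 / sqrt(176))
})

test_that("tuning error loading has rank 2", {
  tun <- generate_tuning(sim_config(n_channels = 64), seed = 2)
  sv <- svd(tun$error_loading)$d
  expect_length(sv, 2L)
  expect_gt(sv[2], 0)
})

test_that("emit_counts draws Poisson counts with the contract rate", {
  cfg <- sim_config(n_channels = 4, baseline_rate = 10, tuning_depth = 0,
                    error_gain = 0)
  tun <- generate_tuning(cfg, seed = 1)
  tun$baseline <- rep(10, 4); tun$depth <- rep(0, 4)
  # v = 0, e = 0: mean count = baseline * dt
  set.seed(1)
  draws <- replicate(25000, sum(emit_counts(tun, c(0, 0), 0, dt = 0.02)) / 4)
  expect_equal(mean(draws), 0.2, tolerance = 0.01)
  # linearity in the error loading
  tun$error_loading <- cbind(c(5, 0, 0, 0), 0)
  set.seed(2)
  draws1 <- replicate(100000, emit_counts(tun, c(0, 0), 1, dt = 0.02)[1])
  expect_equal(mean(draws1), (10 + 5) * 0.02, tolerance = 0.01)
  expect_error(emit_counts(tun, c(0, 0), 0, dt = -0.01), "dt")
  expect_error(emit_counts(tun, c(0, 0), 1.5, dt = 0.02), "error_latent")
})

test_that("smooth_rates uses a unit-sum causal kernel in Hz", {
  k <- smoothing_kernel(0.44, 0.02)
  expect_length(k, 22L)
  expect_equal(sum(k), 1)
  expect_true(all(diff(k) < 0))
  # constant 1 count/bin converges to 50 Hz
  r <- smooth_rates(matrix(1, 60, 2), dt = 0.02, tau = 0.44)
  expect_equal(unname(r[60, ]), c(50, 50))
  # zeros map to zeros
  expect_true(all(smooth_rates(matrix(0, 10, 3), 0.02, 0.44) == 0))
  # single impulse decays monotonically
  x <- matrix(0, 40, 1); x[5, 1] <- 1
  r <- smooth_rates(x, 0.02, 0.44)
  tail_part <- r[5:26, 1]
  expect_true(all(diff(tail_part) < 0))
  expect_true(all(r[27:40, 1] == 0))  # truncated support
  expect_error(smooth_rates(matrix(1, 5, 1), 0.02, 0), "tau")
  expect_error(smooth_rates(matrix(-1, 5, 1), 0.02, 0.44), "non-negative")
})

test_that("user command tracks intent with no perturbations", {
  cfg <- tiny_config(perturb_rate = 0, command_noise = 0)
  set.seed(1)
  st <- NULL
  for (i in 1:100) {
    out <- simulate_user_command(c(0, 1), st, cfg)
    st <- out$state
    expect_equal(out$error_latent, 0)
    expect_false(out$perturb_on)
    expect_equal(out$command, c(0, cfg$nominal_speed))
  }
})

test_that("error latent exceeds 0.5 at least error_lead before the event", {
  cfg <- tiny_config(perturb_rate = 2, perturb_duration = 0.5,
                     error_lead = 0.2)
  for (rep in 1:5) {
    set.seed(rep)
    st <- NULL
    lat <- numeric(400); on <- logical(400)
    for (i in 1:400) {
      out <- simulate_user_command(c(1, 0), st, cfg)
      st <- out$state
      lat[i] <- out$error_latent; on[i] <- out$perturb_on
    }
    onsets <- which(on & !c(FALSE, on[-400]))
    for (o in onsets) {
      lead_bin <- o - round(cfg$error_lead / cfg$bin_dt)
      if (lead_bin < 1) next
      first_cross <- which(lat > 0.5)[1]
      expect_lte(min(which(lat[seq_len(o)] > 0.5)), lead_bin)
    }
  }
})

test_that("fraction of time perturbed matches rate x duration for rare events", {
  cfg <- tiny_config(perturb_rate = 0.1, perturb_duration = 0.5)
  set.seed(42)
  st <- NULL
  n <- 40000
  on <- logical(n)
  for (i in seq_len(n)) {
    out <- simulate_user_command(c(1, 0), st, cfg)
    st <- out$state
    on[i] <- out$perturb_on
  }
  expected <- cfg$perturb_rate * cfg$perturb_duration
  expect_equal(mean(on), expected, tolerance = 0.25)
})

test_that("sessions are bit-identical for a fixed config and seed", {
  cfg <- tiny_config(seed = 5)
  s1 <- generate_session(cfg, 6, seed = 5, cursor_mode = "auto")
  s2 <- generate_session(cfg, 6, seed = 5, cursor_mode = "auto")
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$bins, s2$bins)
  expect_identical(s1$trials, s2$trials)
})

test_that("auto-cursor sessions succeed with straight trajectories", {
  cfg <- tiny_config(seed = 2)
  s <- generate_session(cfg, 8, seed = 2, cursor_mode = "auto")
  expect_equal(nrow(s$trials), 8L)
  expect_true(all(s$trials$success))
  m <- session_metrics(s)
  # a perfect straight path stops at the success radius, so its length is
  # (ring - radius) / ring of the ideal center-to-target line
  ideal <- (cfg$target_ring - cfg$target_radius) / cfg$target_ring
  expect_equal(m$normalized_path_length, ideal, tolerance = 0.05)
  expect_equal(m$path_deviation, 0, tolerance = 1e-8)
})

test_that("session arrays satisfy the container invariants", {
  s <- small_session()
  expect_true(all(s$counts >= 0))
  expect_true(is.integer(s$counts))
  expect_true(all(s$rates >= 0))
  # exact non-overlapping row partition by trial
  expect_equal(as.vector(table(s$bins$trial_id)), s$trials$n_bins)
  expect_equal(nrow(s$bins), sum(s$trials$n_bins))
  # engine's streaming smoother equals the batch smoother
  expect_equal(s$rates, smooth_rates(s$counts, s$config$bin_dt,
                                     s$config$smoothing_tau),
               tolerance = 1e-10)
})

test_that("the neural latent leads the kinematic error label", {
  s <- small_session()
  b <- s$bins
  lead_bins <- round(s$config$error_lead / s$config$bin_dt)
  hits <- 0L; total <- 0L
  for (tr in unique(b$trial_id[b$perturb_on])) {
    idx <- which(b$trial_id == tr)
    on <- b$perturb_on[idx]
    onset <- which(on & !c(FALSE, on[-length(on)]))
    # only bouts whose lead window lies inside the trial are assessable
    onset <- onset[onset > lead_bins + 2]
    for (o in onset) {
      first_err <- which(b$label[idx] == "error")
      first_err <- first_err[first_err >= o]
      if (length(first_err) == 0) next
      cross <- which(b$error_latent[idx] > 0.5)
      cross <- cross[cross <= first_err[1]]
      total <- total + 1L
      if (length(cross) > 0 &&
          cross[1] <= first_err[1] - lead_bins + 1) hits <- hits + 1L
    }
  }
  expect_gt(total, 5L)
  expect_gt(hits / total, 0.9)
})

test_that("session round-trips through the on-disk text format", {
  cfg <- tiny_config(seed = 9)
  s <- label_session(generate_session(cfg, 4, seed = 9, cursor_mode = "auto"))
  dir <- withr::local_tempdir()
  write_session(s, dir)
  expect_true(file.exists(file.path(dir, "session.json")))
  meta <- jsonlite::read_json(file.path(dir, "session.json"))
  expect_false(is.null(meta$format_version))
  s2 <- read_session(dir)
  expect_equal(s2$counts, s$counts)
  expect_equal(s2$rates, s$rates, tolerance = 1e-8)
  expect_equal(as.data.frame(s2$bins), as.data.frame(s$bins),
               tolerance = 1e-8)
  expect_equal(s2$trials$success, s$trials$success)
  expect_equal(s2$config$n_channels, s$config$n_channels)
  expect_error(read_session(withr::local_tempdir()), "session")
})
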