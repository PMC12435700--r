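test_that("calcium kernel has the double-exponential shape", {
  kp <- kernel_params(0.1, 1.0)
  expect_equal(calcium_kernel(0, kp), 0)
  expect_lt(abs(calcium_kernel(10, kp)), 1e-4)
  # peak location vs numeric maximization on a 1 ms grid
  tg <- seq(0, 3, by = 0.001)
  v <- calcium_kernel(tg, kp)
  t_grid <- tg[which.max(v)]
  expect_equal(t_grid, 0.2558, tolerance = 1e-3)
  expect_equal(stmdrift:::kernel_peak(kp)$time, t_grid, tolerance = 1e-3)
  # unit-peak normalization
  expect_equal(max(calcium_kernel(tg, kp, normalize = TRUE)), 1,
               tolerance = 1e-6)
  expect_error(kernel_params(1.0, 0.5), "tau_decay")
})

test_that("trace synthesis is an impulse-kernel convolution", {
  kp <- kernel_params()
  expect_equal(synthesize_trace(300, c(10, 100), betas = 0), numeric(300))
  tr1 <- synthesize_trace(600, 50, betas = 1)
  k <- stmdrift:::kernel_frames(kp, 30)
  expect_equal(tr1[50:(49 + length(k))], k)
  # linearity in the amplitudes
  tr2 <- synthesize_trace(600, c(50, 200), betas = c(1, 2))
  tr4 <- synthesize_trace(600, c(50, 200), betas = c(2, 4))
  expect_equal(tr4, 2 * tr2)
  # seeded noise determinism
  a <- synthesize_trace(300, 10, noise_sd = 0.5, seed = 42)
  b <- synthesize_trace(300, 10, noise_sd = 0.5, seed = 42)
  expect_identical(a, b)
  expect_error(synthesize_trace(100, 200), "outside")
})

test_that("generated sessions have a balanced, reproducible design", {
  for (n_trials in c(20, 33, 60)) {
    s <- generate_session(n_neurons = 12, n_trials = n_trials,
                          noise_sd = 0.1, seed = 1)
    tab <- table(s$trials$stim_dir)
    expect_lte(abs(tab[["left"]] - tab[["right"]]), 1)
    expect_identical(s$trials$outcome == "correct",
                     s$trials$stim_dir == s$trials$resp_dir)
    expect_true(all(diff(s$trials$stim_onset) > 0))
  }
  s1 <- generate_session(n_neurons = 15, n_trials = 20, seed = 99)
  s2 <- generate_session(n_neurons = 15, n_trials = 20, seed = 99)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$trials, s2$trials)
  s0 <- generate_session(n_neurons = 10, n_trials = 20, error_rate = 0,
                         seed = 3)
  expect_identical(sum(s0$trials$outcome == "error"), 0L)
})

test_that("planted selectivity is direction-pure without noise", {
  s <- generate_session(n_neurons = 20, n_trials = 20, mix = c(sample = 1),
                        noise_sd = 0, drift_rate = 0, seed = 4)
  gt <- s$ground_truth
  tensor <- stmdrift:::trial_tensor(s)
  left_trials <- which(s$trials$stim_dir == "left")
  right_trials <- which(s$trials$stim_dir == "right")
  for (j in which(gt$preferred_direction == "right")) {
    # nothing on left trials beyond truncated kernel tails (< 0.5% of peak)
    expect_lt(max(abs(tensor[, j, left_trials])), 0.005)
    expect_gt(max(tensor[, j, right_trials]), 0.9)
  }
})

test_that("without drift, error-trial delay activity matches correct trials", {
  s <- generate_session(n_neurons = 20, n_trials = 24, noise_sd = 0,
                        drift_rate = 0, error_rate = 0.25, seed = 6)
  tensor <- stmdrift:::trial_tensor(s)
  dl <- s$timing$delay_frames
  for (d in c("right", "left")) {
    cor_i <- stmdrift:::cond_trials(s$trials, d, "correct")
    err_i <- stmdrift:::cond_trials(s$trials, d, "error")
    # reward neurons respond only on rewarded trials; compare the rest
    nr <- which(s$ground_truth$selective_phase != "reward")
    expect_equal(tensor[dl, nr, err_i[1]], tensor[dl, nr, cor_i[1]],
                 tolerance = 1e-3)
  }
})

test_that("movies paint disjoint footprints over quiet background", {
  s <- generate_session(n_neurons = 6, n_trials = 12, mix = c(sample = 1),
                        noise_sd = 0, seed = 2)
  mv <- generate_movie(s, neurons = 1:2, footprint_px = 3,
                       image_size = c(16, 16), background_sd = 0, seed = 1)
  expect_equal(length(mv$footprints), 2)
  expect_true(all(mv$overlap <= 1))
  fp <- do.call(rbind, mv$footprints)
  quiet <- apply(mv$stack, c(2, 3), function(v) all(v == 0))
  quiet[fp] <- NA
  expect_true(all(quiet, na.rm = TRUE))
  mv2 <- generate_movie(s, neurons = 1:2, footprint_px = 3,
                        image_size = c(16, 16), background_sd = 0.2, seed = 9)
  mv3 <- generate_movie(s, neurons = 1:2, footprint_px = 3,
                        image_size = c(16, 16), background_sd = 0.2, seed = 9)
  expect_identical(mv2$stack, mv3$stack)
  expect_warning(
    generate_movie(s, neurons = 1:2, footprint_px = 3,
                   image_size = c(16, 16), background_sd = 0,
                   positions = rbind(c(2, 2), c(3, 3))),
    "overlap")
})

test_that("sessions round-trip through plain-text files", {
  s <- generate_session(n_neurons = 8, n_trials = 12, noise_sd = 0.1,
                        seed = 11)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$traces, s$traces, tolerance = 1e-12)
  expect_equal(s2$trials$stim_dir, s$trials$stim_dir)
  expect_equal(s2$ground_truth$preferred_direction,
               s$ground_truth$preferred_direction)
  expect_equal(s2$timing$delay_frames, s$timing$delay_frames)
})
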