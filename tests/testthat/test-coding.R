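test_that("mode vectors are unit-norm window-mean differences", {
  s <- small_session(drift_rate = 0, noise_sd = 0.1, seed = 17,
                     n_neurons = 30, n_trials = 24)
  for (kind in c("CD_sample", "CD_delay", "CD_reward", "D_reward")) {
    m <- compute_mode(s, kind)
    expect_equal(sqrt(sum(m$weights^2)), 1, tolerance = 1e-12)
    expect_equal(m$weights, m$raw_delta / sqrt(sum(m$raw_delta^2)),
                 tolerance = 1e-12)
  }
  # l2 arithmetic on a two-neuron toy session
  m <- compute_mode(s, "CD_delay")
  expect_equal(m$weights, m$raw_delta / sqrt(sum(m$raw_delta^2)))
  # zeroed neurons carry no weight
  mz <- compute_mode(s, "CD_delay", zero_weight_neurons = 1:5)
  expect_equal(mz$weights[1:5], rep(0, 5))
  # degenerate mode: identical right/left averages
  s0 <- s
  s0$traces[] <- 1
  expect_error(compute_mode(s0, "CD_delay"), "degenerate")
})

test_that("Gram-Schmidt yields an orthonormal ordered basis", {
  withr::with_seed(51, {
    vs <- lapply(1:3, function(i) rnorm(20))
    o <- orthogonalize(vs)
    M <- do.call(cbind, o)
    expect_equal(crossprod(M), diag(3), tolerance = 1e-10)
    # already orthonormal inputs are returned unchanged
    o2 <- orthogonalize(o)
    expect_equal(do.call(cbind, o2), M, tolerance = 1e-12)
    # identical vectors collapse
    expect_error(orthogonalize(list(vs[[1]], vs[[1]])), "collapses")
  })
})

test_that("projections follow the mode geometry and normalization", {
  s <- small_session(drift_rate = 0.5, seed = 7, n_neurons = 30,
                     n_trials = 40)
  # unit vector on neuron 1 projects neuron 1's condition average
  m <- compute_mode(s, "CD_delay")
  m$weights <- c(1, rep(0, 29))
  pr <- project_trials(m, s, normalize = FALSE)
  tensor <- stmdrift:::trial_tensor(s)
  avg <- stmdrift:::trial_average(
    tensor, stmdrift:::cond_trials(s$trials, "right", "correct"))
  expect_equal(pr$series$cor_R, avg[, 1], tolerance = 1e-12)
  # normalized correct-right window mean is 1 by construction
  m2 <- compute_mode(s, "CD_delay")
  pn <- project_trials(m2, s, normalize = TRUE)
  expect_equal(mean(pn$series$cor_R[m2$window]), 1, tolerance = 1e-12)
})

test_that("residual separation is the ratio of projected separations", {
  s <- small_session(drift_rate = 0.5, seed = 7)
  pr <- project_trials(compute_mode(s, "CD_delay"), s)
  rs <- residual_separation(pr)
  w <- pr$window
  manual <- (mean(pr$series$err_R[w]) - mean(pr$series$err_L[w])) /
    (mean(pr$series$cor_R[w]) - mean(pr$series$cor_L[w]))
  expect_equal(rs$value, manual, tolerance = 1e-12)
  # error projections identical to correct ones give exactly 1
  pr1 <- pr
  pr1$series$err_R <- pr1$series$cor_R
  pr1$series$err_L <- pr1$series$cor_L
  expect_equal(residual_separation(pr1)$value, 1)
  # identical error sides give 0; swapped sides flip the sign
  pr0 <- pr
  pr0$series$err_L <- pr0$series$err_R
  expect_equal(residual_separation(pr0)$value, 0)
  prs <- pr
  prs$series$err_R <- pr$series$err_L
  prs$series$err_L <- pr$series$err_R
  expect_lt(residual_separation(prs)$value, 0)
})

test_that("orthogonalized sample/delay modes ignore reward-phase activity", {
  s <- small_session(drift_rate = 0, noise_sd = 0.05, seed = 18,
                     n_neurons = 40, n_trials = 40)
  cd <- coding_direction_analysis(s)
  # reward-phase projection along the orthogonalized sample mode is small
  # relative to its own in-window projection
  pr <- project_trials(cd$orthogonalized$CD_sample, s, normalize = FALSE)
  rw <- s$timing$reward_frames
  expect_lt(abs(mean(pr$series$cor_R[rw] - pr$series$cor_L[rw])),
            0.25 * abs(mean(pr$series$cor_R[66:115] -
                              pr$series$cor_L[66:115])))
})

test_that("delay drift shrinks residual separation in the delay window", {
  s <- small_session(drift_rate = 0.5, seed = 7)
  cd <- coding_direction_analysis(s)
  expect_lt(cd$residual_separation$CD_delay, 1)
  expect_lt(cd$residual_separation$CD_delay, cd$residual_separation$CD_sample)
})

test_that("reaction times uncorrelated with coding distance give r near 0", {
  s <- small_session(drift_rate = 0.5, seed = 7)
  rt <- rt_cd_correlation(s)
  expect_lt(abs(rt$pearson_r), 0.3)
  # planted linear dependence is recovered
  s2 <- s
  m <- compute_mode(s2, "CD_delay")
  tensor <- stmdrift:::trial_tensor(s2)
  proj <- vapply(seq_len(nrow(s2$trials)), function(i)
    mean(tensor[141:170, , i] %*% m$weights), numeric(1))
  cr <- stmdrift:::cond_trials(s2$trials, "right", "correct")
  cl <- stmdrift:::cond_trials(s2$trials, "left", "correct")
  bound <- (mean(proj[cr]) + mean(proj[cl])) / 2
  s2$trials$rt_s <- 0.2 - 0.1 * abs(proj - bound)
  rt2 <- rt_cd_correlation(s2)
  expect_lt(rt2$pearson_r, -0.99)
  # constant reaction time is undefined
  s3 <- s
  s3$trials$rt_s <- 0.15
  expect_true(is.na(rt_cd_correlation(s3)$pearson_r))
})
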