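test_that("least-squares amplitudes recover planted event strengths", {
  tpl <- event_template(c(1, 300, 600), 900)
  y <- rowSums(tpl$design) * 2
  fit <- fit_betas(y, tpl)
  expect_equal(fit$betas, rep(2, 3), tolerance = 1e-10)
  # trace orthogonal to all columns
  y0 <- numeric(900); y0[250:260] <- c(-1, rep(0, 9), 1) # before any overlap? no
  tpl2 <- event_template(c(500, 700), 900)
  fit0 <- fit_betas(rep(0, 900), tpl2)
  expect_equal(fit0$betas, c(0, 0))
  # colliding events are rank deficient
  expect_error(fit_betas(rnorm(900), event_template(c(100, 100), 900)),
               "rank-deficient")
  expect_error(fit_betas(rnorm(10), tpl), "lengths differ")
})

test_that("the amplitude t statistic follows the one-sample formula", {
  fit <- stmdrift:::betafit_from_betas(c(1, 2, 3))
  expect_equal(fit$beta_mean, 2)
  expect_equal(fit$beta_sd, 1)
  expect_equal(fit$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(fit$p_value, pt(2 * sqrt(3), df = 2, lower.tail = FALSE))
  # degenerate zero-variance contracts
  all_one <- stmdrift:::betafit_from_betas(rep(1, 5))
  r1 <- test_event_relevance(all_one)
  expect_true(r1$significant)
  expect_equal(r1$p_value, 0)
  all_zero <- stmdrift:::betafit_from_betas(rep(0, 5))
  expect_false(test_event_relevance(all_zero)$significant)
  # symmetric amplitudes around zero are not significant (one-tailed)
  sym <- stmdrift:::betafit_from_betas(rep(c(-1, 1), 10))
  expect_false(test_event_relevance(sym)$significant)
  expect_gt(sym$p_value, 0.4)
})

test_that("amplitude estimates are scale-equivariant, t is invariant", {
  tpl <- event_template(seq(1, 2000, by = 250), 2200)
  y <- rowSums(tpl$design) + synthesize_trace(2200, integer(0),
                                              noise_sd = 0.3, seed = 8)
  f1 <- fit_betas(y, tpl)
  f3 <- fit_betas(3 * y, tpl)
  expect_equal(f3$betas, 3 * f1$betas, tolerance = 1e-10)
  expect_equal(f3$t_statistic, f1$t_statistic, tolerance = 1e-10)
})

test_that("shuffling event frames destroys detection", {
  # planted events at template frames -> highly significant;
  # random event frames -> rejection near the nominal alpha. The shuffled
  # null requires the baseline-offset term: a misaligned template still
  # overlaps the positive-going calcium signal on average, and only the
  # event-locked structure beyond that offset should count.
  n_px <- 400
  ev <- seq(1, 5000, by = 260)
  tpl <- event_template(ev, 5400)
  withr::with_seed(31, {
    Y_sig <- sapply(seq_len(n_px), function(i)
      rowSums(tpl$design) + rnorm(5400, 0, 0.3))
    p_sig <- event_relevance_pvalues(Y_sig, tpl, intercept = TRUE)
    expect_gt(mean(p_sig < 0.05), 0.99)
    rej <- replicate(5, {
      shuf <- event_template(sort(sample(4000, length(ev))), 5400)
      Y <- matrix(rnorm(5400 * n_px, 0, 1), 5400, n_px) +
        rowSums(tpl$design)
      mean(event_relevance_pvalues(Y, shuf, intercept = TRUE) < 0.05)
    })
    expect_lt(mean(rej), 0.12)
  })
})

test_that("Moore-neighbor labeling respects 8-connectivity and size filter", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE      # touch only diagonally
  expect_equal(max(label_components(m)), 1)
  m[5, 5] <- TRUE                       # separate singleton
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(max(label_components(m, min_size = 2)), 1)
  expect_equal(max(label_components(matrix(FALSE, 4, 4))), 0)
})

test_that("pixelwise detection recovers planted footprints", {
  s <- generate_session(n_neurons = 16, n_trials = 20, mix = c(sample = 1),
                        error_rate = 0.2, drift_rate = 0, noise_sd = 0,
                        seed = 9)
  sel <- which(s$ground_truth$preferred_direction == "right")
  mv <- generate_movie(s, neurons = sel, footprint_px = 3,
                       image_size = c(32, 32), background_sd = 0.1, seed = 2)
  det <- detect_rois(mv, s$trials, kinds = "sample_R")
  expect_equal(length(det$rois), length(sel))
  fp <- do.call(rbind, mv$footprints)
  fp_idx <- (fp[, 2] - 1) * 32 + fp[, 1]
  mask <- as.vector(det$roi_labels) > 0
  expect_equal(mean(mask[fp_idx]), 1)          # every footprint pixel
  expect_lte(mean(mask[-fp_idx]), 0.01)        # almost no background
  # all-zero movie yields no ROIs
  mv0 <- mv; mv0$stack[] <- 0
  det0 <- detect_rois(mv0, s$trials, kinds = "sample_R")
  expect_equal(length(det0$rois), 0)
})

test_that("GLM classification recovers planted labels exactly without noise", {
  s <- generate_session(n_neurons = 40, n_trials = 40, noise_sd = 0,
                        drift_rate = 0, sequence = FALSE, seed = 5)
  lab <- classify_neurons(s)
  expect_identical(lab$phase, s$ground_truth$selective_phase)
  expect_identical(lab$direction, s$ground_truth$preferred_direction)
  # single-neuron wrapper agrees
  one <- classify_neuron(s$traces[, 1], s)
  expect_identical(one$phase, lab$phase[1])
})

test_that("a neuron responsive to both directions is nondirectional", {
  s <- generate_session(n_neurons = 8, n_trials = 24, mix = c(delay = 1),
                        noise_sd = 0, drift_rate = 0, sequence = FALSE,
                        seed = 12)
  # superpose a right- and a left-preferring delay neuron
  j_r <- which(s$ground_truth$preferred_direction == "right")[1]
  j_l <- which(s$ground_truth$preferred_direction == "left")[1]
  both <- s$traces[, j_r] + s$traces[, j_l]
  lab <- classify_neuron(both, s)
  expect_identical(lab$phase, "delay")
  expect_identical(lab$direction, "nondirectional")
})

test_that("drifting-baseline exclusion uses a strict inequality", {
  s <- generate_session(n_neurons = 20, n_trials = 24, noise_sd = 0,
                        drift_rate = 0, sequence = FALSE, seed = 13)
  lab <- classify_neurons(s)
  ex <- exclude_drifting_neurons(lab, s)
  # planted neurons respond to their preferred side: nothing excluded
  expect_false(any(ex$excluded_drifting))
  # invert one directional neuron's activity across directions
  j <- which(lab$direction == "right" & lab$primary_phase == "sample")[1]
  s2 <- s
  opp <- s$traces[, which(s$ground_truth$preferred_direction == "left" &
                            s$ground_truth$selective_phase == "sample")[1]]
  s2$traces[, j] <- 0.2 * s$traces[, j] + opp
  ex2 <- exclude_drifting_neurons(lab, s2)
  expect_true(ex2$excluded_drifting[j])
  expect_identical(ex2$direction[j], "none")
})
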