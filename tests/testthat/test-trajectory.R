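test_that("the PCA space captures exact low-dimensional structure", {
  withr::with_seed(41, {
    # data exactly in a 2-D subspace of 6 neurons
    t_grid <- seq(0, 2 * pi, length.out = 50)
    latent <- cbind(sin(t_grid), cos(2 * t_grid))
    W <- matrix(rnorm(12), 2, 6)
    X <- latent %*% W
    m <- fit_trajectory_space(X, n_components = 2)
    expect_equal(sum(m$explained_variance_fraction[1:2]), 1,
                 tolerance = 1e-9)
    expect_equal(crossprod(m$loadings), diag(2), tolerance = 1e-10)
    # permuting neurons permutes loading rows identically
    perm <- sample(6)
    m2 <- fit_trajectory_space(X[, perm], n_components = 2)
    expect_equal(abs(m2$loadings), abs(m$loadings[perm, ]),
                 tolerance = 1e-8)
  })
})

test_that("top-k eigen variance beats every coordinate subset (oracle)", {
  withr::with_seed(42, {
    X <- matrix(rnorm(40 * 10), 40, 10) %*% matrix(rnorm(100), 10, 10)
    m <- fit_trajectory_space(X, n_components = 5)
    Z <- scale(X)
    ev <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)$values
    top5 <- sum(ev[1:5])
    subsets <- utils::combn(10, 5)
    C <- crossprod(Z) / (nrow(Z) - 1)
    for (i in seq_len(ncol(subsets))) {
      idx <- subsets[, i]
      # variance captured by projecting onto these 5 coordinate axes
      expect_lte(sum(diag(C)[idx]), top5 + 1e-9)
    }
    expect_equal(sum(m$explained_variance_fraction[1:5]) * sum(ev), top5,
                 tolerance = 1e-9)
  })
})

test_that("projection reuses the stored normalization", {
  withr::with_seed(43, {
    X <- matrix(rnorm(60 * 8), 60, 8)
    m <- fit_trajectory_space(X, 3)
    sc <- project_trajectory(m, X)
    Z <- sweep(sweep(X, 2, m$mu), 2, m$sigma, "/")
    expect_equal(sc, Z %*% m$loadings, tolerance = 1e-12)
    # constant input maps to the constant point -mu/sigma %*% V
    X0 <- matrix(0, 10, 8)
    p0 <- project_trajectory(m, X0)
    pt <- as.numeric(matrix(-m$mu / m$sigma, 1) %*% m$loadings)
    for (r in 1:10) expect_equal(as.numeric(p0[r, ]), pt, tolerance = 1e-12)
    expect_error(project_trajectory(m, X[, 1:5]), "mismatch")
  })
})

test_that("trajectory distances are metrics frame by frame", {
  withr::with_seed(44, {
    a <- matrix(rnorm(30 * 5), 30, 5)
    b <- matrix(rnorm(30 * 5), 30, 5)
    c3 <- matrix(rnorm(30 * 5), 30, 5)
    expect_equal(trajectory_distance(a, a), rep(0, 30))
    expect_equal(trajectory_distance(a, b), trajectory_distance(b, a))
    expect_true(all(trajectory_distance(a, c3) <=
                      trajectory_distance(a, b) +
                      trajectory_distance(b, c3) + 1e-12))
    # unit offset along one component
    b1 <- a; b1[, 2] <- b1[, 2] + 1
    expect_equal(trajectory_distance(a, b1), rep(1, 30))
  })
})

test_that("the similarity index follows its closed form and bounds", {
  expect_equal(tsi(0, 2), 1)
  expect_equal(tsi(2, 0), -1)
  expect_equal(tsi(1.5, 1.5), 0)
  expect_equal(tsi(3, 1), -0.5)
  expect_true(is.na(tsi(0, 0)))
  expect_error(tsi(-1, 2), "non-negative")
})

test_that("preferred-direction alignment flips labels per neuron", {
  s <- small_session(drift_rate = 0, noise_sd = 0, seed = 8,
                     n_neurons = 20, n_trials = 20)
  dirs <- s$ground_truth$preferred_direction
  pp <- align_to_preferred(s, condition = "PP")
  # all right-preferring: PP equals the right-correct average; a
  # left-preferring neuron's PP column equals its left-correct average
  tensor <- stmdrift:::trial_tensor(s)
  neurons <- attr(pp, "neurons")
  for (i in seq_along(neurons)) {
    j <- neurons[i]
    idx <- stmdrift:::cond_trials(s$trials, dirs[j], "correct")
    expect_equal(pp[, i], rowMeans(tensor[, j, idx]), tolerance = 1e-12)
  }
  # one column per included (directional) neuron
  expect_equal(ncol(pp), sum(dirs %in% c("right", "left")))
  expect_error(align_to_preferred(s, directions = rep("none", 20)),
               "preferred side")
})

test_that("split-trial distances separate conditions and stay positive", {
  s <- small_session(drift_rate = 0.5, seed = 7)
  tr <- trajectory_distances(s, n_iter = 20, seed = 2)
  expect_true(all(tr$d0 >= 0), all(tr$d1 >= 0))
  # PP vs OO separation exceeds the within-PP baseline through the trial
  expect_true(mean(tr$mean$d1[1:170] > tr$mean$d0[1:170]) > 0.95)
  # drift pulls the error trajectory toward the opposite representation
  delay_late <- 161:170
  expect_lt(mean(tr$mean$d_same_resp[delay_late]),
            mean(tr$mean$d_same_resp[121:130]))
  expect_identical(dim(tr$d0), c(20L, 200L))
})

test_that("per-frame distance ROC matches the pairwise oracle", {
  withr::with_seed(45, {
    a <- matrix(rnorm(8 * 6, 2), 8, 6)
    b <- matrix(rnorm(10 * 6), 10, 6)
    r <- distance_roc(a, b)
    for (f in 1:6)
      expect_equal(r[f], auroc_bruteforce(a[, f], b[, f]), tolerance = 1e-12)
    expect_equal(distance_roc(b, b), rep(0.5, 6))
  })
})
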