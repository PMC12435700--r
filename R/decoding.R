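#' Two-class linear discriminant analysis on population vectors
#'
#' Computes the within-class and between-class scatter matrices from the two
#' sample sets, and the leading eigenvector of `solve(S_W) %*% S_B` as the
#' maximum-separation direction. A ridge term (`1e-6 * trace / dim`) is
#' added with a warning when the within-class scatter is singular. The
#' discriminant is unit norm with its sign fixed so class A projects higher.
#'
#' @param class_a,class_b matrices of population vectors, samples in rows.
#' @return An object of class `stm_lda`: `S_W`, `S_B`, `v_max` (unit norm),
#'   `lambda_max`, `m1`, `m2`, `m` (grand mean), `ridge` (0 if unused).
#' @export
fit_lda <- function(class_a, class_b) {
  A <- as.matrix(class_a); B <- as.matrix(class_b)
  if (nrow(A) < 2 || nrow(B) < 2) stop("need at least 2 samples per class")
  if (ncol(A) != ncol(B)) stop("class dimensions differ")
  m1 <- colMeans(A); m2 <- colMeans(B)
  m <- colMeans(rbind(A, B))
  Sw <- crossprod(sweep(A, 2, m1)) + crossprod(sweep(B, 2, m2))
  Sb <- tcrossprod(m1 - m) + tcrossprod(m2 - m)
  ridge <- 0
  Swr <- Sw
  if (rcond(Sw) < 1e-12) {
    ridge <- 1e-6 * sum(diag(Sw)) / ncol(Sw)
    if (ridge == 0) ridge <- 1e-6
    Swr <- Sw + diag(ridge, ncol(Sw))
    warning("singular within-class scatter; ridge term added")
  }
  W <- solve(Swr, Sb)
  eig <- eigen(W)
  v <- Re(eig$vectors[, which.max(Re(eig$values))])
  v <- v / sqrt(sum(v^2))
  if (sum(v * (m1 - m2)) < 0) v <- -v
  out <- list(S_W = Sw, S_B = Sb, v_max = v,
              lambda_max = max(Re(eig$values)),
              m1 = m1, m2 = m2, m = m, ridge = ridge)
  class(out) <- "stm_lda"
  out
}

# Per-trial population vectors (trials x neurons) at each frame of a window,
# stacked: returns list(x = samples x neurons, frame = frame of each sample,
# trial = trial of each sample).
window_samples <- function(tensor, trial_idx, frames) {
  n_f <- length(frames); n_t <- length(trial_idx)
  x <- matrix(NA_real_, n_f * n_t, dim(tensor)[2])
  fr <- integer(n_f * n_t); tr <- integer(n_f * n_t)
  r <- 1L
  for (i in trial_idx) {
    x[r:(r + n_f - 1L), ] <- tensor[frames, , i]
    fr[r:(r + n_f - 1L)] <- frames
    tr[r:(r + n_f - 1L)] <- i
    r <- r + n_f
  }
  list(x = x, frame = fr, trial = tr)
}

# Projected SNR of two trial groups along v: windowed mean absolute
# separation of the per-frame group means, over the root mean squared
# projected within-group deviation from the per-frame group means across the
# whole trial (time-resolved means isolate trial-to-trial noise).
pair_snr <- function(tensor, v, idx1, idx2, frames_win, frames_all) {
  proj <- function(idx, frames) {
    # frames x trials matrix of projections
    vapply(idx, function(i) as.numeric(tensor[frames, , i] %*% v),
           numeric(length(frames)))
  }
  p1w <- proj(idx1, frames_win); p2w <- proj(idx2, frames_win)
  num <- mean(abs(rowMeans(p1w) - rowMeans(p2w)))
  p1 <- proj(idx1, frames_all); p2 <- proj(idx2, frames_all)
  dev <- c(p1 - rowMeans(p1), p2 - rowMeans(p2))
  den <- sqrt(mean(dev^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' LDA signal-to-noise ratio time course
#'
#' For each sliding window, fits the linear discriminant that best separates
#' correct rightward from correct leftward trials on the window's population
#' vectors, then measures the projected signal-to-noise ratio between the
#' members of the requested trial pairing:
#' \itemize{
#'   \item `same_stimulation`: correct vs error trials sharing the stimulus
#'     (RR vs RL, and LL vs LR), averaged over the two pairings;
#'   \item `same_response`: correct vs error trials sharing the response
#'     (RR vs LR, and LL vs RL).
#' }
#' The SNR numerator is the window-mean absolute separation of the projected
#' per-frame group means; the denominator is the root mean squared projected
#' within-group deviation over all task frames. With `normalize = TRUE` the
#' series is divided by its maximum, so the session maximum equals 1.
#'
#' @param session an `stm_session`.
#' @param pairing `"same_stimulation"` or `"same_response"`.
#' @param window_w window width in frames (default 50).
#' @param window_starts window start frames (default every frame that fits).
#' @param normalize divide by the session maximum (default TRUE).
#' @param ridge ridge fraction added to the within-class scatter when
#'   fitting the discriminant in high-dimensional windows (default 1e-6,
#'   applied only if needed).
#' @return data.frame with `window_start`, `snr`, and attribute
#'   `"session_max"` (the pre-normalization maximum).
#' @export
snr_timecourse <- function(session,
                           pairing = c("same_stimulation", "same_response"),
                           window_w = 50, window_starts = NULL,
                           normalize = TRUE, ridge = 1e-6) {
  pairing <- match.arg(pairing)
  tensor <- trial_tensor(session)
  trials <- session$trials
  n_frames <- dim(tensor)[1]
  if (is.null(window_starts))
    window_starts <- seq_len(n_frames - window_w + 1L)
  rr <- cond_trials(trials, "right", "correct")
  ll <- cond_trials(trials, "left", "correct")
  rl <- cond_trials(trials, "right", "error")   # right stim, left response
  lr <- cond_trials(trials, "left", "error")
  pairs <- if (pairing == "same_stimulation")
    list(list(rr, rl), list(ll, lr)) else list(list(rr, lr), list(ll, rl))
  frames_all <- seq_len(n_frames)
  snr <- vapply(window_starts, function(ws) {
    frames <- ws:(ws + window_w - 1L)
    sa <- window_samples(tensor, rr, frames)
    sb <- window_samples(tensor, ll, frames)
    v <- suppressWarnings(fit_lda(sa$x, sb$x))$v_max
    vals <- vapply(pairs, function(p) {
      if (!length(p[[1]]) || !length(p[[2]])) return(NA_real_)
      pair_snr(tensor, v, p[[1]], p[[2]], frames, frames_all)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  session_max <- max(snr, na.rm = TRUE)
  out <- data.frame(window_start = window_starts,
                    snr = if (normalize) snr / session_max else snr)
  attr(out, "session_max") <- session_max
  attr(out, "pairing") <- pairing
  out
}

#' Sliding-window SVM decoding of stimulus direction
#'
#' Trains a linear-kernel support vector machine (cost 1) on a random 70% of
#' correct trials per window (features: per-neuron mean activity within the
#' window, labels: stimulus direction) and evaluates accuracy on (i) the
#' held-out correct trials, (ii) error trials labeled by stimulus direction,
#' (iii) error trials labeled by response direction, and (iv) held-out
#' correct trials with a label-shuffled training set (chance control).
#' Accuracies are averaged over `n_repeats` random splits.
#'
#' @param session an `stm_session`.
#' @param train_fraction fraction of correct trials used for training
#'   (default 0.7, drawn within each direction).
#' @param n_repeats random split repetitions (default 10).
#' @param window_w window width in frames (default 8).
#' @param window_starts window start frames (default every frame that fits).
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame: `window_start`, `acc_correct`, `acc_err_stim`,
#'   `acc_err_resp`, `acc_shuffled`.
#' @export
svm_decode <- function(session, train_fraction = 0.7, n_repeats = 10,
                       window_w = 8, window_starts = NULL, seed = 1) {
  tensor <- trial_tensor(session)
  trials <- session$trials
  n_frames <- dim(tensor)[1]
  if (is.null(window_starts))
    window_starts <- seq_len(n_frames - window_w + 1L)
  cor_r <- cond_trials(trials, "right", "correct")
  cor_l <- cond_trials(trials, "left", "correct")
  err <- which(trials$outcome == "error")
  acc <- matrix(0, length(window_starts), 4,
                dimnames = list(NULL, c("acc_correct", "acc_err_stim",
                                        "acc_err_resp", "acc_shuffled")))
  withr::with_seed(seed, {
    for (wi in seq_along(window_starts)) {
      frames <- window_starts[wi]:(window_starts[wi] + window_w - 1L)
      # trials x neurons window means
      feats <- t(apply(tensor[frames, , , drop = FALSE], 3, colMeans))
      a <- matrix(0, n_repeats, 4)
      for (r in seq_len(n_repeats)) {
        tr_r <- sample(cor_r, max(2, round(train_fraction * length(cor_r))))
        tr_l <- sample(cor_l, max(2, round(train_fraction * length(cor_l))))
        train <- c(tr_r, tr_l)
        test <- setdiff(c(cor_r, cor_l), train)
        y_train <- factor(trials$stim_dir[train], levels = c("left", "right"))
        fit <- e1071::svm(feats[train, , drop = FALSE], y_train,
                          kernel = "linear", cost = 1, scale = FALSE)
        pred_cor <- predict(fit, feats[test, , drop = FALSE])
        a[r, 1] <- mean(pred_cor == trials$stim_dir[test])
        if (length(err)) {
          pred_err <- predict(fit, feats[err, , drop = FALSE])
          a[r, 2] <- mean(pred_err == trials$stim_dir[err])
          a[r, 3] <- mean(pred_err == trials$resp_dir[err])
        } else a[r, 2:3] <- NA_real_
        y_shuf <- sample(y_train)
        fit_s <- e1071::svm(feats[train, , drop = FALSE], y_shuf,
                            kernel = "linear", cost = 1, scale = FALSE)
        a[r, 4] <- mean(predict(fit_s, feats[test, , drop = FALSE]) ==
                          trials$stim_dir[test])
      }
      acc[wi, ] <- colMeans(a)
    }
  })
  data.frame(window_start = window_starts, acc)
}

# Frame bins of the native-space correlation schemes.
correlation_bins <- function(scheme = c("six_25frame_bins", "sliding_15frame"),
                             n_frames = 200) {
  scheme <- match.arg(scheme)
  if (scheme == "six_25frame_bins") {
    starts <- c(21, 46, 71, 96, 121, 146)
    lapply(starts, function(s) s:(s + 24L))
  } else {
    lapply(seq_len(n_frames - 14L), function(s) s:(s + 14L))
  }
}

#' Native-space population activity correlations
#'
#' Pearson correlations between trial-averaged population activity vectors
#' (neurons x frames within a bin, flattened) in the native (un-reduced)
#' space. Within-correct correlations use repeated random 50/50 splits of
#' the correct trials; correct-vs-error correlations compare the correct
#' mean with the same-stimulus error mean. Values are computed per stimulus
#' direction and averaged.
#'
#' @param session an `stm_session`.
#' @param scheme `"six_25frame_bins"` (the sample/delay bins starting at
#'   frame 21) or `"sliding_15frame"` (half-second sliding window, step 1).
#' @param n_splits random split repetitions for the within-correct baseline
#'   (default 20).
#' @param seed integer seed.
#' @return data.frame: `bin`, `frame_start`, `frame_end`, `r_within`,
#'   `r_error` (NA when a direction has no error trials or a vector is
#'   constant).
#' @export
population_correlation <- function(session,
                                   scheme = c("six_25frame_bins",
                                              "sliding_15frame"),
                                   n_splits = 20, seed = 1) {
  scheme <- match.arg(scheme)
  tensor <- trial_tensor(session)
  trials <- session$trials
  bins <- correlation_bins(scheme, dim(tensor)[1])
  dirs <- c("right", "left")
  cor_idx <- lapply(dirs, function(d) cond_trials(trials, d, "correct"))
  err_idx <- lapply(dirs, function(d) cond_trials(trials, d, "error"))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  r_within <- r_error <- numeric(length(bins))
  withr::with_seed(seed, {
    for (bi in seq_along(bins)) {
      fr <- bins[[bi]]
      rw <- vapply(seq_along(dirs), function(di) {
        idx <- cor_idx[[di]]
        mean(vapply(seq_len(n_splits), function(s) {
          a <- sample(idx, floor(length(idx) / 2))
          b <- setdiff(idx, a)
          safe_cor(as.numeric(trial_average(tensor, a)[fr, ]),
                   as.numeric(trial_average(tensor, b)[fr, ]))
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      r_within[bi] <- mean(rw, na.rm = TRUE)
      re <- vapply(seq_along(dirs), function(di) {
        if (!length(err_idx[[di]])) return(NA_real_)
        safe_cor(as.numeric(trial_average(tensor, cor_idx[[di]])[fr, ]),
                 as.numeric(trial_average(tensor, err_idx[[di]])[fr, ]))
      }, numeric(1))
      r_error[bi] <- mean(re, na.rm = TRUE)
    }
  })
  data.frame(bin = seq_along(bins),
             frame_start = vapply(bins, min, 1L),
             frame_end = vapply(bins, max, 1L),
             r_within = r_within, r_error = r_error)
}
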