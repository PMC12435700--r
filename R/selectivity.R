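#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' auROC of the positive-class values against the negative-class values,
#' with ties credited 0.5 (midranks). Equals the exhaustive pairwise count
#' `(wins + 0.5 * ties) / (n_pos * n_neg)`.
#'
#' @param pos,neg numeric vectors of values for the positive and negative
#'   class.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0 || n2 == 0) stop("both classes must be non-empty")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

roc_index <- function(pos, neg) {
  a <- auroc(pos, neg)
  out <- list(auroc = a, index = 2 * (a - 0.5),
              n_pos = length(pos), n_neg = length(neg))
  class(out) <- "stm_roc_index"
  out
}

#' @export
print.stm_roc_index <- function(x, ...) {
  cat(sprintf("ROC index: %.4f (auROC %.4f; n = %d vs %d)\n",
              x$index, x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Preference index (direction selectivity)
#'
#' ROC-based direction selectivity on trial-mean responses:
#' `PI = 2 * (auROC - 0.5)` with rightward trials as the positive class, so
#' +1 indicates perfect right preference, -1 perfect left preference and 0
#' no directional bias. Identical value sets on both sides give PI = 0.
#'
#' @param trial_means_right per-trial mean activity on rightward trials.
#' @param trial_means_left per-trial mean activity on leftward trials.
#' @return an `stm_roc_index` (fields `auroc`, `index`, `n_pos`, `n_neg`).
#' @export
#' @examples
#' preference_index(c(1, 2, 3), c(2, 3, 4))$index  # -5/9
preference_index <- function(trial_means_right, trial_means_left) {
  if (length(trial_means_right) < 2 || length(trial_means_left) < 2)
    stop("need at least 2 trials per side")
  roc_index(trial_means_right, trial_means_left)
}

#' Reliability index (trial-to-trial consistency)
#'
#' Same ROC construction as the preference index but applied to pooled
#' single-trial per-frame values (no trial averaging), so it measures how
#' consistently individual frames separate the two directions. Callers
#' normally pass values normalized to the neuron's maximum activity across
#' the whole trial (see [selectivity_table()]).
#'
#' @param frame_values_right,frame_values_left pooled per-frame values from
#'   individual rightward / leftward trials.
#' @return an `stm_roc_index`.
#' @export
reliability_index <- function(frame_values_right, frame_values_left) {
  roc_index(frame_values_right, frame_values_left)
}

#' Phase selectivity index
#'
#' ROC index comparing trial-averaged activity during the phase of interest
#' (positive class) against the pooled activity of the remaining phases.
#'
#' @param in_phase_values trial-averaged activity in the preferred phase.
#' @param out_phase_values pooled activity from the other phases.
#' @return an `stm_roc_index`.
#' @export
phase_selectivity_index <- function(in_phase_values, out_phase_values) {
  roc_index(in_phase_values, out_phase_values)
}

#' Permutation validation of phase selectivity
#'
#' For a phase-selective neuron, the per-trial selectivity index is the mean
#' activity in the preferred phase minus the mean of the nonpreferred phases
#' on that trial. A null distribution is built by shuffling the phase labels
#' across trials `n_perm` times (all trial-by-phase mean values are pooled
#' and randomly reassigned to phase slots); the observed session-mean index
#' is then
#' expressed as a Z-score against the null means, the neuron is significant
#' when the observed index exceeds the null's 95th percentile (one-tailed
#' p < 0.05), and the per-trial pass fraction is the fraction of trials
#' whose observed index exceeds that same threshold.
#'
#' @param trace single-neuron trace over the session.
#' @param session the session (for trials and timing).
#' @param preferred_phase `"sample"`, `"delay"` or `"reward"`.
#' @param n_perm number of label shuffles (default 1000).
#' @param seed integer seed (required for reproducibility).
#' @param correct_only use correct trials only (default).
#' @param trials_subset optional trial indices restricting the analysis
#'   (e.g. the preferred-direction trials of a directional neuron, which is
#'   silent on opposite-direction trials).
#' @return An object of class `stm_permutation`: list with `observed_index`
#'   (session mean), `per_trial_index`, `null_distribution` (null session
#'   means), `z_score` (NA if the null has zero spread), `percentile_95`
#'   (the one-tailed p < 0.05 null threshold), `significant` and
#'   `trial_pass_fraction`.
#' @export
permutation_validation <- function(trace, session, preferred_phase,
                                   n_perm = 1000, seed = 1,
                                   correct_only = TRUE,
                                   trials_subset = NULL) {
  phases <- c("sample", "delay", "reward")
  stopifnot(preferred_phase %in% phases)
  trials <- session$trials
  idx <- if (correct_only) which(trials$outcome == "correct")
         else seq_len(nrow(trials))
  if (!is.null(trials_subset)) idx <- intersect(idx, trials_subset)
  if (length(idx) < 2) stop("need at least 2 trials")
  starts <- session$trial_starts[idx]
  pm <- sapply(phases, function(ph) {
    pf <- phase_frames(session$timing, ph)
    vapply(starts, function(st) mean(trace[st + pf - 1L]), numeric(1))
  })                                         # trials x 3 phase means
  pref_col <- match(preferred_phase, phases)
  obs_trial <- pm[, pref_col] - rowMeans(pm[, -pref_col, drop = FALSE])
  observed <- mean(obs_trial)

  n_tr <- nrow(pm)
  vals <- as.numeric(pm)
  withr::with_seed(seed, {
    null_means <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      shuffled <- matrix(sample(vals), n_tr, 3)
      null_means[b] <- mean(shuffled[, pref_col] -
                              rowMeans(shuffled[, -pref_col, drop = FALSE]))
    }
  })
  null_sd <- stats::sd(null_means)
  z <- if (null_sd > 0) (observed - mean(null_means)) / null_sd else NA_real_
  thr <- stats::quantile(null_means, 0.95, names = FALSE)
  out <- list(observed_index = observed, per_trial_index = obs_trial,
              null_distribution = null_means, z_score = z,
              percentile_95 = thr,
              significant = observed > thr,
              trial_pass_fraction = mean(obs_trial > thr),
              n_perm = n_perm, preferred_phase = preferred_phase)
  class(out) <- "stm_permutation"
  out
}

#' Per-neuron selectivity metrics for a session
#'
#' Computes, for every neuron with a directional label, the preference index
#' (trial-mean activity in its selective phase, right vs left correct
#' trials), the reliability index (pooled per-frame single-trial values
#' normalized to the neuron's maximum activity across the whole trial), the
#' phase selectivity index, and the permutation Z-score / per-trial pass
#' fraction for its selective phase.
#'
#' @param session an `stm_session`.
#' @param labels classification table from [classify_neurons()]; defaults to
#'   computing it.
#' @param n_perm permutation count for the Z-score (default 1000).
#' @param seed integer seed.
#' @return data.frame: `neuron`, `phase`, `direction`, `PI`, `RI`, `PSI`,
#'   `z`, `trial_pass_frac`.
#' @export
selectivity_table <- function(session, labels = NULL, n_perm = 1000,
                              seed = 1) {
  if (is.null(labels)) labels <- classify_neurons(session)
  tensor <- trial_tensor(session)
  trials <- session$trials
  timing <- session$timing
  cor_r <- cond_trials(trials, "right", "correct")
  cor_l <- cond_trials(trials, "left", "correct")
  cor_all <- c(cor_r, cor_l)
  res <- labels[, c("neuron", "phase", "direction")]
  res$PI <- res$RI <- res$PSI <- res$z <- res$trial_pass_frac <- NA_real_
  for (j in seq_len(nrow(labels))) {
    ph <- if (!is.null(labels$primary_phase)) labels$primary_phase[j]
          else strsplit(labels$phase[j], ",")[[1]][1]
    if (ph == "none") next
    pf <- phase_frames(timing, ph)
    mean_r <- apply(tensor[pf, j, cor_r, drop = FALSE], 3, mean)
    mean_l <- apply(tensor[pf, j, cor_l, drop = FALSE], 3, mean)
    res$PI[j] <- preference_index(mean_r, mean_l)$index
    mx <- max(abs(tensor[, j, cor_all]))
    if (mx == 0) mx <- 1
    fr_r <- as.numeric(tensor[pf, j, cor_r]) / mx
    fr_l <- as.numeric(tensor[pf, j, cor_l]) / mx
    res$RI[j] <- reliability_index(fr_r, fr_l)$index
    out_f <- setdiff(seq_len(timing$n_frames_trial), pf)
    in_vals <- apply(tensor[pf, j, cor_all, drop = FALSE], 3, mean)
    out_vals <- apply(tensor[out_f, j, cor_all, drop = FALSE], 3, mean)
    res$PSI[j] <- phase_selectivity_index(in_vals, out_vals)$index
    dir <- if (!is.null(labels$primary_direction)) labels$primary_direction[j]
           else labels$direction[j]
    subset <- if (dir %in% c("right", "left"))
      cond_trials(trials, stim = dir) else NULL
    pv <- permutation_validation(session$traces[, j], session, ph,
                                 n_perm = n_perm,
                                 seed = sub_seed(seed, j),
                                 trials_subset = subset)
    res$z[j] <- pv$z_score
    res$trial_pass_frac[j] <- pv$trial_pass_fraction
  }
  res
}
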