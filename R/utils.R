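# Internal helpers shared across analysis stages.

# frames x neurons x trials array, restricted to within-trial task frames.
trial_tensor <- function(session, frames = NULL) {
  timing <- session$timing
  if (is.null(frames)) frames <- seq_len(timing$n_frames_trial)
  n_tr <- nrow(session$trials)
  starts <- session$trial_starts
  out <- array(NA_real_, dim = c(length(frames), ncol(session$traces), n_tr))
  for (i in seq_len(n_tr))
    out[, , i] <- session$traces[starts[i] + frames - 1L, , drop = FALSE]
  out
}

# Trial indices for a stimulus direction / outcome combination.
cond_trials <- function(trials, stim = NULL, outcome = NULL, resp = NULL) {
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(stim)) keep <- keep & trials$stim_dir == stim
  if (!is.null(outcome)) keep <- keep & trials$outcome == outcome
  if (!is.null(resp)) keep <- keep & trials$resp_dir == resp
  which(keep)
}

# frames x neurons average over the given trials of a trial tensor.
trial_average <- function(tensor, trial_idx) {
  if (length(trial_idx) == 0)
    stop("cannot average over zero trials")
  if (length(trial_idx) == 1) return(tensor[, , trial_idx])
  apply(tensor[, , trial_idx, drop = FALSE], c(1, 2), mean)
}

opposite_dir <- function(d) ifelse(d == "right", "left", "right")

# Derive a reproducible sub-seed (kept below 2^31) from a base seed.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
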