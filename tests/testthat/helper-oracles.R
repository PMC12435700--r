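# Independent oracles used to cross-check the implementation on tiny inputs.

# Exhaustive pairwise auROC: (wins + 0.5 * ties) / (n_pos * n_neg).
auroc_bruteforce <- function(pos, neg) {
  wins <- ties <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(pos) * length(neg))
}

# Exhaustive 1-degree grid search for the best 2-D discriminant direction:
# maximizes projected between-class mean separation^2 over projected
# within-class variance.
lda_gridsearch_2d <- function(a, b) {
  best <- NULL; best_j <- -Inf
  for (deg in 0:179) {
    v <- c(cos(deg * pi / 180), sin(deg * pi / 180))
    pa <- a %*% v; pb <- b %*% v
    sw <- sum((pa - mean(pa))^2) + sum((pb - mean(pb))^2)
    if (sw == 0) next
    j <- (mean(pa) - mean(pb))^2 / sw
    if (j > best_j) { best_j <- j; best <- v }
  }
  best
}

# Small deterministic session fixtures shared across test files.
small_session <- function(drift_rate = 0.5, noise_sd = 0.2, seed = 7,
                          n_neurons = 60, n_trials = 60, ...) {
  generate_session(n_neurons = n_neurons, n_trials = n_trials,
                   drift_rate = drift_rate, noise_sd = noise_sd,
                   seed = seed, ...)
}
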