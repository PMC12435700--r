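#' Fit the PCA trajectory space from correct-trial averages
#'
#' Z-scores each neuron's trial-averaged activity (columns of the frames x
#' neurons matrix), forms the neuron-by-neuron covariance of the Z-scored
#' data and keeps the loadings of the top `n_components` eigenvectors. The
#' stored means and standard deviations are reused when projecting held-out
#' data, so projections of error trials are expressed in the correct-trial
#' space. Zero-variance neurons receive a standard-deviation floor of 1e-12
#' and are flagged.
#'
#' @param correct_trial_averages frames x neurons matrix of trial-averaged
#'   activity from (a subset of) correct trials.
#' @param n_components number of retained components (default 5).
#' @return An object of class `stm_trajectory_model`: `loadings` (neurons x
#'   n_components, orthonormal columns), `explained_variance_fraction` (for
#'   all components), `mu`, `sigma`, `flagged_zero_variance`.
#' @export
fit_trajectory_space <- function(correct_trial_averages, n_components = 5) {
  X <- as.matrix(correct_trial_averages)
  if (ncol(X) < n_components)
    stop("need at least n_components neurons")
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  flagged <- sigma < 1e-12
  sigma[flagged] <- 1e-12
  Z <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  C <- crossprod(Z) / (nrow(Z) - 1)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  out <- list(loadings = eig$vectors[, seq_len(n_components), drop = FALSE],
              n_components = n_components,
              explained_variance_fraction = ev / sum(ev),
              mu = mu, sigma = sigma,
              flagged_zero_variance = which(flagged))
  class(out) <- "stm_trajectory_model"
  out
}

#' Project trial-averaged activity into the trajectory space
#'
#' Z-scores the input with the model's stored means and standard deviations
#' and multiplies by the loadings, yielding a frames x n_components
#' trajectory.
#'
#' @param model an `stm_trajectory_model`.
#' @param trial_averages frames x neurons matrix over the same neuron set
#'   and ordering used to fit the model.
#' @return frames x n_components matrix.
#' @export
project_trajectory <- function(model, trial_averages) {
  X <- as.matrix(trial_averages)
  if (ncol(X) != length(model$mu))
    stop("neuron set mismatch: model has ", length(model$mu),
         " neurons, input has ", ncol(X))
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sigma, "/")
  Z %*% model$loadings
}

#' Per-frame Euclidean distance between two trajectories
#'
#' @param a,b frames x components matrices.
#' @return numeric vector of per-frame distances.
#' @export
trajectory_distance <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(rowSums((a - b)^2))
}

#' Trajectory similarity index
#'
#' `TSI = (dOO - dPP) / (dOO + dPP)`: positive when the activity is nearer
#' the preferred-correct (PP) trajectory, negative when nearer the
#' opposite-correct (OO) trajectory, bounded in `[-1, 1]`. Undefined
#' (returned as `NA`) when both distances are zero.
#'
#' @param d_pp,d_oo non-negative distances to the PP and OO trajectories
#'   (vectorized).
#' @return numeric vector in `[-1, 1]` (or `NA` where both inputs are 0).
#' @export
#' @examples
#' tsi(0, 2)   # +1
#' tsi(3, 1)   # -0.5
tsi <- function(d_pp, d_oo) {
  if (any(d_pp < 0, na.rm = TRUE) || any(d_oo < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  s <- d_pp + d_oo
  ifelse(s > 0, (d_oo - d_pp) / s, NA_real_)
}

#' Preferred-direction-aligned trial averages
#'
#' Aligns every directional neuron to a common preferred axis: for
#' left-preferring neurons the left/right trial labels are swapped, so that
#' condition codes are shared across the population ("PP" = preferred
#' stimulus, preferred/correct response; "OO" = opposite-correct; "PO" =
#' preferred stimulus, opposite/incorrect response; "OP" the reverse error).
#' Returns the frames x neurons trial-averaged activity of one aligned
#' condition; neurons without a preferred side are excluded.
#'
#' @param session an `stm_session`.
#' @param directions per-neuron preferred side (`"right"`/`"left"`; any
#'   other value excludes the neuron); defaults to the session's planted
#'   ground truth.
#' @param condition one of `"PP"`, `"OO"`, `"PO"`, `"OP"`.
#' @param frames within-trial frames (default all task frames).
#' @return frames x (included neurons) matrix with attribute `"neurons"`
#'   giving the included neuron indices.
#' @export
align_to_preferred <- function(session, directions = NULL,
                               condition = c("PP", "OO", "PO", "OP"),
                               frames = NULL) {
  condition <- match.arg(condition)
  if (is.null(directions)) {
    if (is.null(session$ground_truth))
      stop("no directions supplied and session has no ground truth")
    directions <- session$ground_truth$preferred_direction
  }
  neurons <- which(directions %in% c("right", "left"))
  if (!length(neurons)) stop("no neuron has a preferred side")
  tensor <- trial_tensor(session, frames)
  out <- aligned_condition_average(tensor, session$trials, directions,
                                   neurons, condition)
  if (is.null(out)) stop("a neuron has no trials in condition ", condition)
  attr(out, "neurons") <- neurons
  out
}

# Per-neuron aligned condition averages. directions: per-neuron preferred
# side ("right"/"left"; anything else excludes the neuron). Returns frames x
# neurons matrices for the requested aligned condition.
aligned_condition_average <- function(tensor, trials, directions, neurons,
                                      condition = c("PP", "OO", "PO", "OP"),
                                      trial_pool = NULL) {
  condition <- match.arg(condition)
  out <- matrix(NA_real_, dim(tensor)[1], length(neurons))
  for (i in seq_along(neurons)) {
    j <- neurons[i]
    pref <- directions[j]
    opp <- opposite_dir(pref)
    idx <- switch(condition,
      PP = cond_trials(trials, stim = pref, outcome = "correct"),
      OO = cond_trials(trials, stim = opp, outcome = "correct"),
      PO = cond_trials(trials, stim = pref, outcome = "error"),
      OP = cond_trials(trials, stim = opp, outcome = "error"))
    if (!is.null(trial_pool)) idx <- intersect(idx, trial_pool)
    if (!length(idx)) return(NULL)
    out[, i] <- if (length(idx) == 1) tensor[, j, idx]
                else rowMeans(tensor[, j, idx])
  }
  out
}

#' Trajectory distances and similarity index for a session
#'
#' Implements the split-trial trajectory analysis: on each of `n_iter`
#' random iterations, 50% of the correct trials (drawn within each stimulus
#' direction) fit the PCA space on preferred-aligned trial averages; the
#' remaining correct trials and all error trials are projected into that
#' space. Per frame the analysis records
#' \itemize{
#'   \item `d0` - distance between the fitting-half PP trajectory and the
#'     held-out PP trajectory (trial-by-trial variability baseline),
#'   \item `d1` - distance between held-out PP and OO trajectories,
#'   \item `d_same_stim` - distance between PP and the error-trial PO
#'     trajectory (same stimulus, opposite response),
#'   \item `d_same_resp` - distance between OO and PO (same response),
#'   \item `tsi` - the trajectory similarity index of the PO trajectory,
#'     using `dPP = d_same_stim` and `dOO = d_same_resp`.
#' }
#' Error trials never enter the PCA fit.
#'
#' @param session an `stm_session`.
#' @param directions per-neuron preferred side (`"right"`/`"left"`); default
#'   uses the session's planted ground truth. Neurons without a side are
#'   excluded.
#' @param n_components retained components (default 5).
#' @param n_iter random split iterations (default 100).
#' @param seed integer seed.
#' @param frames within-trial frames analyzed (default all task frames).
#' @return An object of class `stm_trajectories`: list of `n_iter` x frames
#'   matrices (`d0`, `d1`, `d_same_stim`, `d_same_resp`, `tsi`), their
#'   column means (`mean`, a data.frame), the neuron set used, and the last
#'   fitted model's explained variance.
#' @export
trajectory_distances <- function(session, directions = NULL,
                                 n_components = 5, n_iter = 100, seed = 1,
                                 frames = NULL) {
  if (is.null(directions)) {
    if (is.null(session$ground_truth))
      stop("no directions supplied and session has no ground truth")
    directions <- session$ground_truth$preferred_direction
  }
  neurons <- which(directions %in% c("right", "left"))
  if (length(neurons) < n_components)
    stop("need at least n_components directional neurons")
  tensor <- trial_tensor(session, frames)
  trials <- session$trials
  n_frames <- dim(tensor)[1]
  cor_r <- cond_trials(trials, "right", "correct")
  cor_l <- cond_trials(trials, "left", "correct")
  if (min(length(cor_r), length(cor_l)) < 4)
    stop("need at least 4 correct trials per direction for the d0 split")
  has_err <- any(trials$outcome == "error")

  m <- matrix(NA_real_, n_iter, n_frames)
  res <- list(d0 = m, d1 = m, d_same_stim = m, d_same_resp = m, tsi = m)
  model <- NULL
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      a_r <- sample(cor_r, floor(length(cor_r) / 2))
      a_l <- sample(cor_l, floor(length(cor_l) / 2))
      half_a <- c(a_r, a_l)
      half_b <- setdiff(c(cor_r, cor_l), half_a)
      pp_a <- aligned_condition_average(tensor, trials, directions, neurons,
                                        "PP", half_a)
      pp_b <- aligned_condition_average(tensor, trials, directions, neurons,
                                        "PP", half_b)
      oo_b <- aligned_condition_average(tensor, trials, directions, neurons,
                                        "OO", half_b)
      model <- fit_trajectory_space(pp_a, n_components)
      tr_pp_a <- project_trajectory(model, pp_a)
      tr_pp_b <- project_trajectory(model, pp_b)
      tr_oo_b <- project_trajectory(model, oo_b)
      res$d0[it, ] <- trajectory_distance(tr_pp_a, tr_pp_b)
      res$d1[it, ] <- trajectory_distance(tr_pp_b, tr_oo_b)
      if (has_err) {
        po <- aligned_condition_average(tensor, trials, directions, neurons,
                                        "PO")
        tr_po <- project_trajectory(model, po)
        res$d_same_stim[it, ] <- trajectory_distance(tr_pp_b, tr_po)
        res$d_same_resp[it, ] <- trajectory_distance(tr_oo_b, tr_po)
        res$tsi[it, ] <- tsi(res$d_same_stim[it, ], res$d_same_resp[it, ])
      }
    }
  })
  mean_df <- data.frame(frame = seq_len(n_frames),
                        d0 = colMeans(res$d0),
                        d1 = colMeans(res$d1),
                        d_same_stim = colMeans(res$d_same_stim),
                        d_same_resp = colMeans(res$d_same_resp),
                        tsi = colMeans(res$tsi))
  out <- c(res, list(mean = mean_df, neurons = neurons,
                     explained_variance =
                       if (!is.null(model)) model$explained_variance_fraction,
                     n_iter = n_iter, n_components = n_components))
  class(out) <- "stm_trajectories"
  out
}

#' Per-frame ROC comparison of two distance distributions
#'
#' Compares two per-iteration distance series frame by frame with the same
#' auROC machinery used for the selectivity indices.
#'
#' @param series_a,series_b iterations x frames matrices (e.g. the `d0` and
#'   `d1` components of an `stm_trajectories` object). `series_a` is the
#'   positive class.
#' @return numeric vector of per-frame auROC values.
#' @export
distance_roc <- function(series_a, series_b) {
  stopifnot(ncol(series_a) == ncol(series_b),
            nrow(series_a) >= 2, nrow(series_b) >= 2)
  vapply(seq_len(ncol(series_a)),
         function(f) auroc(series_a[, f], series_b[, f]), numeric(1))
}
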