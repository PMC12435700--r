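# Default mode windows (within-trial frames, 30 Hz layout): the sample mode
# uses a 1.7 s window starting mid-sample, the delay mode the full delay,
# the reward mode the reward second, and the nonselective ramping mode
# contrasts the last delay second with the reward second.
mode_windows <- function() {
  list(CD_sample = 66:115, CD_delay = 121:170, CD_reward = 171:200,
       D_reward = list(late_delay = 141:170, reward = 171:200))
}

#' Compute a coding-direction (or ramping) mode vector
#'
#' For the coding-direction kinds (`CD_sample`, `CD_delay`, `CD_reward`) the
#' raw mode is the per-neuron difference of window-averaged trial-averaged
#' activity between correct rightward and correct leftward trials; for the
#' nonselective ramping mode (`D_reward`) it is the difference between the
#' first reward second and the last delay second, pooling correct trials of
#' both directions. The mode is normalized to unit l2 norm so projections do
#' not depend on the number of recorded neurons; neurons can be zeroed out
#' via `zero_weight_neurons` (e.g. neurons absent in a trial).
#'
#' @param session an `stm_session`.
#' @param kind one of `"CD_sample"`, `"CD_delay"`, `"CD_reward"`,
#'   `"D_reward"`.
#' @param window optional frame window override (for CD kinds).
#' @param zero_weight_neurons indices whose weight is forced to zero before
#'   normalization.
#' @return An object of class `stm_mode`: `weights` (unit norm), `raw_delta`,
#'   `kind`, `window`.
#' @export
compute_mode <- function(session, kind = c("CD_sample", "CD_delay",
                                           "CD_reward", "D_reward"),
                         window = NULL, zero_weight_neurons = integer(0)) {
  kind <- match.arg(kind)
  tensor <- trial_tensor(session)
  trials <- session$trials
  cor_r <- cond_trials(trials, "right", "correct")
  cor_l <- cond_trials(trials, "left", "correct")
  if (kind == "D_reward") {
    w <- mode_windows()$D_reward
    avg <- trial_average(tensor, c(cor_r, cor_l))
    delta <- colMeans(avg[w$reward, , drop = FALSE]) -
      colMeans(avg[w$late_delay, , drop = FALSE])
    window <- w
  } else {
    if (is.null(window)) window <- mode_windows()[[kind]]
    avg_r <- trial_average(tensor, cor_r)
    avg_l <- trial_average(tensor, cor_l)
    delta <- colMeans(avg_r[window, , drop = FALSE]) -
      colMeans(avg_l[window, , drop = FALSE])
  }
  delta[zero_weight_neurons] <- 0
  nrm <- sqrt(sum(delta^2))
  if (nrm == 0) stop("degenerate mode: identical condition averages")
  out <- list(weights = delta / nrm, raw_delta = delta, kind = kind,
              window = window)
  class(out) <- "stm_mode"
  out
}

#' Gram-Schmidt orthogonalization of mode vectors
#'
#' Orthogonalizes the modes in the given order; each output is unit norm and
#' pairwise inner products vanish to numerical precision. A mode that
#' collapses (norm below `tol` after removing the preceding components) is
#' an error naming the offending mode.
#'
#' @param modes ordered list of `stm_mode` objects (or bare numeric
#'   vectors) of common dimension.
#' @param tol collapse tolerance on the residual norm (default 1e-10).
#' @return list of `stm_mode` objects with orthonormal `weights`.
#' @export
orthogonalize <- function(modes, tol = 1e-10) {
  vecs <- lapply(modes, function(m)
    if (inherits(m, "stm_mode")) m$weights else as.numeric(m))
  d <- unique(vapply(vecs, length, 1L))
  if (length(d) != 1) stop("modes must have the same dimension")
  out <- modes
  basis <- list()
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    for (b in basis) v <- v - sum(v * b) * b
    nrm <- sqrt(sum(v^2))
    nm <- if (inherits(modes[[i]], "stm_mode")) modes[[i]]$kind else
      paste0("mode ", i)
    if (nrm < tol) stop("mode collapses after orthogonalization: ", nm)
    v <- v / nrm
    basis[[length(basis) + 1]] <- v
    if (inherits(out[[i]], "stm_mode")) out[[i]]$weights <- v
    else out[[i]] <- v
  }
  out
}

#' Project condition-averaged activity onto a mode
#'
#' Computes per-frame projections `P(t) = x(t)' m` of the trial-averaged
#' population activity of the four outcome conditions (correct/error x
#' right/left stimulus). With `normalize = TRUE` every projection is divided
#' by the mean correct-rightward projection inside the mode's window, so the
#' normalized correct-right window mean equals 1 by construction.
#'
#' @param mode an `stm_mode`.
#' @param session an `stm_session`.
#' @param normalize logical (default TRUE).
#' @return An object of class `stm_projection`: data.frame `series` with
#'   columns `frame`, `cor_R`, `cor_L`, `err_R`, `err_L` (error columns NA
#'   when a condition has no trials), plus `normalization` and `window`.
#' @export
project_trials <- function(mode, session, normalize = TRUE) {
  tensor <- trial_tensor(session)
  trials <- session$trials
  conds <- list(cor_R = cond_trials(trials, "right", "correct"),
                cor_L = cond_trials(trials, "left", "correct"),
                err_R = cond_trials(trials, "right", "error"),
                err_L = cond_trials(trials, "left", "error"))
  n_frames <- dim(tensor)[1]
  series <- data.frame(frame = seq_len(n_frames))
  for (nm in names(conds)) {
    series[[nm]] <- if (length(conds[[nm]]))
      as.numeric(trial_average(tensor, conds[[nm]]) %*% mode$weights)
    else NA_real_
  }
  win <- if (is.list(mode$window)) mode$window$reward else mode$window
  norm_const <- mean(series$cor_R[win])
  if (normalize) {
    if (norm_const == 0) {
      warning("normalization constant is zero; returning unnormalized projections")
      normalize <- FALSE
    } else {
      for (nm in names(conds)) series[[nm]] <- series[[nm]] / norm_const
    }
  }
  out <- list(series = series, normalization = norm_const,
              normalized = normalize, window = win, kind = mode$kind)
  class(out) <- "stm_projection"
  out
}

#' Residual separation of error-trial projections
#'
#' Ratio of the incorrect-trial separation to the correct-trial separation
#' of window-averaged projections along a mode:
#' `(mean Rincorrect - mean Lincorrect) / (mean Rcorrect - mean Lcorrect)`.
#' A value of 1 means error trials separate as well as correct trials; 0
#' means no residual separation; a negative value means the separation is
#' reversed.
#'
#' @param proj an `stm_projection` (all four conditions present).
#' @param window frame window over which projections are averaged; defaults
#'   to the projection's mode window.
#' @return list with `value` (NA with a warning if the correct-trial
#'   separation is zero) and `window`.
#' @export
residual_separation <- function(proj, window = NULL) {
  if (is.null(window)) window <- proj$window
  s <- proj$series
  if (anyNA(s$err_R[window]) || anyNA(s$err_L[window]))
    stop("all four conditions must be present")
  num <- mean(s$err_R[window]) - mean(s$err_L[window])
  den <- mean(s$cor_R[window]) - mean(s$cor_L[window])
  if (den == 0) {
    warning("zero correct-trial separation; residual separation undefined")
    return(list(value = NA_real_, window = window))
  }
  list(value = num / den, window = window)
}

#' Correlation between reaction time and delay coding-direction distance
#'
#' Projects each trial's population activity onto the delay coding
#' direction, averages the projection over the final second of the delay,
#' measures each trial's absolute distance to the decision boundary (the
#' midpoint between the mean correct-right and correct-left projections) and
#' correlates it with the trial's relative reaction time (deviation from the
#' session median RT).
#'
#' @param session an `stm_session` whose trial table carries an `rt_s`
#'   column.
#' @param mode the delay coding direction; defaults to
#'   `compute_mode(session, "CD_delay")`.
#' @param window frames averaged per trial (default the last delay second,
#'   frames 141-170).
#' @param trials_subset optional trial indices (default all trials).
#' @return list with `pearson_r`, `p_value`, `n`, and the per-trial
#'   `distance` and `relative_rt` (r is NA with constant RT).
#' @export
rt_cd_correlation <- function(session, mode = NULL, window = 141:170,
                              trials_subset = NULL) {
  if (is.null(mode)) mode <- compute_mode(session, "CD_delay")
  trials <- session$trials
  if (is.null(trials$rt_s)) stop("trial table has no rt_s column")
  idx <- if (is.null(trials_subset)) seq_len(nrow(trials)) else trials_subset
  if (length(idx) < 3) stop("need at least 3 trials")
  tensor <- trial_tensor(session)
  proj <- vapply(idx, function(i)
    mean(tensor[window, , i] %*% mode$weights), numeric(1))
  cor_r <- intersect(idx, cond_trials(trials, "right", "correct"))
  cor_l <- intersect(idx, cond_trials(trials, "left", "correct"))
  pr <- vapply(match(cor_r, idx), function(i) proj[i], numeric(1))
  pl <- vapply(match(cor_l, idx), function(i) proj[i], numeric(1))
  boundary <- (mean(pr) + mean(pl)) / 2
  distance <- abs(proj - boundary)
  rel_rt <- trials$rt_s[idx] - stats::median(trials$rt_s[idx])
  if (stats::sd(rel_rt) == 0 || stats::sd(distance) == 0)
    return(list(pearson_r = NA_real_, p_value = NA_real_, n = length(idx),
                distance = distance, relative_rt = rel_rt))
  ct <- stats::cor.test(distance, rel_rt)
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(idx), distance = distance, relative_rt = rel_rt)
}

#' Full coding-direction analysis of a session
#'
#' Computes the sample, delay and reward coding directions and the
#' nonselective ramping mode, orthogonalizes them in the two declared orders
#' (reward mode, ramping mode, then sample; and reward mode, ramping mode,
#' then delay), projects the four outcome conditions onto the orthogonalized
#' sample and delay directions, and reports the residual separation in each
#' mode's window.
#'
#' @param session an `stm_session`.
#' @param normalize normalize projections by the correct-right window mean.
#' @return list with `modes` (raw), `orthogonalized` (named list with
#'   `CD_sample` and `CD_delay`), `projections`, `residual_separation`.
#' @export
coding_direction_analysis <- function(session, normalize = TRUE) {
  modes <- list(CD_sample = compute_mode(session, "CD_sample"),
                CD_delay = compute_mode(session, "CD_delay"),
                CD_reward = compute_mode(session, "CD_reward"),
                D_reward = compute_mode(session, "D_reward"))
  o_sample <- orthogonalize(list(modes$CD_reward, modes$D_reward,
                                 modes$CD_sample))[[3]]
  o_delay <- orthogonalize(list(modes$CD_reward, modes$D_reward,
                                modes$CD_delay))[[3]]
  proj <- list(CD_sample = project_trials(o_sample, session, normalize),
               CD_delay = project_trials(o_delay, session, normalize))
  rs <- list(CD_sample = residual_separation(proj$CD_sample)$value,
             CD_delay = residual_separation(proj$CD_delay)$value)
  list(modes = modes,
       orthogonalized = list(CD_sample = o_sample, CD_delay = o_delay),
       projections = proj, residual_separation = rs)
}
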