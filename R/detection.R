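#' Least-squares event amplitudes for a calcium trace
#'
#' Fits per-event amplitudes jointly by ordinary least squares of the trace
#' against all template columns, so that overlapping kernel copies are
#' disentangled by multiple regression. Records the amplitude mean, standard
#' deviation and the one-sample t statistic used to gate event relevance.
#'
#' @param trace numeric trace (length must match the template).
#' @param template an [event_template()] / [build_event_template()] object,
#'   or a bare design matrix.
#' @param intercept include a baseline offset column in the design (its
#'   coefficient is not part of the amplitude test). The default `FALSE`
#'   matches the plain template regression of zero-baseline traces;
#'   set `TRUE` when traces carry a nonzero baseline so the amplitude test
#'   measures event-locked structure only.
#' @return An object of class `stm_betafit`: list with `betas`, `beta_mean`,
#'   `beta_sd`, `t_statistic`, `p_value` (one-tailed, positive activation),
#'   and `k` (number of events).
#' @export
#' @examples
#' tpl <- event_template(c(1, 200, 400), 600)
#' fit <- fit_betas(rowSums(tpl$design) * 2, tpl)
#' fit$betas  # all 2
fit_betas <- function(trace, template, intercept = FALSE) {
  X <- if (inherits(template, "stm_template")) template$design else template
  if (length(trace) != nrow(X))
    stop("trace and template lengths differ")
  Xi <- if (intercept) cbind(1, X) else X
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    off <- as.integer(intercept)
    bad <- setdiff(seq_len(ncol(Xi)), qrX$pivot[seq_len(qrX$rank)]) - off
    bad <- bad[bad >= 1]
    ev <- if (inherits(template, "stm_template"))
      template$event_frames[bad] else bad
    stop("rank-deficient template: colliding events at ",
         paste(ev, collapse = ", "))
  }
  betas <- as.numeric(qr.coef(qrX, trace))
  if (intercept) betas <- betas[-1]
  betafit_from_betas(betas)
}

betafit_from_betas <- function(betas) {
  tol <- 1e-8 * max(abs(betas), .Machine$double.eps)
  betas[abs(betas) < tol] <- 0
  k <- length(betas)
  m <- mean(betas)
  s <- if (k >= 2) stats::sd(betas) else NA_real_
  tt <- t_and_p(m, s, k)
  out <- list(betas = betas, beta_mean = m, beta_sd = s,
              t_statistic = tt$t, p_value = tt$p, k = k)
  class(out) <- "stm_betafit"
  out
}

# One-sample t statistic and one-tailed p for positive mean amplitude, with
# the degenerate zero-variance contract: s = 0 with nonzero mean is maximally
# significant (p = 0); s = 0 with zero mean carries no evidence (p = 1).
t_and_p <- function(m, s, k, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (k < 2) return(list(t = NA_real_, p = NA_real_))
  if (is.na(s)) return(list(t = NA_real_, p = NA_real_))
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1))
    t <- sign(m) * Inf
    p <- if (tail == "one") ifelse(m > 0, 0, 1) else 0
    return(list(t = t, p = p))
  }
  t <- m / (s / sqrt(k))
  p <- if (tail == "one") stats::pt(t, df = k - 1, lower.tail = FALSE)
       else 2 * stats::pt(-abs(t), df = k - 1)
  list(t = t, p = p)
}

#' Event-relevance test for a fitted amplitude set
#'
#' One-sample t test of the per-event amplitudes against zero, with `k - 1`
#' degrees of freedom. Event-related calcium transients are positive-going,
#' so the default test is one-tailed (significant only for positive mean
#' amplitude); a two-tailed variant is available.
#'
#' @param fit an `stm_betafit` from [fit_betas()].
#' @param alpha significance threshold (0.05 is the pixel-level default).
#' @param tail `"one"` (default) or `"two"`.
#' @return list with `significant`, `p_value`, `t_statistic`.
#' @export
test_event_relevance <- function(fit, alpha = 0.05, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (fit$k < 2) stop("need at least 2 events for the t test")
  tt <- t_and_p(fit$beta_mean, fit$beta_sd, fit$k, tail)
  sig <- !is.na(tt$p) && tt$p < alpha
  if (tail == "one") sig <- sig && fit$beta_mean > 0
  list(significant = sig, p_value = tt$p, t_statistic = tt$t)
}

# Vectorized joint OLS over many traces (columns of Y) against one design.
# An intercept column absorbs baseline offsets; its coefficient is dropped.
# Returns the k x n event-coefficient matrix.
fit_betas_matrix <- function(Y, X, intercept = FALSE) {
  Xi <- if (intercept) cbind(1, X) else X
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) stop("rank-deficient design")
  B <- qr.coef(qrX, Y)
  if (intercept) B <- B[-1, , drop = FALSE]
  B
}

# Per-kind one-sample t tests on grouped coefficient rows.
# B: k x n coefficients; kind: length-k labels. Returns list of p and t
# matrices (kinds x n) plus mean amplitude per kind. Amplitudes below a
# relative numerical floor (1e-8 of the trace's largest fitted amplitude)
# are snapped to zero so that exact fits do not produce spurious
# significance from floating-point residue.
grouped_beta_tests <- function(B, kind, tail = "one") {
  B <- as.matrix(B)
  tol <- 1e-8 * pmax(apply(abs(B), 2, max), .Machine$double.eps)
  B <- B * (abs(B) >= rep(tol, each = nrow(B)))
  kinds <- unique(kind)
  n <- ncol(B)
  p <- t <- m <- matrix(NA_real_, length(kinds), n,
                        dimnames = list(kinds, NULL))
  for (i in seq_along(kinds)) {
    Bi <- B[kind == kinds[i], , drop = FALSE]
    k <- nrow(Bi)
    mm <- colMeans(Bi)
    ss <- sqrt(colSums((Bi - rep(mm, each = k))^2) / (k - 1))
    tv <- ifelse(ss == 0, ifelse(mm == 0, 0, sign(mm) * Inf),
                 mm / (ss / sqrt(k)))
    pv <- ifelse(ss == 0, ifelse(mm == 0, 1, ifelse(mm > 0, 0, 1)),
                 stats::pt(tv, df = k - 1, lower.tail = FALSE))
    if (tail == "two")
      pv <- ifelse(ss == 0, ifelse(mm == 0, 1, 0),
                   2 * stats::pt(-abs(tv), df = k - 1))
    p[i, ] <- pv; t[i, ] <- tv; m[i, ] <- mm
  }
  list(p = p, t = t, mean = m)
}

#' Event-relevance p-values for many traces at once
#'
#' Vectorized version of [fit_betas()] + [test_event_relevance()]: fits all
#' traces (columns of `traces`) against one event template by least squares
#' and returns the per-trace one-sample t-test p-value on the event
#' amplitudes. Used for pixelwise screening and null calibration.
#'
#' @param traces frames x traces matrix.
#' @param template an `stm_template` (or design matrix).
#' @param tail `"one"` (default) or `"two"`.
#' @param intercept include a baseline offset column (see [fit_betas()]).
#' @return numeric vector of p-values, one per trace.
#' @export
event_relevance_pvalues <- function(traces, template,
                                    tail = c("one", "two"),
                                    intercept = FALSE) {
  tail <- match.arg(tail)
  X <- if (inherits(template, "stm_template")) template$design else template
  B <- fit_betas_matrix(as.matrix(traces), X, intercept = intercept)
  as.numeric(grouped_beta_tests(B, rep("all", ncol(X)), tail)$p[1, ])
}

#' Pixelwise detection of event-related ROIs
#'
#' Regresses every pixel trace of a movie against the event templates of the
#' requested task event kinds (jointly, one amplitude per event), gates each
#' pixel by the one-sample t test on its per-kind amplitudes, and clusters
#' significant pixels into ROIs by 8-connectivity (the Moore neighborhood).
#' Clusters smaller than `min_roi_size` pixels are discarded as speckle: real
#' somata at this magnification span at least a 3x3 footprint.
#'
#' @param movie an `stm_movie` (or an array frames x height x width).
#' @param trials trial table.
#' @param kinds event kinds to test (see [event_kinds()]).
#' @param timing,kernel timing and kernel configuration.
#' @param alpha per-pixel significance threshold (default 0.05).
#' @param min_roi_size minimum ROI pixel count (default 3).
#' @param tail `"one"` or `"two"` tailed amplitude test.
#' @return An object of class `stm_rois`: list with `significance_mask`
#'   (logical matrix), `roi_labels` (integer matrix, 0 = background), `rois`
#'   (list of pixel-coordinate matrices), `p_values` (kinds x pixels) and
#'   `beta_means`.
#' @export
detect_rois <- function(movie, trials, kinds = c("sample_R", "sample_L"),
                        timing = timing_config(), kernel = kernel_params(),
                        alpha = 0.05, min_roi_size = 3,
                        tail = c("one", "two")) {
  tail <- match.arg(tail)
  stack <- if (inherits(movie, "stm_movie")) movie$stack else movie
  stopifnot(length(dim(stack)) == 3, all(is.finite(stack)))
  d <- dim(stack); Fn <- d[1]; H <- d[2]; W <- d[3]
  Y <- matrix(stack, Fn, H * W)
  X <- joint_design(trials, kinds, timing, kernel, Fn)
  B <- fit_betas_matrix(Y, X)
  tests <- grouped_beta_tests(B, attr(X, "kind"), tail)
  sig <- apply(tests$p < alpha, 2, any)
  mask <- matrix(sig, H, W)
  labels <- label_components(mask, min_size = min_roi_size)
  rois <- lapply(seq_len(max(labels, 0)), function(l)
    which(labels == l, arr.ind = TRUE))
  rois <- rois[vapply(rois, nrow, 1L) > 0]
  out <- list(significance_mask = mask, roi_labels = labels, rois = rois,
              p_values = tests$p, beta_means = tests$mean,
              alpha = alpha, kinds = kinds, min_roi_size = min_roi_size)
  class(out) <- "stm_rois"
  out
}

#' Label connected components under the Moore (8-connected) neighborhood
#'
#' @param mask logical matrix.
#' @param min_size components with fewer pixels are relabeled background.
#' @return integer matrix of component labels (0 = background), numbered
#'   consecutively from 1.
#' @export
label_components <- function(mask, min_size = 1) {
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (px - 1L) %% H + 1L
      c <- (px - 1L) %/% H + 1L
      rr <- r + nb[, 1]; cc <- c + nb[, 2]
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      nidx <- (cc[ok] - 1L) * H + rr[ok]
      nidx <- nidx[mask[nidx] & labels[nidx] == 0L]
      labels[nidx] <- cur
      queue <- c(queue, nidx)
    }
  }
  if (min_size > 1 && cur > 0) {
    sizes <- tabulate(labels[labels > 0], nbins = cur)
    keep <- which(sizes >= min_size)
    remap <- integer(cur)
    remap[keep] <- seq_along(keep)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  labels
}

#' GLM-based phase / direction classification of neurons
#'
#' Fits each neuron's trace jointly against the six task-event templates
#' (right/left x sample/delay/reward, defined on correct trials) and tests
#' each regressor group's amplitudes by the one-sample t test at
#' `alpha_neuron`. A neuron's phase label is the set of phases with at least
#' one significant regressor; the direction label is `right` or `left` when
#' only that direction's regressors are significant, `nondirectional` when
#' both directions pass, and `none` when nothing passes.
#'
#' @param session an `stm_session`, or pass `traces`, `trials`, `timing`,
#'   `kernel` explicitly.
#' @param alpha_neuron neuron-level threshold (default 0.01).
#' @param tail tail of the amplitude test.
#' @return data.frame with one row per neuron: `neuron`, `phase`
#'   (comma-separated set, `"none"` if empty), `direction`,
#'   `primary_phase` / `primary_direction` (phase and direction of the
#'   single strongest significant regressor; neurons with secondary labels
#'   from weaker regressors are thereby flagged but still usable
#'   downstream), and the six per-regressor p-values `p_sample_R`, ...,
#'   `p_reward_L`.
#' @export
classify_neurons <- function(session, alpha_neuron = 0.01,
                             tail = c("one", "two")) {
  tail <- match.arg(tail)
  X <- joint_design(session$trials, event_kinds(), session$timing,
                    session$kernel, nrow(session$traces))
  B <- fit_betas_matrix(session$traces, X)
  tests <- grouped_beta_tests(B, attr(X, "kind"), tail)
  n <- ncol(session$traces)
  p <- tests$p
  phases <- dirs <- pphase <- pdir <- character(n)
  for (j in seq_len(n)) {
    sig <- rownames(p)[p[, j] < alpha_neuron]
    ph <- unique(sub("_.*", "", sig))
    phases[j] <- if (length(ph)) paste(ph, collapse = ",") else "none"
    has_r <- any(grepl("_R$", sig)); has_l <- any(grepl("_L$", sig))
    dirs[j] <- if (has_r && has_l) "nondirectional"
               else if (has_r) "right"
               else if (has_l) "left"
               else "none"
    if (length(sig)) {
      best <- rownames(p)[which.min(replace(p[, j], !(rownames(p) %in% sig),
                                            Inf))]
      pphase[j] <- sub("_.*", "", best)
      pdir[j] <- if (grepl("_R$", best)) "right" else "left"
    } else pphase[j] <- pdir[j] <- "none"
  }
  out <- data.frame(neuron = seq_len(n), phase = phases, direction = dirs,
                    primary_phase = pphase, primary_direction = pdir,
                    stringsAsFactors = FALSE)
  for (kd in event_kinds()) out[[paste0("p_", kd)]] <- p[kd, ]
  out
}

#' @rdname classify_neurons
#' @param trace a single neuron trace (for `classify_neuron`).
#' @export
classify_neuron <- function(trace, session, alpha_neuron = 0.01,
                            tail = c("one", "two")) {
  s <- session
  s$traces <- matrix(trace, ncol = 1)
  classify_neurons(s, alpha_neuron, tail)[1, ]
}

#' Exclude neurons with drifting baselines from directional labels
#'
#' Removes (relabels as `direction = "none"`) any directional neuron whose
#' mean activity during its selective phase on correct trials is strictly
#' higher for the nonpreferred stimulus than for the preferred one; slow
#' baseline drifts can otherwise masquerade as opposite-direction responses.
#' Equality retains the neuron.
#'
#' @param labels a classification table from [classify_neurons()].
#' @param session the session the labels were computed from.
#' @return the labels table with an added logical column `excluded_drifting`
#'   and offending neurons relabeled `direction = "none"`.
#' @export
exclude_drifting_neurons <- function(labels, session) {
  tensor <- trial_tensor(session)
  trials <- session$trials
  excluded <- logical(nrow(labels))
  for (j in seq_len(nrow(labels))) {
    dir <- labels$direction[j]
    if (!dir %in% c("right", "left")) next
    ph <- if (!is.null(labels$primary_phase)) labels$primary_phase[j]
          else strsplit(labels$phase[j], ",")[[1]][1]
    if (ph == "none") next
    pf <- phase_frames(session$timing, ph)
    pref_tr <- cond_trials(trials, stim = dir, outcome = "correct")
    opp_tr <- cond_trials(trials, stim = opposite_dir(dir),
                          outcome = "correct")
    m_pref <- mean(tensor[pf, j, pref_tr])
    m_opp <- mean(tensor[pf, j, opp_tr])
    if (m_opp > m_pref) excluded[j] <- TRUE
  }
  labels$excluded_drifting <- excluded
  labels$direction[excluded] <- "none"
  labels
}
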