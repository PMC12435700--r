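#' Double-exponential calcium impulse response
#'
#' Evaluates the fluorescence impulse response
#' `c(t) = exp(-t / tau_decay) - exp(-t / tau_rise)` on a time grid. With
#' `normalize = TRUE` (the default used when building regression templates)
#' the kernel is scaled so that its peak equals 1.
#'
#' @param t non-negative, increasing time grid in seconds.
#' @param params an [kernel_params()] object.
#' @param normalize logical; scale the kernel to unit peak.
#' @return numeric vector of kernel values on `t`.
#' @export
#' @examples
#' k <- calcium_kernel(seq(0, 5, by = 1 / 30), kernel_params())
calcium_kernel <- function(t, params = kernel_params(), normalize = FALSE) {
  if (!inherits(params, "stm_kernel")) params <- do.call(kernel_params, params)
  if (any(t < 0)) stop("time grid must be non-negative")
  if (is.unsorted(t)) stop("time grid must be increasing")
  v <- exp(-t / params$tau_decay_s) - exp(-t / params$tau_rise_s)
  if (normalize) {
    pk <- kernel_peak(params)
    v <- v / pk$value
  }
  v
}

# Closed-form peak location/value of the double-exponential kernel.
kernel_peak <- function(params) {
  tr <- params$tau_rise_s
  td <- params$tau_decay_s
  tstar <- tr * td / (td - tr) * log(td / tr)
  list(time = tstar,
       value = exp(-tstar / td) - exp(-tstar / tr))
}

# Discrete kernel sampled at the frame rate, truncated where it has decayed
# to < 1e-4 of its peak.
kernel_frames <- function(params, frame_rate_hz, normalize = TRUE) {
  n <- ceiling(10 * params$tau_decay_s * frame_rate_hz)
  t <- (seq_len(n) - 1) / frame_rate_hz
  v <- calcium_kernel(t, params, normalize = normalize)
  pk <- max(v)
  keep <- max(which(v >= 1e-4 * pk))
  v[seq_len(keep)]
}

#' Synthesize a single-neuron \eqn{\Delta F/F} trace
#'
#' Builds a trace as the sum of amplitude-scaled kernel copies placed at the
#' given event frames (the convolution of an amplitude-weighted spike train
#' with the indicator kernel), plus i.i.d. Gaussian noise.
#'
#' @param n_frames total trace length in frames.
#' @param events integer vector of event onset frames (1-based).
#' @param betas per-event amplitudes, recycled to `length(events)`.
#' @param params kernel parameters ([kernel_params()]).
#' @param frame_rate_hz imaging frame rate in Hz.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed controlling the noise; identical seeds yield
#'   identical traces.
#' @return numeric vector of length `n_frames`.
#' @export
synthesize_trace <- function(n_frames, events, betas = 1,
                             params = kernel_params(), frame_rate_hz = 30,
                             noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0, n_frames >= 1)
  events <- as.integer(events)
  if (length(events) && (any(events < 1) || any(events > n_frames)))
    stop("event frame outside the session (1..n_frames)")
  betas <- rep_len(betas, length(events))
  trace <- numeric(n_frames)
  if (length(events)) {
    k <- kernel_frames(params, frame_rate_hz, normalize = TRUE)
    for (i in seq_along(events)) {
      idx <- events[i]:min(n_frames, events[i] + length(k) - 1L)
      trace[idx] <- trace[idx] + betas[i] * k[seq_along(idx)]
    }
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(n_frames, 0, noise_sd) else
      withr::with_seed(seed, stats::rnorm(n_frames, 0, noise_sd))
    trace <- trace + noise
  }
  trace
}

# Default neuron mix: fractions of the population selective for each phase
# (split evenly between right- and left-preferring); the remainder carries no
# event-locked signal. Proportions emulate a population in which roughly 60%
# of neurons are task-selective with sample selectivity more common than
# delay, and delay more common than reward.
default_mix <- function() c(sample = 0.25, delay = 0.20, reward = 0.15)

#' Generate a synthetic trial-structured calcium session
#'
#' Simulates a delayed match-to-sample session: balanced pseudo-random left /
#' right stimuli, a configurable error rate, and a population of neurons with
#' planted phase and direction selectivity. Selective neurons emit one
#' calcium event per trial of their preferred direction, with peak times
#' tiling their phase (an activity sequence). On error trials the activity of
#' delay-selective neurons is linearly mixed toward the pattern evoked by the
#' opposite stimulus, with mixing weight `w(t) = min(1, drift_rate * s)`
#' where `s` is the elapsed time in seconds since delay onset; this emulates
#' the delay-period drift of population activity toward the opposite
#' representation on error trials. Reward-selective neurons respond only on
#' rewarded (correct) trials of their preferred direction.
#'
#' @param n_neurons number of neurons.
#' @param n_trials number of trials; left/right counts differ by at most 1.
#' @param mix named fractions (`sample`, `delay`, `reward`) of selective
#'   neurons; must sum to at most 1. Each phase group is split evenly between
#'   right- and left-preferring neurons.
#' @param error_rate fraction of trials (per direction) with an incorrect
#'   response, in `[0, 1]`.
#' @param drift_rate drift slope in units of mixing weight per second of
#'   delay, in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (\eqn{\Delta F/F} units).
#' @param amplitude event amplitude (the per-event regression amplitude of
#'   planted responses).
#' @param timing,kernel timing and kernel configuration objects.
#' @param peak_span numeric length-2: fraction of each phase over which the
#'   planted peak times of that phase's neurons are evenly spaced.
#' @param sequence logical; if `FALSE` all planted events occur exactly at
#'   their phase onset (no latency tiling). Useful for exact-recovery checks
#'   where planted responses must lie in the span of the event templates.
#' @param seed integer seed; sessions are bit-identical given the same
#'   configuration and seed.
#' @return An object of class `stm_session`: a list with `traces` (frames x
#'   neurons matrix), `trials` (the trial table), `timing`, `kernel`,
#'   `ground_truth` (per-neuron planted labels), `trial_starts` and `seed`.
#' @export
#' @examples
#' s <- generate_session(n_neurons = 12, n_trials = 12, noise_sd = 0, seed = 1)
#' dim(s$traces)
generate_session <- function(n_neurons = 60, n_trials = 60,
                             mix = default_mix(),
                             error_rate = 0.3, drift_rate = 0.5,
                             noise_sd = 0.2, amplitude = 1,
                             timing = timing_config(),
                             kernel = kernel_params(),
                             peak_span = c(0.05, 0.6),
                             sequence = TRUE,
                             seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            drift_rate >= 0, drift_rate <= 1,
            noise_sd >= 0, n_neurons >= 1)
  if (sum(mix) > 1 + 1e-12) stop("mix fractions must sum to <= 1")
  n_right <- ceiling(n_trials / 2)
  n_left <- n_trials - n_right
  n_err_r <- round(error_rate * n_right)
  n_err_l <- round(error_rate * n_left)
  if (n_right - n_err_r < 2 || n_left - n_err_l < 2)
    stop("need at least 2 correct trials per direction (downstream ROC undefined)")

  withr::with_seed(seed, {
    stim <- sample(rep(c("right", "left"), c(n_right, n_left)))
    err <- logical(n_trials)
    err[sample(which(stim == "right"), n_err_r)] <- TRUE
    err[sample(which(stim == "left"), n_err_l)] <- TRUE
    resp <- ifelse(err, ifelse(stim == "right", "left", "right"), stim)
    delay_s <- sample(c(1.5, 2), n_trials, replace = TRUE)
    rt_s <- pmax(0.05, 0.15 + stats::rnorm(n_trials, 0, 0.03))

    L <- timing$n_frames_total
    trial_starts <- (seq_len(n_trials) - 1L) * L + 1L + timing$pre_frames
    trials <- data.frame(
      trial = seq_len(n_trials),
      stim_dir = stim,
      resp_dir = resp,
      outcome = ifelse(err, "error", "correct"),
      stim_onset = trial_starts,
      delay_onset = trial_starts + min(timing$delay_frames) - 1L,
      port_contact = trial_starts + min(timing$reward_frames) - 1L,
      delay_s = delay_s,
      rt_s = rt_s,
      stringsAsFactors = FALSE)

    gt <- plant_neurons(n_neurons, mix, timing, kernel, peak_span, sequence)
    n_frames <- n_trials * L
    traces <- matrix(0, n_frames, n_neurons)
    kfr <- kernel_frames(kernel, timing$frame_rate_hz, normalize = TRUE)
    fs <- timing$frame_rate_hz
    delay_on_rel <- min(timing$delay_frames)

    for (j in seq_len(n_neurons)) {
      if (gt$preferred_direction[j] == "none") next
      onset_rel <- gt$event_frame[j]     # within-trial event onset frame
      pref <- gt$preferred_direction[j]
      phase <- gt$selective_phase[j]
      for (i in seq_len(n_trials)) {
        st <- trial_starts[i]
        correct <- trials$outcome[i] == "correct"
        if (phase == "reward" && !correct) next  # no reward delivered
        resp_stim <- if (stim[i] == pref) amplitude else 0
        resp_opp <- if (stim[i] != pref) amplitude else 0
        drifting <- phase == "delay" && !correct && drift_rate > 0
        if (!drifting && resp_stim == 0) next
        ev <- st + onset_rel - 1L
        idx <- ev:min(n_frames, ev + length(kfr) - 1L)
        kv <- kfr[seq_along(idx)]
        if (!drifting) {
          traces[idx, j] <- traces[idx, j] + resp_stim * kv
        } else {
          # mixing weight grows linearly in delay time at drift_rate per s
          tsec <- ((idx - st + 1L) - delay_on_rel) / fs
          w <- pmin(1, pmax(0, drift_rate * tsec))
          traces[idx, j] <- traces[idx, j] +
            ((1 - w) * resp_stim + w * resp_opp) * kv
        }
      }
    }
    if (noise_sd > 0)
      traces <- traces + matrix(stats::rnorm(length(traces), 0, noise_sd),
                                nrow(traces), ncol(traces))
  })

  out <- list(traces = traces, trials = trials, timing = timing,
              kernel = kernel, ground_truth = gt,
              trial_starts = trial_starts, seed = seed)
  class(out) <- "stm_session"
  out
}

# Assign phase / direction labels and within-trial event frames to neurons.
plant_neurons <- function(n_neurons, mix, timing, kernel, peak_span, sequence) {
  counts <- round(mix * n_neurons)
  counts <- pmin(counts, n_neurons)
  while (sum(counts) > n_neurons) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  phase <- rep("none", n_neurons)
  pref <- rep("none", n_neurons)
  pos <- 1L
  for (ph in names(counts)) {
    k <- counts[[ph]]
    if (k == 0) next
    idx <- pos:(pos + k - 1L)
    phase[idx] <- ph
    pref[idx] <- rep_len(c("right", "left"), k)
    pos <- pos + k
  }
  peak_lag <- round(kernel_peak(kernel)$time * timing$frame_rate_hz)
  event_frame <- rep(NA_integer_, n_neurons)
  for (ph in names(counts)) {
    pf <- phase_frames(timing, ph)
    for (dr in c("right", "left")) {
      idx <- which(phase == ph & pref == dr)
      if (!length(idx)) next
      if (!sequence) {
        event_frame[idx] <- min(pf)
        next
      }
      span <- min(pf) + round(peak_span * (length(pf) - 1))
      peaks <- round(seq(span[1], span[2], length.out = length(idx)))
      event_frame[idx] <- pmax(min(pf), peaks - peak_lag)
    }
  }
  data.frame(neuron = seq_len(n_neurons),
             preferred_direction = pref,
             selective_phase = phase,
             event_frame = event_frame,
             peak_time_frame = ifelse(is.na(event_frame), NA_integer_,
                                      event_frame + peak_lag),
             amplitude_beta = ifelse(pref == "none", 0, 1),
             stringsAsFactors = FALSE)
}

#' @export
print.stm_session <- function(x, ...) {
  cat(sprintf(
    "stm_session: %d neurons, %d trials (%d correct, %d error), %d frames\n",
    ncol(x$traces), nrow(x$trials), sum(x$trials$outcome == "correct"),
    sum(x$trials$outcome == "error"), nrow(x$traces)))
  invisible(x)
}

#' Render a session as a pixel movie
#'
#' Paints each selective ground-truth neuron onto a compact square pixel
#' footprint of an image stack and adds Gaussian background noise to every
#' pixel. Footprints are placed on a regular non-overlapping grid unless
#' explicit `positions` are supplied; overlapping explicit footprints
#' trigger a warning and an overlap map is recorded.
#'
#' @param session an `stm_session`.
#' @param neurons indices of session neurons to paint; defaults to all
#'   neurons with a planted preferred direction.
#' @param footprint_px side length of the square footprint in pixels (3 or 4
#'   emulate typical somata at this magnification).
#' @param image_size integer length-2, image height and width in pixels.
#' @param background_sd Gaussian noise added to every pixel trace.
#' @param positions optional integer matrix (neurons x 2) of top-left footprint
#'   corners (row, col); defaults to a regular grid.
#' @param seed integer seed for the background noise.
#' @return An object of class `stm_movie`: list with `stack` (frames x height
#'   x width array), `footprints` (list of pixel-coordinate matrices),
#'   `overlap` (matrix counting footprint coverage), `neurons`, `seed`.
#' @export
generate_movie <- function(session, neurons = NULL, footprint_px = 3,
                           image_size = c(32, 32), background_sd = 0.1,
                           positions = NULL, seed = 1) {
  stopifnot(inherits(session, "stm_session"), background_sd >= 0)
  if (is.null(neurons))
    neurons <- which(session$ground_truth$preferred_direction != "none")
  n <- length(neurons)
  H <- image_size[1]; W <- image_size[2]
  if (is.null(positions)) {
    step <- footprint_px + 2L
    rows <- seq(2L, H - footprint_px, by = step)
    cols <- seq(2L, W - footprint_px, by = step)
    grid <- expand.grid(row = rows, col = cols)
    if (n > nrow(grid)) stop("too many neurons for the image size")
    positions <- as.matrix(grid[seq_len(n), , drop = FALSE])
  }
  if (any(positions < 1) || any(positions[, 1] + footprint_px - 1 > H) ||
      any(positions[, 2] + footprint_px - 1 > W))
    stop("footprints must fit inside the image")
  footprints <- vector("list", n)
  overlap <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    r <- positions[i, 1]:(positions[i, 1] + footprint_px - 1L)
    c <- positions[i, 2]:(positions[i, 2] + footprint_px - 1L)
    fp <- as.matrix(expand.grid(row = r, col = c))
    footprints[[i]] <- fp
    overlap[fp] <- overlap[fp] + 1L
  }
  if (any(overlap > 1L)) warning("overlapping footprints recorded in overlap map")

  Fn <- nrow(session$traces)
  stack <- array(0, dim = c(Fn, H, W))
  if (background_sd > 0)
    stack[] <- withr::with_seed(seed,
      stats::rnorm(Fn * H * W, 0, background_sd))
  for (i in seq_len(n)) {
    tr <- session$traces[, neurons[i]]
    fp <- footprints[[i]]
    for (p in seq_len(nrow(fp)))
      stack[, fp[p, 1], fp[p, 2]] <- stack[, fp[p, 1], fp[p, 2]] + tr
  }
  out <- list(stack = stack, footprints = footprints, overlap = overlap,
              neurons = neurons, image_size = c(H, W), seed = seed)
  class(out) <- "stm_movie"
  out
}
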