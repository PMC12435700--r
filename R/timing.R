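#' Trial timing configuration
#'
#' Frame-based layout of a single trial at a fixed imaging frame rate. The
#' default layout is a 30 Hz session with a 4 s sample phase (frames 1-120),
#' a delay phase (frames 121-170), a reward phase (frames 171-200), and a
#' configurable inter-trial interval appended after the reward phase. All
#' analysis windows in this package are expressed in these within-trial frame
#' indices.
#'
#' @param frame_rate_hz imaging frame rate in Hz; must be positive.
#' @param sample_frames integer vector of within-trial frames forming the
#'   sample phase.
#' @param delay_frames integer vector of frames forming the delay phase.
#' @param reward_frames integer vector of frames forming the reward phase.
#' @param iti_frames number of inter-trial frames appended after the reward
#'   phase (baseline, no task events).
#' @param pre_frames number of baseline frames before stimulus onset.
#'
#' @return An object of class `stm_timing`: a list with the phase frame
#'   vectors, the frame rate, the per-trial frame count `n_frames_trial`
#'   (task frames only) and `n_frames_total` (including the ITI).
#' @export
#' @examples
#' tm <- timing_config()
#' tm$n_frames_trial
timing_config <- function(frame_rate_hz = 30,
                          sample_frames = 1:120,
                          delay_frames = 121:170,
                          reward_frames = 171:200,
                          iti_frames = 60,
                          pre_frames = 0) {
  stopifnot(is.numeric(frame_rate_hz), length(frame_rate_hz) == 1,
            frame_rate_hz > 0, iti_frames >= 0, pre_frames >= 0)
  sample_frames <- as.integer(sample_frames)
  delay_frames <- as.integer(delay_frames)
  reward_frames <- as.integer(reward_frames)
  phases <- list(sample = sample_frames, delay = delay_frames,
                 reward = reward_frames)
  all_f <- unlist(phases)
  if (anyDuplicated(all_f) > 0)
    stop("phase frame windows must be disjoint")
  if (!(max(sample_frames) < min(delay_frames) &&
        max(delay_frames) < min(reward_frames)))
    stop("phase windows must be ordered sample < delay < reward")
  out <- list(frame_rate_hz = frame_rate_hz,
              sample_frames = sample_frames,
              delay_frames = delay_frames,
              reward_frames = reward_frames,
              iti_frames = as.integer(iti_frames),
              pre_frames = as.integer(pre_frames),
              n_frames_trial = max(reward_frames),
              n_frames_total = max(reward_frames) + as.integer(iti_frames) +
                as.integer(pre_frames))
  class(out) <- "stm_timing"
  out
}

#' Calcium indicator kernel parameters
#'
#' Time constants of the double-exponential fluorescence impulse response
#' used throughout the package. The decay constant defaults to 1.0 s, the
#' value appropriate for a cytosolic indicator; nuclear-localized indicators
#' use 3.0 s (`kernel_params(tau_decay_s = 3)`). The rise constant defaults
#' to 0.1 s, a typical fast-indicator onset; it is configurable because only
#' the decay is constrained by the indicator localization.
#'
#' @param tau_rise_s rise time constant in seconds, positive.
#' @param tau_decay_s decay time constant in seconds, must exceed
#'   `tau_rise_s` for the kernel to be non-negative.
#' @return An object of class `stm_kernel`.
#' @export
kernel_params <- function(tau_rise_s = 0.1, tau_decay_s = 1.0) {
  if (!is.numeric(tau_rise_s) || !is.numeric(tau_decay_s) ||
      tau_rise_s <= 0 || tau_decay_s <= tau_rise_s)
    stop("invalid kernel parameters: need tau_decay_s > tau_rise_s > 0")
  out <- list(tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s)
  class(out) <- "stm_kernel"
  out
}

#' @export
print.stm_timing <- function(x, ...) {
  cat("Trial timing:", x$frame_rate_hz, "Hz;",
      "sample", min(x$sample_frames), "-", max(x$sample_frames), ";",
      "delay", min(x$delay_frames), "-", max(x$delay_frames), ";",
      "reward", min(x$reward_frames), "-", max(x$reward_frames), ";",
      "ITI", x$iti_frames, "frames\n")
  invisible(x)
}

#' @export
print.stm_kernel <- function(x, ...) {
  cat(sprintf("Calcium kernel: tau_rise = %g s, tau_decay = %g s\n",
              x$tau_rise_s, x$tau_decay_s))
  invisible(x)
}

#' Frames belonging to a named task phase
#'
#' @param timing an `stm_timing` object.
#' @param phase one of `"sample"`, `"delay"`, `"reward"`.
#' @return integer vector of within-trial frame indices.
#' @export
phase_frames <- function(timing, phase = c("sample", "delay", "reward")) {
  phase <- match.arg(phase)
  switch(phase,
         sample = timing$sample_frames,
         delay = timing$delay_frames,
         reward = timing$reward_frames)
}
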