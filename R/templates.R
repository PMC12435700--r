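#' Event-locked regression template
#'
#' Builds the design matrix for event-related regression: one column per
#' event, each a unit-peak copy of the calcium kernel anchored at the event
#' onset frame and spanning the remainder of the session.
#'
#' @param event_frames integer vector of event onset frames (1-based).
#' @param n_frames total session length in frames.
#' @param kernel kernel parameters ([kernel_params()]).
#' @param frame_rate_hz frame rate in Hz.
#' @return An object of class `stm_template`: list with `design` (n_frames x
#'   k matrix), `event_frames` and `kernel`.
#' @export
event_template <- function(event_frames, n_frames, kernel = kernel_params(),
                           frame_rate_hz = 30) {
  event_frames <- as.integer(event_frames)
  if (length(event_frames) == 0) stop("no events supplied")
  if (any(event_frames < 1) || any(event_frames > n_frames))
    stop("event frame outside the session")
  k <- kernel_frames(kernel, frame_rate_hz, normalize = TRUE)
  X <- matrix(0, n_frames, length(event_frames))
  for (i in seq_along(event_frames)) {
    idx <- event_frames[i]:min(n_frames, event_frames[i] + length(k) - 1L)
    X[idx, i] <- k[seq_along(idx)]
  }
  out <- list(design = X, event_frames = event_frames, kernel = kernel,
              frame_rate_hz = frame_rate_hz)
  class(out) <- "stm_template"
  out
}

# The six task event kinds: direction x phase.
event_kinds <- function() {
  c("sample_R", "sample_L", "delay_R", "delay_L", "reward_R", "reward_L")
}

# Onset frames (global) of one event kind, from the trial table.
event_onsets <- function(trials, event_kind, timing,
                         correct_only = TRUE) {
  parts <- strsplit(event_kind, "_")[[1]]
  phase <- parts[1]
  dir <- if (parts[2] == "R") "right" else "left"
  keep <- trials$stim_dir == dir
  if (correct_only) keep <- keep & trials$outcome == "correct"
  if (!any(keep)) stop("no matching trials for event kind ", event_kind)
  offset <- min(phase_frames(timing, phase)) - 1L
  trials$stim_onset[keep] + offset
}

#' Build the template for one task event kind
#'
#' Anchors one unit-peak kernel copy at the phase onset of every matching
#' trial (by default correct trials only, since task events are defined on
#' correct trials).
#'
#' @param trials a session trial table.
#' @param event_kind one of `"sample_R"`, `"sample_L"`, `"delay_R"`,
#'   `"delay_L"`, `"reward_R"`, `"reward_L"`.
#' @param timing an [timing_config()] object.
#' @param kernel kernel parameters.
#' @param n_frames session length in frames.
#' @param correct_only use correct trials only (default).
#' @return An `stm_template`, with one column per matching trial.
#' @export
build_event_template <- function(trials, event_kind, timing, kernel,
                                 n_frames, correct_only = TRUE) {
  ev <- event_onsets(trials, event_kind, timing, correct_only)
  event_template(ev, n_frames, kernel, timing$frame_rate_hz)
}

# Joint design across several event kinds: columns grouped by kind, with a
# `kind` attribute mapping each column to its event kind.
joint_design <- function(trials, kinds, timing, kernel, n_frames,
                         correct_only = TRUE) {
  mats <- list(); labels <- character(0); onsets <- integer(0)
  for (kd in kinds) {
    tpl <- build_event_template(trials, kd, timing, kernel, n_frames,
                                correct_only)
    mats[[kd]] <- tpl$design
    labels <- c(labels, rep(kd, ncol(tpl$design)))
    onsets <- c(onsets, tpl$event_frames)
  }
  X <- do.call(cbind, mats)
  attr(X, "kind") <- labels
  attr(X, "onsets") <- onsets
  X
}
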