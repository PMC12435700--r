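#' Write a session to plain-text files
#'
#' Writes the trace matrix as CSV (`dff.csv`, frames x neurons), the trial
#' table as `trials.csv` with the columns
#' `trial,stim_dir,resp_dir,outcome,stim_onset,delay_onset,port_contact,delay_s,rt_s`,
#' and the timing/kernel configuration plus ground truth (when present) as
#' `session.json`.
#'
#' @param session an `stm_session`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_tr <- file.path(dir, "dff.csv")
  p_trials <- file.path(dir, "trials.csv")
  p_meta <- file.path(dir, "session.json")
  data.table::fwrite(data.table::as.data.table(session$traces), p_tr)
  data.table::fwrite(session$trials, p_trials)
  meta <- list(timing = unclass(session$timing),
               kernel = unclass(session$kernel),
               trial_starts = session$trial_starts,
               seed = session$seed,
               ground_truth = session$ground_truth)
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p_tr, p_trials, p_meta))
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing `dff.csv`, `trials.csv`, `session.json`.
#' @return an `stm_session`.
#' @export
read_session <- function(dir) {
  traces <- as.matrix(data.table::fread(file.path(dir, "dff.csv")))
  dimnames(traces) <- NULL
  trials <- as.data.frame(data.table::fread(file.path(dir, "trials.csv")))
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  timing <- timing_config(frame_rate_hz = meta$timing$frame_rate_hz,
                          sample_frames = meta$timing$sample_frames,
                          delay_frames = meta$timing$delay_frames,
                          reward_frames = meta$timing$reward_frames,
                          iti_frames = meta$timing$iti_frames,
                          pre_frames = meta$timing$pre_frames)
  kernel <- kernel_params(meta$kernel$tau_rise_s, meta$kernel$tau_decay_s)
  gt <- meta$ground_truth
  if (!is.null(gt)) gt <- as.data.frame(gt)
  out <- list(traces = traces, trials = trials, timing = timing,
              kernel = kernel, ground_truth = gt,
              trial_starts = meta$trial_starts, seed = meta$seed)
  class(out) <- "stm_session"
  out
}
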