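#' Default pipeline configuration
#'
#' Nested configuration covering every stage of the analysis pipeline. The
#' analysis constants mirror the task layout: 30 Hz frames, sample frames
#' 1-120, delay 121-170, reward 171-200; mode windows 66-115 / 121-170 /
#' 141-170 / 171-200; pixel-level alpha 0.05 and neuron-level alpha 0.01;
#' 1,000 permutations; 5 principal components with 100 split iterations;
#' 50-frame LDA windows, 8-frame SVM windows with a 70/30 split and 10
#' repeats; six 25-frame correlation bins. Every stochastic stage derives
#' its own seed from the top-level seed.
#'
#' @param seed top-level integer seed.
#' @return a named list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    session = list(n_neurons = 60, n_trials = 60, error_rate = 0.3,
                   drift_rate = 0.5, noise_sd = 0.2, amplitude = 1),
    detection = list(alpha_neuron = 0.01, alpha_pixel = 0.05),
    selectivity = list(n_perm = 1000),
    trajectory = list(n_components = 5, n_iter = 100),
    decoding = list(snr_window = 50, svm_window = 8, train_fraction = 0.7,
                    n_repeats = 10, svm_starts = NULL, snr_starts = NULL,
                    correlation_scheme = "six_25frame_bins", n_splits = 20),
    stages = list(detection = TRUE, selectivity = TRUE, trajectory = TRUE,
                  coding_direction = TRUE, decoding = TRUE)
  )
}

#' Validate a pipeline configuration
#'
#' @param config a configuration list as produced by [default_config()].
#' @return character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "missing or invalid top-level seed")
  s <- config$session
  chk(!is.null(s), "missing session block")
  if (!is.null(s)) {
    chk(isTRUE(s$error_rate >= 0 && s$error_rate <= 1),
        "session error_rate must be in [0, 1]")
    chk(isTRUE(s$drift_rate >= 0 && s$drift_rate <= 1),
        "session drift_rate must be in [0, 1]")
    chk(isTRUE(s$noise_sd >= 0), "session noise_sd must be non-negative")
  }
  d <- config$detection
  if (!is.null(d)) {
    chk(isTRUE(d$alpha_neuron > 0 && d$alpha_neuron < 1),
        "alpha_neuron must be in (0, 1)")
    chk(isTRUE(d$alpha_pixel > 0 && d$alpha_pixel < 1),
        "alpha_pixel must be in (0, 1)")
  }
  tm <- tryCatch(do.call(timing_config, config$timing %||% list()),
                 error = function(e) conditionMessage(e))
  if (is.character(tm)) v <- c(v, paste("timing:", tm))
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic or loaded session
#'
#' Executes, in order: session generation (or loading), GLM neuron
#' classification with drifting-neuron exclusion, ROC selectivity metrics,
#' trajectory distances with the similarity index, coding-direction
#' projections with residual separation, and population decoding (LDA-SNR,
#' SVM, native-space correlations). All stage outputs are written as
#' CSV/JSON under `out_dir` together with a run manifest carrying the
#' configuration hash and per-file checksums; two runs from one
#' configuration produce byte-identical outputs.
#'
#' @param config configuration list (see [default_config()]); unset fields
#'   take their defaults.
#' @param out_dir output directory.
#' @param session optionally, a pre-built `stm_session` to analyze instead
#'   of generating one.
#' @return the manifest (also written to `manifest.json`): list with the
#'   config hash, package version, completed stages, and per-file md5
#'   checksums.
#' @export
run_pipeline <- function(config = default_config(), out_dir, session = NULL) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  seed <- config$seed
  stages_done <- character(0)

  if (is.null(session)) {
    s <- config$session
    session <- generate_session(
      n_neurons = s$n_neurons %||% 60, n_trials = s$n_trials %||% 60,
      error_rate = s$error_rate %||% 0.3, drift_rate = s$drift_rate %||% 0.5,
      noise_sd = s$noise_sd %||% 0.2, amplitude = s$amplitude %||% 1,
      seed = sub_seed(seed, 1))
  }
  write_session(session, file.path(out_dir, "session"))
  stages_done <- c(stages_done, "synthetic_data")

  labels <- NULL
  if (isTRUE(config$stages$detection %||% TRUE)) {
    labels <- classify_neurons(session,
                               config$detection$alpha_neuron %||% 0.01)
    labels <- exclude_drifting_neurons(labels, session)
    data.table::fwrite(labels, file.path(out_dir, "neuron_labels.csv"))
    stages_done <- c(stages_done, "event_detection")
  }
  if (isTRUE(config$stages$selectivity %||% TRUE)) {
    if (is.null(labels)) labels <- classify_neurons(session)
    metrics <- selectivity_table(session, labels,
                                 n_perm = config$selectivity$n_perm %||% 1000,
                                 seed = sub_seed(seed, 2))
    data.table::fwrite(metrics, file.path(out_dir, "selectivity.csv"))
    stages_done <- c(stages_done, "selectivity_metrics")
  }
  directions <- if (!is.null(labels)) {
    d <- labels$direction
    d[!d %in% c("right", "left")] <- "none"
    d
  } else session$ground_truth$preferred_direction
  if (isTRUE(config$stages$trajectory %||% TRUE)) {
    tr <- trajectory_distances(session, directions,
                               n_components =
                                 config$trajectory$n_components %||% 5,
                               n_iter = config$trajectory$n_iter %||% 100,
                               seed = sub_seed(seed, 3))
    data.table::fwrite(tr$mean, file.path(out_dir, "trajectory.csv"))
    stages_done <- c(stages_done, "trajectory_analysis")
  }
  if (isTRUE(config$stages$coding_direction %||% TRUE)) {
    cd <- coding_direction_analysis(session)
    w <- data.frame(neuron = seq_along(cd$modes$CD_delay$weights),
                    CD_sample = cd$modes$CD_sample$weights,
                    CD_delay = cd$modes$CD_delay$weights,
                    CD_reward = cd$modes$CD_reward$weights,
                    D_reward = cd$modes$D_reward$weights)
    data.table::fwrite(w, file.path(out_dir, "mode_weights.csv"))
    data.table::fwrite(cd$projections$CD_delay$series,
                       file.path(out_dir, "projections_cd_delay.csv"))
    data.table::fwrite(cd$projections$CD_sample$series,
                       file.path(out_dir, "projections_cd_sample.csv"))
    jsonlite::write_json(cd$residual_separation,
                         file.path(out_dir, "residual_separation.json"),
                         auto_unbox = TRUE, digits = NA)
    stages_done <- c(stages_done, "coding_direction")
  }
  if (isTRUE(config$stages$decoding %||% TRUE)) {
    dc <- config$decoding
    snr_ss <- snr_timecourse(session, "same_stimulation",
                             window_w = dc$snr_window %||% 50,
                             window_starts = dc$snr_starts)
    snr_sr <- snr_timecourse(session, "same_response",
                             window_w = dc$snr_window %||% 50,
                             window_starts = dc$snr_starts)
    snr <- data.frame(window_start = snr_ss$window_start,
                      snr_same_stim = snr_ss$snr,
                      snr_same_resp = snr_sr$snr)
    data.table::fwrite(snr, file.path(out_dir, "snr_timecourse.csv"))
    dec <- svm_decode(session, train_fraction = dc$train_fraction %||% 0.7,
                      n_repeats = dc$n_repeats %||% 10,
                      window_w = dc$svm_window %||% 8,
                      window_starts = dc$svm_starts,
                      seed = sub_seed(seed, 4))
    data.table::fwrite(dec, file.path(out_dir, "decoding.csv"))
    pc <- population_correlation(session,
                                 dc$correlation_scheme %||% "six_25frame_bins",
                                 n_splits = dc$n_splits %||% 20,
                                 seed = sub_seed(seed, 5))
    data.table::fwrite(pc, file.path(out_dir, "correlations.csv"))
    stages_done <- c(stages_done, "population_decoding")
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  sums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(sums) <- files
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   package_version =
                     as.character(utils::packageVersion("stmdrift")),
                   stages = stages_done,
                   checksums = sums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
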