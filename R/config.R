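#' Pipeline configuration
#'
#' All tunable analysis constants with their study defaults. Fractions are
#' proportions in (0, 1]; the band is in Hz and must sit below the Nyquist
#' frequency of the 7.81 Hz sampling rate.
#'
#' @param coherence_threshold channels with mean cardiac phase coherence
#'   strictly below this are rejected (default 0.85).
#' @param bad_timepoint_channel_fraction channels with a flagged-sample
#'   fraction strictly above this are rejected (default 0.25).
#' @param bad_channel_participant_fraction participants with a rejected
#'   channel fraction strictly above this are excluded (default 0.50).
#' @param band band-pass edges in Hz for spontaneous hemodynamics
#'   (default 0.01-0.08).
#' @param filter_order Butterworth order (default 4), applied zero-phase.
#' @param cardiac_band band (Hz) used for cardiac phase coherence.
#' @param artifact_window_s moving-std window in seconds.
#' @param artifact_z_thresh moving-std threshold as a multiple of its median.
#' @param n_segments number of random 60-s segments drawn (default 200).
#' @param segment_length_s segment length in seconds (default 60).
#' @param segment_valid_fraction minimum valid-sample fraction for a
#'   segment to be retained (default 0.90, inclusive).
#' @param thresholds threshold sweep grid (default 0.01..0.85 step 0.01).
#' @param n_random_nets random null networks per thresholded matrix
#'   (default 100).
#' @param n_permutations permutations for the group tests (default 2000).
#' @param alpha significance level (default 0.05).
#' @param max_ar_order maximum AR order for prewhitening (default 20).
#' @param use_prewhitened compute connectivity from the prewhitened
#'   series instead of the PCA-filtered one (default FALSE: correlations
#'   are computed on the PCA-filtered concentration signal; prewhitening
#'   drastically down-weights the narrow spontaneous band relative to
#'   residual broadband noise and so attenuates band-limited coupling).
#' @param rng_seed master seed; all stochastic stages derive their seeds
#'   deterministically from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(coherence_threshold = 0.85,
                            bad_timepoint_channel_fraction = 0.25,
                            bad_channel_participant_fraction = 0.50,
                            band = c(0.01, 0.08),
                            filter_order = 4,
                            cardiac_band = c(0.5, 2.0),
                            artifact_window_s = 1,
                            artifact_z_thresh = 3,
                            n_segments = 200,
                            segment_length_s = 60,
                            segment_valid_fraction = 0.90,
                            thresholds = seq(0.01, 0.85, by = 0.01),
                            n_random_nets = 100,
                            n_permutations = 2000,
                            alpha = 0.05,
                            max_ar_order = 20,
                            use_prewhitened = FALSE,
                            rng_seed = 1L) {
  cfg <- list(coherence_threshold = coherence_threshold,
              bad_timepoint_channel_fraction = bad_timepoint_channel_fraction,
              bad_channel_participant_fraction = bad_channel_participant_fraction,
              band = band, filter_order = filter_order,
              cardiac_band = cardiac_band,
              artifact_window_s = artifact_window_s,
              artifact_z_thresh = artifact_z_thresh,
              n_segments = n_segments, segment_length_s = segment_length_s,
              segment_valid_fraction = segment_valid_fraction,
              thresholds = thresholds, n_random_nets = n_random_nets,
              n_permutations = n_permutations, alpha = alpha,
              max_ar_order = max_ar_order, use_prewhitened = use_prewhitened,
              rng_seed = as.integer(rng_seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg, fs = 7.81) {
  fr <- c("coherence_threshold", "bad_timepoint_channel_fraction",
          "bad_channel_participant_fraction", "segment_valid_fraction")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      stop(sprintf("config field `%s` must be a fraction in (0, 1], got %s",
                   f, format(v)))
    }
  }
  if (length(cfg$band) != 2 || cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2] ||
      cfg$band[2] >= fs / 2) {
    stop("config field `band` must satisfy 0 < low < high < fs/2")
  }
  if (length(cfg$cardiac_band) != 2 || cfg$cardiac_band[1] <= 0 ||
      cfg$cardiac_band[1] >= cfg$cardiac_band[2] || cfg$cardiac_band[2] >= fs / 2) {
    stop("config field `cardiac_band` must satisfy 0 < low < high < fs/2")
  }
  th <- cfg$thresholds
  if (any(th <= 0) || any(th >= 1) || any(diff(th) <= 0)) {
    stop("config field `thresholds` must be strictly increasing in (0, 1)")
  }
  for (f in c("n_segments", "n_random_nets", "n_permutations", "max_ar_order")) {
    if (cfg[[f]] < 1) stop(sprintf("config field `%s` must be >= 1", f))
  }
  if (cfg$segment_length_s <= 0) stop("config field `segment_length_s` must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("config field `alpha` must be in (0, 1)")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown fields are rejected; out-of-range values raise an error naming
#' the field. Fields absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Deterministic sub-seed derivation: one master seed, expanded per
# participant/stage so every stochastic stage is reproducible in isolation.
derive_seed <- function(master, index, stage = 0L) {
  as.integer((as.double(master) * 48271 + index * 9973 + stage * 7919) %% 2147483647)
}
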