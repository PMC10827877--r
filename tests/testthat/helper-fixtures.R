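# Small fixtures built in code: reduced montages, quick simulation and
# pipeline configurations, and handmade recordings.

tiny_montage <- function() make_montage(n_sources = 4, n_detectors = 4)

quick_sim <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 120, artifact_rate = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}

quick_cfg <- function(...) {
  pipeline_config(n_segments = 10, n_random_nets = 10, n_permutations = 200, ...)
}

# recording with a pure modulation signal per channel/wavelength:
# dod_fun(t, ch, wl) returns the optical-density fluctuation
make_recording <- function(n, nch = 2, fs = 7.81, dod_fun = function(t, ch, wl) 0,
                           I0 = 1000, participant = NULL) {
  t <- (seq_len(n) - 1) / fs
  intensity <- array(0, c(n, nch, 2))
  for (ch in seq_len(nch)) for (wl in 1:2) {
    intensity[, ch, wl] <- I0 * 10^(-dod_fun(t, ch, wl))
  }
  nirs_recording(intensity, fs = fs, participant = participant)
}
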