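#' Probe montage: source-detector channels and their regions of interest
#'
#' A montage describes the optode layout of a continuous-wave NIRS cap:
#' which source-detector pairs form measurement channels, the two optical
#' wavelengths, the source-detector separation, and the region of interest
#' (ROI) each channel samples. The default study layout has 16 sources and
#' 16 detectors yielding 64 channels at 3 cm separation, recorded at
#' 760 and 850 nm, with seven ROIs per hemisphere.
#'
#' @param sources integer vector of source IDs.
#' @param detectors integer vector of detector IDs.
#' @param channels data.frame with integer columns `source`, `detector`,
#'   one row per channel.
#' @param wavelengths two distinct positive wavelengths in nm.
#' @param channel_distance source-detector separation in cm (> 0).
#' @param roi_of_channel character vector, ROI label per channel.
#' @param rois ordered character vector of all ROI labels.
#' @return An object of class `probe_montage`.
#' @export
probe_montage <- function(sources, detectors, channels, wavelengths = c(760, 850),
                          channel_distance = 3, roi_of_channel, rois) {
  stopifnot(is.data.frame(channels), all(c("source", "detector") %in% names(channels)))
  if (length(wavelengths) != 2 || any(wavelengths <= 0) ||
      wavelengths[1] == wavelengths[2]) {
    stop("`wavelengths` must be two distinct positive values (nm)")
  }
  if (channel_distance <= 0) stop("`channel_distance` must be > 0 (cm)")
  if (length(roi_of_channel) != nrow(channels)) {
    stop("`roi_of_channel` must have one ROI label per channel")
  }
  bad <- setdiff(unique(roi_of_channel), rois)
  if (length(bad)) {
    stop("channel ROI labels not in `rois`: ", paste(bad, collapse = ", "))
  }
  if (!all(channels$source %in% sources) || !all(channels$detector %in% detectors)) {
    stop("channels reference unknown sources or detectors")
  }
  structure(
    list(sources = as.integer(sources), detectors = as.integer(detectors),
         channels = channels, wavelengths = as.numeric(wavelengths),
         channel_distance = channel_distance,
         roi_of_channel = as.character(roi_of_channel),
         rois = as.character(rois)),
    class = "probe_montage")
}

#' Default ROI labels
#'
#' Seven regions per hemisphere, anterior to posterior: prefrontal, Broca,
#' premotor, motor, inferior parietal, lateral temporal, temporal pole;
#' left hemisphere first.
#'
#' @return Character vector of 14 ROI labels.
#' @export
default_rois <- function() {
  base <- c("Prefrontal", "Broca", "Premotor", "Motor",
            "InferiorParietal", "TemporalLateral", "TemporalPole")
  c(paste0(base, "L"), paste0(base, "R"))
}

#' Frontal ROI labels (both hemispheres)
#'
#' The anterior regions treated as "frontal" when injecting or reporting
#' frontal hyperconnectivity: prefrontal, Broca, premotor and motor
#' cortices of each hemisphere.
#'
#' @return Character vector of 8 ROI labels.
#' @export
frontal_rois <- function() {
  base <- c("Prefrontal", "Broca", "Premotor", "Motor")
  c(paste0(base, "L"), paste0(base, "R"))
}

#' Build the default 64-channel probe montage
#'
#' Constructs a deterministic montage with `n_sources` sources and
#' `n_detectors` detectors split evenly between hemispheres; each source is
#' paired with four neighbouring detectors of its hemisphere, yielding
#' `4 * n_sources` channels. Channels are assigned to the seven ROIs of
#' their hemisphere in contiguous, roughly balanced blocks (5/5/5/5/4/4/4
#' channels per ROI for the default 32 channels per hemisphere).
#'
#' @param n_sources,n_detectors number of sources/detectors (even; default 16).
#' @param wavelengths two wavelengths in nm.
#' @param channel_distance separation in cm.
#' @return A `probe_montage` with 64 channels and 14 ROIs under defaults.
#' @export
make_montage <- function(n_sources = 16, n_detectors = 16,
                         wavelengths = c(760, 850), channel_distance = 3) {
  stopifnot(n_sources %% 2 == 0, n_detectors %% 2 == 0)
  half_s <- n_sources / 2
  half_d <- n_detectors / 2
  ch <- list()
  for (hemi in 0:1) {
    for (s in seq_len(half_s)) {
      for (j in 0:3) {
        ch[[length(ch) + 1L]] <- c(source = hemi * half_s + s,
                                   detector = hemi * half_d + ((s - 1 + j) %% half_d) + 1L)
      }
    }
  }
  channels <- as.data.frame(do.call(rbind, ch))
  rois <- default_rois()
  per_hemi <- nrow(channels) / 2
  sizes <- rep(per_hemi %/% 7, 7)
  extra <- per_hemi - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  roi_hemi_L <- rep(rois[1:7], times = sizes)
  roi_hemi_R <- rep(rois[8:14], times = sizes)
  probe_montage(sources = seq_len(n_sources), detectors = seq_len(n_detectors),
                channels = channels, wavelengths = wavelengths,
                channel_distance = channel_distance,
                roi_of_channel = c(roi_hemi_L, roi_hemi_R), rois = rois)
}

#' @exportS3Method base::print
print.probe_montage <- function(x, ...) {
  cat(sprintf("probe_montage: %d sources, %d detectors, %d channels, %d ROIs\n",
              length(x$sources), length(x$detectors), nrow(x$channels),
              length(x$rois)))
  cat(sprintf("wavelengths: %s nm; separation: %g cm\n",
              paste(x$wavelengths, collapse = "/"), x$channel_distance))
  invisible(x)
}

n_channels <- function(montage) nrow(montage$channels)

#' Write / read a montage as CSV
#'
#' One row per channel: `source`, `detector`, `roi`; wavelengths and
#' separation stored in `#`-prefixed header lines.
#'
#' @param montage a `probe_montage`.
#' @param path file path.
#' @return `read_montage` returns a `probe_montage`; `write_montage` its path.
#' @export
write_montage <- function(montage, path) {
  hdr <- c(sprintf("#wavelengths=%s", paste(montage$wavelengths, collapse = ",")),
           sprintf("#channel_distance=%g", montage$channel_distance))
  df <- cbind(montage$channels, roi = montage$roi_of_channel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^#%s=", key), "", grep(sprintf("^#%s=", key), hdr, value = TRUE))
  wl <- as.numeric(strsplit(get("wavelengths"), ",")[[1]])
  dist <- as.numeric(get("channel_distance"))
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  probe_montage(sources = sort(unique(df$source)), detectors = sort(unique(df$detector)),
                channels = df[, c("source", "detector")], wavelengths = wl,
                channel_distance = dist, roi_of_channel = df$roi,
                rois = unique(df$roi))
}
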