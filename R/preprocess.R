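#' Channel quality by cardiac phase coherence
#'
#' A usable NIRS channel carries the cardiac pulsation at both
#' wavelengths. Both wavelength series are band-passed to the cardiac band,
#' their instantaneous phases extracted from the analytic signal, and the
#' channel scored by the phase-locking value
#' \eqn{|\langle e^{i(\phi_{760}-\phi_{850})}\rangle|} over valid samples:
#' 1 for perfectly locked phases, near \eqn{1/\sqrt{N}} for independent
#' noise. Channels without a heartbeat (poor scalp coupling) score low.
#'
#' @param rec a `nirs_recording`.
#' @param cardiac_band band in Hz containing the heart rate
#'   (default 0.5-2.0).
#' @param order Butterworth order of the band filter.
#' @return Numeric vector, one score in \[0, 1\] per channel.
#' @export
cardiac_phase_coherence <- function(rec, cardiac_band = c(0.5, 2.0), order = 4) {
  if (any(cardiac_band <= 0) || any(cardiac_band >= rec$fs / 2)) {
    stop("cardiac_band must lie inside (0, fs/2)")
  }
  n <- dim(rec$intensity)[1]
  if (n / rec$fs < 10 / cardiac_band[1]) {
    stop("recording shorter than 10 cardiac cycles; phase coherence unreliable")
  }
  nch <- dim(rec$intensity)[2]
  # log-intensity fluctuations; filtering removes the mean anyway
  X <- matrix(log10(pmax(rec$intensity[, , 1], .Machine$double.eps)), n, nch)
  Y <- matrix(log10(pmax(rec$intensity[, , 2], .Machine$double.eps)), n, nch)
  A1 <- band_analytic(X, rec$fs, cardiac_band, order)
  A2 <- band_analytic(Y, rec$fs, cardiac_band, order)
  Z <- A1 * Conj(A2)
  Z <- Z / pmax(Mod(Z), .Machine$double.xmin)
  score <- numeric(nch)
  for (ch in seq_len(nch)) {
    ok <- rec$valid_mask[, ch]
    if (!any(ok)) {
      warning(sprintf("channel %d has no valid samples; coherence set to 0", ch))
      score[ch] <- 0
    } else {
      score[ch] <- Mod(mean(Z[ok, ch]))
    }
  }
  score
}

#' Motion-artifact detection by moving standard deviation
#'
#' Flags samples where the moving standard deviation of the log-intensity
#' exceeds `z_thresh` times its median over the recording, in either
#' wavelength; flagged regions are dilated by half a window on each side.
#' A constant channel yields no flags.
#'
#' @param rec a `nirs_recording`.
#' @param window_s moving window in seconds (default 1).
#' @param z_thresh threshold as a multiple of the channel's median moving
#'   std (default 3).
#' @return Logical time x channel matrix, TRUE = artifact.
#' @export
detect_motion_artifacts <- function(rec, window_s = 1, z_thresh = 3) {
  win <- max(2L, round(window_s * rec$fs))
  n <- dim(rec$intensity)[1]
  nch <- dim(rec$intensity)[2]
  flag <- matrix(FALSE, n, nch)
  for (w in seq_len(dim(rec$intensity)[3])) {
    L <- matrix(log10(pmax(rec$intensity[, , w], .Machine$double.eps)), n, nch)
    ms <- moving_std(L, win)
    med <- apply(ms, 2, stats::median)
    flag <- flag | sweep(ms, 2, z_thresh * med, ">")
  }
  half <- win %/% 2
  if (half > 0) {
    k <- rep(1, 2 * half + 1)
    d <- stats::filter(flag + 0, k, sides = 2)
    d[is.na(d)] <- 0
    # edges: undilated flags still count
    flag <- (d > 0) | flag
  }
  flag
}

#' Assemble a quality report and apply the rejection rules
#'
#' A channel is rejected if its cardiac phase coherence is strictly below
#' the coherence threshold, or if strictly more than the allowed fraction
#' of its time points are flagged. A participant is excluded if strictly
#' more than half of the channels are rejected (all cut-offs strict, and
#' configurable).
#'
#' @param report list with `coherence_of_channel` (numeric per channel),
#'   `artifact_mask` (logical time x channel) and optionally
#'   `valid_mask`; see [cardiac_phase_coherence()] and
#'   [detect_motion_artifacts()].
#' @param cfg a `pipeline_config`.
#' @return An object of class `quality_report` with the rejected channel
#'   set (with reason codes), per-channel bad fractions, the combined
#'   validity mask and the participant-level exclusion flag.
#' @export
apply_rejection_rules <- function(report, cfg = pipeline_config()) {
  coh <- report$coherence_of_channel
  art <- report$artifact_mask
  nch <- length(coh)
  stopifnot(ncol(art) == nch)
  bad_frac <- colMeans(art)
  low_coh <- which(coh < cfg$coherence_threshold)
  high_bad <- which(bad_frac > cfg$bad_timepoint_channel_fraction)
  rejected <- sort(union(low_coh, high_bad))
  reasons <- lapply(rejected, function(ch) {
    c(if (ch %in% low_coh) "low_coherence",
      if (ch %in% high_bad) "bad_fraction")
  })
  names(reasons) <- as.character(rejected)
  excluded <- length(rejected) / nch > cfg$bad_channel_participant_fraction
  valid <- if (!is.null(report$valid_mask)) report$valid_mask & !art else !art
  valid[, rejected] <- FALSE
  structure(list(coherence_of_channel = coh,
                 bad_fraction_of_channel = bad_frac,
                 rejected_channels = rejected,
                 rejection_reasons = reasons,
                 artifact_mask = art,
                 valid_mask = valid,
                 participant_excluded = excluded,
                 exclusion_reason = if (excluded)
                   sprintf("%d of %d channels rejected (> %g%%)", length(rejected),
                           nch, 100 * cfg$bad_channel_participant_fraction)
                 else NA_character_),
            class = "quality_report")
}

#' Zero-phase Butterworth band-pass
#'
#' Band-passes each column of `x` with a Butterworth filter of the given
#' order applied with zero phase (forward-backward magnitude response).
#' The default 0.01-0.08 Hz band isolates spontaneous hemodynamics and
#' suppresses cardiac (~1.1 Hz), respiratory (~0.2 Hz) and Mayer-wave
#' (~0.1 Hz) oscillations; a 1.1 Hz probe is attenuated by far more than
#' 40 dB while the passband is flat to within 1 dB.
#'
#' @param x numeric vector or time x channel matrix.
#' @param fs sampling rate in Hz.
#' @param band band edges in Hz; must lie strictly inside (0, fs/2).
#' @param order Butterworth order (default 4).
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, fs, band = c(0.01, 0.08), order = 4) {
  if (length(band) != 2 || any(!is.finite(band)) || band[1] <= 0 ||
      band[1] >= band[2] || band[2] >= fs / 2) {
    stop("config error: band edges must satisfy 0 < low < high < fs/2")
  }
  zero_phase_filter(x, fs, band, order, type = "pass")
}

#' Optical-density change from intensity
#'
#' For each channel, wavelength and contiguous valid segment, the change
#' in optical density is \eqn{\Delta OD = -\log_{10}(I / \bar I)} with
#' \eqn{\bar I} the segment mean, so each good segment is normalized by
#' its own average and dOD fluctuates around zero. Invalid samples are
#' returned as 0 (they stay masked downstream).
#'
#' @param intensity time x channel x wavelength array (or time x channel
#'   matrix for a single wavelength), strictly positive where valid.
#' @param valid_mask logical time x channel matrix; defaults to all valid.
#' @return Array of the same shape: unitless optical-density changes.
#' @export
to_optical_density <- function(intensity, valid_mask = NULL) {
  if (length(dim(intensity)) == 2) {
    intensity <- array(intensity, c(dim(intensity), 1))
    drop_wl <- TRUE
  } else drop_wl <- FALSE
  d <- dim(intensity)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1], d[2])
  dod <- array(0, d)
  for (ch in seq_len(d[2])) {
    runs <- true_runs(valid_mask[, ch])
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      idx <- runs[r, 1]:runs[r, 2]
      for (w in seq_len(d[3])) {
        seg <- intensity[idx, ch, w]
        if (any(seg <= 0)) {
          stop(sprintf("non-positive intensity in valid segment: channel %d, sample %d",
                       ch, idx[which(seg <= 0)[1]]))
        }
        dod[idx, ch, w] <- -log10(seg / mean(seg))
      }
    }
  }
  if (drop_wl) matrix(dod[, , 1], d[1], d[2]) else dod
}

#' Differential pathlength factor (general age/wavelength equation)
#'
#' Evaluates the published general equation for the DPF of the adult
#' frontal head as a function of age \eqn{A} (years) and wavelength
#' \eqn{\lambda} (nm):
#' \deqn{DPF = 223.3 + 0.05624\,A^{0.8493} - 5.723\times 10^{-7}\lambda^3
#'       + 0.001245\,\lambda^2 - 0.9025\,\lambda}
#' The DPF increases monotonically with age at a fixed wavelength. The
#' equation was fitted over roughly 690-832 nm; the default accepted range
#' extends to 860 nm so the common 850 nm NIRS wavelength can be used (a
#' mild extrapolation); wavelengths outside the accepted range error.
#'
#' @param age age in years (> 0).
#' @param wavelength wavelength in nm.
#' @param wavelength_range accepted wavelength interval in nm.
#' @return Unitless DPF value (vectorized over `age` and `wavelength`).
#' @export
dpf <- function(age, wavelength, wavelength_range = c(690, 860)) {
  if (any(age <= 0)) stop("age must be positive")
  if (any(wavelength < wavelength_range[1] | wavelength > wavelength_range[2])) {
    stop(sprintf("wavelength %s nm outside accepted range [%g, %g] nm",
                 paste(unique(wavelength), collapse = ", "),
                 wavelength_range[1], wavelength_range[2]))
  }
  223.3 + 0.05624 * age^0.8493 - 5.723e-7 * wavelength^3 +
    0.001245 * wavelength^2 - 0.9025 * wavelength
}

#' Hemoglobin extinction coefficients
#'
#' Tabulated base-10 molar extinction coefficients of oxy- and
#' deoxyhemoglobin at the two recording wavelengths, expressed per
#' micromolar and centimeter, i.e. units 1/(uM cm). These are data, not
#' code: supply your own table to [mbll()] to use another tabulation.
#'
#' @param wavelengths wavelengths (nm) to return rows for.
#' @return data.frame with columns `wavelength`, `HbO`, `HbR`.
#' @export
extinction_table <- function(wavelengths = c(760, 850)) {
  tab <- data.frame(wavelength = c(760, 850),
                    HbO = c(586, 1058) * 1e-6,
                    HbR = c(1548.52, 691.32) * 1e-6)
  idx <- match(wavelengths, tab$wavelength)
  if (any(is.na(idx))) {
    stop("no shipped extinction coefficients for wavelength(s): ",
         paste(wavelengths[is.na(idx)], collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

#' Modified Beer-Lambert law inversion
#'
#' Converts optical-density changes at two wavelengths into oxy- and
#' deoxyhemoglobin concentration changes by solving, per time point and
#' channel, the 2x2 linear system
#' \deqn{\Delta OD(\lambda) = \sum_c \varepsilon_c(\lambda)\,\Delta c\; d\,DPF(\lambda)}
#' with \eqn{d} the source-detector separation (cm) and DPF the
#' differential pathlength factor. With extinction coefficients in
#' 1/(uM cm), concentrations come out in uM.
#'
#' @param dod time x channel x 2 array of optical-density changes (order
#'   matching `wavelengths`).
#' @param age participant age in years (sets the DPF).
#' @param wavelengths the two wavelengths in nm.
#' @param distance source-detector separation in cm.
#' @param extinction extinction table as from [extinction_table()].
#' @param dpf_values optional length-2 DPF override (else computed from age).
#' @return time x channel x 2 array; third dimension is (HbO, HbR), in uM.
#' @export
mbll <- function(dod, age, wavelengths = c(760, 850), distance = 3,
                 extinction = extinction_table(wavelengths),
                 dpf_values = NULL) {
  stopifnot(length(dim(dod)) == 3, dim(dod)[3] == 2)
  if (is.null(dpf_values)) dpf_values <- dpf(age, wavelengths)
  A <- cbind(extinction$HbO, extinction$HbR) * distance * dpf_values
  cond_num <- kappa(A, exact = TRUE)
  if (!is.finite(cond_num) || abs(det(A)) < .Machine$double.eps) {
    stop("extinction system is singular; cannot separate HbO/HbR")
  }
  Ainv <- solve(A)
  out <- array(0, dim(dod))
  out[, , 1] <- Ainv[1, 1] * dod[, , 1] + Ainv[1, 2] * dod[, , 2]
  out[, , 2] <- Ainv[2, 1] * dod[, , 1] + Ainv[2, 2] * dod[, , 2]
  attr(out, "condition_number") <- cond_num
  dimnames(out) <- list(NULL, NULL, c("HbO", "HbR"))
  out
}

#' Forward modified Beer-Lambert law
#'
#' Generates optical-density changes from known concentration changes;
#' the exact inverse of [mbll()]. Used by the simulator and as a
#' round-trip oracle.
#'
#' @param dcon time x channel x 2 array (HbO, HbR) in uM.
#' @inheritParams mbll
#' @return time x channel x 2 array of optical-density changes.
#' @export
mbll_forward <- function(dcon, age, wavelengths = c(760, 850), distance = 3,
                         extinction = extinction_table(wavelengths),
                         dpf_values = NULL) {
  stopifnot(length(dim(dcon)) == 3, dim(dcon)[3] == 2)
  if (is.null(dpf_values)) dpf_values <- dpf(age, wavelengths)
  A <- cbind(extinction$HbO, extinction$HbR) * distance * dpf_values
  out <- array(0, dim(dcon))
  out[, , 1] <- A[1, 1] * dcon[, , 1] + A[1, 2] * dcon[, , 2]
  out[, , 2] <- A[2, 1] * dcon[, , 1] + A[2, 2] * dcon[, , 2]
  out
}

#' Remove the first principal component across channels
#'
#' Systemic physiology (residual cardiac, respiration, blood-pressure
#' waves) is the dominant source of shared variance across channels at
#' rest. The time x channel matrix of each chromophore is decomposed by
#' singular value decomposition and recomposed without its first
#' component, so the output's largest singular value equals the input's
#' second.
#'
#' @param x time x channel matrix (one chromophore).
#' @return Matrix of the same shape with the rank-1 dominant component
#'   removed. With a single channel the input is returned with a warning.
#' @export
pca_filter <- function(x) {
  if (is.null(dim(x)) || ncol(x) < 2) {
    warning("pca_filter needs >= 2 channels; returning input unchanged")
    return(x)
  }
  C <- crossprod(x)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  x - (x %*% v) %*% t(v)
}

#' Autoregressive prewhitening
#'
#' Fits an AR model per channel (Yule-Walker, order selected by AIC up to
#' `max_order`) and returns the innovation series, removing the temporal
#' autocorrelation that violates independence assumptions downstream.
#' Cross-channel correlation of the innovations is preserved up to the
#' (mild) difference between channel filters.
#'
#' @param x time x channel matrix.
#' @param max_order maximum AR order considered (default 20).
#' @return list with `whitened` (matrix, same shape; the first `order`
#'   samples of each channel are zero-padded partial residuals) and
#'   `orders` (selected AR order per channel).
#' @export
prewhiten <- function(x, max_order = 20) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  if (n <= 3 * max_order) stop("series too short for AR order selection")
  if (any(!is.finite(X))) stop("prewhiten requires finite input (mask gaps first)")
  Xc <- sweep(X, 2, colMeans(X))
  # autocovariance up to max_order for every channel at once
  acov <- matrix(0, max_order + 1, ncol(X))
  for (k in 0:max_order) {
    acov[k + 1, ] <- colSums(Xc[1:(n - k), , drop = FALSE] *
                               Xc[(1 + k):n, , drop = FALSE]) / n
  }
  W <- matrix(0, n, ncol(X))
  orders <- integer(ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- acov[, j]
    if (r[1] <= 0) { W[, j] <- Xc[, j]; next }
    sel <- levinson_aic(r, n, max_order)
    orders[j] <- sel$order
    p <- sel$order
    e <- Xc[, j]
    if (p > 0) {
      for (k in seq_len(p)) {
        e[(k + 1):n] <- e[(k + 1):n] - sel$phi[k] * Xc[1:(n - k), j]
      }
      e[seq_len(p)] <- 0  # incomplete history
    }
    W[, j] <- e
  }
  list(whitened = if (vec) drop(W) else W, orders = orders)
}

# Levinson-Durbin recursion with AIC order selection.
levinson_aic <- function(r, n, max_order) {
  sigma2 <- r[1]
  best <- list(order = 0L, phi = numeric(0),
               aic = n * log(sigma2))
  phi <- numeric(0)
  for (p in seq_len(max_order)) {
    k <- (r[p + 1] - if (p > 1) sum(phi * r[p:2]) else 0) / sigma2
    phi <- c(phi - k * rev(phi), k)
    sigma2 <- sigma2 * (1 - k^2)
    if (sigma2 <= 0) break
    aic <- n * log(sigma2) + 2 * p
    if (aic < best$aic) best <- list(order = p, phi = phi, aic = aic)
  }
  best
}

#' Preprocess one participant end-to-end
#'
#' Runs the full preprocessing chain in order: cardiac-coherence quality
#' control, motion-artifact masking, rejection rules, band-pass filtering
#' (applied to the intensity fluctuation around each valid segment's mean,
#' preserving positivity), optical-density normalization per good segment,
#' modified Beer-Lambert conversion with the age-dependent DPF, PCA
#' confound removal, and AR prewhitening. A stage audit log records the
#' executed order.
#'
#' @param rec a `nirs_recording` (participant metadata supplies the age).
#' @param montage the `probe_montage` (separation and wavelengths).
#' @param cfg a `pipeline_config`.
#' @param run_pca,run_prewhiten stage toggles (both default TRUE).
#' @return list with `dcon` (time x channel x 2, HbO/HbR, uM; prewhitened
#'   if configured), `dcon_pca` (PCA-filtered, not prewhitened),
#'   `dcon_band` (band-passed concentrations before the PCA filter: the
#'   "raw" concentration signal used for channel-level graph analysis),
#'   `report` (a `quality_report`), `retained` (channel indices),
#'   `ar_orders`, and `stage_log` (character vector of executed stages,
#'   in order).
#' @export
preprocess_participant <- function(rec, montage, cfg = pipeline_config(),
                                   run_pca = TRUE, run_prewhiten = TRUE) {
  stages <- character(0)
  coh <- cardiac_phase_coherence(rec, cfg$cardiac_band, cfg$filter_order)
  stages <- c(stages, "qc_phase_coherence")
  art <- detect_motion_artifacts(rec, cfg$artifact_window_s, cfg$artifact_z_thresh)
  stages <- c(stages, "artifact_mask")
  report <- apply_rejection_rules(
    list(coherence_of_channel = coh, artifact_mask = art,
         valid_mask = rec$valid_mask), cfg)
  nch <- dim(rec$intensity)[2]
  retained <- setdiff(seq_len(nch), report$rejected_channels)
  valid <- report$valid_mask

  # band-pass the intensity fluctuation around each valid run's mean
  d <- dim(rec$intensity)
  nwl <- d[3]
  fluct <- matrix(0, d[1], d[2] * nwl)
  base <- matrix(0, d[1], d[2] * nwl)
  for (ch in retained) {
    runs <- true_runs(valid[, ch])
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      idx <- runs[r, 1]:runs[r, 2]
      for (w in seq_len(nwl)) {
        col <- (w - 1) * d[2] + ch
        m <- mean(rec$intensity[idx, ch, w])
        base[idx, col] <- m
        fluct[idx, col] <- rec$intensity[idx, ch, w] - m
      }
    }
  }
  filt <- zero_phase_filter(fluct, rec$fs, cfg$band, cfg$filter_order, "pass")
  stages <- c(stages, "bandpass")
  ifilt <- array(0, d)
  for (w in seq_len(nwl)) {
    cols <- (w - 1) * d[2] + seq_len(d[2])
    ifilt[, , w] <- base[, cols] + filt[, cols]
  }
  # filtered fluctuations can graze zero only for pathological amplitudes;
  # clamp to keep the log defined
  ifilt[ifilt <= 0 & rep(valid, nwl)] <- .Machine$double.eps
  ifilt[rep(!valid, nwl)] <- 1  # placeholder outside valid runs

  dod <- to_optical_density(ifilt, valid)
  stages <- c(stages, "optical_density")
  age <- if (!is.null(rec$participant)) rec$participant$age else 30
  dcon <- mbll(dod, age = age, wavelengths = rec$wavelengths,
               distance = montage$channel_distance)
  stages <- c(stages, "mbll")

  dcon_pca <- dcon
  if (run_pca && length(retained) >= 2) {
    for (c in 1:2) dcon_pca[, retained, c] <- pca_filter(dcon[, retained, c])
    stages <- c(stages, "pca_filter")
  }
  ar_orders <- NULL
  dcon_out <- dcon_pca
  if (run_prewhiten) {
    for (c in 1:2) {
      pw <- prewhiten(dcon_pca[, retained, c, drop = TRUE], cfg$max_ar_order)
      dcon_out[, retained, c] <- pw$whitened
      if (c == 1) ar_orders <- pw$orders
    }
    stages <- c(stages, "prewhiten")
  }
  list(dcon = dcon_out, dcon_pca = dcon_pca, dcon_band = dcon,
       report = report, retained = retained, ar_orders = ar_orders,
       stage_log = stages)
}
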