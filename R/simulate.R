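#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the pipeline expects: a 12-min
#' resting recording at 7.81 Hz, 25 + 28 participants aged 45-51,
#' band-limited (0.01-0.08 Hz) spontaneous hemodynamics with an ROI-block
#' latent correlation structure, cardiac (~1.1 Hz), respiratory (~0.2 Hz)
#' and Mayer-wave (~0.1 Hz) confounds riding on the optical densities,
#' white measurement noise, occasional motion artifacts, rare dead
#' channels, and a lower childhood SES in the previously malnourished
#' (PEM) arm. Group effects are injected on the latent correlations:
#' `frontal_boost` deepens the frontal coupling block of PEM
#' participants (frontal hyperconnectivity), and `clustering_boost`
#' rewires their network lattice-ward -- long-range backbone coupling is
#' weakened and reallocated into within-ROI coupling (higher segregation,
#' lower integration). Amplitudes are in optical-density units.
#'
#' @param n_pem,n_con participants per arm (defaults 25 / 28).
#' @param duration_s recording length in seconds (default 720).
#' @param fs sampling rate in Hz (default 7.81).
#' @param base_within,base_between latent correlation within / between
#'   ROI blocks (defaults 0.6 / 0.15): strong local coupling, modest
#'   long-range coupling, as seen in band-limited resting NIRS after
#'   systemic-confound removal.
#' @param base_frontal baseline latent correlation of distinct-ROI
#'   channel pairs within the boosted frontal set (`boost_rois`), for
#'   both arms (default 0.45): homotopic and neighbouring frontal
#'   couplings are strong in everyone, so the PEM boost deepens existing
#'   connections instead of creating new long-range edges.
#' @param frontal_boost additive latent-correlation increase on distinct
#'   `boost_rois` pairs for PEM (default 0.3).
#' @param boost_rois ROI labels receiving the PEM frontal
#'   hyperconnectivity (default both prefrontal cortices and left Broca,
#'   echoing the left-dominant and interhemispheric frontal emphasis of
#'   resting-state malnutrition findings).
#' @param clustering_boost rewiring parameter in \[0, 1\] (default 0.6):
#'   scales the lattice-ward rewiring of the PEM arm's latent network --
#'   long-range backbone couplings are weakened by
#'   `backbone_weaken * clustering_boost` while within-ROI coupling
#'   rises by `clustering_realloc * clustering_boost`. Rewiring toward a
#'   lattice-like topology raises clustering and local efficiency and
#'   lowers global efficiency.
#' @param clustering_realloc within-ROI latent-correlation increment per
#'   unit of `clustering_boost` (default 0.25).
#' @param base_backbone baseline latent correlation of the long-range
#'   integration backbone, both arms (default 0.7): the homotopic
#'   left/right blocks of the non-boosted ROIs plus dorsal frontoparietal
#'   blocks (premotor/motor to inferior parietal, within each
#'   hemisphere). These are the strongest long-range couplings of resting
#'   cortical hemodynamics and carry most of the network's integration.
#' @param backbone_weaken amount subtracted from the PEM arm's backbone
#'   coupling per unit of `clustering_boost` (default 0.92, landing the
#'   weakened backbone at the plain between-ROI baseline): losing the
#'   backbone highways lowers global efficiency, and being
#'   block-localized the deficit survives the PCA confound filter.
#' @param match_baseline subtract/add a uniform offset on the plain
#'   between-ROI pairs of the PEM arm so both arms share the same mean
#'   latent correlation (default TRUE). The PCA filter removes each
#'   participant's global covariance mode, so an unmatched baseline would
#'   re-emerge inverted after filtering rather than as a group
#'   difference.
#' @param conn_jitter SD of per-participant latent-correlation jitter on
#'   the Fisher-z scale (default 0.045): between-subject variability,
#'   calibrated so cohort-level group effects land in the moderate-F
#'   regime typical of resting-state group studies.
#' @param amp_hbo SD of the HbO concentration fluctuation in uM
#'   (default 1); HbR is `-hbr_ratio` times HbO.
#' @param amp_systemic SD (uM HbO-equivalent) of the systemic
#'   low-frequency oscillation: a single band-limited (0.01-0.08 Hz)
#'   scalp-hemodynamic time course shared by all channels with
#'   channel-specific gain (default 1.5, i.e. larger than the cerebral
#'   signal, as at rest). This shared component is the dominant
#'   cross-channel covariance the PCA filter is designed to remove.
#' @param hbr_ratio HbR/HbO amplitude ratio (default 0.5).
#' @param amp_cardiac,amp_resp,amp_mayer,amp_noise confound amplitudes in
#'   dOD units (defaults 0.015, 0.01, 0.008, 0.003).
#' @param f_cardiac,f_resp,f_mayer confound frequencies in Hz
#'   (defaults 1.1, 0.2, 0.1).
#' @param artifact_rate motion artifacts per minute (default 2).
#' @param dead_channel_prob probability a channel lacks the cardiac
#'   signal (default 0.02).
#' @param ses_shift mean childhood-SES deficit of the PEM arm
#'   (default 0.81, in factor-score units).
#' @param age_range recording ages, drawn uniformly (default 45-51).
#' @param seed master seed for the cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pem = 25, n_con = 28, duration_s = 720, fs = 7.81,
                       base_within = 0.6, base_between = 0.15,
                       base_frontal = 0.45, frontal_boost = 0.3,
                       boost_rois = c("PrefrontalL", "BrocaL",
                                      "PrefrontalR"),
                       clustering_boost = 0.6,
                       clustering_realloc = 0.25,
                       base_backbone = 0.7, backbone_weaken = 0.92,
                       match_baseline = TRUE,
                       conn_jitter = 0.045,
                       amp_hbo = 1, amp_systemic = 1.5, hbr_ratio = 0.5,
                       amp_cardiac = 0.015, amp_resp = 0.01,
                       amp_mayer = 0.008, amp_noise = 0.003,
                       f_cardiac = 1.1, f_resp = 0.2, f_mayer = 0.1,
                       artifact_rate = 2, dead_channel_prob = 0.02,
                       ses_shift = 0.81, age_range = c(45, 51), seed = 1L) {
  cfg <- as.list(environment())
  amps <- c(amp_hbo, amp_cardiac, amp_resp, amp_mayer, amp_noise)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  for (v in c(base_within, base_between)) {
    if (v < -1 || v > 1) stop("base correlations must lie in [-1, 1]")
  }
  if (f_cardiac >= fs / 2) stop("f_cardiac must be below fs/2")
  if (dead_channel_prob < 0 || dead_channel_prob > 1) {
    stop("dead_channel_prob must be a probability")
  }
  structure(cfg, class = "sim_config")
}

#' Latent channel correlation matrix for one participant
#'
#' ROI-block structure mapped to channels: `base_within` inside an ROI,
#' `base_between` across ROIs, `base_frontal` on the frontal coupling
#' block, `base_backbone` on the long-range integration backbone
#' (homotopic and parietal-association blocks). PEM participants receive
#' the frontal boost and the lattice-ward rewiring (backbone weakened,
#' within-ROI reinforced), with the arms' mean latent correlation
#' matched; per-participant jitter is applied on the Fisher-z scale.
#' Correlations are clipped to [-0.95, 0.95] (keeping the Fisher
#' transform finite) and projected to the nearest positive semidefinite
#' correlation matrix.
#'
#' @param cfg a `sim_config`.
#' @param montage the `probe_montage`.
#' @param group `"PEM"` or `"CON"`.
#' @param seed jitter seed (NULL for no jitter).
#' @return list with `latent` (channel x channel correlation matrix) and
#'   `effect_map` (data.frame roi_a, roi_b, boost of injected effects).
#' @export
latent_correlation <- function(cfg, montage, group = "CON", seed = NULL) {
  roi <- montage$roi_of_channel
  nc <- length(roi)
  same_roi <- outer(roi, roi, "==")
  R <- matrix(cfg$base_between, nc, nc)
  R[same_roi] <- cfg$base_within
  effect <- data.frame(roi_a = character(0), roi_b = character(0),
                       boost = numeric(0))
  is_pem <- group == "PEM"
  fr <- intersect(cfg$boost_rois, montage$rois)
  is_fr <- roi %in% fr
  frontal_block <- outer(is_fr, is_fr, "&") & !same_roi
  R[frontal_block] <- cfg$base_frontal
  # long-range integration backbone: homotopic left/right blocks of the
  # non-boosted ROIs plus dorsal frontoparietal blocks per hemisphere
  backbone <- matrix(FALSE, nc, nc)
  base_names <- unique(sub("[LR]$", "", montage$rois))
  for (bn in base_names) {
    if (paste0(bn, "L") %in% fr || paste0(bn, "R") %in% fr) next
    li <- roi == paste0(bn, "L")
    ri <- roi == paste0(bn, "R")
    backbone[outer(li, ri) | outer(ri, li)] <- TRUE
  }
  for (h in c("L", "R")) {
    par <- roi == paste0("InferiorParietal", h)
    for (other in c("Premotor", "Motor", "TemporalLateral")) {
      oi <- roi == paste0(other, h)
      backbone[outer(oi, par) | outer(par, oi)] <- TRUE
    }
  }
  backbone <- backbone & !frontal_block & !same_roi
  R[backbone] <- cfg$base_backbone
  if (is_pem && cfg$clustering_boost != 0) {
    R[backbone] <- R[backbone] - cfg$backbone_weaken * cfg$clustering_boost
    R[same_roi] <- R[same_roi] + cfg$clustering_realloc * cfg$clustering_boost
  }
  if (is_pem && cfg$frontal_boost != 0) {
    R[frontal_block] <- R[frontal_block] + cfg$frontal_boost
    pairs <- t(utils::combn(fr, 2))
    effect <- data.frame(roi_a = pairs[, 1], roi_b = pairs[, 2],
                         boost = cfg$frontal_boost)
  }
  diag(R) <- 1
  if (is_pem && cfg$match_baseline) {
    # equalize the arms' mean latent correlation: the PCA stage removes
    # each participant's global covariance mode, so a baseline mismatch
    # would re-emerge inverted after filtering
    plain <- !same_roi & !frontal_block & !backbone
    target <- cfg$base_within * sum(same_roi & upper.tri(R)) +
      cfg$base_frontal * sum(frontal_block & upper.tri(R)) +
      cfg$base_backbone * sum(backbone & upper.tri(R)) +
      cfg$base_between * sum(plain & upper.tri(R))
    excess <- sum(R[upper.tri(R)]) - target
    R[plain] <- R[plain] - 2 * excess / sum(plain)
  }
  if (!is.null(seed) && cfg$conn_jitter > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    J <- matrix(stats::rnorm(nc * nc, 0, cfg$conn_jitter), nc, nc)
    J[lower.tri(J, diag = TRUE)] <- 0
    J <- J + t(J)
    off <- row(R) != col(R)
    R[off] <- tanh(atanh(pmin(pmax(R[off], -0.95), 0.95)) + J[off])
  }
  R[] <- pmin(pmax(R, -0.95), 0.95)
  diag(R) <- 1
  list(latent = nearest_psd_correlation(R), effect_map = effect)
}

#' Nearest positive semidefinite correlation matrix
#'
#' Projects a symmetric unit-diagonal matrix onto the positive
#' semidefinite correlation cone with Higham's alternating-projections
#' algorithm ([Matrix::nearPD()] with `corr = TRUE`), which preserves the
#' off-diagonal structure far better than one-shot eigenvalue clipping.
#' Falls back to eigenvalue clipping with rescaling if the iteration
#' fails to converge. Errors if the result is still not usable.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param floor smallest retained eigenvalue.
#' @return Symmetric positive definite correlation matrix.
#' @export
nearest_psd_correlation <- function(R, floor = 1e-8) {
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev > 0)) return(R)
  M <- tryCatch(
    as.matrix(Matrix::nearPD(R, corr = TRUE, eig.tol = 1e-7,
                             posd.tol = 1e-7)$mat),
    error = function(e) NULL)
  if (is.null(M)) {
    e <- eigen(R, symmetric = TRUE)
    v <- pmax(e$values, floor)
    M <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(M))
    M <- M / outer(d, d)
  }
  if (any(!is.finite(M))) stop("latent matrix not repairable to PSD")
  (M + t(M)) / 2
}

#' Band-limited correlated slow component
#'
#' White Gaussian noise with channel covariance `R` is band-passed to the
#' spontaneous-hemodynamics band and each channel rescaled to unit SD, so
#' the channel correlation of the output matches `R` up to sampling error.
#'
#' @param R channel correlation matrix.
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param band band in Hz.
#' @return n x channel matrix, unit SD per channel.
#' @export
simulate_slow_component <- function(R, n, fs = 7.81, band = c(0.01, 0.08)) {
  nc <- nrow(R)
  # eigen square root: tolerates semidefinite R (e.g. perfectly
  # correlated channels), unlike the Cholesky factor
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  B <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  Z <- matrix(stats::rnorm(n * nc), n, nc) %*% B
  S <- zero_phase_filter(Z, fs, band, 4, "pass")
  sweep(S, 2, pmax(apply(S, 2, stats::sd), .Machine$double.xmin), "/")
}

#' Simulate one participant's recording
#'
#' Builds the optical-density signal model: band-limited correlated HbO
#' fluctuations (HbR anti-correlated at `-hbr_ratio`), forward modified
#' Beer-Lambert projection onto the two wavelengths, shared-phase cardiac
#' / respiratory / Mayer sinusoids with channel-specific amplitude and
#' phase (cardiac amplitude ~0 on dead channels), white measurement
#' noise, and Poisson-timed motion artifacts (spikes and short baseline
#' shifts of random sign). Intensity is a positive baseline times
#' 10^(-dOD).
#'
#' @param cfg a `sim_config`.
#' @param info a `participant_info` (group determines injected effects).
#' @param montage the `probe_montage`.
#' @param seed participant seed.
#' @param keep_signal store the true (noise-free) HbO time series in the
#'   ground truth, for parameter-recovery tests (default FALSE).
#' @return list with `recording` (a `nirs_recording`) and `ground_truth`
#'   (latent correlation, effect map, dead channels, artifact times).
#' @export
simulate_participant <- function(cfg, info, montage, seed = 1L,
                                 keep_signal = FALSE) {
  lat <- latent_correlation(cfg, montage, info$group, seed = seed + 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nc <- n_channels(montage)
  n <- round(cfg$duration_s * cfg$fs)
  if (cfg$duration_s < 60) stop("duration must cover at least one segment")
  t <- (seq_len(n) - 1) / cfg$fs

  S <- simulate_slow_component(lat$latent, n, cfg$fs, c(0.01, 0.08))
  hbo <- cfg$amp_hbo * S
  if (cfg$amp_systemic > 0) {
    # systemic low-frequency oscillation: one shared scalp-hemodynamic
    # time course, channel-specific gain, same band as the cerebral signal
    g <- simulate_slow_component(matrix(1, 1, 1), n, cfg$fs, c(0.01, 0.08))
    gain <- stats::runif(nc, 0.5, 1.5)
    hbo <- hbo + cfg$amp_systemic * as.vector(g) %o% gain
  }
  dcon <- array(0, c(n, nc, 2))
  dcon[, , 1] <- hbo
  dcon[, , 2] <- -cfg$hbr_ratio * hbo
  dod <- mbll_forward(dcon, age = info$age, wavelengths = montage$wavelengths,
                      distance = montage$channel_distance)

  dead <- which(stats::runif(nc) < cfg$dead_channel_prob)
  wl_scale <- c(1, 0.8)
  add_osc <- function(dod, f, amp, per_channel_amp, shared_phase) {
    if (amp <= 0) return(dod)
    ph <- stats::runif(nc, 0, 2 * pi) * (1 - shared_phase) +
      stats::runif(1, 0, 2 * pi) * shared_phase
    a <- amp * per_channel_amp
    osc <- sin(outer(t, rep(2 * pi * f, nc)) + matrix(ph, n, nc, byrow = TRUE))
    for (w in 1:2) dod[, , w] <- dod[, , w] + osc %*% diag(a * wl_scale[w], nc)
    dod
  }
  card_amp <- stats::runif(nc, 0.6, 1.4)
  if (length(dead)) card_amp[dead] <- 0.001
  f_card <- cfg$f_cardiac * stats::runif(1, 0.95, 1.05)
  dod <- add_osc(dod, f_card, cfg$amp_cardiac, card_amp, shared_phase = 0)
  dod <- add_osc(dod, cfg$f_resp, cfg$amp_resp, stats::runif(nc, 0.5, 1.5), 1)
  dod <- add_osc(dod, cfg$f_mayer, cfg$amp_mayer, stats::runif(nc, 0.5, 1.5), 1)
  if (cfg$amp_noise > 0) {
    dod <- dod + array(stats::rnorm(n * nc * 2, 0, cfg$amp_noise), c(n, nc, 2))
  }

  n_art <- stats::rpois(1, cfg$artifact_rate * cfg$duration_s / 60)
  art_times <- sort(stats::runif(n_art, 0, cfg$duration_s))
  for (ta in art_times) {
    i0 <- max(1L, round(ta * cfg$fs))
    hit <- which(stats::runif(nc) < 0.7)
    if (!length(hit)) next
    if (stats::runif(1) < 0.5) {  # spike with exponential decay (~0.5 s)
      len <- min(round(0.5 * cfg$fs) + 1L, n - i0 + 1L)
      shape <- exp(-(0:(len - 1)) / (0.15 * cfg$fs))
      amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.2)
    } else {  # baseline shift lasting 1-3 s
      len <- min(round(stats::runif(1, 1, 3) * cfg$fs), n - i0 + 1L)
      shape <- rep(1, len)
      amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.02, 0.08)
    }
    idx <- i0:(i0 + len - 1L)
    for (w in 1:2) {
      dod[idx, hit, w] <- dod[idx, hit, w] + amp * shape
    }
  }

  I0 <- exp(stats::rnorm(nc, log(1000), 0.2))
  intensity <- array(0, c(n, nc, 2))
  for (w in 1:2) {
    intensity[, , w] <- matrix(I0, n, nc, byrow = TRUE) * 10^(-dod[, , w])
  }
  rec <- nirs_recording(intensity, fs = cfg$fs,
                        wavelengths = montage$wavelengths, participant = info)
  gt <- list(latent_correlation = lat$latent, effect_map = lat$effect_map,
             dead_channels = dead, artifact_times = art_times)
  if (keep_signal) gt$hbo <- cfg$amp_hbo * S
  list(recording = rec, ground_truth = gt)
}

#' Simulate a full cohort
#'
#' Draws a roster (ages uniform in `age_range`, SES normal with the PEM
#' arm shifted down by `ses_shift`, sex and handedness matched across
#' arms) and one recording plus ground truth per participant, with all
#' seeds derived deterministically from the master seed.
#'
#' @param cfg a `sim_config`.
#' @param montage the `probe_montage` (default [make_montage()]).
#' @param recordings generate recordings (set FALSE for a roster-only
#'   draw).
#' @return list with `roster` (list of `participant_info`), `recordings`,
#'   `ground_truths`.
#' @export
simulate_cohort <- function(cfg, montage = make_montage(), recordings = TRUE) {
  stopifnot(cfg$n_pem >= 1, cfg$n_con >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(derive_seed(cfg$seed, 0L, 1L))
  ntot <- cfg$n_pem + cfg$n_con
  groups <- c(rep("PEM", cfg$n_pem), rep("CON", cfg$n_con))
  ages <- stats::runif(ntot, cfg$age_range[1], cfg$age_range[2])
  sexes <- ifelse(stats::runif(ntot) < 0.53, "M", "F")
  hands <- ifelse(stats::runif(ntot) < 0.11, "L", "R")
  ses <- stats::rnorm(ntot, ifelse(groups == "PEM", -cfg$ses_shift, 0), 0.76)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  roster <- lapply(seq_len(ntot), function(i) {
    participant_info(sprintf("%s%03d", substr(groups[i], 1, 1), i), groups[i],
                     ages[i], sexes[i], hands[i], ses[i])
  })
  recs <- gts <- NULL
  if (recordings) {
    sims <- lapply(seq_len(ntot), function(i) {
      simulate_participant(cfg, roster[[i]], montage,
                           seed = derive_seed(cfg$seed, i, 2L))
    })
    recs <- lapply(sims, `[[`, "recording")
    gts <- lapply(sims, `[[`, "ground_truth")
  }
  list(roster = roster, recordings = recs, ground_truths = gts)
}
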