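test_that("phase coherence is ~1 for a shared cardiac sinusoid", {
  rec <- make_recording(1200, nch = 2, dod_fun = function(t, ch, wl) {
    0.01 * sin(2 * pi * 1.1 * t + ch) + rnorm(length(t), 0, 5e-4)
  })
  coh <- cardiac_phase_coherence(rec)
  expect_true(all(coh > 0.97))
})

test_that("phase coherence of independent noise stays well below threshold", {
  set.seed(10)
  scores <- replicate(50, {
    rec <- make_recording(600, nch = 1, dod_fun = function(t, ch, wl) {
      rnorm(length(t), 0, 0.01)  # independent across wavelengths
    })
    cardiac_phase_coherence(rec)
  })
  expect_lt(mean(scores), 0.5)
  expect_lt(mean(scores > 0.85), 0.1)
})

test_that("phase coherence rejects too-short recordings and flags dead masks", {
  rec <- make_recording(50, nch = 1)
  expect_error(cardiac_phase_coherence(rec), "cardiac cycles")
  rec2 <- make_recording(600, nch = 2,
                         dod_fun = function(t, ch, wl) 0.01 * sin(2 * pi * 1.1 * t))
  rec2$valid_mask[, 2] <- FALSE
  expect_warning(coh <- cardiac_phase_coherence(rec2), "no valid samples")
  expect_equal(coh[2], 0)
})

test_that("motion detector flags spikes with dilation and ignores clean signals", {
  n <- 1000
  clean <- make_recording(n, nch = 1,
                          dod_fun = function(t, ch, wl) 0.01 * sin(2 * pi * 0.05 * t))
  expect_equal(sum(detect_motion_artifacts(clean)), 0)

  spiky <- make_recording(n, nch = 1, dod_fun = function(t, ch, wl) {
    x <- 0.005 * sin(2 * pi * 0.05 * t) + rnorm(length(t), 0, 0.001)
    x[500] <- x[500] + 0.4
    x
  })
  flags <- detect_motion_artifacts(spiky)
  expect_true(flags[500, 1])
  # dilation: neighbours inside half a window are flagged too
  expect_true(all(flags[497:503, 1]))
  expect_lt(mean(flags), 0.05)
})

test_that("rejection rules follow the strict threshold semantics", {
  cfg <- pipeline_config()
  art <- matrix(FALSE, 100, 64)
  mk <- function(coh, art) apply_rejection_rules(
    list(coherence_of_channel = coh, artifact_mask = art), cfg)

  # coherence exactly at threshold is retained (strictly below rejects)
  coh <- rep(0.95, 64)
  coh[1] <- 0.85
  coh[2] <- 0.8499
  rep1 <- mk(coh, art)
  expect_equal(rep1$rejected_channels, 2L)
  expect_equal(rep1$rejection_reasons[["2"]], "low_coherence")

  # bad fraction strictly above 25% rejects
  art2 <- art
  art2[1:25, 3] <- TRUE   # exactly 25% -> retained
  art2[1:26, 4] <- TRUE   # 26% -> rejected
  rep2 <- mk(rep(0.95, 64), art2)
  expect_equal(rep2$rejected_channels, 4L)
  expect_equal(rep2$rejection_reasons[["4"]], "bad_fraction")
  expect_equal(rep2$bad_fraction_of_channel[3], 0.25)

  # participant exclusion strictly above 50% of channels
  rep3 <- mk(c(rep(0.2, 32), rep(0.95, 32)), art)
  expect_false(rep3$participant_excluded)  # exactly half
  rep4 <- mk(c(rep(0.2, 33), rep(0.95, 31)), art)
  expect_true(rep4$participant_excluded)
  expect_match(rep4$exclusion_reason, "33 of 64")
})

test_that("a 30%-artifact channel is rejected by the 25% rule", {
  n <- 1000
  art <- matrix(FALSE, n, 2)
  art[seq_len(300), 2] <- TRUE
  rep <- apply_rejection_rules(
    list(coherence_of_channel = c(0.95, 0.95), artifact_mask = art),
    pipeline_config())
  expect_equal(rep$rejected_channels, 2L)
})

test_that("band-pass meets its gain specification", {
  fs <- 7.81
  t <- (0:9999) / fs
  amp_of <- function(f) {
    x <- if (f == 0) rep(1, length(t)) else sin(2 * pi * f * t)
    y <- bandpass(x, fs)
    mid <- y[2500:7500]
    if (f == 0) abs(mean(mid)) else sqrt(2) * sd(mid)
  }
  expect_gt(20 * log10(amp_of(0.04)), -1)       # passband flat within 1 dB
  expect_lt(20 * log10(amp_of(1.1)), -40)       # cardiac suppressed >= 40 dB
  expect_lt(amp_of(0), 1e-3)                    # DC removed
  expect_error(bandpass(t, fs, band = c(0, 0.08)), "band edges")
  expect_error(bandpass(t, fs, band = c(0.01, 4)), "band edges")
})

test_that("FFT zero-phase filter matches filtfilt", {
  fs <- 7.81
  set.seed(2)
  x <- rnorm(6000)
  # well-conditioned band: the two implementations agree to machine precision
  ours <- nirsgraph:::zero_phase_filter(x, fs, c(0.5, 2.0), 4, "pass")
  bt <- signal::butter(4, c(0.5, 2.0) / (fs / 2), type = "pass")
  ref <- signal::filtfilt(bt, x)
  mid <- 1000:5000
  expect_lt(sqrt(mean((ours[mid] - ref[mid])^2)) / sd(ref[mid]), 1e-8)
  # (in the ultra-narrow 0.01-0.08 Hz band filtfilt's fixed padding cannot
  # absorb the ~1000-sample impulse response and is itself inaccurate; the
  # narrowband behaviour is validated by the analytic gain tests above)
})

test_that("optical density normalizes each good segment by its mean", {
  const <- matrix(1000, 50, 1)
  expect_equal(to_optical_density(const), matrix(0, 50, 1))

  x <- 0.03 * sin(seq_len(200) / 10)
  I <- matrix(1000 * 10^(-x), ncol = 1)
  dod <- to_optical_density(I)
  expect_equal(as.vector(dod), x - (-log10(mean(10^(-x)))), tolerance = 1e-12)

  dip <- matrix(1000, 100, 1)
  dip[50, 1] <- 990  # 1% intensity dip
  dod2 <- to_optical_density(dip)
  # against the segment mean this is -log10(0.99) up to the tiny mean shift
  expect_equal(dod2[50, 1], -log10(990 / mean(dip)), tolerance = 1e-12)
  expect_equal(dod2[50, 1], 0.004364805, tolerance = 0.02)

  bad <- matrix(1, 10, 1)
  bad[3, 1] <- -1
  expect_error(to_optical_density(bad), "channel 1, sample 3")
})

test_that("the DPF equation behaves as published", {
  expect_gt(dpf(51, 760), dpf(45, 760))              # monotone in age
  expect_false(dpf(48.6, 760) == dpf(48.6, 850))     # wavelength dependent
  # transcription of the published coefficients, evaluated independently
  expect_equal(dpf(48.6, 760), 6.80835359594, tolerance = 1e-9)
  expect_equal(dpf(48.6, 850), 5.74608089594, tolerance = 1e-9)
  expect_error(dpf(48.6, 1200), "outside accepted range")
  expect_error(dpf(-1, 760), "age")
})

test_that("MBLL inverts its forward model exactly", {
  n <- 20
  dcon <- array(0, c(n, 2, 2))
  dcon[, , 1] <- 1.0    # HbO in uM
  dcon[, , 2] <- -0.25  # HbR
  dod <- mbll_forward(dcon, age = 48)
  back <- mbll(dod, age = 48)
  expect_lt(max(abs(back - dcon)), 1e-9)

  # zero in, zero out
  expect_equal(mbll(array(0, c(5, 1, 2)), age = 48), array(0, c(5, 1, 2)),
               ignore_attr = TRUE)

  # linearity and inverse scaling with distance
  a <- 3.7
  expect_equal(mbll(dod * a, age = 48), back * a, ignore_attr = TRUE,
               tolerance = 1e-12)
  half <- mbll(dod, age = 48, distance = 6)
  expect_equal(unclass(half), unclass(back) / 2, ignore_attr = TRUE,
               tolerance = 1e-12)

  bad_ext <- data.frame(wavelength = c(760, 850), HbO = c(1, 1), HbR = c(1, 1))
  expect_error(mbll(dod, age = 48, extinction = bad_ext), "singular")
})

test_that("PCA filter removes exactly the leading component", {
  n <- 300
  u1 <- sin(2 * pi * (1:n) / 40)
  v1 <- c(1, 1, 1, 1) / 2
  rank1 <- u1 %o% (v1 * 5)
  out <- pca_filter(rank1)
  expect_lt(max(abs(out)), 1e-9)

  # orthogonal second component survives untouched
  u2 <- sin(2 * pi * (1:n) / 11)
  u1o <- u1 - sum(u1 * u2) / sum(u2 * u2) * u2
  v2 <- c(1, -1, 1, -1) / 2
  X <- 5 * u1o %o% v1 + 1 * u2 %o% v2
  out2 <- pca_filter(X)
  expect_lt(max(abs(out2 - u2 %o% v2)), 1e-6)

  # shared global signal: mean inter-channel correlation drops
  set.seed(3)
  g <- sin(2 * pi * (1:n) / 25)
  Y <- g %o% runif(6, 0.8, 1.2) + matrix(rnorm(n * 6, 0, 0.5), n, 6)
  before <- mean(cor(Y)[upper.tri(diag(6))])
  after <- mean(cor(pca_filter(Y))[upper.tri(diag(6))])
  expect_lt(after, before - 0.2)

  expect_warning(same <- pca_filter(matrix(1:5, ncol = 1)), ">= 2 channels")
  expect_equal(same, matrix(1:5, ncol = 1))
})

test_that("prewhitening removes autocorrelation and keeps cross-correlation", {
  set.seed(8)
  n <- 2000
  # white noise passes through almost unchanged
  w <- matrix(rnorm(n), ncol = 1)
  pw <- prewhiten(w)
  expect_lte(pw$orders[1], 8)
  expect_gt(cor(pw$whitened[-(1:20), 1], w[-(1:20), 1]), 0.98)

  # AR(1) phi = 0.8: innovations have |lag-1 autocorrelation| < 0.1
  x <- as.vector(arima.sim(list(ar = 0.8), n))
  pw2 <- prewhiten(matrix(x, ncol = 1))
  r1 <- acf(pw2$whitened[-(1:20), 1], plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r1), 0.1)

  # selected order agrees with stats::ar.yw on the same series
  ref <- stats::ar.yw(x, order.max = 20)
  expect_lt(abs(pw2$orders[1] - ref$order), 3)

  # channels driven by correlated innovations keep their correlation
  e1 <- rnorm(n); e2 <- 0.6 * e1 + sqrt(1 - 0.36) * rnorm(n)
  y1 <- as.vector(stats::filter(e1, 0.8, method = "recursive"))
  y2 <- as.vector(stats::filter(e2, 0.8, method = "recursive"))
  pw3 <- prewhiten(cbind(y1, y2))
  r <- cor(pw3$whitened[-(1:20), 1], pw3$whitened[-(1:20), 2])
  expect_lt(abs(r - 0.6), 3 / sqrt(n) + 0.05)

  expect_error(prewhiten(rnorm(30), max_order = 20), "too short")
})

test_that("the preprocessing chain runs in the documented stage order", {
  mont <- tiny_montage()
  sim <- simulate_participant(quick_sim(seed = 4),
                              participant_info("s1", "CON", 48), mont, seed = 9)
  pre <- preprocess_participant(sim$recording, mont, quick_cfg())
  expect_equal(pre$stage_log,
               c("qc_phase_coherence", "artifact_mask", "bandpass",
                 "optical_density", "mbll", "pca_filter", "prewhiten"))
  expect_equal(dim(pre$dcon), c(dim(sim$recording$intensity)[1], 16, 2))
  expect_true(all(is.finite(pre$dcon[, pre$retained, ])))

  # determinism: identical input yields an identical quality report
  pre2 <- preprocess_participant(sim$recording, mont, quick_cfg())
  expect_identical(pre$report, pre2$report)
  expect_identical(pre$dcon, pre2$dcon)
})

test_that("preprocessing is near-identity on the slow component without confounds", {
  mont <- tiny_montage()
  cfg <- quick_sim(duration_s = 240, amp_cardiac = 0, amp_resp = 0,
                   amp_mayer = 0, amp_noise = 0, amp_systemic = 0,
                   artifact_rate = 0, dead_channel_prob = 0)
  sim <- simulate_participant(cfg, participant_info("s2", "CON", 48), mont,
                              seed = 13, keep_signal = TRUE)
  # a high artifact threshold keeps the detector from flagging the
  # (legitimate) high-amplitude epochs of the slow wave itself
  pre <- preprocess_participant(sim$recording, mont,
                                quick_cfg(artifact_z_thresh = 10),
                                run_pca = FALSE, run_prewhiten = FALSE)
  hbo <- sim$ground_truth$hbo
  cors <- vapply(seq_len(ncol(hbo)), function(ch) {
    cor(pre$dcon[, ch, 1], hbo[, ch])
  }, 0)
  expect_true(all(cors > 0.95))
})
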