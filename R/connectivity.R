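#' Randomly sample fixed-length segments, keeping sufficiently valid ones
#'
#' Draws `n` segment start offsets uniformly (with replacement, so
#' overlaps are allowed -- 200 non-overlapping 60-s windows cannot fit a
#' 12-min recording) and retains segments whose valid-sample fraction is
#' at least `min_valid` (inclusive). Validity of a time point is its mean
#' validity over the retained channels.
#'
#' @param valid_mask logical time x channel matrix (retained channels only).
#' @param fs sampling rate in Hz.
#' @param n number of segments drawn (default 200).
#' @param length_s segment length in seconds (default 60).
#' @param min_valid minimum valid fraction to retain a segment
#'   (default 0.90).
#' @param seed RNG seed: the same seed always yields the same segments.
#' @return Integer matrix with columns `start`, `end` (sample indices),
#'   one row per retained segment.
#' @export
sample_segments <- function(valid_mask, fs, n = 200, length_s = 60,
                            min_valid = 0.90, seed = 1L) {
  nt <- nrow(valid_mask)
  len <- round(length_s * fs)
  if (nt < len) stop("recording shorter than one segment")
  frac_valid <- rowMeans(valid_mask)
  cs <- c(0, cumsum(frac_valid))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  starts <- sample.int(nt - len + 1L, n, replace = TRUE)
  frac <- (cs[starts + len] - cs[starts]) / len
  keep <- frac >= min_valid
  seg <- cbind(start = starts[keep], end = starts[keep] + len - 1L)
  if (!nrow(seg)) {
    stop("no segment reached the required valid fraction; participant unusable")
  }
  seg
}

#' Mean Pearson correlation over resampled segments
#'
#' Computes the channel x channel Pearson correlation within each retained
#' segment, using the segment's valid time points (rows valid across the
#' supplied channels), and averages the per-segment matrices, giving an
#' estimate representative of the whole recording. Pairs undefined in a
#' segment (constant channel, too few valid samples) are excluded from
#' that segment's contribution with a warning.
#'
#' @param x time x channel matrix (one chromophore).
#' @param segments matrix from [sample_segments()].
#' @param valid_mask logical time x channel matrix aligned with `x`; NULL
#'   for all-valid.
#' @return Symmetric channel x channel matrix with unit diagonal.
#' @export
mean_segment_correlation <- function(x, segments, valid_mask = NULL) {
  nch <- ncol(x)
  acc <- matrix(0, nch, nch)
  cnt <- matrix(0, nch, nch)
  dropped <- 0
  for (s in seq_len(nrow(segments))) {
    idx <- segments[s, 1]:segments[s, 2]
    xs <- x[idx, , drop = FALSE]
    if (!is.null(valid_mask)) {
      vm <- valid_mask[idx, , drop = FALSE]
      if (!all(vm)) {
        rows <- rowSums(vm) == ncol(vm)
        if (sum(rows) < 3) next
        xs <- xs[rows, , drop = FALSE]
      }
    }
    r <- suppressWarnings(stats::cor(xs))
    ok <- is.finite(r)
    if (any(!ok)) dropped <- dropped + 1
    acc[ok] <- acc[ok] + r[ok]
    cnt <- cnt + ok
  }
  if (dropped > 0) {
    warning(sprintf("%d segment(s) had undefined correlations for some pairs; those pairs averaged over fewer segments", dropped))
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- NA
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Fisher transformation of a correlation matrix
#'
#' Applies \eqn{z = \mathrm{atanh}(r)} elementwise off the diagonal to
#' variance-stabilize the correlation distribution; the diagonal is set to
#' 0 by convention. Off-diagonal values at exactly +/-1 are clipped to
#' +/-0.999999 with a warning.
#'
#' @param r correlation matrix.
#' @return Matrix of Fisher z values.
#' @export
fisher_z <- function(r) {
  z <- r
  off <- row(r) != col(r)
  v <- r[off]
  if (any(abs(v) >= 1, na.rm = TRUE)) {
    warning("off-diagonal |r| >= 1 clipped to 0.999999 before atanh")
    v <- pmin(pmax(v, -0.999999), 0.999999)
  }
  z[off] <- atanh(v)
  diag(z) <- 0
  z
}

#' Average a channel-level matrix into ROI blocks
#'
#' Entry (A, B) is the mean of `z` over all retained channel pairs with
#' one channel in ROI A and the other in ROI B; the diagonal (A = A)
#' averages the distinct within-ROI pairs. ROIs with no retained channel
#' (or, on the diagonal, fewer than two) yield NA and are logged with a
#' warning.
#'
#' @param z channel x channel matrix (e.g. Fisher-z connectivity).
#' @param montage the `probe_montage` assigning channels to ROIs.
#' @param retained channel indices that survived quality control.
#' @return Symmetric 14 x 14 (n-ROI x n-ROI) matrix.
#' @export
roi_average <- function(z, montage, retained = seq_len(nrow(z))) {
  rois <- montage$rois
  nro <- length(rois)
  out <- matrix(NA_real_, nro, nro, dimnames = list(rois, rois))
  members <- lapply(rois, function(g) {
    intersect(retained, which(montage$roi_of_channel == g))
  })
  empty <- rois[vapply(members, length, 1L) == 0]
  if (length(empty)) {
    warning("ROIs with no retained channels: ", paste(empty, collapse = ", "))
  }
  for (a in seq_len(nro)) {
    for (b in a:nro) {
      ma <- members[[a]]; mb <- members[[b]]
      if (!length(ma) || !length(mb)) next
      if (a == b) {
        if (length(ma) < 2) next
        block <- z[ma, ma, drop = FALSE]
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.vector(z[ma, mb, drop = FALSE])
      }
      out[a, b] <- out[b, a] <- mean(vals, na.rm = TRUE)
    }
  }
  out
}

#' Segment-resampled connectivity for one participant
#'
#' Chains [sample_segments()], [mean_segment_correlation()], [fisher_z()]
#' and [roi_average()] for one chromophore of a preprocessed participant.
#'
#' @param dcon time x channel x chromophore array from
#'   [preprocess_participant()].
#' @param valid_mask logical time x channel matrix.
#' @param montage the `probe_montage`.
#' @param retained retained channel indices.
#' @param cfg a `pipeline_config`.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param seed segment-sampling seed.
#' @param fs sampling rate in Hz.
#' @return An object of class `connectivity_result`: list with `r_channel`
#'   (mean Pearson, retained channels only on the full channel grid, NA
#'   elsewhere), `z_channel`, `z_roi`, `n_segments_used`, `chromophore`,
#'   `retained`.
#' @export
participant_connectivity <- function(dcon, valid_mask, montage, retained,
                                     cfg = pipeline_config(),
                                     chromophore = c("HbO", "HbR"), seed = 1L,
                                     fs = 7.81) {
  chromophore <- match.arg(chromophore)
  ci <- if (chromophore == "HbO") 1 else 2
  segs <- sample_segments(valid_mask[, retained, drop = FALSE], fs,
                          n = cfg$n_segments, length_s = cfg$segment_length_s,
                          min_valid = cfg$segment_valid_fraction, seed = seed)
  x <- dcon[, retained, ci, drop = TRUE]
  vm <- valid_mask[, retained, drop = FALSE]
  all_valid <- all(vm)
  r_ret <- mean_segment_correlation(x, segs, if (all_valid) NULL else vm)
  nch <- dim(dcon)[2]
  r_channel <- matrix(NA_real_, nch, nch)
  r_channel[retained, retained] <- r_ret
  z_channel <- matrix(NA_real_, nch, nch)
  z_channel[retained, retained] <- fisher_z(r_ret)
  z_roi <- roi_average(z_channel, montage, retained)
  structure(list(r_channel = r_channel, z_channel = z_channel, z_roi = z_roi,
                 n_segments_used = nrow(segs), chromophore = chromophore,
                 retained = retained),
            class = "connectivity_result")
}
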