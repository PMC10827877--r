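#' Cohort graph-topology analysis
#'
#' Implements the threshold-sweep graph pipeline at cohort level:
#' \enumerate{
#'   \item absolutized channel connectivity per participant;
#'   \item threshold selection on the cohort-average matrix -- the range
#'     of thresholds where the average network is fully connected
#'     (Kmin >= 1, CCmin >= 0) and small-world (SW >= 1, with SW from the
#'     average matrix's own random nulls);
#'   \item per participant and in-range threshold, the real metrics and
#'     the mean metrics of degree-preserving random nulls;
#'   \item normalization of each participant's real curves by the mean of
#'     all participants' null curves (grand mean by default; set
#'     `normalization = "participant"` to use each participant's own
#'     nulls), SW = NormCC/NormLL;
#'   \item trapezoidal AUC of each normalized metric over the selected
#'     range.
#' }
#'
#' @param r_list list of channel x channel mean-correlation matrices (NA
#'   rows/columns for rejected channels are dropped per participant).
#' @param cfg a `pipeline_config` (threshold grid, null count, seed).
#' @param normalization `"grand"` (default) or `"participant"`.
#' @param null_subgrid evaluate the random-null metric means at every
#'   `null_subgrid`-th threshold of the selected range (always including
#'   both endpoints) and interpolate linearly in between (default 1,
#'   i.e. every threshold). The null-mean curves are smooth in the
#'   threshold, so a coarser subgrid changes the normalization
#'   denominators negligibly while cutting most of the null-network
#'   computation.
#' @return list with `range` (lo/hi/idx), `grid`, `avg_curves`
#'   (cohort-average-matrix criterion curves), `auc` (data.frame, one row
#'   per participant with CC/LE/GE/LL/SW AUCs), `normalized` (list of
#'   per-participant normalized curve matrices), `random_grand_mean`.
#' @export
cohort_graph_analysis <- function(r_list, cfg = pipeline_config(),
                                  normalization = c("grand", "participant"),
                                  null_subgrid = 1L) {
  normalization <- match.arg(normalization)
  grid <- cfg$thresholds
  np <- length(r_list)
  stack <- simplify2array(r_list)
  avg <- apply(stack, c(1, 2), mean, na.rm = TRUE)
  avg[!is.finite(avg)] <- 0
  W_avg <- absolutize(avg)

  # criterion curves on the cohort-average matrix
  n_null_avg <- cfg$n_random_nets
  kmin <- ccmin <- sw <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    g <- W_avg
    g[g <= grid[i]] <- 0
    m <- cpp_criterion_metrics(g)
    kmin[i] <- m$K_min
    ccmin[i] <- m$CC_min
    if (sum(g > 0) == 0 || m$K_min < 1) next
    nulls <- random_null(g, n = n_null_avg,
                         seed = derive_seed(cfg$rng_seed, i, 10L))
    ncc <- nll <- numeric(length(nulls))
    for (k in seq_along(nulls)) {
      nm <- cpp_criterion_metrics(nulls[[k]])
      ncc[k] <- nm$CC_mean
      nll[k] <- nm$LL
    }
    norm_cc <- m$CC_mean / mean(ncc)
    norm_ll <- m$LL / mean(nll, na.rm = TRUE)
    sw[i] <- norm_cc / norm_ll
  }
  range_sel <- select_threshold_range(grid, kmin, ccmin, sw)
  idx <- range_sel$idx
  avg_curves <- data.frame(threshold = grid, K_min = kmin, CC_min = ccmin,
                           SW = sw)

  # per-participant real and null curves inside the selected range;
  # null means are evaluated on a subgrid and interpolated when requested
  mnames <- c("K", "GE", "LE", "LL", "CC")
  null_subgrid <- max(1L, as.integer(null_subgrid))
  null_ii <- unique(c(seq(1L, length(idx), by = null_subgrid), length(idx)))
  real <- array(NA_real_, c(np, length(idx), 5),
                dimnames = list(NULL, NULL, mnames))
  rand <- array(NA_real_, c(np, length(idx), 5),
                dimnames = list(NULL, NULL, mnames))
  for (p in seq_len(np)) {
    Rm <- r_list[[p]]
    keep <- which(colSums(is.finite(Rm)) > 1)
    W <- absolutize(Rm[keep, keep, drop = FALSE])
    for (ii in seq_along(idx)) {
      t <- grid[idx[ii]]
      g <- W
      g[g <= t] <- 0
      m <- cpp_graph_metrics(g)
      real[p, ii, ] <- c(m$K_min, m$GE, m$LE_mean, m$LL, m$CC_mean)
      if (!(ii %in% null_ii) || sum(g > 0) == 0) next
      nulls <- random_null(g, n = cfg$n_random_nets,
                           seed = derive_seed(cfg$rng_seed, p * 1000L + idx[ii], 11L))
      acc <- numeric(5)
      cnt <- numeric(5)
      for (k in seq_along(nulls)) {
        nm <- cpp_graph_metrics(nulls[[k]])
        v <- c(nm$K_min, nm$GE, nm$LE_mean, nm$LL, nm$CC_mean)
        ok <- is.finite(v)
        acc[ok] <- acc[ok] + v[ok]
        cnt <- cnt + ok
      }
      rand[p, ii, ] <- acc / pmax(cnt, 1)
    }
    if (length(null_ii) < length(idx)) {
      for (mi in seq_len(5)) {
        known <- null_ii[is.finite(rand[p, null_ii, mi])]
        if (length(known) >= 2) {
          rand[p, , mi] <- stats::approx(known, rand[p, known, mi],
                                         xout = seq_along(idx), rule = 2)$y
        }
      }
    }
  }
  grand <- apply(rand, c(2, 3), mean, na.rm = TRUE)
  normalized <- vector("list", np)
  auc <- data.frame(CC = numeric(np), LE = numeric(np), GE = numeric(np),
                    LL = numeric(np), SW = numeric(np))
  for (p in seq_len(np)) {
    denom <- if (normalization == "grand") grand else rand[p, , ]
    nm <- real[p, , ] / denom
    nm[!is.finite(nm)] <- NA
    swp <- nm[, "CC"] / nm[, "LL"]
    normalized[[p]] <- cbind(nm, SW = swp)
    x <- grid[idx]
    for (m in c("CC", "LE", "GE", "LL")) {
      auc[[m]][p] <- metric_auc(x, nm[, m])
    }
    auc$SW[p] <- metric_auc(x, swp)
  }
  list(range = range_sel, grid = grid, avg_curves = avg_curves, auc = auc,
       normalized = normalized, random_grand_mean = grand)
}

#' Run the full resting-state pipeline on a cohort
#'
#' Chains simulation (optional), preprocessing, segment-resampled
#' connectivity, ROI-pair permutation ANCOVAs, the graph-topology sweep
#' with AUC group tests, and the demographics table. Participants whose
#' quality report excludes them (too many rejected channels) are dropped
#' from all statistics and listed in `excluded`.
#'
#' @param cohort list with `roster` and `recordings` (as from
#'   [simulate_cohort()]).
#' @param montage the `probe_montage`.
#' @param cfg a `pipeline_config`.
#' @param chromophore chromophore analysed (default HbO).
#' @param null_subgrid passed to [cohort_graph_analysis()].
#' @return list with `connectivity` (per-participant
#'   `connectivity_result`), `roi_tests`, `graph`, `auc_tests`,
#'   `demographics`, `excluded`, `reports`.
#' @export
run_cohort_pipeline <- function(cohort, montage = make_montage(),
                                cfg = pipeline_config(),
                                chromophore = c("HbO", "HbR"),
                                null_subgrid = 1L) {
  chromophore <- match.arg(chromophore)
  roster <- cohort$roster
  recs <- cohort$recordings
  np <- length(recs)
  keep <- logical(np)
  conn <- vector("list", np)
  reports <- vector("list", np)
  r_list <- list()
  for (i in seq_len(np)) {
    # AR prewhitening is only computed when connectivity will consume it
    pre <- preprocess_participant(recs[[i]], montage, cfg,
                                  run_prewhiten = cfg$use_prewhitened)
    reports[[i]] <- pre$report
    if (pre$report$participant_excluded) next
    keep[i] <- TRUE
    conn_input <- if (cfg$use_prewhitened) pre$dcon else pre$dcon_pca
    res <- participant_connectivity(
      conn_input, pre$report$valid_mask, montage, pre$retained, cfg,
      chromophore = chromophore,
      seed = derive_seed(cfg$rng_seed, i, 20L), fs = recs[[i]]$fs)
    conn[[i]] <- res
    # graph analysis consumes the raw (channel-level, un-averaged)
    # Pearson matrices of the same confound-cleaned signal
    r_list[[length(r_list) + 1L]] <- res$r_channel
  }
  roster_kept <- roster[keep]
  z_stack <- simplify2array(lapply(conn[keep], `[[`, "z_roi"))
  z_stack <- aperm(z_stack, c(3, 1, 2))
  dimnames(z_stack)[[2]] <- dimnames(z_stack)[[3]] <- montage$rois
  roi_tests <- connectivity_group_test(z_stack, roster_kept, cfg)
  graph <- cohort_graph_analysis(r_list, cfg, null_subgrid = null_subgrid)
  auc_tab <- cbind(graph$auc,
                   group = vapply(roster_kept, `[[`, "", "group"),
                   ses = vapply(roster_kept, `[[`, 0, "ses"))
  auc_tests <- graph_auc_group_test(auc_tab, cfg = cfg)
  list(connectivity = conn[keep], roi_tests = roi_tests, graph = graph,
       auc_tests = auc_tests, demographics = demographics(roster_kept),
       excluded = which(!keep), reports = reports, roster = roster_kept,
       z_roi_stack = z_stack)
}
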