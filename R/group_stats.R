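#' ANCOVA F statistic for the group effect
#'
#' Least-squares fit of `y ~ intercept + group + ses`; the F statistic for
#' the group term is the extra-sum-of-squares ratio
#' \deqn{F = \frac{(SSR_{reduced} - SSR_{full})/1}{SSR_{full}/(n-3)}}
#' with the reduced model dropping group. Denominator degrees of freedom
#' are n - 3 (intercept + group + covariate).
#'
#' @param y numeric outcome per participant.
#' @param group factor/character with exactly two levels.
#' @param ses numeric covariate.
#' @return list with `F`, `df` (c(1, n-3)) and `direction` (sign of the
#'   adjusted PEM-CON difference when levels are PEM/CON, else of
#'   level2-level1).
#' @export
ancova_f <- function(y, group, ses) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  n <- length(y)
  if (n < 4) stop("need at least 4 observations")
  if (any(!is.finite(y))) stop("missing outcome values")
  X_full <- cbind(1, as.numeric(g == levels(g)[2]), ses)
  X_red <- cbind(1, ses)
  fit_full <- stats::lm.fit(X_full, y)
  fit_red <- stats::lm.fit(X_red, y)
  ssr_full <- sum(fit_full$residuals^2)
  ssr_red <- sum(fit_red$residuals^2)
  df2 <- n - 3
  if (ssr_full <= .Machine$double.eps * sum(y^2)) {
    # perfect fit: unbounded evidence, report a large finite F
    Fv <- .Machine$double.xmax^0.5
  } else {
    Fv <- (ssr_red - ssr_full) / (ssr_full / df2)
  }
  beta <- unname(fit_full$coefficients[2])
  dir_sign <- sign(beta)
  # orient as PEM - CON when those labels are present
  if (all(c("PEM", "CON") %in% levels(g)) && levels(g)[2] == "PEM") {
    # beta is PEM - CON already
  } else if (all(c("PEM", "CON") %in% levels(g))) {
    dir_sign <- -dir_sign
  }
  list(F = Fv, df = c(1, df2), direction = dir_sign)
}

#' Permutation p-value for the group F statistic
#'
#' The null distribution is built by randomly permuting the cases
#' (outcome values) across participants `n_perm` times and recomputing F
#' each time; the p-value uses the add-one convention
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})}, so the
#' smallest attainable p is 1/(n_perm + 1). The permuted F values are
#' computed in one matrix pass via the projection residuals of the full
#' and reduced models.
#'
#' @param y,group,ses as in [ancova_f()].
#' @param n_perm number of permutations (default 2000).
#' @param seed RNG seed (same seed, same p).
#' @param f_obs optional precomputed observed F.
#' @return list with `p`, `F`, `df`.
#' @export
permutation_p <- function(y, group, ses, n_perm = 2000, seed = 1L,
                          f_obs = NULL) {
  obs <- if (is.null(f_obs)) ancova_f(y, group, ses) else f_obs
  n <- length(y)
  g <- as.factor(group)
  X_full <- cbind(1, as.numeric(g == levels(g)[2]), ses)
  X_red <- cbind(1, ses)
  M_full <- diag(n) - X_full %*% solve(crossprod(X_full), t(X_full))
  M_red <- diag(n) - X_red %*% solve(crossprod(X_red), t(X_red))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Y <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) Y[, b] <- y[sample.int(n)]
  ssr_full <- colSums((M_full %*% Y)^2)
  ssr_red <- colSums((M_red %*% Y)^2)
  df2 <- n - 3
  Fp <- (ssr_red - ssr_full) / pmax(ssr_full / df2, .Machine$double.xmin)
  p <- (1 + sum(Fp >= obs$F)) / (1 + n_perm)
  list(p = p, F = obs$F, df = obs$df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], after validating
#' that all inputs lie in (0, 1]. Adjusted values are never smaller than
#' the input and are capped at 1.
#'
#' @param p numeric p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Distinct ROI pairs in reporting order: intrahemispheric left,
# interhemispheric, intrahemispheric right (within-ROI diagonal excluded).
roi_pair_table <- function(rois) {
  nh <- length(rois) / 2
  left <- rois[seq_len(nh)]
  right <- rois[nh + seq_len(nh)]
  pair_rows <- function(a_set, b_set, same_set) {
    out <- list()
    if (same_set) {
      cmb <- utils::combn(a_set, 2)
      for (k in seq_len(ncol(cmb))) out[[k]] <- cmb[, k]
    } else {
      for (a in a_set) for (b in b_set) out[[length(out) + 1L]] <- c(a, b)
    }
    do.call(rbind, out)
  }
  rbind(
    cbind(pair_rows(left, NULL, TRUE), block = "intra_L"),
    cbind(pair_rows(left, right, FALSE), block = "inter"),
    cbind(pair_rows(right, NULL, TRUE), block = "intra_R"))
}

#' Permutation-ANCOVA group test for each ROI pair
#'
#' For every distinct ROI pair, tests the group difference in
#' Fisher-z ROI connectivity with childhood SES as covariate: observed F
#' from the ANCOVA, permutation p from `n_perm` case permutations, then
#' Benjamini-Hochberg FDR across all pairs (one family per call). Pairs
#' with missing values for any participant (e.g. an ROI lost to channel
#' rejection) are skipped with a message. Rows are ordered
#' intrahemispheric-left, interhemispheric, intrahemispheric-right.
#'
#' @param z_roi_stack 3-d array participants x ROI x ROI (Fisher-z), or a
#'   list of 14 x 14 matrices.
#' @param roster list of `participant_info` aligned with the stack.
#' @param cfg a `pipeline_config` (permutations, master seed).
#' @return data.frame: `roi_a`, `roi_b`, `block`, `F`, `df1`, `df2`,
#'   `p_perm`, `p_fdr`, `direction` ("PEM > CON" / "CON > PEM").
#' @export
connectivity_group_test <- function(z_roi_stack, roster,
                                    cfg = pipeline_config()) {
  if (is.list(z_roi_stack)) {
    rois <- rownames(z_roi_stack[[1]])
    z_roi_stack <- simplify2array(z_roi_stack)
    z_roi_stack <- aperm(z_roi_stack, c(3, 1, 2))
  } else {
    rois <- dimnames(z_roi_stack)[[2]]
  }
  group <- vapply(roster, `[[`, "", "group")
  ses <- vapply(roster, `[[`, 0, "ses")
  if (length(unique(group)) != 2 || min(table(group)) < 2) {
    stop("need at least 2 participants per group")
  }
  pairs <- roi_pair_table(rois)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    y <- z_roi_stack[, match(a, rois), match(b, rois)]
    if (any(!is.finite(y))) {
      message(sprintf("ROI pair %s-%s skipped: missing values", a, b))
      next
    }
    obs <- ancova_f(y, group, ses)
    pp <- permutation_p(y, group, ses, n_perm = cfg$n_permutations,
                        seed = derive_seed(cfg$rng_seed, k, 3L), f_obs = obs)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_a = a, roi_b = b, block = pairs[k, 3], F = obs$F,
      df1 = obs$df[1], df2 = obs$df[2], p_perm = pp$p,
      direction = if (obs$direction >= 0) "PEM > CON" else "CON > PEM",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p_perm)
  out[, c("roi_a", "roi_b", "block", "F", "df1", "df2", "p_perm", "p_fdr",
          "direction")]
}

#' Permutation-ANCOVA group test on graph-metric AUCs
#'
#' One test per normalized metric (CC, LE, GE, LL, SW): group F with SES
#' covariate, permutation p, and the direction of the adjusted group
#' difference. Metrics whose AUC is constant within both groups are
#' flagged with an error message in the `note` column and NA statistics.
#'
#' @param auc_table data.frame with one row per participant: columns
#'   `group`, `ses` and one column per metric AUC.
#' @param metrics metric columns to test.
#' @param cfg a `pipeline_config`.
#' @return data.frame: `metric`, `F`, `df1`, `df2`, `p_perm`, `p_fdr`,
#'   `direction`, `note`.
#' @export
graph_auc_group_test <- function(auc_table,
                                 metrics = c("CC", "LE", "GE", "LL", "SW"),
                                 cfg = pipeline_config()) {
  rows <- list()
  for (k in seq_along(metrics)) {
    m <- metrics[k]
    y <- auc_table[[m]]
    note <- ""
    if (is.null(y)) next
    split_var <- tapply(y, auc_table$group, stats::var)
    if (any(!is.finite(y)) || all(split_var < .Machine$double.eps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, F = NA_real_, df1 = NA, df2 = NA, p_perm = NA_real_,
        direction = NA_character_,
        note = "degenerate AUC (zero variance or missing)",
        stringsAsFactors = FALSE)
      next
    }
    obs <- ancova_f(y, auc_table$group, auc_table$ses)
    pp <- permutation_p(y, auc_table$group, auc_table$ses,
                        n_perm = cfg$n_permutations,
                        seed = derive_seed(cfg$rng_seed, k, 4L), f_obs = obs)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, F = obs$F, df1 = obs$df[1], df2 = obs$df[2], p_perm = pp$p,
      direction = if (obs$direction >= 0) "PEM > CON" else "CON > PEM",
      note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- is.finite(out$p_perm)
  out$p_fdr <- NA_real_
  out$p_fdr[ok] <- fdr_bh(out$p_perm[ok])
  out
}

#' Two-sample pooled t statistic from group summaries
#'
#' @param m1,s1,n1 mean, SD and size of the first group.
#' @param m2,s2,n2 mean, SD and size of the second group.
#' @return list with `t` (sign of m2 - m1... computed as (m2-m1)/SE), `df`
#'   and two-sided `p`.
#' @export
summary_t_test <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 == 0 && s2 == 0) stop("t undefined: zero variance in both groups")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tv <- (m2 - m1) / se
  df <- n1 + n2 - 2
  list(t = tv, df = df, p = 2 * stats::pt(-abs(tv), df))
}

#' Pearson chi-square (1 df, no continuity correction) for a 2x2 table
#'
#' @param tab 2x2 count matrix.
#' @return list with `chisq`, `df`, `p`.
#' @export
chisq_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  out <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(out$statistic), df = 1, p = out$p.value)
}

#' Demographic comparison table
#'
#' Group summaries and tests matching the study's reporting: age and SES
#' by pooled two-sample t from summaries (sign oriented CON - PEM), sex
#' by Pearson 1-df chi-square without continuity correction, handedness
#' by two-sided Fisher exact test.
#'
#' @param roster list of `participant_info`.
#' @return data.frame with one row per characteristic: group summaries,
#'   test statistic and p-value.
#' @export
demographics <- function(roster) {
  df <- roster_frame(roster)
  pem <- df[df$group == "PEM", ]
  con <- df[df$group == "CON", ]
  num_row <- function(name, x_pem, x_con) {
    tt <- summary_t_test(mean(x_pem), stats::sd(x_pem), length(x_pem),
                         mean(x_con), stats::sd(x_con), length(x_con))
    data.frame(characteristic = name,
               pem = sprintf("%.2f (%.2f)", mean(x_pem), stats::sd(x_pem)),
               con = sprintf("%.2f (%.2f)", mean(x_con), stats::sd(x_con)),
               statistic = tt$t, p = tt$p, test = "t", stringsAsFactors = FALSE)
  }
  sex_tab <- rbind(PEM = table(factor(pem$sex, c("M", "F"))),
                   CON = table(factor(con$sex, c("M", "F"))))
  cs <- chisq_2x2(sex_tab)
  hand_tab <- rbind(PEM = table(factor(pem$handedness, c("L", "R"))),
                    CON = table(factor(con$handedness, c("L", "R"))))
  fe <- stats::fisher.test(hand_tab)
  rbind(
    data.frame(characteristic = "n", pem = as.character(nrow(pem)),
               con = as.character(nrow(con)), statistic = NA_real_,
               p = NA_real_, test = "", stringsAsFactors = FALSE),
    data.frame(characteristic = "males_n",
               pem = sprintf("%d (%.2f%%)", sex_tab["PEM", "M"],
                             100 * sex_tab["PEM", "M"] / nrow(pem)),
               con = sprintf("%d (%.2f%%)", sex_tab["CON", "M"],
                             100 * sex_tab["CON", "M"] / nrow(con)),
               statistic = cs$chisq, p = cs$p, test = "chisq",
               stringsAsFactors = FALSE),
    num_row("age_years", pem$age, con$age),
    data.frame(characteristic = "left_handed_n",
               pem = sprintf("%d (%.2f%%)", hand_tab["PEM", "L"],
                             100 * hand_tab["PEM", "L"] / nrow(pem)),
               con = sprintf("%d (%.2f%%)", hand_tab["CON", "L"],
                             100 * hand_tab["CON", "L"] / nrow(con)),
               statistic = NA_real_, p = fe$p.value, test = "fisher",
               stringsAsFactors = FALSE),
    num_row("childhood_ses", pem$ses, con$ses))
}
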