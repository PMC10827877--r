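test_that("the ANCOVA F matches an independent worked example", {
  # six observations; expected F computed independently with car::Anova
  y <- c(1.2, 0.8, 1.5, 2.1, 2.4, 1.9)
  group <- c("CON", "CON", "CON", "PEM", "PEM", "PEM")
  ses <- c(0.3, -0.2, 0.5, -0.8, 0.1, -0.4)
  res <- ancova_f(y, group, ses)
  expect_equal(res$F, 32.3425449528, tolerance = 1e-8)
  expect_equal(res$df, c(1, 3))
  expect_equal(res$direction, 1)  # PEM above CON after adjustment

  skip_if_not_installed("car")
  set.seed(2)
  y2 <- rnorm(24)
  g2 <- rep(c("CON", "PEM"), 12)
  s2 <- rnorm(24)
  fit <- stats::lm(y2 ~ factor(g2) + s2)
  ref <- car::Anova(fit, type = 2)["factor(g2)", "F value"]
  expect_equal(ancova_f(y2, g2, s2)$F, ref, tolerance = 1e-10)
})

test_that("ANCOVA edge cases behave sensibly", {
  set.seed(1)
  n <- 16
  g <- rep(c("CON", "PEM"), each = n / 2)
  ses <- rnorm(n)
  # no group signal: small F
  same <- rnorm(n)
  expect_lt(ancova_f(same, g, ses)$F, 10)
  # outcome identical to the group indicator: effectively infinite evidence
  perfect <- as.numeric(g == "PEM")
  res <- ancova_f(perfect, g, ses)
  expect_gt(res$F, 1e6)
  pp <- permutation_p(perfect, g, ses, n_perm = 500, seed = 1)
  expect_equal(pp$p, 1 / 501)
  expect_error(ancova_f(same, rep("PEM", n), ses), "two levels")
  g6 <- c("CON", "CON", "CON", "PEM", "PEM", "PEM")
  expect_error(ancova_f(c(1, NA, 3, 4, 5, 6), g6, ses[1:6]), "missing")
})

test_that("permutation p-values are deterministic and label-invariant", {
  set.seed(4)
  n <- 20
  g <- rep(c("CON", "PEM"), each = 10)
  ses <- rnorm(n)
  y <- rnorm(n) + 0.8 * (g == "PEM")
  p1 <- permutation_p(y, g, ses, n_perm = 500, seed = 7)$p
  p2 <- permutation_p(y, g, ses, n_perm = 500, seed = 7)$p
  expect_identical(p1, p2)
  # monotone relabeling of the group codes leaves p unchanged
  g_swapped <- ifelse(g == "PEM", "a_first", "z_last")
  p3 <- permutation_p(y, g_swapped, ses, n_perm = 500, seed = 7)$p
  expect_identical(p1, p3)
  expect_gte(p1, 1 / 501)
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(0.3, 5)), rep(0.3, 5))
  p <- c(0.001, 0.2, 0.8, 0.04)
  adj <- fdr_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # idempotent on flat adjusted sequences (re-adjusting a general
  # adjusted vector re-applies the n/rank factors, so only the flat
  # case is exactly stable)
  expect_equal(fdr_bh(rep(0.04, 4)), rep(0.04, 4))
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("demographic tests reproduce the published summary statistics", {
  # sex: 14/25 vs 14/28 males, Pearson chi-square without correction
  tab <- rbind(PEM = c(M = 14, F = 11), CON = c(M = 14, F = 14))
  expect_equal(round(chisq_2x2(tab)$chisq, 2), 0.19)
  # age from group summaries, CON - PEM orientation
  tt <- summary_t_test(48.70, 1.89, 25, 48.54, 1.93, 28)
  expect_equal(round(tt$t, 2), -0.30)
  expect_equal(tt$df, 51)
  # identical summaries give zero statistics
  expect_equal(summary_t_test(1, 1, 10, 1, 1, 12)$t, 0)
  expect_equal(chisq_2x2(rbind(c(5, 5), c(5, 5)))$chisq, 0)
  expect_error(summary_t_test(1, 0, 10, 2, 0, 10), "zero variance")
})

test_that("the demographics table is assembled from a roster", {
  set.seed(6)
  mk <- function(id, group, sex, hand) {
    participant_info(id, group, runif(1, 45, 51), sex, hand,
                     rnorm(1, if (group == "PEM") -1.1 else -0.3, 0.76))
  }
  roster <- c(
    lapply(1:25, function(i) mk(paste0("p", i), "PEM",
                                if (i <= 14) "M" else "F",
                                if (i <= 3) "L" else "R")),
    lapply(1:28, function(i) mk(paste0("c", i), "CON",
                                if (i <= 14) "M" else "F",
                                if (i <= 3) "L" else "R")))
  tab <- demographics(roster)
  expect_equal(tab$characteristic,
               c("n", "males_n", "age_years", "left_handed_n", "childhood_ses"))
  expect_equal(round(tab$statistic[tab$characteristic == "males_n"], 2), 0.19)
  expect_equal(tab$test, c("", "chisq", "t", "fisher", "t"))
  expect_true(all(is.finite(tab$p[-1])))
})

test_that("ROI-pair group tests are invariant to participant order", {
  mont <- tiny_montage()
  set.seed(11)
  np <- 12
  groups <- rep(c("PEM", "CON"), each = np / 2)
  roster <- lapply(seq_len(np), function(i) {
    participant_info(paste0("x", i), groups[i], 48, ses = rnorm(1))
  })
  stack <- array(rnorm(np * 14 * 14, sd = 0.2), c(np, 14, 14))
  for (i in seq_len(np)) {
    stack[i, , ] <- (stack[i, , ] + t(stack[i, , ])) / 2
  }
  dimnames(stack)[[2]] <- dimnames(stack)[[3]] <- mont$rois
  cfg <- quick_cfg(rng_seed = 5)
  res1 <- connectivity_group_test(stack, roster, cfg)
  perm <- sample(np)
  res2 <- connectivity_group_test(stack[perm, , ], roster[perm], cfg)
  expect_equal(res1$F, res2$F, tolerance = 1e-12)
  # permutation p is exchangeable across row orders up to Monte-Carlo error
  expect_lt(max(abs(res1$p_perm - res2$p_perm)), 0.12)
  expect_equal(nrow(res1), choose(7, 2) * 2 + 49)  # intra-L, intra-R, inter
  expect_true(all(res1$p_fdr >= res1$p_perm))

  # a pair with missing values is skipped with a message
  stack[1, 1, 2] <- NA
  expect_message(res3 <- connectivity_group_test(stack, roster, cfg),
                 "skipped")
  expect_equal(nrow(res3), nrow(res1) - 1)
})

test_that("AUC group tests flag degenerate metrics", {
  set.seed(3)
  n <- 16
  tab <- data.frame(CC = rnorm(n), LE = rnorm(n), GE = rnorm(n),
                    LL = rnorm(n), SW = rep(1, n),
                    group = rep(c("PEM", "CON"), each = n / 2),
                    ses = rnorm(n))
  res <- graph_auc_group_test(tab, cfg = quick_cfg())
  expect_equal(res$metric, c("CC", "LE", "GE", "LL", "SW"))
  expect_true(is.na(res$F[res$metric == "SW"]))
  expect_match(res$note[res$metric == "SW"], "degenerate")
  expect_true(all(is.finite(res$F[res$metric != "SW"])))
})

test_that("permutation ANCOVA holds its size under the null", {
  # small-scale calibration; the full study is in the acceptance suite
  set.seed(17)
  nrep <- 150
  n <- 12
  g <- rep(c("CON", "PEM"), each = n / 2)
  ps <- replicate(nrep, {
    ses <- rnorm(n)
    y <- rnorm(n)
    permutation_p(y, g, ses, n_perm = 200, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps <= 0.05), 0.005)
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
})

test_that("the SES covariate absorbs an SES-linked confound", {
  set.seed(23)
  n <- 40
  g <- rep(c("CON", "PEM"), each = n / 2)
  ses <- rnorm(n, mean = ifelse(g == "PEM", -0.8, 0))
  y <- 1.5 * ses + rnorm(n)  # outcome driven by SES only
  # unadjusted group difference looks large ...
  t_raw <- abs(t.test(y ~ g)$statistic)
  expect_gt(t_raw, 2)
  # ... but the SES-adjusted group F stays modest
  expect_lt(ancova_f(y, g, ses)$F, t_raw^2 / 2)
})
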