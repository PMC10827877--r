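test_that("absolutize retains magnitudes and zeroes the diagonal", {
  m <- matrix(c(1, -0.4, -0.4, 1), 2)
  w <- absolutize(m)
  expect_equal(w[1, 2], 0.4)
  expect_equal(diag(w), c(0, 0))
  set.seed(1)
  r <- matrix(rnorm(25), 5); r <- (r + t(r)) / 2
  expect_gte(min(absolutize(r)), 0)
  pos <- abs(r); diag(pos) <- 0
  expect_equal(absolutize(r), pos)
  expect_error(absolutize(matrix(0, 2, 3)), "square")
})

test_that("threshold sweep yields one graph per grid point with strict cut", {
  w <- rand_sym_graph(10, 0.8, seed = 2)
  sw <- threshold_sweep(w)
  expect_length(sw, 85)
  expect_true(all(sw[["0.50"]][sw[["0.50"]] > 0] > 0.5))

  # strict inequality: an edge exactly at the threshold is removed
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- 0.30
  expect_equal(sum(threshold_sweep(w2, 0.30)[[1]]), 0)
  expect_equal(sum(threshold_sweep(w2, 0.29)[[1]] > 0), 2)

  # threshold above the maximum weight empties the graph
  expect_equal(sum(threshold_sweep(w, 0.999)[[1]]), 0)
  expect_error(threshold_sweep(w, c(0, 0.5)), "thresholds")
})

test_that("random nulls conserve degree sequence and weights", {
  for (s in 1:10) {
    w <- rand_sym_graph(12, runif(1, 0.2, 0.7), seed = s)
    if (sum(w) == 0) next
    nulls <- random_null(w, n = 5, seed = s)
    for (nu in nulls) {
      expect_equal(dim(nu), dim(w))
      expect_true(isSymmetric(nu))
      expect_equal(sum(nu > 0), sum(w > 0))
      expect_equal(sort(rowSums(nu > 0)), sort(rowSums(w > 0)))
      expect_equal(sort(nu[upper.tri(nu)][nu[upper.tri(nu)] > 0]),
                   sort(w[upper.tri(w)][w[upper.tri(w)] > 0]))
    }
  }

  # complete graph: no swap can change K_n; weights still shuffle
  wc <- matrix(runif(16), 4); wc <- (wc + t(wc)) / 2; diag(wc) <- 0
  nu <- random_null(wc, 3, seed = 1)
  for (x in nu) expect_equal(x > 0, wc > 0)

  # single-edge graph: swap impossible, weight preserved
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 0.7
  nu1 <- random_null(w1, 2, seed = 1)
  for (x in nu1) expect_equal(sort(x[upper.tri(x)]), c(0, 0, 0.7))

  expect_error(random_null(matrix(0, 3, 3)), "no edges")
  # determinism
  expect_identical(random_null(wc, 3, seed = 9), random_null(wc, 3, seed = 9))
})

test_that("degree matches brute force and closed forms", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  d <- degree(star)
  expect_equal(unname(d$degree), c(5, rep(1, 5)))
  expect_equal(d$min, 1)
  expect_equal(degree(matrix(0, 4, 4))$degree, rep(0, 4))
  w <- rand_sym_graph(10, 0.5, seed = 3)
  expect_equal(degree(w)$degree, oracle_degree(w))
})

test_that("global efficiency matches closed forms", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(global_efficiency(k4), 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
})

test_that("local efficiency matches closed forms and the subgraph oracle", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(local_efficiency(k4)$per_node, rep(1, 4))
  star <- matrix(0, 6, 6); star[1, 2:6] <- star[2:6, 1] <- 1
  expect_equal(local_efficiency(star)$per_node, rep(0, 6))
  w <- rand_sym_graph(10, 0.5, seed = 4)
  expect_equal(local_efficiency(w)$per_node, oracle_le(w), tolerance = 1e-12)
})

test_that("characteristic path length matches closed forms", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(char_path_length(tri)$value, 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(char_path_length(path3)$value, 4 / 3, tolerance = 1e-12)
  expect_false(char_path_length(path3)$disconnected)
  disc <- matrix(0, 4, 4); disc[1, 2] <- disc[2, 1] <- 1
  cp <- char_path_length(disc)
  expect_true(cp$disconnected)
  expect_equal(cp$value, 1)
  expect_true(is.na(char_path_length(matrix(0, 3, 3))$value))
})

test_that("clustering coefficient matches closed forms and enumeration", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_coefficient(tri)$per_node, rep(1, 3))
  expect_equal(clustering_coefficient(tri, binary = TRUE)$per_node, rep(1, 3))
  star <- matrix(0, 6, 6); star[1, 2:6] <- star[2:6, 1] <- 1
  expect_equal(clustering_coefficient(star)$per_node, rep(0, 6))
  A <- (rand_sym_graph(12, 0.4, seed = 5) > 0) * 1
  expect_equal(clustering_coefficient(A, binary = TRUE)$per_node,
               oracle_cc_binary(A), tolerance = 1e-12)
  w <- rand_sym_graph(12, 0.5, seed = 6)
  expect_equal(clustering_coefficient(w)$per_node, oracle_cc_onnela(w),
               tolerance = 1e-12)
})

test_that("compiled metrics agree with brute-force oracles on small graphs", {
  for (s in 1:20) {
    n <- sample(4:8, 1)
    w <- rand_sym_graph(n, runif(1, 0.3, 0.9), seed = 100 + s)
    m <- graph_metrics(w)
    expect_equal(m$GE, oracle_ge(w), tolerance = 1e-10)
    expect_equal(m$LL, oracle_ll(w), tolerance = 1e-10)
    expect_equal(as.numeric(m$LE), oracle_le(w), tolerance = 1e-10)
    expect_equal(as.numeric(m$CC), oracle_cc_onnela(w), tolerance = 1e-10)
    expect_equal(as.numeric(m$degree), unname(oracle_degree(w)))
  }
})

test_that("distances agree with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  w <- rand_sym_graph(15, 0.4, seed = 11)
  D <- nirsgraph:::cpp_distances(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  Dref <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  expect_equal(unname(D), unname(Dref), tolerance = 1e-10)
})

test_that("normalization and small-world index behave on reference ensembles", {
  # real curves equal to random means normalize to 1, SW = 1
  real <- matrix(2, 5, 5, dimnames = list(NULL, c("K", "GE", "LE", "LL", "CC")))
  nz <- normalize_and_smallworld(real, real)
  expect_true(all(nz$normalized == 1))
  expect_true(all(nz$sw == 1))

  # Erdos-Renyi graphs are their own null model: normalized metrics ~ 1
  set.seed(31)
  ncc <- nll <- numeric(20)
  for (i in 1:20) {
    w <- erdos_renyi_graph(24, 0.3, seed = 400 + i)
    m <- graph_metrics(w)
    nulls <- random_null(w, 15, seed = i)
    cc <- sapply(nulls, function(x) graph_metrics(x)$CC_mean)
    ll <- sapply(nulls, function(x) graph_metrics(x)$LL)
    ncc[i] <- m$CC_mean / mean(cc)
    nll[i] <- m$LL / mean(ll)
  }
  expect_lt(abs(mean(ncc) - 1), 0.1)
  expect_lt(abs(mean(nll) - 1), 0.1)

  # ring lattices are small-world-like relative to rewired nulls
  w <- ring_lattice_graph(24, k = 3)
  # perturb weights so rewiring changes structure
  set.seed(5)
  w[w > 0] <- w[w > 0] * runif(sum(w > 0), 0.8, 1.2)
  w <- (w + t(w)) / 2
  m <- graph_metrics(w)
  nulls <- random_null(w, 25, seed = 2)
  cc <- sapply(nulls, function(x) graph_metrics(x)$CC_mean)
  ll <- sapply(nulls, function(x) graph_metrics(x)$LL)
  sw <- (m$CC_mean / mean(cc)) / (m$LL / mean(ll))
  expect_gt(sw, 1)
})

test_that("threshold-range selection returns the maximal qualifying run", {
  grid <- seq(0.01, 0.1, by = 0.01)
  ok_all <- select_threshold_range(grid, rep(2, 10), rep(0.1, 10), rep(1.5, 10))
  expect_equal(ok_all$lo, 0.01)
  expect_equal(ok_all$hi, 0.10)

  kmin <- c(2, 2, 2, 2, 2, 0, 0, 2, 2, 2)  # Kmin binds in the middle
  sel <- select_threshold_range(grid, kmin, rep(0, 10), rep(1.2, 10))
  expect_equal(sel$idx, 1:5)

  # tie between two equal runs resolves toward the lowest thresholds
  sw <- c(1.1, 1.1, 0.5, 1.1, 1.1, 0.5, 0.5, 0.5, 0.5, 0.5)
  sel2 <- select_threshold_range(grid, rep(2, 10), rep(0, 10), sw)
  expect_equal(sel2$idx, 1:2)

  expect_error(select_threshold_range(grid, rep(0, 10), rep(0, 10), rep(2, 10)),
               "no threshold")
})

test_that("trapezoidal AUC matches closed forms and the cumsum oracle", {
  grid <- seq(0.1, 0.5, by = 0.01)
  expect_equal(metric_auc(grid, rep(2, length(grid))), 2 * 0.4,
               tolerance = 1e-12)
  lin <- seq(1, 3, length.out = length(grid))
  expect_equal(metric_auc(grid, lin), 0.4 * (1 + 3) / 2, tolerance = 1e-12)
  set.seed(8)
  y <- rnorm(length(grid))
  expect_equal(metric_auc(grid, y), oracle_trapz(grid, y), tolerance = 1e-12)
  expect_equal(metric_auc(grid, y, idx = 5:15),
               oracle_trapz(grid[5:15], y[5:15]), tolerance = 1e-12)
})

test_that("edge count and Kmin decrease monotonically along the sweep", {
  w <- absolutize(rand_sym_graph(20, 0.9, seed = 12))
  sweep_list <- threshold_sweep(w, seq(0.05, 0.8, by = 0.05))
  edges <- vapply(sweep_list, function(g) sum(g > 0), 0)
  kmins <- vapply(sweep_list, function(g) degree(g)$min, 0)
  expect_true(all(diff(edges) <= 0))
  expect_true(all(diff(kmins) <= 0))
})

test_that("scaling weights rescales efficiency and keeps topology", {
  w <- rand_sym_graph(12, 0.5, seed = 13)
  c0 <- 2.5
  expect_equal(degree(c0 * w)$degree, degree(w)$degree)
  expect_equal(global_efficiency(c0 * w), c0 * global_efficiency(w),
               tolerance = 1e-12)
  expect_equal(char_path_length(c0 * w)$value, char_path_length(w)$value / c0,
               tolerance = 1e-12)
})
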