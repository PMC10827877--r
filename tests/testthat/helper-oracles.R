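# Brute-force graph oracles, independent of the package's compiled
# kernels: plain-R Floyd-Warshall, exhaustive triangle / neighbourhood
# enumeration, and a cumulative-sum trapezoid.

oracle_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_ge <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_distances(W)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.finite(D[i, j]) && D[i, j] > 0) s <- s + 1 / D[i, j]
  }
  s / (n * (n - 1) / 2)
}

oracle_ll <- function(W) {
  D <- oracle_distances(W)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

oracle_degree <- function(W) rowSums(W > 0)

oracle_le <- function(W) {
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0 & seq_len(n) != i)
    if (length(nb) < 2) return(0)
    oracle_ge(W[nb, nb, drop = FALSE])
  })
}

oracle_cc_binary <- function(W) {
  A <- (W > 0) * 1
  diag(A) <- 0
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (A[nb[a], nb[b]] > 0) tri <- tri + 1
    }
    tri / (k * (k - 1) / 2)
  })
}

oracle_cc_onnela <- function(W) {
  n <- nrow(W)
  wmax <- max(W)
  if (wmax <= 0) return(rep(0, n))
  Wh <- W / wmax
  sapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0 & seq_len(n) != i)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (W[nb[a], nb[b]] > 0) {
        s <- s + (Wh[i, nb[a]] * Wh[i, nb[b]] * Wh[nb[a], nb[b]])^(1 / 3)
      }
    }
    2 * s / (k * (k - 1))
  })
}

oracle_trapz <- function(x, y) {
  # cumulative-sum composite trapezoid (independent of metric_auc)
  cs <- cumsum(c(0, (y[-1] + y[-length(y)]) / 2 * diff(x)))
  cs[length(cs)]
}

rand_sym_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- ifelse(runif(sum(ut)) < density, runif(sum(ut), 0.1, 1), 0)
  W[ut] <- w
  W <- W + t(W)
  diag(W) <- 0
  W
}

erdos_renyi_graph <- function(n, p, seed) {
  rand_sym_graph(n, density = p, seed = seed)
}

ring_lattice_graph <- function(n, k = 2, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k)) {
    j <- ((i - 1 + d) %% n) + 1
    W[i, j] <- W[j, i] <- w
  }
  diag(W) <- 0
  W
}
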