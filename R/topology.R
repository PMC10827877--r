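#' Absolutize a connectivity matrix into a weighted graph
#'
#' Negative correlations are hard to interpret in channel-space NIRS
#' connectivity, so their absolute values are retained as edge weights.
#' The diagonal is zeroed (no self-edges).
#'
#' @param m square symmetric matrix (e.g. mean Pearson correlations).
#' @return Nonnegative symmetric weight matrix with zero diagonal.
#' @export
absolutize <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  w <- abs(m)
  diag(w) <- 0
  w
}

#' Threshold sweep
#'
#' For each threshold t in the grid, edge weights strictly greater than t
#' are retained at their value and all others set to 0, yielding one
#' weighted graph per grid point (85 for the default 0.01..0.85 grid).
#'
#' @param w weight matrix (see [absolutize()]).
#' @param grid thresholds, strictly increasing in (0, 1).
#' @return List of weight matrices, one per threshold, named by threshold.
#' @export
threshold_sweep <- function(w, grid = seq(0.01, 0.85, by = 0.01)) {
  if (any(grid <= 0) || any(grid >= 1)) stop("thresholds must lie in (0, 1)")
  out <- lapply(grid, function(t) {
    g <- w
    g[g <= t] <- 0
    g
  })
  names(out) <- formatC(grid, format = "f", digits = 2)
  out
}

#' Degree-preserving random null networks
#'
#' Generates `n` random networks from a weighted graph by
#' degree-sequence-preserving edge rewiring (iterative edge swaps,
#' `swaps_per_edge * |E|` attempts) followed by random reassignment of the
#' original weight multiset onto the rewired edges. Every null therefore
#' preserves node count, edge count, degree sequence and weight multiset.
#' Graphs too sparse or too dense for any effective swap (e.g. complete
#' graphs) keep their topology and only the weights are shuffled.
#'
#' @param w weight matrix with at least one edge.
#' @param n number of nulls (default 100).
#' @param seed RNG seed.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return List of `n` weight matrices.
#' @export
random_null <- function(w, n = 100, seed = 1L, swaps_per_edge = 10) {
  if (sum(w[upper.tri(w)] > 0) < 1) stop("graph has no edges; cannot randomize")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) cpp_rewire_null(w, swaps_per_edge))
}

#' Node degree
#'
#' Number of nonzero-weight neighbours of each node.
#'
#' @param w weight matrix.
#' @return list with `degree` (per node) and `min` (Kmin).
#' @export
degree <- function(w) {
  k <- rowSums(w > 0)
  list(degree = k, min = min(k))
}

#' Global efficiency
#'
#' Mean over unordered node pairs of the inverse shortest path distance,
#' with edge lengths 1/weight and 1/infinity = 0 for disconnected pairs.
#' 1 for a complete unit-weight graph; 0 for a graph with no edges.
#'
#' @param w weight matrix.
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(w) {
  cpp_graph_metrics(w)$GE
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on its
#' neighbours (the node itself removed); nodes with fewer than two
#' neighbours score 0. The node average summarizes the network.
#'
#' @param w weight matrix.
#' @return list with `per_node` and `mean`.
#' @export
local_efficiency <- function(w) {
  le <- cpp_local_efficiency(w)
  list(per_node = le, mean = mean(le))
}

#' Characteristic path length
#'
#' Mean shortest path distance (edge lengths 1/weight) over connected
#' unordered node pairs; disconnected pairs are excluded and flagged.
#'
#' @param w weight matrix.
#' @return list with `value` (NA when no pair is connected) and
#'   `disconnected` (TRUE if any pair was unreachable).
#' @export
char_path_length <- function(w) {
  m <- cpp_graph_metrics(w)
  list(value = m$LL, disconnected = m$disconnected)
}

#' Weighted clustering coefficient
#'
#' Onnela formulation: per node, the sum over neighbour pairs of the
#' geometric mean of the three triangle weights (normalized by the
#' graph's maximum weight), divided by the k(k-1)/2 possible pairs; nodes
#' with fewer than two neighbours score 0. `binary = TRUE` reduces to the
#' classic fraction of connected neighbour pairs.
#'
#' @param w weight matrix.
#' @param binary ignore weights (0/1 topology).
#' @return list with `per_node`, `mean` and `min`.
#' @export
clustering_coefficient <- function(w, binary = FALSE) {
  cc <- cpp_clustering(w, binary)
  list(per_node = cc, mean = mean(cc), min = min(cc))
}

#' All graph metrics of one weighted graph
#'
#' @param w weight matrix.
#' @param binary_cc use binary clustering.
#' @return list with `K_min`, `GE`, `LL`, `LE_mean`, `CC_mean`, `CC_min`,
#'   `disconnected`, and the per-node vectors.
#' @export
graph_metrics <- function(w, binary_cc = FALSE) {
  cpp_graph_metrics(w, binary_cc)
}

metric_names <- c("K", "GE", "LE", "LL", "CC")

# Metric curves (rows = thresholds) for one weight matrix over a grid.
# Returns a matrix thresholds x metrics; K is Kmin (connectivity summary),
# the others are the network summaries used for AUC analysis. Also
# CC_min column for the threshold-selection criterion.
metric_curves_matrix <- function(w, grid) {
  out <- matrix(NA_real_, length(grid), length(metric_names) + 1,
                dimnames = list(formatC(grid, format = "f", digits = 2),
                                c(metric_names, "CC_min")))
  for (i in seq_along(grid)) {
    g <- w
    g[g <= grid[i]] <- 0
    m <- cpp_graph_metrics(g)
    out[i, ] <- c(m$K_min, m$GE, m$LE_mean, m$LL, m$CC_mean, m$CC_min)
  }
  out
}

#' Normalize real metric curves by random-network means and form SW
#'
#' Each participant's real metric value at each threshold is divided by
#' the mean of the corresponding null-network metric at that threshold.
#' The default denominator is the grand mean over all participants' nulls
#' (`random_mean` shared across the cohort); passing a per-participant
#' matrix normalizes each participant by their own nulls instead. The
#' small-world index is then SW = NormCC / NormLL. Zero denominators give
#' NA.
#'
#' @param real thresholds x metrics matrix of real metric values
#'   (columns GE, LE, LL, CC at least).
#' @param random_mean matrix of the same shape: null-metric means.
#' @return list with `normalized` (matrix) and `sw` (vector per threshold).
#' @export
normalize_and_smallworld <- function(real, random_mean) {
  stopifnot(all(dim(real) == dim(random_mean)))
  normalized <- real / random_mean
  normalized[!is.finite(normalized)] <- NA
  sw <- normalized[, "CC"] / normalized[, "LL"]
  sw[!is.finite(sw)] <- NA
  list(normalized = normalized, sw = sw)
}

#' Select the analysis threshold range
#'
#' Returns the maximal contiguous run of thresholds on which the cohort
#' curves describe a fully connected (Kmin >= 1, CCmin >= min_cc) network
#' with small-world organization (SW >= 1). Ties between equally long runs
#' are broken toward the lowest thresholds. Note the CCmin >= 0 criterion
#' is vacuous for nonnegative weights unless `min_cc` is raised above 0.
#'
#' @param grid threshold grid.
#' @param k_min Kmin per threshold (cohort curve).
#' @param cc_min CCmin per threshold.
#' @param sw small-world index per threshold.
#' @param min_cc CCmin cut-off (default 0, the literal criterion).
#' @return list with `lo`, `hi` (grid values), `idx` (grid indices).
#' @export
select_threshold_range <- function(grid, k_min, cc_min, sw, min_cc = 0) {
  ok <- (k_min >= 1) & (cc_min >= min_cc) & !is.na(sw) & (sw >= 1)
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) {
    stop("no threshold satisfies Kmin >= 1, CCmin criterion and SW >= 1; densify the grid or relax the criteria")
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  lens <- runs[, 2] - runs[, 1] + 1L
  best <- which.max(lens)  # first maximal run = lowest thresholds
  idx <- runs[best, 1]:runs[best, 2]
  list(lo = grid[idx[1]], hi = grid[idx[length(idx)]], idx = idx)
}

#' Trapezoidal area under a metric curve
#'
#' Composite trapezoid on the threshold grid restricted to the selected
#' range; grid spacing is part of the measure (units: metric x threshold).
#' NA values inside the range propagate to an NA area.
#'
#' @param grid threshold grid.
#' @param values metric value per grid point.
#' @param idx indices of the selected range (from
#'   [select_threshold_range()]).
#' @return Scalar area.
#' @export
metric_auc <- function(grid, values, idx = seq_along(grid)) {
  x <- grid[idx]
  y <- values[idx]
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
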