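## Network construction: partial-correlation connectivity matrices and their
## binarization into nested stacks of undirected graphs over a sparsity grid.

#' Construct a connectivity-matrix object
#'
#' @param values N x N symmetric numeric matrix of partial correlations;
#'   the diagonal is stored as zero.
#' @param roi_labels region names (defaults to dimnames).
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, roi_labels = colnames(values)) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (nrow(values) != n || n < 2L) {
    pn_stop("connectivity matrix must be square with N >= 2",
            "presbynet_shape_error")
  }
  if (max(abs(values - t(values))) > 1e-10) {
    pn_stop("connectivity matrix is not symmetric (tolerance 1e-10)",
            "presbynet_value_error")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(n))
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(list(values = values, roi_labels = roi_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, |r| range [%.3f, %.3f]\n",
              ncol(x$values), ncol(x$values),
              min(abs(x$values[upper.tri(x$values)])),
              max(abs(x$values[upper.tri(x$values)]))))
  invisible(x)
}

#' Partial-correlation connectivity matrix
#'
#' Entry (i, j) is the correlation between regions i and j conditioned on
#' all remaining regions, computed from the precision matrix P as
#' `-P_ij / sqrt(P_ii * P_jj)`. Requires more time points than regions
#' unless diagonal-loading shrinkage is enabled.
#'
#' @param ts an [roi_timeseries()] with T > N (or shrinkage enabled).
#' @param shrinkage non-negative diagonal loading added to the sample
#'   covariance (as a fraction of its mean diagonal) before inversion;
#'   default 0 (none).
#' @return A [connectivity_matrix()].
#' @export
partial_correlation_matrix <- function(ts, shrinkage = 0) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  n <- ncol(x)
  if (any(apply(x, 2, sd) == 0)) {
    pn_stop("constant ROI column: zero variance", "presbynet_value_error")
  }
  if (nrow(x) <= n && shrinkage <= 0) {
    pn_stop(sprintf(
      "T (%d) must exceed N (%d) for a full partial correlation; enable shrinkage",
      nrow(x), n), "presbynet_insufficient_samples_error")
  }
  s <- cov(x)
  if (shrinkage > 0) s <- s + diag(shrinkage * mean(diag(s)), n)
  prec <- tryCatch(chol2inv(chol(s)), error = function(e) {
    pn_stop("sample covariance is singular; enable shrinkage",
            "presbynet_conditioning_error")
  })
  d <- sqrt(diag(prec))
  pc <- -prec / outer(d, d)
  diag(pc) <- 0
  pc <- pmin(pmax(pc, -1), 1)
  connectivity_matrix(pc, roi_labels = ts_labels(ts))
}

#' Sparsity-threshold grid
#'
#' Arithmetic sequence of sparsity values; the defaults (0.06 to 0.40 in
#' steps of 0.01) give the conventional 35-level grid.
#'
#' @param s_min,s_max,step grid bounds and increment.
#' @return Numeric vector of strictly increasing sparsities.
#' @export
sparsity_grid <- function(s_min = 0.06, s_max = 0.40, step = 0.01) {
  stopifnot_scalar_prob(s_min, "s_min")
  stopifnot_scalar_prob(s_max, "s_max")
  if (s_min > s_max || step <= 0) {
    pn_stop("need 0 < s_min <= s_max and step > 0", "presbynet_config_error")
  }
  k <- floor((s_max - s_min) / step + 1e-9)
  grid <- s_min + step * (0:k)
  if (length(grid) == 0) pn_stop("empty sparsity grid", "presbynet_config_error")
  grid
}

#' Advisory minimum sparsity for a connected small-world regime
#'
#' Returns the sparsity at which the mean node degree equals `2 ln(N)`,
#' i.e. `S = 2 ln(N) / (N - 1)`, clamped to (0, 1]. Advisory only: the
#' default analysis grid starts at the configured lower bound.
#'
#' @param n_nodes number of nodes (>= 3).
#' @return A single sparsity value.
#' @export
minimum_sparsity_rule <- function(n_nodes) {
  if (!is_count(n_nodes) || n_nodes < 3) {
    pn_stop("n_nodes must be an integer >= 3", "presbynet_config_error")
  }
  min(1, 2 * log(n_nodes) / (n_nodes - 1))
}

# Deterministic ranking of node pairs by decreasing |weight|; ties broken by
# lexicographic (i, j). Returns a list with the pair index matrix (i < j) in
# rank order and a flag for ties anywhere in the ordering.
#' @noRd
rank_pairs <- function(values) {
  n <- ncol(values)
  ut <- which(upper.tri(values), arr.ind = TRUE)
  w <- abs(values[upper.tri(values)])
  ord <- order(-w, ut[, 1], ut[, 2])
  list(pairs = ut[ord, , drop = FALSE], weights = w[ord],
       has_ties = anyDuplicated(w) > 0)
}

#' Construct a binary-graph object
#' @param adjacency N x N symmetric 0/1 matrix with zero diagonal.
#' @param sparsity the sparsity level this graph was thresholded at.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, sparsity = NA_real_) {
  adjacency <- as.matrix(adjacency)
  n <- ncol(adjacency)
  if (nrow(adjacency) != n) pn_stop("adjacency must be square",
                                    "presbynet_shape_error")
  if (!all(adjacency %in% c(0, 1))) {
    pn_stop("adjacency entries must be 0/1", "presbynet_value_error")
  }
  if (any(adjacency != t(adjacency))) {
    pn_stop("adjacency must be symmetric (undirected graph)",
            "presbynet_value_error")
  }
  if (any(diag(adjacency) != 0)) {
    pn_stop("self-loops are not allowed", "presbynet_value_error")
  }
  storage.mode(adjacency) <- "integer"
  if (is.null(colnames(adjacency))) {
    dimnames(adjacency) <- rep(list(sprintf("ROI%03d", seq_len(n))), 2)
  }
  structure(list(adjacency = adjacency, sparsity = sparsity),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %s)\n",
              ncol(x$adjacency), sum(x$adjacency) / 2,
              format(x$sparsity)))
  invisible(x)
}

#' @noRd
graph_edge_count <- function(g) sum(g$adjacency) %/% 2L

#' @noRd
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Binarize a connectivity matrix at one sparsity level
#'
#' Keeps the `round(s * N(N-1)/2)` node pairs with the largest absolute
#' partial correlation as edges (round half away from zero). Ties at the
#' cutoff are broken by lexicographic pair order and reported with a warning.
#'
#' @param conn a [connectivity_matrix()].
#' @param s sparsity in (0, 1]: fraction of all possible edges retained.
#' @return A [binary_graph()].
#' @export
binarize_at_sparsity <- function(conn, s) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  stopifnot_scalar_prob(s, "s")
  if (all(conn$values == 0)) {
    pn_stop("all-zero connectivity matrix cannot be thresholded",
            "presbynet_degenerate_input_error")
  }
  n <- ncol(conn$values)
  m <- as.integer(round_half_up(s * n * (n - 1) / 2))
  rk <- rank_pairs(conn$values)
  if (rk$has_ties && m < nrow(rk$pairs) &&
      m >= 1 && rk$weights[m] == rk$weights[m + 1]) {
    warning("tied |partial correlations| at the sparsity cutoff; ",
            "broken by lexicographic pair order", call. = FALSE)
  }
  adj <- matrix(0L, n, n, dimnames = dimnames(conn$values))
  if (m > 0) {
    keep <- rk$pairs[seq_len(min(m, nrow(rk$pairs))), , drop = FALSE]
    adj[keep] <- 1L
    adj[keep[, c(2, 1), drop = FALSE]] <- 1L
  }
  binary_graph(adj, sparsity = s)
}

#' Threshold a connectivity matrix over a whole sparsity grid
#'
#' One binary graph per grid value. Because every graph keeps the top-ranked
#' pairs under a single deterministic ordering, the edge sets are nested:
#' the graph at a lower sparsity is a subgraph of every higher one.
#'
#' @param conn a [connectivity_matrix()].
#' @param grid strictly increasing sparsity values (default [sparsity_grid()]).
#' @return An object of class `threshold_series`: list with `graphs` (list of
#'   [binary_graph()]) and `grid`.
#' @export
build_threshold_series <- function(conn, grid = sparsity_grid()) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  if (length(grid) < 1 || any(diff(grid) <= 0)) {
    pn_stop("grid must be non-empty and strictly increasing",
            "presbynet_config_error")
  }
  graphs <- lapply(grid, function(s) binarize_at_sparsity(conn, s))
  structure(list(graphs = graphs, grid = grid,
                 roi_labels = conn$roi_labels),
            class = "threshold_series")
}

#' @export
print.threshold_series <- function(x, ...) {
  cat(sprintf("<threshold_series> %d graphs on %d nodes, sparsity %.2f..%.2f\n",
              length(x$graphs), ncol(x$graphs[[1]]$adjacency),
              min(x$grid), max(x$grid)))
  invisible(x)
}
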