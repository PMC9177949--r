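## Global and nodal graph metrics on binary undirected graphs, degree-
## preserving random-reference normalization, and AUC aggregation over the
## sparsity grid. Shortest paths and betweenness go through igraph; the
## Maslov-Sneppen double-edge-swap null model is implemented here because its
## accept/retry semantics are part of the method definition.

#' Mean clustering coefficient (Cp)
#'
#' Mean over nodes of `2 * triangles_i / (k_i (k_i - 1))`; nodes with degree
#' below 2 contribute 0.
#'
#' @param g a [binary_graph()] with at least 3 nodes.
#' @return A single number in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (ncol(g$adjacency) < 3) pn_stop("need at least 3 nodes",
                                     "presbynet_shape_error")
  cc <- igraph::transitivity(as_igraph(g), type = "local", isolates = "zero")
  mean(cc)
}

#' Characteristic path length (Lp)
#'
#' Mean shortest-path length over all pairs of distinct nodes that are
#' connected. Unreachable pairs are excluded from the mean and counted in
#' the `unreachable_pairs` attribute (the convention used by connectome
#' toolboxes, which keeps the statistic finite on low-sparsity graphs).
#'
#' @param g a [binary_graph()] with at least one edge.
#' @return A single number with attribute `unreachable_pairs` (count of
#'   unordered node pairs with no connecting path).
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (graph_edge_count(g) == 0) {
    pn_stop("characteristic path length is undefined on an edgeless graph",
            "presbynet_undefined_metric_error")
  }
  d <- igraph::distances(as_igraph(g))
  off <- d[upper.tri(d)]
  reachable <- is.finite(off)
  structure(mean(off[reachable]),
            unreachable_pairs = sum(!reachable))
}

#' Global efficiency (Eglob)
#'
#' Mean over distinct node pairs of the inverse shortest-path length, with
#' unreachable pairs contributing 0.
#'
#' @param g a [binary_graph()].
#' @return A single number in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- igraph::distances(as_igraph(g))
  off <- d[upper.tri(d)]
  mean(1 / off)  # 1/Inf = 0 for unreachable pairs
}

#' @noRd
subgraph_efficiency <- function(adj, members) {
  if (length(members) < 2) return(0)
  sub <- binary_graph(adj[members, members, drop = FALSE])
  global_efficiency(sub)
}

#' Local efficiency (Eloc)
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours. By the standard convention the index node itself is
#' excluded from its neighbour subgraph; set `include_node = TRUE` for the
#' literal "node and its neighbours" variant. Nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param g a [binary_graph()].
#' @param include_node include the index node in its neighbour subgraph?
#' @return A single number in `[0, 1]`.
#' @export
local_efficiency <- function(g, include_node = FALSE) {
  stopifnot(inherits(g, "binary_graph"))
  mean(nodal_local_efficiency(g, include_node))
}

#' @noRd
nodal_local_efficiency <- function(g, include_node = FALSE) {
  adj <- g$adjacency
  vapply(seq_len(ncol(adj)), function(i) {
    nb <- which(adj[, i] == 1L)
    if (length(nb) < 2) return(0)
    if (include_node) nb <- c(i, nb)
    subgraph_efficiency(adj, nb)
  }, numeric(1))
}

#' Nodal metrics at a single sparsity
#'
#' Degree centrality (DC), betweenness centrality (BC, raw geodesic-fraction
#' sums, unnormalized), nodal efficiency (NE, mean inverse distance to every
#' other node, unreachable contributing 0) and nodal local efficiency (NLE,
#' the neighbour-subgraph efficiency of each node).
#'
#' @param g a [binary_graph()] with at least 3 nodes.
#' @param normalize_bc divide BC by `(N-1)(N-2)/2`? (default FALSE)
#' @param include_node passed to the NLE neighbour-subgraph rule.
#' @return A data.frame with columns `node`, `dc`, `bc`, `ne`, `nle`.
#' @export
nodal_metrics <- function(g, normalize_bc = FALSE, include_node = FALSE) {
  stopifnot(inherits(g, "binary_graph"))
  n <- ncol(g$adjacency)
  if (n < 3) pn_stop("need at least 3 nodes", "presbynet_shape_error")
  ig <- as_igraph(g)
  dc <- igraph::degree(ig)
  bc <- igraph::betweenness(ig, directed = FALSE)
  if (normalize_bc) bc <- bc / ((n - 1) * (n - 2) / 2)
  d <- igraph::distances(ig)
  diag(d) <- Inf
  ne <- rowMeans(1 / d) * n / (n - 1)
  nle <- nodal_local_efficiency(g, include_node)
  data.frame(node = colnames(g$adjacency), dc = as.numeric(dc),
             bc = as.numeric(bc), ne = as.numeric(ne), nle = nle,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Degree-preserving double-edge swaps (Maslov-Sneppen). Targets
# `target_swaps` accepted swaps with at most `max_attempts` proposals; every
# accepted swap keeps the graph simple and preserves every node's degree.
# The proposal loop lives in compiled code (src/rewire.cpp) and draws from
# R's RNG, so results are reproducible under set.seed().
#' @noRd
double_edge_swap <- function(adj, target_swaps, max_attempts) {
  cpp_double_edge_swap(adj, as.integer(target_swaps),
                       as.integer(max_attempts))
}

#' Degree-preserving random-reference ensemble
#'
#' Generates `n_null` randomized copies of `g` by double-edge swaps
#' (target `10 |E|` accepted swaps per null, proposal cap `100 |E|`), and
#' returns the ensemble means of the clustering coefficient and the
#' characteristic path length. Every null has exactly the degree sequence of
#' `g`. Graphs too constrained to rewire (e.g. a star) yield identity copies
#' with a warning.
#'
#' @param g a [binary_graph()] with at least 2 edges.
#' @param n_null ensemble size (default 100).
#' @param seed integer seed for the private RNG stream.
#' @return A list of class `random_reference_stats`: `cp_rand`, `lp_rand`,
#'   `n_null`, `seed`, `mean_accepted_swaps`.
#' @export
random_reference_ensemble <- function(g, n_null = 100L, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  m <- graph_edge_count(g)
  if (m < 2) pn_stop("need at least 2 edges to build a null ensemble",
                     "presbynet_degenerate_input_error")
  if (!is_count(n_null) || n_null < 1) {
    pn_stop("n_null must be a positive integer", "presbynet_config_error")
  }
  seeds <- spawn_seeds(seed, n_null)
  cp <- lp <- acc <- numeric(n_null)
  for (i in seq_len(n_null)) {
    sw <- with_seed(seeds[i],
                    double_edge_swap(g$adjacency, 10L * m, 100L * m))
    null_g <- binary_graph(sw$adjacency, sparsity = g$sparsity)
    cp[i] <- clustering_coefficient(null_g)
    lp[i] <- as.numeric(characteristic_path_length(null_g))
    acc[i] <- sw$accepted
  }
  if (all(acc == 0)) {
    warning("graph could not be rewired (degree sequence too constrained); ",
            "null ensemble equals the input graph", call. = FALSE)
  }
  structure(list(cp_rand = mean(cp), lp_rand = mean(lp),
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 mean_accepted_swaps = mean(acc)),
            class = "random_reference_stats")
}

#' Small-world indices
#'
#' `gamma = Cp / Cp_rand`, `lambda = Lp / Lp_rand`, `sigma = gamma / lambda`.
#' A small-world graph has `gamma > 1`, `lambda` near 1 and `sigma > 1`.
#'
#' @param g a [binary_graph()].
#' @param ref a [random_reference_ensemble()] result for `g`.
#' @return Named numeric vector `c(gamma, lambda, sigma)`.
#' @export
small_world_indices <- function(g, ref) {
  stopifnot(inherits(g, "binary_graph"),
            inherits(ref, "random_reference_stats"))
  if (!is.finite(ref$cp_rand) || ref$cp_rand <= 0) {
    pn_stop("cp_rand is zero or non-finite; gamma undefined",
            "presbynet_division_guard_error")
  }
  if (!is.finite(ref$lp_rand) || ref$lp_rand <= 0) {
    pn_stop("lp_rand is zero or non-finite; lambda undefined",
            "presbynet_division_guard_error")
  }
  gamma <- clustering_coefficient(g) / ref$cp_rand
  lambda <- as.numeric(characteristic_path_length(g)) / ref$lp_rand
  c(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Area under a metric curve over the sparsity grid
#'
#' Composite trapezoid rule on the grid nodes:
#' `sum_k (s_{k+1} - s_k) * (y_k + y_{k+1}) / 2`.
#'
#' @param values metric values aligned to `grid`.
#' @param grid strictly increasing sparsity values (>= 2 points).
#' @return A single number.
#' @export
metric_auc <- function(values, grid) {
  if (length(values) != length(grid)) {
    pn_stop("values and grid lengths differ", "presbynet_shape_error")
  }
  if (length(grid) < 2) {
    pn_stop("AUC needs at least 2 grid points", "presbynet_shape_error")
  }
  sum(diff(grid) * (head(values, -1) + values[-1]) / 2)
}

#' Global metric profile over a threshold series
#'
#' Computes Cp, Lp, Eglob, Eloc at every sparsity; gamma, lambda and sigma
#' against a fresh degree-preserving null ensemble per graph; and the AUC of
#' each of the seven curves over the grid.
#'
#' @param series a [build_threshold_series()] result.
#' @param n_null null-ensemble size per graph (default 100).
#' @param seed integer seed for the null ensembles.
#' @return An object of class `global_metric_profile`: list with `metrics`
#'   (data.frame, one row per sparsity, columns `sparsity, cp, lp, eglob,
#'   eloc, gamma, lambda, sigma, unreachable_pairs`) and `auc` (named vector).
#' @export
global_metrics_over_grid <- function(series, n_null = 100L, seed = 1L) {
  stopifnot(inherits(series, "threshold_series"))
  seeds <- spawn_seeds(seed, length(series$graphs))
  rows <- lapply(seq_along(series$graphs), function(k) {
    g <- series$graphs[[k]]
    cp <- clustering_coefficient(g)
    lp <- characteristic_path_length(g)
    ref <- random_reference_ensemble(g, n_null = n_null, seed = seeds[k])
    sw <- small_world_indices(g, ref)
    data.frame(sparsity = series$grid[k], cp = cp, lp = as.numeric(lp),
               eglob = global_efficiency(g), eloc = local_efficiency(g),
               gamma = sw[["gamma"]], lambda = sw[["lambda"]],
               sigma = sw[["sigma"]],
               unreachable_pairs = attr(lp, "unreachable_pairs"))
  })
  metrics <- do.call(rbind, rows)
  auc <- vapply(c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma"),
                function(mm) metric_auc(metrics[[mm]], series$grid),
                numeric(1))
  structure(list(metrics = metrics, auc = auc,
                 n_null = n_null, seed = seed),
            class = "global_metric_profile")
}

#' @export
print.global_metric_profile <- function(x, ...) {
  cat(sprintf("<global_metric_profile> %d sparsity levels, %d nulls/graph\n",
              nrow(x$metrics), x$n_null))
  cat("AUC: ", paste(sprintf("%s=%.3f", names(x$auc), x$auc),
                     collapse = "  "), "\n")
  invisible(x)
}

#' Nodal metric profiles over a threshold series
#'
#' BC, DC, NE and NLE for every node at every sparsity, plus per-node AUCs.
#'
#' @param series a [build_threshold_series()] result.
#' @param normalize_bc,include_node passed to [nodal_metrics()].
#' @return An object of class `nodal_metric_profile`: list of N x K matrices
#'   `bc`, `dc`, `ne`, `nle` (rows = nodes, columns = sparsities) and `auc`,
#'   an N x 4 matrix of per-node AUCs.
#' @export
nodal_metrics_over_grid <- function(series, normalize_bc = FALSE,
                                    include_node = FALSE) {
  stopifnot(inherits(series, "threshold_series"))
  per_graph <- lapply(series$graphs, nodal_metrics,
                      normalize_bc = normalize_bc,
                      include_node = include_node)
  grab <- function(col) {
    mat <- vapply(per_graph, function(df) df[[col]],
                  numeric(nrow(per_graph[[1]])))
    mat <- matrix(mat, nrow = nrow(per_graph[[1]]))
    rownames(mat) <- per_graph[[1]]$node
    colnames(mat) <- format(series$grid)
    mat
  }
  out <- list(bc = grab("bc"), dc = grab("dc"),
              ne = grab("ne"), nle = grab("nle"))
  out$auc <- vapply(out, function(mat) {
    apply(mat, 1, metric_auc, grid = series$grid)
  }, numeric(nrow(out$bc)))
  structure(out, class = "nodal_metric_profile")
}
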