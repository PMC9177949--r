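## Intra- and inter-modular connection strengths over the fixed anatomical
## module partition (no data-driven community detection).

#' Intra- and inter-modular connection strengths
#'
#' For every graph in a threshold series, counts edges with both endpoints
#' inside each module (intra) and edges with exactly one endpoint in the
#' module (inter), then averages the counts over the sparsity grid. "Strength"
#' is a binary edge count by default; set `weighted = TRUE` together with a
#' [connectivity_matrix()] in `weights` to sum absolute partial correlations
#' instead.
#'
#' @param series a [build_threshold_series()] result (or a single
#'   [binary_graph()]).
#' @param partition a [module_partition()] covering the graph's node labels.
#' @param weighted sum |weights| instead of counting edges?
#' @param weights a [connectivity_matrix()]; required when `weighted = TRUE`.
#' @return An object of class `modular_connectivity`: list with
#'   `intra_strength` (named per-module means over the grid), `inter_strength`
#'   (idem), `pair_counts` (module x module matrix of mean inter-module edge
#'   counts, intra counts on the diagonal) and `per_sparsity` (data.frame of
#'   raw per-sparsity counts).
#' @export
modular_connection_strengths <- function(series, partition,
                                         weighted = FALSE, weights = NULL) {
  if (inherits(series, "binary_graph")) {
    series <- structure(list(graphs = list(series),
                             grid = series$sparsity,
                             roi_labels = colnames(series$adjacency)),
                        class = "threshold_series")
  }
  stopifnot(inherits(series, "threshold_series"),
            inherits(partition, "module_partition"))
  labels <- series$roi_labels
  if (!all(labels %in% names(partition))) {
    pn_stop("graph node labels missing from the module partition",
            "presbynet_alignment_error")
  }
  node_mod <- factor(as.character(partition[labels]), levels = levels(partition))
  mods <- levels(node_mod)
  k <- length(mods)
  w_mat <- NULL
  if (weighted) {
    if (is.null(weights) || !inherits(weights, "connectivity_matrix")) {
      pn_stop("weighted strengths need `weights` as a connectivity_matrix",
              "presbynet_config_error")
    }
    w_mat <- abs(weights$values[labels, labels])
  }
  per <- lapply(seq_along(series$graphs), function(s) {
    adj <- series$graphs[[s]]$adjacency
    contrib <- if (weighted) adj * w_mat else adj
    # module-by-module sums of the upper triangle
    pair <- matrix(0, k, k, dimnames = list(mods, mods))
    ut <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    if (nrow(ut)) {
      mi <- as.integer(node_mod[ut[, 1]])
      mj <- as.integer(node_mod[ut[, 2]])
      vals <- contrib[ut]
      lo <- pmin(mi, mj); hi <- pmax(mi, mj)
      for (e in seq_along(vals)) {
        pair[lo[e], hi[e]] <- pair[lo[e], hi[e]] + vals[e]
      }
    }
    pair[lower.tri(pair)] <- t(pair)[lower.tri(pair)]
    pair
  })
  mean_pair <- Reduce(`+`, per) / length(per)
  intra <- diag(mean_pair)
  inter <- rowSums(mean_pair) - intra
  per_sparsity <- do.call(rbind, lapply(seq_along(per), function(s) {
    data.frame(sparsity = series$grid[s], module = mods,
               intra = diag(per[[s]]),
               inter = rowSums(per[[s]]) - diag(per[[s]]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(intra_strength = setNames(intra, mods),
                 inter_strength = setNames(inter, mods),
                 pair_counts = mean_pair,
                 per_sparsity = per_sparsity,
                 weighted = weighted),
            class = "modular_connectivity")
}

#' @export
print.modular_connectivity <- function(x, ...) {
  cat("<modular_connectivity> mean strengths over the sparsity grid\n")
  print(round(rbind(intra = x$intra_strength, inter = x$inter_strength), 2))
  invisible(x)
}
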