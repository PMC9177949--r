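## Rich-club organization: hub selection from group-average degree and
## classification of edges into rich-club / feeder / local connections.

#' Group-average nodal degree
#'
#' Per-node degree averaged over subjects and over all sparsity levels of
#' their threshold series.
#'
#' @param series_list list of [build_threshold_series()] results sharing node
#'   labels and grid.
#' @return Named numeric vector of mean degrees.
#' @export
group_average_degree <- function(series_list) {
  if (inherits(series_list, "threshold_series")) {
    series_list <- list(series_list)
  }
  stopifnot(length(series_list) >= 1,
            all(vapply(series_list, inherits, logical(1), "threshold_series")))
  ref <- series_list[[1]]
  for (s in series_list[-1]) {
    if (!identical(s$roi_labels, ref$roi_labels) ||
        length(s$grid) != length(ref$grid) ||
        max(abs(s$grid - ref$grid)) > 1e-9) {
      pn_stop("all subjects must share node labels and sparsity grid",
              "presbynet_alignment_error")
    }
  }
  total <- 0
  n_graphs <- 0L
  for (s in series_list) {
    for (g in s$graphs) {
      total <- total + colSums(g$adjacency)
      n_graphs <- n_graphs + 1L
    }
  }
  total / n_graphs
}

#' Select rich-club nodes
#'
#' The top `floor(fraction * N)` nodes by average degree. With the default
#' 90-node atlas and fraction 0.12 this is the conventional 10-node rich
#' club. Ties spanning the cutoff are broken by node order with a warning.
#'
#' @param avg_degree named per-node average degrees, e.g. from
#'   [group_average_degree()].
#' @param fraction proportion of nodes in the rich club, in (0, 1).
#' @return Character vector of rich-node labels, ordered by descending
#'   average degree.
#' @export
select_rich_nodes <- function(avg_degree, fraction = 0.12) {
  stopifnot_scalar_prob(fraction, "fraction", closed1 = FALSE)
  n <- length(avg_degree)
  k <- floor(fraction * n)
  if (k < 1) pn_stop("fraction too small: empty rich club",
                     "presbynet_config_error")
  if (is.null(names(avg_degree))) {
    names(avg_degree) <- sprintf("ROI%03d", seq_len(n))
  }
  ord <- order(-avg_degree, seq_len(n))
  if (k < n && avg_degree[ord[k]] == avg_degree[ord[k + 1]]) {
    warning("tied average degree at the rich-club cutoff; ",
            "broken by node order", call. = FALSE)
  }
  names(avg_degree)[ord[seq_len(k)]]
}

#' Classify edges as rich-club, feeder or local
#'
#' An edge is `rich` when both endpoints are rich-club nodes, `feeder` when
#' exactly one is, and `local` when neither is. The three classes partition
#' the edge set.
#'
#' @param g a [binary_graph()].
#' @param rich character vector of rich-node labels (subset of the graph's
#'   nodes).
#' @return A list: `edges` (data.frame `from`, `to`, `class`) and `counts`
#'   (named vector `rich`, `feeder`, `local` summing to `|E|`).
#' @export
classify_edges <- function(g, rich) {
  stopifnot(inherits(g, "binary_graph"))
  labels <- colnames(g$adjacency)
  if (!all(rich %in% labels)) {
    pn_stop("rich nodes must be a subset of the graph's nodes",
            "presbynet_alignment_error")
  }
  ut <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  is_rich <- labels %in% rich
  n_rich_ends <- (is_rich[ut[, 1]] + is_rich[ut[, 2]])
  cls <- c("local", "feeder", "rich")[n_rich_ends + 1L]
  edges <- data.frame(from = labels[ut[, 1]], to = labels[ut[, 2]],
                      class = cls, stringsAsFactors = FALSE)
  counts <- setNames(
    as.numeric(table(factor(cls, levels = c("rich", "feeder", "local")))),
    c("rich", "feeder", "local"))
  list(edges = edges, counts = counts)
}

#' Per-subject mean strength of rich, feeder and local connections
#'
#' For each subject, classifies every graph's edges against a fixed rich set
#' and averages the three class counts over the sparsity grid. The rows feed
#' directly into the group-comparison stage.
#'
#' @param series_list list of per-subject [build_threshold_series()] results
#'   (named by subject id).
#' @param rich character vector of rich-node labels.
#' @return data.frame with columns `subject_id`, `rich`, `feeder`, `local`
#'   (mean counts over sparsity).
#' @export
class_strengths <- function(series_list, rich) {
  if (inherits(series_list, "threshold_series")) {
    series_list <- list(subject = series_list)
  }
  ids <- names(series_list) %||% sprintf("subject%02d", seq_along(series_list))
  rows <- lapply(seq_along(series_list), function(i) {
    counts <- vapply(series_list[[i]]$graphs,
                     function(g) classify_edges(g, rich)$counts,
                     numeric(3))
    mc <- rowMeans(matrix(counts, nrow = 3))
    data.frame(subject_id = ids[i], rich = mc[1], feeder = mc[2],
               local = mc[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
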