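# Global and nodal graph metrics, null-model normalization, AUC.

complete_graph <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L
  binary_graph(adj)
}

star_graph <- function(n) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1L
  binary_graph(adj)
}

path_graph <- function(n) {
  graph_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

test_that("clustering coefficient matches closed forms and the triangle oracle", {
  expect_equal(clustering_coefficient(complete_graph(5)), 1)
  expect_equal(clustering_coefficient(star_graph(6)), 0)
  g7 <- graph_from_edges(7, list(c(1,2), c(2,3), c(1,3), c(3,4), c(4,5),
                                 c(5,6), c(4,6), c(6,7)))
  expect_equal(clustering_coefficient(g7), oracle_clustering(g7$adjacency),
               tolerance = 1e-12)
})

test_that("characteristic path length handles paths and disconnection", {
  expect_equal(as.numeric(characteristic_path_length(complete_graph(4))), 1)
  lp4 <- characteristic_path_length(path_graph(4))
  expect_equal(as.numeric(lp4), 10 / 6)
  expect_equal(attr(lp4, "unreachable_pairs"), 0)
  two_k3 <- graph_from_edges(6, list(c(1,2), c(2,3), c(1,3),
                                     c(4,5), c(5,6), c(4,6)))
  lp2 <- characteristic_path_length(two_k3)
  expect_equal(as.numeric(lp2), 1)
  expect_equal(attr(lp2, "unreachable_pairs"), 9)
  empty <- binary_graph(matrix(0L, 4, 4))
  expect_error(characteristic_path_length(empty),
               class = "presbynet_undefined_metric_error")
})

test_that("efficiencies match closed forms and the BFS oracle", {
  expect_equal(global_efficiency(complete_graph(4)), 1)
  expect_equal(local_efficiency(complete_graph(4)), 1)
  expect_equal(global_efficiency(binary_graph(matrix(0L, 5, 5))), 0)
  adj <- random_adj(9, 0.35, seed = 51)
  g <- binary_graph(adj)
  expect_equal(global_efficiency(g), oracle_eglob(adj), tolerance = 1e-12)
  expect_equal(local_efficiency(g), oracle_eloc(adj), tolerance = 1e-12)
})

test_that("nodal metrics match hand cases and the path-counting oracle", {
  p3 <- path_graph(3)
  nm3 <- nodal_metrics(p3)
  expect_equal(nm3$bc, c(0, 1, 0))          # unique geodesic through centre
  st <- star_graph(6)
  nms <- nodal_metrics(st)
  expect_equal(nms$dc[1], 5)
  expect_equal(nms$ne[1], 1)
  adj <- random_adj(10, 0.4, seed = 52)
  nm <- nodal_metrics(binary_graph(adj))
  expect_equal(nm$dc, colSums(adj), ignore_attr = TRUE)
  expect_equal(nm$bc, oracle_bc(adj), tolerance = 1e-10)
  expect_equal(nm$ne, oracle_ne(adj), tolerance = 1e-10)
  expect_equal(nm$nle, oracle_nle(adj), tolerance = 1e-10)
})

test_that("betweenness is equal across nodes of a cycle (vertex transitivity)", {
  cyc <- graph_from_edges(8, c(lapply(1:7, function(i) c(i, i + 1)), list(c(8, 1))))
  bc <- nodal_metrics(cyc)$bc
  expect_true(all(abs(bc - bc[1]) < 1e-12))
})

test_that("null ensembles preserve degree sequences exactly", {
  adj <- random_adj(20, 0.2, seed = 53)
  g <- binary_graph(adj)
  seeds <- presbynet:::spawn_seeds(99, 5)
  for (s in seeds) {
    sw <- presbynet:::with_seed(s,
      presbynet:::double_edge_swap(g$adjacency,
                                   10L * sum(adj) / 2L, 100L * sum(adj) / 2L))
    expect_equal(colSums(sw$adjacency), colSums(adj), ignore_attr = TRUE)
    expect_equal(diag(sw$adjacency), rep(0L, 20), ignore_attr = TRUE)
    expect_true(all(sw$adjacency == t(sw$adjacency)))
    expect_gt(sw$accepted, 0)
  }
})

test_that("randomization lowers lattice clustering and is reproducible", {
  g <- binary_graph(ring_lattice_adj(50, 4))
  ref1 <- random_reference_ensemble(g, n_null = 20, seed = 7)
  ref2 <- random_reference_ensemble(g, n_null = 20, seed = 7)
  expect_identical(ref1$cp_rand, ref2$cp_rand)
  expect_lt(ref1$cp_rand, clustering_coefficient(g))
  expect_gt(ref1$cp_rand, 0)
})

test_that("unrewireable graphs fall back to identity nulls with a warning", {
  st <- star_graph(8)
  expect_warning(ref <- random_reference_ensemble(st, n_null = 3, seed = 1),
                 "could not be rewired")
  expect_equal(ref$cp_rand, clustering_coefficient(st))
  expect_error(random_reference_ensemble(
    graph_from_edges(4, list(c(1, 2))), n_null = 2, seed = 1),
    class = "presbynet_degenerate_input_error")
})

test_that("small-world indices are 1 against self-referential nulls", {
  g <- binary_graph(ring_lattice_adj(30, 4))
  self_ref <- structure(list(cp_rand = clustering_coefficient(g),
                             lp_rand = as.numeric(characteristic_path_length(g)),
                             n_null = 1L, seed = 1L),
                        class = "random_reference_stats")
  sw <- small_world_indices(g, self_ref)
  expect_equal(unname(sw), c(1, 1, 1))
  bad <- structure(list(cp_rand = 0, lp_rand = 2),
                   class = "random_reference_stats")
  expect_error(small_world_indices(g, bad),
               class = "presbynet_division_guard_error")
})

test_that("a lattice with shortcuts is small-world; dense random graphs are not", {
  # ring lattice (k = 10) with deterministic long-range shortcuts
  adj <- ring_lattice_adj(90, 10)
  for (i in seq(1, 90, by = 9)) {
    j <- ((i + 44) %% 90) + 1
    adj[i, j] <- adj[j, i] <- 1L
  }
  g <- binary_graph(adj)
  ref <- random_reference_ensemble(g, n_null = 10, seed = 3)
  sw <- small_world_indices(g, ref)
  expect_gt(sw[["gamma"]], 1)
  expect_gt(sw[["sigma"]], 1)
  # Erdos-Renyi-like graphs: gamma near 1 (20 replicates, N = 200)
  gammas <- vapply(1:20, function(r) {
    adj_er <- random_adj(200, 0.05, seed = 600 + r)
    g_er <- binary_graph(adj_er)
    ref_er <- random_reference_ensemble(g_er, n_null = 3, seed = r)
    clustering_coefficient(g_er) / ref_er$cp_rand
  }, numeric(1))
  expect_lt(abs(mean(gammas) - 1), 0.2)
})

test_that("AUC follows the trapezoid rule and is linear", {
  grid <- sparsity_grid()
  expect_equal(metric_auc(rep(2, 35), grid), 0.68)
  expect_equal(metric_auc(c(0, 0.5, 1), c(0, 0.5, 1)), 0.5)
  withr::with_seed(54, {
    y1 <- rnorm(35); y2 <- rnorm(35)
  })
  riemann <- sum(diff(grid) * (y1[-35] + y1[-1]) / 2)   # direct summation
  expect_equal(metric_auc(y1, grid), riemann, tolerance = 1e-12)
  expect_equal(metric_auc(3 * y1 - 2 * y2, grid),
               3 * metric_auc(y1, grid) - 2 * metric_auc(y2, grid),
               tolerance = 1e-10)
  expect_error(metric_auc(y1[1:10], grid), class = "presbynet_shape_error")
  expect_error(metric_auc(1, 0.5), class = "presbynet_shape_error")
})

test_that("global profiles cover every sparsity with AUCs and sane values", {
  withr::with_seed(55, {
    v <- matrix(rnorm(400), 20); v <- (v + t(v)) / 2; diag(v) <- 0
  })
  ser <- build_threshold_series(connectivity_matrix(v),
                                grid = sparsity_grid(0.1, 0.4, 0.1))
  prof <- global_metrics_over_grid(ser, n_null = 5, seed = 9)
  expect_equal(nrow(prof$metrics), 4)
  expect_named(prof$auc, c("cp", "lp", "eglob", "eloc",
                           "gamma", "lambda", "sigma"))
  expect_true(all(is.finite(prof$metrics$gamma)))
  # complete graphs at every level: Cp = Eglob = 1
  ser_k <- structure(list(graphs = list(complete_graph(8), complete_graph(8)),
                          grid = c(0.5, 1), roi_labels = NULL),
                     class = "threshold_series")
  prof_k <- suppressWarnings(global_metrics_over_grid(ser_k, n_null = 2, seed = 1))
  expect_equal(prof_k$metrics$cp, c(1, 1))
  expect_equal(prof_k$metrics$eglob, c(1, 1))
})

test_that("Eglob never decreases and Lp never increases along nested series", {
  withr::with_seed(56, {
    v <- matrix(rnorm(225), 15); v <- (v + t(v)) / 2; diag(v) <- 0
  })
  # plant a dominant ring so every graph in the series is connected
  for (i in 1:15) {
    j <- (i %% 15) + 1
    v[i, j] <- v[j, i] <- 5 + i / 15
  }
  ser <- build_threshold_series(connectivity_matrix(v),
                                sparsity_grid(0.2, 0.4, 0.01))
  lp0 <- characteristic_path_length(ser$graphs[[1]])
  expect_equal(attr(lp0, "unreachable_pairs"), 0)  # connected regime
  eg <- vapply(ser$graphs, global_efficiency, numeric(1))
  lp <- vapply(ser$graphs,
               function(g) as.numeric(characteristic_path_length(g)),
               numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
  expect_true(all(diff(lp) <= 1e-12))
})

test_that("nodal profiles produce per-node curves and AUCs", {
  withr::with_seed(57, {
    v <- matrix(rnorm(144), 12); v <- (v + t(v)) / 2; diag(v) <- 0
  })
  ser <- build_threshold_series(connectivity_matrix(v),
                                grid = c(0.2, 0.3, 0.4))
  prof <- nodal_metrics_over_grid(ser)
  expect_equal(dim(prof$dc), c(12, 3))
  expect_equal(colnames(prof$auc), c("bc", "dc", "ne", "nle"))
  expect_equal(prof$auc[, "dc"],
               apply(prof$dc, 1, metric_auc, grid = ser$grid))
})
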