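## End-to-end orchestration: configuration, file I/O (TSV time series, CSV
## tables, BrainNet-Viewer-style .node/.edge exports) and the full
## cohort-to-statistics pipeline.

#' Read an ROI time-series TSV
#'
#' Expects a header of ROI labels and one row per time point. When
#' `expected_labels` is supplied, the file must contain exactly those columns;
#' a permuted column order is realigned by label with a warning.
#'
#' @param path TSV file path.
#' @param tr_s repetition time attached to the result (default 2 s).
#' @param expected_labels optional character vector of required ROI labels
#'   (e.g. [aal90_labels()]).
#' @return An [roi_timeseries()].
#' @export
read_timeseries <- function(path, tr_s = 2, expected_labels = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1]
      pn_stop(sprintf("non-numeric cell at row %s, column `%s` of %s",
                      bad %||% "?", names(tab)[j], basename(path)),
              "presbynet_parse_error")
    }
  }
  mat <- as.matrix(tab)
  if (!is.null(expected_labels)) {
    if (ncol(mat) != length(expected_labels) ||
        !setequal(colnames(mat), expected_labels)) {
      pn_stop(sprintf(
        "%s has %d columns; expected the %d atlas labels",
        basename(path), ncol(mat), length(expected_labels)),
        "presbynet_schema_error")
    }
    if (!identical(colnames(mat), expected_labels)) {
      warning("ROI columns reordered to match the atlas label order",
              call. = FALSE)
      mat <- mat[, expected_labels, drop = FALSE]
    }
  }
  roi_timeseries(mat, tr_s = tr_s)
}

#' Write an ROI time-series TSV
#' @param ts an [roi_timeseries()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  write.table(ts$values, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `roster.csv`, `<id>.tsv` and
#'   `<id>_motion.tsv` files.
#' @param tr_s repetition time (default 2 s).
#' @param expected_labels optional atlas labels passed to [read_timeseries()].
#' @return A list with `roster`, `timeseries`, `motion` (as in a
#'   `synthetic_cohort`).
#' @export
read_cohort <- function(dir, tr_s = 2, expected_labels = NULL) {
  roster <- read.csv(file.path(dir, "roster.csv"), stringsAsFactors = FALSE)
  timeseries <- list(); motion <- list()
  for (sid in roster$subject_id) {
    timeseries[[sid]] <- read_timeseries(file.path(dir, paste0(sid, ".tsv")),
                                         tr_s = tr_s,
                                         expected_labels = expected_labels)
    mpath <- file.path(dir, paste0(sid, "_motion.tsv"))
    if (file.exists(mpath)) {
      motion[[sid]] <- as.matrix(read.delim(mpath, check.names = FALSE))
    }
  }
  list(roster = roster, timeseries = timeseries, motion = motion)
}

#' Write a connectivity matrix as labeled TSV
#' @param conn a [connectivity_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_connectivity <- function(conn, path) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  write.table(conn$values, path, sep = "\t", row.names = TRUE,
              col.names = NA, quote = FALSE)
  invisible(path)
}

#' Export a graph in BrainNet-Viewer .node/.edge format
#'
#' Writes `<prefix>.edge` (N x N whitespace-separated 0/1 adjacency) and
#' `<prefix>.node` (x, y, z, color, size, label per row). Node coordinates
#' come from the packaged schematic centroid table; colors default to the
#' module index and sizes to the node degree. Rich-club members can be
#' highlighted via `rich`.
#'
#' @param g a [binary_graph()] on the 90-node atlas (or matching `atlas`).
#' @param prefix output path prefix (without extension).
#' @param atlas atlas lookup with coordinates, default
#'   `aal90_atlas(with_coordinates = TRUE)`.
#' @param rich optional character vector of rich-node labels: rich nodes get
#'   color code `nlevels(module) + 1`.
#' @return Invisibly, the two file paths.
#' @export
write_brainnet <- function(g, prefix, atlas = aal90_atlas(with_coordinates = TRUE),
                           rich = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  labels <- colnames(g$adjacency)
  if (!all(labels %in% atlas$roi_label)) {
    pn_stop("graph labels missing from the atlas table",
            "presbynet_alignment_error")
  }
  atlas <- atlas[match(labels, atlas$roi_label), ]
  color <- as.integer(factor(atlas$module))
  if (!is.null(rich)) color[labels %in% rich] <- max(color) + 1L
  node <- data.frame(x = atlas$x, y = atlas$y, z = atlas$z,
                     color = color, size = colSums(g$adjacency),
                     label = labels)
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  write.table(node, node_path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(g$adjacency, edge_path, sep = " ", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(c(node_path, edge_path))
}

#' Configure an end-to-end pipeline run
#'
#' Consolidates every stage's parameters: either a synthetic-cohort
#' configuration or a data directory, preprocessing settings, the sparsity
#' grid, null-ensemble size, rich-club fraction and significance level.
#'
#' @param cohort a [cohort_config()] for a synthetic run, or `NULL`.
#' @param data_dir directory of an on-disk cohort (used when `cohort` is
#'   `NULL`).
#' @param n_discard initial volumes to discard (default 10).
#' @param trans_limit_mm,rot_limit_deg motion exclusion limits (2.0 / 2.0).
#' @param low_hz,high_hz bandpass edges (0.01 / 0.08 Hz).
#' @param grid sparsity grid (default [sparsity_grid()]: 0.06..0.40 by 0.01).
#' @param shrinkage diagonal loading passed to
#'   [partial_correlation_matrix()] (default 1.0, i.e. loading equal to the
#'   mean diagonal). Bandpass filtering leaves fewer independent frequency
#'   components than regions, so the post-filter covariance is rank-deficient
#'   and unregularized precision-matrix partial correlation is undefined;
#'   heavy loading both restores conditioning and substantially stabilizes
#'   the edge-weight *ranking* that binarization uses (the null
#'   partial-correlation spread drops from about 0.088 to 0.031 at
#'   T = 220, N = 90).
#' @param n_null null networks per graph for gamma/lambda/sigma (default 100).
#' @param rich_fraction rich-club fraction (default 0.12).
#' @param alpha significance level (default 0.05).
#' @param nodal compute nodal metric profiles and statistics? (default TRUE)
#' @param seed mandatory integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, data_dir = NULL, n_discard = 10L,
                            trans_limit_mm = 2.0, rot_limit_deg = 2.0,
                            low_hz = 0.01, high_hz = 0.08,
                            grid = sparsity_grid(), shrinkage = 1.0,
                            n_null = 100L,
                            rich_fraction = 0.12, alpha = 0.05,
                            nodal = TRUE, seed) {
  if (missing(seed) || !is_count(seed)) {
    pn_stop("pipeline_config() requires an integer seed",
            "presbynet_config_error")
  }
  if (is.null(cohort) && is.null(data_dir)) {
    pn_stop("provide either a cohort_config or a data_dir",
            "presbynet_config_error")
  }
  structure(list(cohort = cohort, data_dir = data_dir,
                 n_discard = as.integer(n_discard),
                 trans_limit_mm = trans_limit_mm,
                 rot_limit_deg = rot_limit_deg,
                 low_hz = low_hz, high_hz = high_hz, grid = grid,
                 shrinkage = shrinkage,
                 n_null = as.integer(n_null),
                 rich_fraction = rich_fraction, alpha = alpha,
                 nodal = isTRUE(nodal), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Synthetic generation (or cohort loading), per-subject preprocessing with
#' motion screening, partial-correlation network construction over the
#' sparsity grid, global and (optionally) nodal metric profiles with AUCs,
#' modular connection strengths, per-group rich-club classification, and the
#' three-group covariate-adjusted statistics on every AUC summary. Fully
#' deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_report`: list with elements `roster`
#'   (with inclusion flags), `global_auc` (subjects x metrics data.frame),
#'   `global_profiles`, `nodal` (profiles + statistics, when enabled),
#'   `modular`, `richclub`, `stats` (group-comparison reports), `log`
#'   (character vector of stage records) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # --- stage 1: cohort ------------------------------------------------------
  cohort <- if (!is.null(config$cohort)) {
    note("cohort: synthetic, seed %d", config$cohort$seed)
    generate_cohort(config$cohort)
  } else {
    note("cohort: loaded from %s", config$data_dir)
    read_cohort(config$data_dir)
  }
  roster <- cohort$roster
  n_subj <- nrow(roster)

  # --- stage 2: preprocessing ----------------------------------------------
  clean <- list()
  included <- logical(n_subj)
  for (i in seq_len(n_subj)) {
    sid <- roster$subject_id[i]
    pre <- preprocess_timeseries(
      cohort$timeseries[[sid]], motion = cohort$motion[[sid]],
      n_discard = config$n_discard,
      trans_limit_mm = config$trans_limit_mm,
      rot_limit_deg = config$rot_limit_deg,
      low_hz = config$low_hz, high_hz = config$high_hz)
    included[i] <- pre$included
    if (pre$included) {
      clean[[sid]] <- pre$ts
    } else {
      note("preprocess: excluded %s (%s = %.2f at t=%d)", sid,
           pre$screen$offending_column, pre$screen$offending_value,
           pre$screen$offending_time)
    }
  }
  roster$included <- included
  if (!any(included)) {
    pn_stop("every subject was excluded by motion screening: empty cohort",
            "presbynet_empty_cohort_error")
  }
  note("preprocess: %d/%d subjects retained", sum(included), n_subj)
  kept <- roster[roster$included, , drop = FALSE]

  # --- stage 3: network construction ---------------------------------------
  series <- lapply(clean, function(ts) {
    build_threshold_series(
      partial_correlation_matrix(ts, shrinkage = config$shrinkage),
      config$grid)
  })
  note("networks: %d graphs per subject over sparsity %.2f..%.2f",
       length(config$grid), min(config$grid), max(config$grid))

  # --- stage 4: global metrics ---------------------------------------------
  mseeds <- spawn_seeds(config$seed, length(series))
  global_profiles <- lapply(seq_along(series), function(i) {
    global_metrics_over_grid(series[[i]], n_null = config$n_null,
                             seed = mseeds[i])
  })
  names(global_profiles) <- names(series)
  global_auc <- cbind(
    kept[, c("subject_id", "group"), drop = FALSE],
    do.call(rbind, lapply(global_profiles, function(p) as.data.frame(t(p$auc)))))
  rownames(global_auc) <- NULL

  # --- stage 5: modularity --------------------------------------------------
  part <- module_partition()
  modular <- NULL
  if (all(series[[1]]$roi_labels %in% names(part))) {
    modular <- lapply(series, modular_connection_strengths, partition = part)
  } else {
    note("modularity: skipped (node labels not covered by the default atlas)")
  }

  # --- stage 6: rich club ---------------------------------------------------
  groups <- unique(kept$group)
  rich_by_group <- list()
  class_tab <- NULL
  for (g in groups) {
    ids <- kept$subject_id[kept$group == g]
    avg_deg <- group_average_degree(series[ids])
    rich_by_group[[g]] <- select_rich_nodes(avg_deg, config$rich_fraction)
    ct <- class_strengths(series[ids], rich_by_group[[g]])
    ct$group <- g
    class_tab <- rbind(class_tab, ct)
  }
  note("rich club: %d nodes per group at fraction %.2f",
       length(rich_by_group[[1]]), config$rich_fraction)

  # --- stage 7: statistics --------------------------------------------------
  covars <- intersect(c("age", "sex", "education_years"), names(kept))
  add_covars <- function(tab) {
    cbind(tab, merge_covars(tab, kept, covars))
  }
  stats <- list()
  if (length(groups) >= 2 && all(table(kept$group) >= 3)) {
    stats$global <- compare_groups(
      add_covars(global_auc),
      metrics = c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma"),
      covariates = covars, alpha = config$alpha)
    if (!is.null(modular)) {
      mod_tab <- modular_auc_table(modular, kept)
      stats$modular <- compare_groups(
        add_covars(mod_tab),
        metrics = setdiff(names(mod_tab), c("subject_id", "group")),
        covariates = covars, alpha = config$alpha)
    }
    rc_tab <- merge(class_tab[, c("subject_id", "rich", "feeder", "local")],
                    kept[, c("subject_id", "group")], by = "subject_id")
    stats$richclub <- compare_groups(
      add_covars(rc_tab), metrics = c("rich", "feeder", "local"),
      covariates = covars, alpha = config$alpha)
  } else {
    note("stats: skipped (need >= 2 groups with >= 3 subjects)")
  }

  # --- nodal metrics (optional) --------------------------------------------
  nodal <- NULL
  if (config$nodal) {
    nodal_profiles <- lapply(series, nodal_metrics_over_grid)
    nodal <- list(profiles = nodal_profiles)
    if (length(groups) >= 2 && all(table(kept$group) >= 3)) {
      nodal$stats <- nodal_group_stats(nodal_profiles, kept,
                                       alpha = config$alpha)
    }
  }

  structure(list(roster = roster, global_auc = global_auc,
                 global_profiles = global_profiles, modular = modular,
                 richclub = list(rich_nodes = rich_by_group,
                                 class_strengths = class_tab),
                 nodal = nodal, stats = stats, log = log, config = config),
            class = "run_report")
}

#' @noRd
merge_covars <- function(tab, kept, covars) {
  kept[match(tab$subject_id, kept$subject_id), covars, drop = FALSE]
}

# Per-subject module-strength AUC-style table (mean over grid already taken
# by modular_connection_strengths).
#' @noRd
modular_auc_table <- function(modular, kept) {
  rows <- lapply(names(modular), function(sid) {
    m <- modular[[sid]]
    vals <- c(setNames(m$intra_strength,
                       paste0("intra_", names(m$intra_strength))),
              setNames(m$inter_strength,
                       paste0("inter_", names(m$inter_strength))))
    cbind(data.frame(subject_id = sid,
                     group = kept$group[kept$subject_id == sid],
                     stringsAsFactors = FALSE),
          as.data.frame(t(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Omnibus + Bonferroni (m = number of nodes) per nodal metric.
#' @noRd
nodal_group_stats <- function(nodal_profiles, kept, alpha = 0.05) {
  metrics <- c("bc", "dc", "ne", "nle")
  ids <- names(nodal_profiles)
  grp <- kept$group[match(ids, kept$subject_id)]
  out <- list()
  for (mm in metrics) {
    auc <- vapply(nodal_profiles, function(p) p$auc[, mm],
                  numeric(nrow(nodal_profiles[[1]]$auc)))
    # auc: nodes x subjects
    p_raw <- apply(auc, 1, function(v) omnibus_compare(v, grp)$p)
    adj <- bonferroni_adjust(p_raw, alpha = alpha, m = nrow(auc))
    out[[mm]] <- data.frame(node = rownames(auc), adj,
                            stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d subjects (%d retained), %d sparsity levels\n",
              nrow(x$roster), sum(x$roster$included), length(x$config$grid)))
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Tidy CSV tables (global per-sparsity metrics, global AUCs, modular
#' strengths, rich-club membership and class strengths, nodal AUCs and
#' statistics when present) plus a JSON summary of the statistical reports
#' and the run log.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$roster, file.path(dir, "roster.csv"), row.names = FALSE)
  write.csv(report$global_auc, file.path(dir, "global_auc.csv"),
            row.names = FALSE)
  curves <- do.call(rbind, lapply(names(report$global_profiles), function(sid) {
    cbind(subject_id = sid, report$global_profiles[[sid]]$metrics)
  }))
  write.csv(curves, file.path(dir, "global_metrics_by_sparsity.csv"),
            row.names = FALSE)
  rc <- report$richclub
  rc_rows <- do.call(rbind, lapply(names(rc$rich_nodes), function(g) {
    data.frame(group = g, rank = seq_along(rc$rich_nodes[[g]]),
               roi_label = rc$rich_nodes[[g]], stringsAsFactors = FALSE)
  }))
  write.csv(rc_rows, file.path(dir, "rich_club_nodes.csv"), row.names = FALSE)
  write.csv(rc$class_strengths, file.path(dir, "edge_class_strengths.csv"),
            row.names = FALSE)
  stats_json <- lapply(report$stats, function(s) {
    list(omnibus = s$omnibus, posthoc = s$posthoc,
         alpha = s$alpha, family_size = s$family_size,
         covariates = s$covariates)
  })
  jsonlite::write_json(
    list(log = report$log, seed = report$config$seed, stats = stats_json),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", null = "null")
  invisible(dir)
}
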