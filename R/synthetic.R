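## Synthetic-cohort generator: planted modular small-world covariance,
## multivariate-normal ROI time series, head-motion traces, and a roster with
## demographics matched to the three-group presbycusis study design
## (PCD = presbycusis with cognitive decline, PNCD = without, HC = controls).

# Default per-group demographic distributions (mean, sd) and exact M/F counts.
# Age is truncated at 60 y (study inclusion), education at 8 y; MoCA is an
# integer score truncated at the 26-point cognitive-decline boundary per
# group; pure-tone averages are truncated so the better ear is > 25 dB HL in
# patients and <= 25 dB HL in controls.
default_demographics <- function() {
  list(
    PCD  = list(n = 30, age = c(63.03, 7.30), education = c(10.40, 2.18),
                pta_left = c(33.08, 3.79), pta_right = c(33.16, 6.66),
                moca = c(24.57, 0.77), sex_mf = c(14, 16)),
    PNCD = list(n = 30, age = c(62.47, 7.12), education = c(11.47, 1.72),
                pta_left = c(33.11, 5.00), pta_right = c(33.52, 5.28),
                moca = c(26.63, 0.72), sex_mf = c(12, 18)),
    HC   = list(n = 50, age = c(61.08, 3.93), education = c(10.78, 1.79),
                pta_left = c(17.93, 5.84), pta_right = c(17.40, 5.19),
                moca = c(26.74, 1.23), sex_mf = c(24, 26))
  )
}

#' Specify a planted modular covariance structure
#'
#' Describes a block-structured correlation matrix over `n_nodes` regions:
#' every within-module pair of regions has correlation `within_module_corr`,
#' every between-module pair `between_module_corr`, and an optional set of
#' hub regions has its correlation to all other regions raised to `hub_corr`
#' (hub pairs end up even more strongly coupled, mimicking a rich club).
#'
#' @param n_nodes number of regions (default 90).
#' @param partition integer/factor of length `n_nodes` mapping each node to a
#'   module; default is the six-lobe AAL90 partition when `n_nodes == 90`,
#'   otherwise up to six contiguous equal blocks.
#' @param within_module_corr,between_module_corr correlations in `[0, 1)`,
#'   with `within_module_corr >= between_module_corr`.
#' @param hub_nodes integer indices of hub regions (may be empty). Default
#'   for the 90-node spec is ten regions spread evenly over the atlas.
#' @param hub_boost multiplier (>= 1) on the between-module correlation for
#'   pairs involving a hub: a hub's correlation to a region in another module
#'   is `hub_boost * between_module_corr` (default 2), and hub-hub pairs are
#'   boosted quadratically, mimicking a rich club.
#' @param noise_sd marginal standard deviation of every region's signal.
#' @return An object of class `covariance_spec`.
#' @seealso [plant_covariance()]
#' @export
covariance_spec <- function(n_nodes = 90,
                            partition = NULL,
                            within_module_corr = 0.5,
                            between_module_corr = 0.1,
                            hub_nodes = if (n_nodes == 90) seq(1L, 82L, by = 9L) else integer(0),
                            hub_boost = 2,
                            noise_sd = 1) {
  if (!is_count(n_nodes) || n_nodes < 2) {
    pn_stop("n_nodes must be an integer >= 2", "presbynet_config_error")
  }
  n_nodes <- as.integer(n_nodes)
  if (is.null(partition)) {
    partition <- if (n_nodes == 90) {
      as.integer(module_partition())
    } else {
      as.integer(cut(seq_len(n_nodes), breaks = min(6L, n_nodes), labels = FALSE))
    }
  }
  partition <- as.integer(as.factor(partition))
  if (length(partition) != n_nodes) {
    pn_stop("partition length must equal n_nodes", "presbynet_shape_error")
  }
  stopifnot_scalar_prob(within_module_corr, "within_module_corr",
                        open0 = FALSE, closed1 = FALSE)
  stopifnot_scalar_prob(between_module_corr, "between_module_corr",
                        open0 = FALSE, closed1 = FALSE)
  if (within_module_corr < between_module_corr) {
    pn_stop("within_module_corr must be >= between_module_corr",
            "presbynet_config_error")
  }
  hub_nodes <- sort(unique(as.integer(hub_nodes)))
  if (length(hub_nodes) &&
      (min(hub_nodes) < 1 || max(hub_nodes) > n_nodes)) {
    pn_stop("hub_nodes out of range", "presbynet_config_error")
  }
  if (length(hub_nodes)) {
    if (between_module_corr <= 0) {
      pn_stop("hub enrichment requires between_module_corr > 0",
              "presbynet_config_error")
    }
    if (!is.numeric(hub_boost) || length(hub_boost) != 1L || hub_boost < 1) {
      pn_stop("hub_boost must be a single multiplier >= 1",
              "presbynet_config_error")
    }
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    pn_stop("noise_sd must be a single positive number",
            "presbynet_config_error")
  }
  structure(list(n_nodes = n_nodes, partition = partition,
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 hub_nodes = hub_nodes, hub_boost = hub_boost,
                 noise_sd = noise_sd),
            class = "covariance_spec")
}

#' Realize the covariance matrix implied by a covariance spec
#'
#' The matrix is assembled from a latent-factor representation: every region
#' loads `sqrt(between)` on a shared global factor (hubs load
#' `hub_boost * sqrt(between)`, raising their cross-module correlation to
#' `hub_boost * between`) and
#' `sqrt(within - between)` on its module factor, with unique variance
#' topping each region up to `noise_sd^2`. With no hubs this reproduces the
#' exact block-constant matrix (within-module entries `within_module_corr`,
#' between-module entries `between_module_corr`) and is positive definite by
#' construction; definiteness is still verified by eigendecomposition.
#'
#' @param spec a [covariance_spec()].
#' @return N x N symmetric positive-definite covariance matrix.
#' @export
plant_covariance <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  n <- spec$n_nodes
  b <- spec$between_module_corr
  w <- spec$within_module_corr - b
  g_load <- rep(sqrt(b), n)
  if (length(spec$hub_nodes) && spec$hub_boost > 1) {
    # hub-to-nonhub cross-module correlation = g_hub * sqrt(b) = hub_boost * b
    g_load[spec$hub_nodes] <- spec$hub_boost * sqrt(b)
  }
  sigma <- outer(g_load, g_load)
  same_module <- outer(spec$partition, spec$partition, "==")
  sigma[same_module] <- sigma[same_module] + w
  diag(sigma) <- 1
  uniq <- 1 - (g_load^2 + w)
  if (any(uniq <= 0)) {
    pn_stop(paste0("hub loadings leave no unique variance ",
                   "(lower hub_corr or within_module_corr)"),
            "presbynet_definiteness_error")
  }
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-10) {
    pn_stop(sprintf(
      "planted covariance is not positive definite (smallest eigenvalue %.3e)",
      ev_min), "presbynet_definiteness_error", smallest_eigenvalue = ev_min)
  }
  sigma * spec$noise_sd^2
}

#' Sample a multivariate-normal ROI time series
#'
#' Draws `n_timepoints` independent zero-mean Gaussian observations with the
#' given covariance. Reproducible: the same `seed` yields a bit-identical
#' series; the global RNG state is left untouched.
#'
#' @param cov positive-definite N x N covariance matrix.
#' @param n_timepoints number of rows to sample (>= 2).
#' @param seed integer seed for the private RNG stream.
#' @param tr_s repetition time in seconds attached to the result.
#' @param roi_labels optional column labels (defaults to `cov`'s dimnames or
#'   generated names).
#' @return An [roi_timeseries()].
#' @export
generate_timeseries <- function(cov, n_timepoints, seed, tr_s = 2,
                                roi_labels = NULL) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) {
    pn_stop("covariance matrix must be square", "presbynet_shape_error")
  }
  if (!is_count(n_timepoints) || n_timepoints < 2) {
    pn_stop("n_timepoints must be an integer >= 2", "presbynet_config_error")
  }
  R <- tryCatch(chol(cov), error = function(e) {
    pn_stop("covariance matrix is not positive definite",
            "presbynet_definiteness_error")
  })
  n <- ncol(cov)
  z <- with_seed(seed, matrix(rnorm(n_timepoints * n), nrow = n_timepoints))
  x <- z %*% R
  labels <- roi_labels %||% colnames(cov) %||%
    if (n == 90) aal90_labels() else sprintf("ROI%03d", seq_len(n))
  roi_timeseries(x, tr_s = tr_s, roi_labels = labels)
}

#' Simulate a six-parameter head-motion trace
#'
#' Produces a T x 6 table (3 translations in mm, 3 rotations in degrees) as
#' slow random walks. With `exceeds_threshold = FALSE` every entry stays
#' strictly below the 2.0 mm / 2.0 degree exclusion limits; with
#' `exceeds_threshold = TRUE` one translation excursion beyond 2.0 mm is
#' planted so the subject is flagged by [screen_head_motion()].
#'
#' @param n_timepoints number of rows (>= 1).
#' @param exceeds_threshold plant an above-limit excursion?
#' @param seed integer seed.
#' @return A `motion_trace`: numeric matrix with columns
#'   `trans_x,trans_y,trans_z,rot_x,rot_y,rot_z`.
#' @export
generate_motion_trace <- function(n_timepoints, exceeds_threshold = FALSE,
                                  seed = 1L) {
  if (!is_count(n_timepoints) || n_timepoints < 1) {
    pn_stop("n_timepoints must be a positive integer", "presbynet_config_error")
  }
  vals <- with_seed(seed, {
    walk <- apply(matrix(rnorm(n_timepoints * 6, sd = 0.02),
                         nrow = n_timepoints), 2, cumsum)
    walk <- matrix(walk, nrow = n_timepoints)
    # keep well inside the 2.0 mm / 2.0 deg limits
    peak <- apply(abs(walk), 2, max)
    scale <- ifelse(peak > 1.0, 1.0 / peak, 1)
    walk <- sweep(walk, 2, scale, "*")
    if (exceeds_threshold) {
      # plant the excursion in the second half of the run so it is still
      # present after the initial volumes are discarded
      lo <- max(1L, ceiling(n_timepoints / 2))
      t_hit <- if (lo < n_timepoints) sample(lo:n_timepoints, 1) else lo
      walk[t_hit, 1] <- 2.5 * sign(walk[t_hit, 1] + 1e-12)
    }
    walk
  })
  colnames(vals) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
  structure(vals, class = c("motion_trace", class(vals)))
}

#' Specify a planted conditional-dependence (partial-correlation) structure
#'
#' Unlike [covariance_spec()], which plants structure in the *marginal*
#' correlations, this spec plants the network directly in the conditional
#' domain that the pipeline estimates: it describes a Gaussian graphical
#' model whose precision matrix encodes (1) a short-range "lattice" of
#' graded partial correlations along a ring ordered by module (so the
#' lattice is intrinsically modular: nearby nodes share a module), giving
#' high clustering and segregated modules, and (2) a set of hub regions with
#' long-range shortcut connections that shorten paths and form a rich club.
#' Structure planted in marginal correlations is largely explained away by
#' conditioning and is therefore invisible to a partial-correlation
#' pipeline; this conditional design is recoverable by construction.
#'
#' @param n_nodes number of regions (default 90).
#' @param partition node-to-module map as in [covariance_spec()].
#' @param lattice_strength peak short-range partial correlation between ring
#'   neighbours (default 0.09).
#' @param lattice_decay e-folding distance (ring steps) of the short-range
#'   kernel (default 2.5).
#' @param lattice_radius maximum ring distance carrying lattice weight
#'   (default 8).
#' @param n_hubs number of hub regions, spread evenly around the ring
#'   (default 10).
#' @param shortcut_strength partial correlation of each hub's long-range
#'   shortcuts (default 0.07).
#' @param n_shortcuts long-range shortcuts per hub (default 12).
#' @param noise_sd marginal standard deviation of every region's signal.
#' @return An object of class `conditional_spec`.
#' @seealso [plant_conditional_covariance()]
#' @export
conditional_spec <- function(n_nodes = 90,
                             partition = NULL,
                             lattice_strength = 0.09,
                             lattice_decay = 2.5,
                             lattice_radius = 8,
                             n_hubs = 10,
                             shortcut_strength = 0.07,
                             n_shortcuts = 12,
                             noise_sd = 1) {
  if (!is_count(n_nodes) || n_nodes < 6) {
    pn_stop("n_nodes must be an integer >= 6", "presbynet_config_error")
  }
  n_nodes <- as.integer(n_nodes)
  if (is.null(partition)) {
    partition <- if (n_nodes == 90) {
      as.integer(module_partition())
    } else {
      as.integer(cut(seq_len(n_nodes), breaks = min(6L, n_nodes),
                     labels = FALSE))
    }
  }
  partition <- as.integer(as.factor(partition))
  if (length(partition) != n_nodes) {
    pn_stop("partition length must equal n_nodes", "presbynet_shape_error")
  }
  for (nm in c("lattice_strength", "lattice_decay", "shortcut_strength",
               "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      pn_stop(sprintf("`%s` must be a single positive number", nm),
              "presbynet_config_error")
    }
  }
  if (!is_count(lattice_radius) || !is_count(n_hubs) ||
      !is_count(n_shortcuts) || n_hubs > n_nodes) {
    pn_stop("lattice_radius, n_hubs and n_shortcuts must be valid counts",
            "presbynet_config_error")
  }
  # deterministic ring order: nodes sorted by module, hubs spread evenly
  ring_order <- order(partition, seq_len(n_nodes))
  hub_nodes <- if (n_hubs > 0) {
    sort(ring_order[unique(round(seq(1, n_nodes,
                                     length.out = n_hubs + 1)))[seq_len(n_hubs)]])
  } else integer(0)
  structure(list(n_nodes = n_nodes, partition = partition,
                 lattice_strength = lattice_strength,
                 lattice_decay = lattice_decay,
                 lattice_radius = as.integer(lattice_radius),
                 hub_nodes = hub_nodes,
                 shortcut_strength = shortcut_strength,
                 n_shortcuts = as.integer(n_shortcuts),
                 ring_order = ring_order,
                 noise_sd = noise_sd),
            class = "conditional_spec")
}

#' Realize the covariance implied by a conditional spec
#'
#' Builds the precision matrix `P = I - W`, where `W` holds the planted
#' partial correlations (short-range lattice plus hub shortcuts), verifies
#' positive definiteness, and returns the corresponding correlation-scaled
#' covariance. Group effects enter as multiplicative scales: `within_scale`
#' on the short-range (predominantly within-module) lattice weights and
#' `between_scale` on the long-range hub shortcuts. Values of
#' `within_scale > 1` with `between_scale < 1` yield more segregated, less
#' integrated networks — higher clustering, longer characteristic path
#' length, lower global efficiency — the profile reported for patients.
#'
#' @param spec a [conditional_spec()].
#' @param within_scale multiplier on short-range lattice weights (default 1).
#' @param between_scale multiplier on hub shortcut weights (default 1).
#' @param hub_nodes optional override of the hub set.
#' @return N x N positive-definite covariance matrix (unit diagonal scaled
#'   by `noise_sd^2`).
#' @export
plant_conditional_covariance <- function(spec, within_scale = 1,
                                         between_scale = 1,
                                         hub_nodes = NULL) {
  stopifnot(inherits(spec, "conditional_spec"))
  if (within_scale <= 0 || between_scale < 0) {
    pn_stop("scales must be positive (between_scale may be 0)",
            "presbynet_config_error")
  }
  n <- spec$n_nodes
  pos <- match(seq_len(n), spec$ring_order)
  dd <- abs(outer(pos, pos, "-"))
  dd <- pmin(dd, n - dd)
  W <- spec$lattice_strength * within_scale *
    exp(-(dd - 1) / spec$lattice_decay) *
    (dd >= 1 & dd <= spec$lattice_radius)
  hubs <- hub_nodes %||% spec$hub_nodes
  if (length(hubs)) {
    if (min(hubs) < 1 || max(hubs) > n) {
      pn_stop("hub_nodes out of range", "presbynet_config_error")
    }
    for (hi in seq_along(hubs)) {
      h <- hubs[hi]; ph <- pos[h]
      for (j in seq_len(spec$n_shortcuts)) {
        pt <- ((ph - 1 + round(j * n / (spec$n_shortcuts + 1))) %% n) + 1
        t1 <- spec$ring_order[pt]
        if (t1 != h && dd[h, t1] > spec$lattice_radius) {
          W[h, t1] <- W[t1, h] <- spec$shortcut_strength * between_scale
        }
      }
    }
  }
  lam <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  if (lam >= 0.95) {
    pn_stop(sprintf(
      "planted precision I - W is near-singular (largest eigenvalue of W = %.3f); lower the planted strengths",
      lam), "presbynet_definiteness_error", largest_w_eigenvalue = lam)
  }
  prec <- diag(n) - W
  sigma <- stats::cov2cor(chol2inv(chol(prec)))
  sigma * spec$noise_sd^2
}

#' Configure a synthetic cohort
#'
#' Collects everything [generate_cohort()] needs: group sizes, acquisition
#' length and TR, the base planted structure, per-group effects, demographic
#' distributions and the mandatory seed. `base_spec` may be a
#' [conditional_spec()] (the default: structure planted in the partial
#' correlations the pipeline estimates) or a [covariance_spec()]
#' (block-constant marginal correlations). Group effects are multiplicative:
#' `within_scale` strengthens short-range/within-module coupling and
#' `between_scale` weakens long-range/between-module coupling; patient
#' defaults (`PCD` within 1.25 / between 0.6, `PNCD` within 1.10 /
#' between 0.8) plant the increased-segregation profile — higher Cp and Lp,
#' lower Eglob — in moderate strength. Optional per-group `hub_nodes` model
#' rich-club reorganization.
#'
#' @param group_sizes named integer vector (default `c(PCD=30, PNCD=30, HC=50)`).
#' @param n_timepoints_acquired volumes acquired per subject (default 230;
#'   the first 10 are discarded during preprocessing, leaving 220).
#' @param tr_s repetition time, seconds.
#' @param base_spec a [conditional_spec()] (default) or [covariance_spec()]
#'   describing the control-group structure.
#' @param group_effect named list; each element a list with any of
#'   `within_scale`, `between_scale` (positive scalars) and `hub_nodes`
#'   (integer indices). For a [covariance_spec()] base, only `between_scale`
#'   (on the marginal between-module correlation) and `hub_nodes` apply.
#' @param demographics named list of per-group distributions; see
#'   `default_demographics` in the package source for the expected shape.
#' @param motion_exceed_fraction fraction of subjects per group whose motion
#'   trace is planted above the exclusion limits (default 0).
#' @param seed mandatory integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(PCD = 30L, PNCD = 30L, HC = 50L),
                          n_timepoints_acquired = 230L,
                          tr_s = 2,
                          base_spec = conditional_spec(),
                          group_effect = list(
                            PCD = list(within_scale = 1.25, between_scale = 0.6),
                            PNCD = list(within_scale = 1.10, between_scale = 0.8),
                            HC = list(within_scale = 1.00, between_scale = 1.0)),
                          demographics = default_demographics(),
                          motion_exceed_fraction = 0,
                          seed) {
  if (missing(seed) || !is_count(seed)) {
    pn_stop("cohort_config() requires an integer seed", "presbynet_config_error")
  }
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    pn_stop("group_sizes must be a named vector", "presbynet_config_error")
  }
  if (any(group_sizes < 2)) {
    pn_stop("all group sizes must be >= 2", "presbynet_config_error")
  }
  n_discard_default <- 10L
  if (!is_count(n_timepoints_acquired) ||
      n_timepoints_acquired <= n_discard_default) {
    pn_stop("n_timepoints_acquired must exceed the number of discarded volumes",
            "presbynet_config_error")
  }
  if (!inherits(base_spec, "conditional_spec") &&
      !inherits(base_spec, "covariance_spec")) {
    pn_stop("base_spec must be a conditional_spec or covariance_spec",
            "presbynet_config_error")
  }
  for (g in names(group_sizes)) {
    if (is.null(group_effect[[g]])) group_effect[[g]] <- list()
    for (sc in c("within_scale", "between_scale")) {
      v <- group_effect[[g]][[sc]] %||% 1.0
      if (!is.numeric(v) || length(v) != 1L || v <= 0) {
        pn_stop(sprintf("group_effect$%s$%s must be > 0", g, sc),
                "presbynet_config_error")
      }
      group_effect[[g]][[sc]] <- v
    }
    if (is.null(demographics[[g]])) {
      pn_stop(sprintf("no demographics configured for group %s", g),
              "presbynet_config_error")
    }
  }
  structure(list(group_sizes = setNames(as.integer(group_sizes),
                                        names(group_sizes)),
                 n_timepoints_acquired = as.integer(n_timepoints_acquired),
                 tr_s = tr_s, base_spec = base_spec,
                 group_effect = group_effect, demographics = demographics,
                 motion_exceed_fraction = motion_exceed_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Vectorized rejection sampler for a truncated normal.
#' @noRd
rtruncnorm_rej <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) {
      pn_stop("truncated-normal rejection sampling failed to converge",
              "presbynet_config_error")
    }
  }
  out
}

#' @noRd
sample_group_demographics <- function(group, n, dem) {
  is_patient <- group %in% c("PCD", "PNCD")
  age <- rtruncnorm_rej(n, dem$age[1], dem$age[2], lower = 60)
  edu <- rtruncnorm_rej(n, dem$education[1], dem$education[2], lower = 8)
  pta_l <- numeric(n); pta_r <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      l <- rnorm(1, dem$pta_left[1], dem$pta_left[2])
      r <- rnorm(1, dem$pta_right[1], dem$pta_right[2])
      better <- min(l, r)
      ok <- if (is_patient) better > 25 else better <= 25 && better > 0
      if (ok) { pta_l[i] <- l; pta_r[i] <- r; break }
    }
  }
  moca_bounds <- if (group == "PCD") c(0, 25) else c(26, 30)
  moca <- round(rtruncnorm_rej(n, dem$moca[1], dem$moca[2],
                               lower = moca_bounds[1] - 0.49,
                               upper = moca_bounds[2] + 0.49))
  moca <- pmin(pmax(moca, moca_bounds[1]), moca_bounds[2])
  # exact M/F counts, order shuffled
  counts <- round(dem$sex_mf / sum(dem$sex_mf) * n)
  n_m <- min(counts[1], n)
  sex <- sample(c(rep("M", n_m), rep("F", n - n_m)))
  data.frame(age = round(age, 1), sex = sex,
             education_years = round(edu, 1),
             pta_left = round(pta_l, 1), pta_right = round(pta_r, 1),
             moca = as.integer(moca), stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' For every subject, draws demographics from the configured per-group
#' distributions, plants the group-specific covariance (between-module
#' scaling and optional hub reassignment applied to the base spec), samples
#' the ROI time series and a paired head-motion trace. The whole cohort is a
#' deterministic function of `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `roster`
#'   (data.frame: `subject_id, group, age, sex, education_years, pta_left,
#'   pta_right, moca`), `timeseries` (named list of [roi_timeseries()]),
#'   `motion` (named list of motion traces) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   group_sizes = c(PCD = 2, PNCD = 2, HC = 2),
#'   base_spec = covariance_spec(n_nodes = 20, hub_nodes = integer(0)),
#'   seed = 7))
#' nrow(coh$roster)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_sizes)
  n_total <- sum(config$group_sizes)
  seeds <- spawn_seeds(config$seed, 2L * n_total + length(groups))
  # per-group covariance
  cov_by_group <- list()
  for (g in groups) {
    eff <- config$group_effect[[g]]
    cov_by_group[[g]] <- if (inherits(config$base_spec, "conditional_spec")) {
      plant_conditional_covariance(config$base_spec,
                                   within_scale = eff$within_scale,
                                   between_scale = eff$between_scale,
                                   hub_nodes = eff$hub_nodes)
    } else {
      spec <- config$base_spec
      spec$between_module_corr <- spec$between_module_corr * eff$between_scale
      if (spec$between_module_corr > spec$within_module_corr) {
        pn_stop(sprintf(
          "group %s: scaled between-module correlation exceeds within", g),
          "presbynet_config_error")
      }
      if (!is.null(eff$hub_nodes)) {
        spec$hub_nodes <- sort(as.integer(eff$hub_nodes))
      }
      plant_covariance(spec)
    }
  }
  roster <- NULL
  timeseries <- list(); motion <- list()
  idx <- 0L
  demo_seeds <- utils::tail(seeds, length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_g <- config$group_sizes[[g]]
    dem <- with_seed(demo_seeds[gi],
                     sample_group_demographics(g, n_g, config$demographics[[g]]))
    n_exceed <- floor(config$motion_exceed_fraction * n_g)
    for (i in seq_len(n_g)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      timeseries[[sid]] <- generate_timeseries(
        cov_by_group[[g]], config$n_timepoints_acquired,
        seed = seeds[idx], tr_s = config$tr_s)
      motion[[sid]] <- generate_motion_trace(
        config$n_timepoints_acquired,
        exceeds_threshold = i <= n_exceed,
        seed = seeds[n_total + idx])
      roster <- rbind(roster, cbind(
        data.frame(subject_id = sid, group = g, stringsAsFactors = FALSE),
        dem[i, , drop = FALSE]))
    }
  }
  rownames(roster) <- NULL
  structure(list(roster = roster, timeseries = timeseries, motion = motion,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), T = %d, TR = %g s\n",
              nrow(x$roster),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = "/"),
              x$config$n_timepoints_acquired, x$config$tr_s))
  invisible(x)
}

#' Write a cohort to disk in plain-text formats
#'
#' Writes `roster.csv`, one `<subject_id>.tsv` time-series table (rows = time
#' points, columns = ROI labels), one `<subject_id>_motion.tsv` 6-column
#' table per subject, and the configuration (including the seed) as
#' `config.yaml`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$roster, file.path(dir, "roster.csv"),
            row.names = FALSE, quote = FALSE)
  for (sid in names(cohort$timeseries)) {
    write_timeseries(cohort$timeseries[[sid]],
                     file.path(dir, paste0(sid, ".tsv")))
    write.table(cohort$motion[[sid]],
                file.path(dir, paste0(sid, "_motion.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cfg <- cohort$config
  spec_fields <- cfg$base_spec[setdiff(names(cfg$base_spec),
                                       c("partition", "ring_order"))]
  yaml::write_yaml(list(
    group_sizes = as.list(cfg$group_sizes),
    n_timepoints_acquired = cfg$n_timepoints_acquired,
    tr_s = cfg$tr_s,
    structure = class(cfg$base_spec)[1],
    base_spec = spec_fields,
    group_effect = lapply(cfg$group_effect, function(e)
      list(within_scale = e$within_scale, between_scale = e$between_scale,
           hub_nodes = e$hub_nodes)),
    motion_exceed_fraction = cfg$motion_exceed_fraction,
    seed = cfg$seed
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
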