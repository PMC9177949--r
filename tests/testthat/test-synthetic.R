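# Synthetic-data generator: planted covariances, time-series sampling,
# motion traces and full cohorts.

test_that("block covariance is constructed exactly by definition", {
  spec <- covariance_spec(n_nodes = 6, partition = rep(1:2, each = 3),
                          within_module_corr = 0.5,
                          between_module_corr = 0.1,
                          hub_nodes = integer(0))
  S <- plant_covariance(spec)
  expect_equal(dim(S), c(6, 6))
  expect_equal(diag(S), rep(1, 6))
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[1, 4], 0.1)
  same <- outer(rep(1:2, each = 3), rep(1:2, each = 3), "==")
  expect_true(all(S[same & upper.tri(S)] == 0.5))
  expect_true(all(S[!same & upper.tri(S)] == 0.1))
})

test_that("zero correlations give the identity covariance", {
  spec <- covariance_spec(n_nodes = 8, partition = rep(1:2, each = 4),
                          within_module_corr = 0, between_module_corr = 0,
                          hub_nodes = integer(0))
  expect_equal(plant_covariance(spec), diag(8))
})

test_that("default 90-node covariance is positive definite (eigen oracle)", {
  S <- plant_covariance(covariance_spec())
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # hub rows carry more total correlation than non-hub rows
  hubs <- covariance_spec()$hub_nodes
  expect_gt(min(rowSums(S)[hubs]), max(rowSums(S)[-hubs]))
})

test_that("invalid covariance configurations are rejected", {
  expect_error(covariance_spec(within_module_corr = 0.1,
                               between_module_corr = 0.5),
               class = "presbynet_config_error")
  expect_error(covariance_spec(n_nodes = 10, hub_nodes = 11),
               class = "presbynet_config_error")
  # hub loadings that exhaust the unit variance trip the definiteness check
  spec <- covariance_spec(within_module_corr = 0.6,
                          between_module_corr = 0.3, hub_boost = 1.8)
  expect_error(plant_covariance(spec),
               class = "presbynet_definiteness_error")
})

test_that("conditional-spec covariance is PD and plants graded partials", {
  spec <- conditional_spec()
  S <- plant_conditional_covariance(spec)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(S), rep(1, 90))
  # population partial correlations: ring neighbours strongest
  P <- solve(S); d <- sqrt(diag(P)); pc <- -P / outer(d, d); diag(pc) <- 0
  ord <- spec$ring_order
  nn <- cbind(ord, ord[c(2:90, 1)])            # ring-adjacent pairs
  expect_gt(mean(pc[nn]), 3 * mean(abs(pc[upper.tri(pc)])))
  # hubs have the largest total planted coupling
  expect_gt(min(rowSums(abs(pc))[spec$hub_nodes]),
            median(rowSums(abs(pc))[-spec$hub_nodes]))
  # scales shift the within/between balance in the intended directions
  S_pat <- plant_conditional_covariance(spec, within_scale = 1.25,
                                        between_scale = 0.6)
  expect_gt(min(eigen(S_pat, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("overplanted conditional strengths trip the definiteness guard", {
  spec <- conditional_spec(lattice_strength = 0.3)
  expect_error(plant_conditional_covariance(spec, within_scale = 2),
               class = "presbynet_definiteness_error")
})

test_that("generated series are reproducible and match the planted covariance", {
  S <- plant_covariance(covariance_spec(
    n_nodes = 10, partition = rep(1:2, each = 5),
    within_module_corr = 0.5, between_module_corr = 0.1,
    hub_nodes = integer(0)))
  a <- generate_timeseries(S, 500, seed = 9)
  b <- generate_timeseries(S, 500, seed = 9)
  expect_identical(a$values, b$values)
  # Monte-Carlo convergence at T = 10000
  big <- generate_timeseries(S, 10000, seed = 10)
  expect_lt(max(abs(cov(big$values) - S)), 0.05)
  # identity covariance: off-diagonal sample correlations near zero
  iid <- generate_timeseries(diag(12), 10000, seed = 11)
  cc <- cor(iid$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  # block structure: within-block sample correlations exceed between-block
  mid <- generate_timeseries(S, 5000, seed = 12)
  cm <- cor(mid$values)
  same <- outer(rep(1:2, each = 5), rep(1:2, each = 5), "==")
  expect_gt(min(cm[same & upper.tri(cm)]), max(cm[!same & upper.tri(cm)]))
})

test_that("timeseries generation validates inputs", {
  expect_error(generate_timeseries(matrix(1, 3, 2), 10, seed = 1),
               class = "presbynet_shape_error")
  expect_error(generate_timeseries(diag(3), 1, seed = 1),
               class = "presbynet_config_error")
  expect_error(generate_timeseries(matrix(c(1, 2, 2, 1), 2), 10, seed = 1),
               class = "presbynet_definiteness_error")
})

test_that("motion traces respect the exclusion limits by construction", {
  ok <- generate_motion_trace(200, exceeds_threshold = FALSE, seed = 3)
  expect_equal(dim(ok), c(200, 6))
  expect_lt(max(abs(ok)), 2.0)
  expect_true(screen_head_motion(ok)$include)
  bad <- generate_motion_trace(200, exceeds_threshold = TRUE, seed = 3)
  expect_false(screen_head_motion(bad)$include)
  expect_identical(generate_motion_trace(50, seed = 7),
                   generate_motion_trace(50, seed = 7))
})

test_that("default cohort yields 110 subjects split 30/30/50 with valid groups", {
  coh <- generate_cohort(cohort_config(
    base_spec = conditional_spec(),
    n_timepoints_acquired = 20L,   # short series: roster checks only
    seed = 21))
  r <- coh$roster
  expect_equal(nrow(r), 110)
  expect_equal(as.vector(table(factor(r$group, c("PCD", "PNCD", "HC")))),
               c(30, 30, 50))
  expect_equal(length(coh$timeseries), 110)
  expect_equal(nrow(coh$timeseries$S001$values), 20)
  # grouping rule consistency: patients better-ear PTA > 25, PCD MoCA < 26
  expect_identical(classify_subjects(r), r$group)
  expect_true(all(r$moca[r$group == "PCD"] < 26))
  expect_true(all(r$moca[r$group != "PCD"] >= 26))
  expect_true(all(r$age >= 60), all(r$education_years >= 8))
  # sex counts match the configured M/F split exactly
  expect_equal(sum(r$sex[r$group == "PCD"] == "M"), 14)
  expect_equal(sum(r$sex[r$group == "HC"] == "M"), 24)
})

test_that("cohorts are bit-identical for a fixed seed and reject bad configs", {
  cfg <- cohort_config(group_sizes = c(PCD = 2, PNCD = 2, HC = 2),
                       n_timepoints_acquired = 30L, seed = 5)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$roster, b$roster)
  expect_identical(a$timeseries$S004$values, b$timeseries$S004$values)
  expect_identical(a$motion$S002, b$motion$S002)
  expect_error(cohort_config(group_sizes = c(PCD = 1, HC = 5), seed = 1),
               class = "presbynet_config_error")
  expect_error(cohort_config(seed = 1, n_timepoints_acquired = 5),
               class = "presbynet_config_error")
  expect_error(cohort_config(), class = "presbynet_config_error")
})

test_that("cohort round-trips through the on-disk plain-text formats", {
  coh <- generate_cohort(cohort_config(
    group_sizes = c(PCD = 2, PNCD = 2, HC = 2),
    n_timepoints_acquired = 25L, seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$seed, 13)
  back <- read_cohort(dir, expected_labels = aal90_labels())
  expect_equal(back$roster$subject_id, coh$roster$subject_id)
  expect_equal(back$timeseries$S003$values, coh$timeseries$S003$values,
               tolerance = 1e-9)
})
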