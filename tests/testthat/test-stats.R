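# Group statistics: normality gate, omnibus tests, chi-squared,
# covariate-adjusted post hocs, Bonferroni, subject classification.

test_that("normality screen flags deterministic normal scores as normal", {
  vals <- qnorm((1:50 - 0.5) / 50)           # exact normal quantiles
  res <- normality_screen(rep(vals, 2), rep(c("a", "b"), each = 50))
  expect_true(res$normal)
  expect_named(res$p_by_group, c("a", "b"))
  expect_error(normality_screen(rnorm(5), c("a", "a", "a", "b", "b")),
               class = "presbynet_config_error")
})

test_that("skewed samples are flagged non-normal almost always", {
  flags <- withr::with_seed(101, vapply(1:100, function(i) {
    vals <- rexp(100)
    normality_screen(vals, rep(c("a", "b"), each = 50))$normal
  }, logical(1)))
  expect_gte(mean(!flags), 0.95)
})

test_that("omnibus comparison chooses ANOVA or Kruskal-Wallis correctly", {
  withr::with_seed(102, {
    vals <- rnorm(90)
    groups <- rep(c("g1", "g2", "g3"), each = 30)
  })
  res <- omnibus_compare(vals, groups, normal = TRUE)
  expect_equal(res$test, "anova")
  ref <- summary(aov(vals ~ factor(groups)))[[1]]
  expect_equal(res$statistic, ref[["F value"]][1])
  res_np <- omnibus_compare(vals, groups, normal = FALSE)
  expect_equal(res_np$test, "kruskal")
  expect_equal(res_np$p, kruskal.test(vals, factor(groups))$p.value)
  # identical groups: F ~ 0, p ~ 1
  same <- rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 3)
  res0 <- omnibus_compare(same, rep(c("a", "b", "c"), each = 5), normal = TRUE)
  expect_lt(res0$statistic, 1e-20)
  expect_gt(res0$p, 0.999)
  expect_error(omnibus_compare(1:3, c("a", "a", "b"), normal = TRUE),
               class = "presbynet_config_error")
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  withr::with_seed(103, {
    x <- rnorm(20, 0); y <- rnorm(25, 0.5)
  })
  res <- omnibus_compare(c(x, y), rep(c("a", "b"), c(20, 25)), normal = TRUE)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("summary-statistic ANOVA matches raw-data ANOVA exactly", {
  withr::with_seed(104, {
    vals <- rnorm(60, sd = 2)
    groups <- rep(c("a", "b", "c"), each = 20)
  })
  sp <- split(vals, groups)
  res <- summary_stat_anova(sapply(sp, mean), sapply(sp, sd),
                            sapply(sp, length))
  raw <- summary(aov(vals ~ factor(groups)))[[1]]
  expect_equal(res$statistic, raw[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, raw[["Pr(>F)"]][1], tolerance = 1e-10)
  # equal means: F = 0
  expect_equal(summary_stat_anova(c(3, 3, 3), c(1, 2, 1), c(10, 10, 10))$statistic, 0)
  expect_error(summary_stat_anova(1:2, 1:2, c(1, 5)),
               class = "presbynet_config_error")
})

test_that("published demographic rows reproduce their printed p-values", {
  age <- summary_stat_anova(c(63.03, 62.47, 61.08), c(7.30, 7.12, 3.93),
                            c(30, 30, 50))
  expect_lt(abs(age$p - 0.321), 0.005)
  edu <- summary_stat_anova(c(10.40, 11.47, 10.78), c(2.18, 1.72, 1.79),
                            c(30, 30, 50))
  expect_lt(abs(edu$p - 0.087), 0.005)
})

test_that("chi-squared test matches the expected-count formula", {
  tab <- rbind(M = c(14, 12, 24), F = c(16, 18, 26))
  res <- categorical_compare(tab)
  expect_equal(res$df, 2)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp_counts)^2 / exp_counts)
  expect_equal(res$statistic, chi2, tolerance = 1e-12)
  expect_equal(res$p, pchisq(chi2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # perfectly proportional table: chi2 = 0, p = 1
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  res0 <- categorical_compare(prop)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  # random 2x2 against the direct formula
  t22 <- rbind(c(7, 13), c(11, 9))
  e22 <- outer(rowSums(t22), colSums(t22)) / sum(t22)
  expect_equal(categorical_compare(t22)$statistic,
               sum((t22 - e22)^2 / e22), tolerance = 1e-12)
  expect_error(categorical_compare(rbind(c(0, 0), c(1, 2))),
               class = "presbynet_config_error")
})

test_that("post hoc without covariates is exactly the pooled two-sample t", {
  withr::with_seed(105, {
    vals <- c(rnorm(15), rnorm(18, 0.8))
    groups <- rep(c("a", "b"), c(15, 18))
  })
  ph <- pairwise_posthoc(vals, groups)
  tt <- t.test(vals[groups == "a"], vals[groups == "b"], var.equal = TRUE)
  expect_equal(abs(ph$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(ph$p, tt$p.value, tolerance = 1e-10)
  expect_equal(ph$df, 31)
})

test_that("a covariate identical to the outcome absorbs the group effect", {
  withr::with_seed(106, {
    vals <- c(rnorm(20), rnorm(20, 2))
    groups <- rep(c("a", "b"), each = 20)
  })
  # lm warns about the essentially perfect fit; the point is the estimate
  ph <- suppressWarnings(pairwise_posthoc(vals, groups,
                                          covariates = data.frame(conf = vals)))
  expect_lt(abs(ph$estimate), 1e-8)
})

test_that("adjusting for a correlated covariate sharpens the group test", {
  hits <- withr::with_seed(107, vapply(1:50, function(i) {
    n <- 20
    covar <- rnorm(2 * n)
    g <- rep(0:1, each = n)
    y <- 0.8 * g + 2 * covar + rnorm(2 * n)
    groups <- c("a", "b")[g + 1]
    p_adj <- pairwise_posthoc(y, groups,
                              covariates = data.frame(covar = covar))$p
    p_raw <- pairwise_posthoc(y, groups)$p
    p_adj < p_raw
  }, logical(1)))
  expect_gte(mean(hits), 0.8)
})

test_that("three-group post hocs cover all pairs and encode sex covariates", {
  withr::with_seed(108, {
    df <- data.frame(
      vals = rnorm(45),
      groups = rep(c("PCD", "PNCD", "HC"), each = 15),
      age = rnorm(45, 63, 5),
      sex = sample(c("M", "F"), 45, replace = TRUE))
  })
  ph <- pairwise_posthoc(df$vals, df$groups,
                         covariates = df[, c("age", "sex")])
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$covariates == "age+sex"))
  expect_error(pairwise_posthoc(df$vals[1:6], df$groups[1:6],
                                covariates = df[1:6, c("age", "sex")],
                                pairs = list(c("PCD", "PNCD"))),
               class = "presbynet_config_error")
})

test_that("Bonferroni adjustment matches the alpha/m rule", {
  res <- bonferroni_adjust(0.01, m = 90)
  expect_equal(res$p_adjusted, 0.9)
  expect_false(res$significant)
  ident <- bonferroni_adjust(c(0.03, 0.2), m = 1)
  expect_equal(ident$p_adjusted, c(0.03, 0.2))
  withr::with_seed(109, p <- runif(200))
  res2 <- bonferroni_adjust(p, alpha = 0.05, m = 200)
  expect_equal(res2$significant, p < 0.05 / 200)
  expect_true(all(res2$p_adjusted <= 1))
})

test_that("subjects are classified by better-ear PTA and MoCA boundaries", {
  roster <- data.frame(
    pta_left = c(20, 33, 30),
    pta_right = c(22, 35, 28),
    moca = c(28, 24, 26))
  expect_equal(classify_subjects(roster), c("HC", "PCD", "PNCD"))
  expect_error(classify_subjects(data.frame(pta_left = 1, pta_right = 2,
                                            moca = NA)),
               class = "presbynet_config_error")
})

test_that("tests are invariant to group-label permutation", {
  withr::with_seed(110, {
    vals <- rnorm(60)
    groups <- rep(c("a", "b", "c"), each = 20)
  })
  relab <- c(a = "c", b = "a", c = "b")[groups]
  r1 <- omnibus_compare(vals, groups, normal = TRUE)
  r2 <- omnibus_compare(vals, relab, normal = TRUE)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("compare_groups gates post hocs on the omnibus p-value", {
  withr::with_seed(111, {
    df <- data.frame(
      group = rep(c("PCD", "PNCD", "HC"), each = 20),
      m_null = rnorm(60),
      m_effect = c(rnorm(20, 2), rnorm(20), rnorm(20)))
  })
  rep <- compare_groups(df, metrics = c("m_null", "m_effect"))
  expect_equal(nrow(rep$omnibus), 2)
  expect_true(all(rep$posthoc$metric == "m_effect"))
  # corrected flags are a subset of uncorrected flags
  expect_true(all(!rep$omnibus$significant | rep$omnibus$p < rep$alpha))
})
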