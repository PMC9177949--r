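## Three-group statistical flow: Shapiro-Wilk normality gate, one-way ANOVA
## or Kruskal-Wallis omnibus, chi-squared for categorical tables, linear-model
## post hocs with age/sex/education covariates, Bonferroni correction, and
## the roster-level grouping rule.

#' Per-group Shapiro-Wilk normality screen
#'
#' A variable is flagged non-normal when any group's Shapiro-Wilk p-value
#' falls below `alpha`.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param alpha screening level (default 0.05).
#' @return A list: `p_by_group` (named vector), `normal` (logical).
#' @export
normality_screen <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (any(table(groups) < 3)) {
    pn_stop("Shapiro-Wilk needs at least 3 observations per group",
            "presbynet_config_error")
  }
  p <- vapply(split(values, groups), function(v) {
    if (length(unique(v)) == 1) return(0)  # degenerate: constant is non-normal
    shapiro.test(v)$p.value
  }, numeric(1))
  list(p_by_group = p, normal = all(p >= alpha))
}

#' Omnibus three-group comparison
#'
#' One-way ANOVA (F) for normally distributed variables, Kruskal-Wallis (H)
#' otherwise. When `normal` is `NULL` the choice is gated by
#' [normality_screen()].
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length (>= 2 levels, each
#'   with >= 2 observations).
#' @param normal logical; force the parametric (`TRUE`) or non-parametric
#'   (`FALSE`) branch, or `NULL` to screen.
#' @return A list: `test` ("anova" or "kruskal"), `statistic`, `df`, `p`.
#' @export
omnibus_compare <- function(values, groups, normal = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    pn_stop("need >= 2 groups with >= 2 observations each",
            "presbynet_config_error")
  }
  if (is.null(normal)) normal <- normality_screen(values, groups)$normal
  if (normal) {
    fit <- summary(aov(values ~ groups))[[1]]
    list(test = "anova", statistic = fit[["F value"]][1],
         df = c(fit[["Df"]][1], fit[["Df"]][2]), p = fit[["Pr(>F)"]][1])
  } else {
    kw <- kruskal.test(values, groups)
    list(test = "kruskal", statistic = unname(kw$statistic),
         df = unname(kw$parameter), p = kw$p.value)
  }
}

#' One-way ANOVA from group summary statistics
#'
#' Classical between/within decomposition computed from per-group means,
#' standard deviations and sizes; identical to raw-data ANOVA when the
#' summaries are exact. Useful for re-testing published demographic tables.
#'
#' @param means,sds,ns equal-length vectors of group means, SDs and sizes
#'   (k >= 2 groups, each n >= 2).
#' @return A list: `statistic` (F), `df`, `p`.
#' @examples
#' # age row of a published three-group demographic table
#' summary_stat_anova(c(63.03, 62.47, 61.08), c(7.30, 7.12, 3.93), c(30, 30, 50))
#' @export
summary_stat_anova <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k || any(ns < 2)) {
    pn_stop("need k >= 2 groups with matching means/sds and each n >= 2",
            "presbynet_config_error")
  }
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- n_tot - k
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, df = c(df1, df2),
       p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; `df = (r - 1)(k - 1)`.
#'
#' @param contingency counts matrix (e.g. 2 x k sex-by-group table).
#' @return A list: `statistic`, `df`, `p`, `expected`.
#' @examples
#' categorical_compare(rbind(M = c(14, 12, 24), F = c(16, 18, 26)))
#' @export
categorical_compare <- function(contingency) {
  contingency <- as.matrix(contingency)
  expected <- outer(rowSums(contingency), colSums(contingency)) /
    sum(contingency)
  if (any(expected <= 0)) {
    pn_stop("all expected counts must be positive", "presbynet_config_error")
  }
  res <- suppressWarnings(chisq.test(contingency, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = expected)
}

#' Covariate-adjusted pairwise post-hoc tests
#'
#' For each pair of groups, fits `value ~ group + covariates` on that pair's
#' subjects and reports the t statistic and p-value of the group indicator.
#' With no covariates this is exactly the pooled-variance two-sample t-test.
#'
#' @param values numeric outcome vector.
#' @param groups factor/character of group labels.
#' @param covariates optional data.frame/matrix of covariate columns aligned
#'   to `values` (e.g. age, sex, education; factors are expanded to
#'   indicators).
#' @param pairs optional list of 2-vectors of group levels to compare;
#'   default all pairs.
#' @return data.frame with columns `group1`, `group2`, `estimate` (the
#'   adjusted group difference, level 2 minus level 1), `t`, `df`, `p`,
#'   `covariates`.
#' @export
pairwise_posthoc <- function(values, groups, covariates = NULL, pairs = NULL) {
  groups <- droplevels(as.factor(groups))
  lv <- levels(groups)
  if (is.null(pairs)) {
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  cov_df <- NULL
  cov_names <- "none"
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    cov_names <- paste(names(cov_df), collapse = "+")
    # encode two-level factors/characters as 0/1
    for (nm in names(cov_df)) {
      if (!is.numeric(cov_df[[nm]])) {
        cov_df[[nm]] <- as.numeric(as.factor(cov_df[[nm]])) - 1
      }
    }
  }
  rows <- lapply(pairs, function(pr) {
    sel <- groups %in% pr
    n_cov <- if (is.null(cov_df)) 0L else ncol(cov_df)
    if (sum(sel) <= n_cov + 2L ||
        any(table(factor(groups[sel], levels = pr)) < 2)) {
      pn_stop(sprintf(
        "pair %s-%s: need >= 2 subjects per group and more than %d in total",
        pr[1], pr[2], n_cov + 2L), "presbynet_config_error")
    }
    gi <- as.numeric(groups[sel] == pr[2])
    X <- cbind(group = gi,
               if (!is.null(cov_df)) as.matrix(cov_df[sel, , drop = FALSE]))
    dat <- data.frame(y = values[sel], X)
    fit <- lm(y ~ ., data = dat)
    sm <- coef(summary(fit))["group", ]
    data.frame(group1 = pr[1], group2 = pr[2],
               estimate = unname(sm["Estimate"]),
               t = unname(sm["t value"]), df = fit$df.residual,
               p = unname(sm["Pr(>|t|)"]), covariates = cov_names,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`; significant iff `p_adj < alpha` (equivalently
#' `p < alpha / m`).
#'
#' @param pvals numeric vector of raw p-values.
#' @param alpha family-wise error level (default 0.05).
#' @param m family size (default `length(pvals)`).
#' @return data.frame with columns `p`, `p_adjusted`, `significant`.
#' @export
bonferroni_adjust <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (!is_count(m) || m < 1) pn_stop("family size m must be >= 1",
                                     "presbynet_config_error")
  p_adj <- pmin(1, pvals * m)
  data.frame(p = pvals, p_adjusted = p_adj,
             significant = p_adj < alpha)
}

#' Assign study groups from roster measurements
#'
#' Presbycusis iff the better-ear pure-tone average exceeds 25 dB HL; among
#' patients, cognitive decline (PCD) iff MoCA < 26, otherwise PNCD; all
#' others are healthy controls (HC).
#'
#' @param roster data.frame with columns `pta_left`, `pta_right`, `moca`.
#' @return Character vector of group labels ("PCD", "PNCD", "HC").
#' @export
classify_subjects <- function(roster) {
  need <- c("pta_left", "pta_right", "moca")
  if (!all(need %in% names(roster)) ||
      anyNA(roster[need])) {
    pn_stop("roster needs complete pta_left, pta_right and moca columns",
            "presbynet_config_error")
  }
  better <- pmin(roster$pta_left, roster$pta_right)
  ifelse(better > 25,
         ifelse(roster$moca < 26, "PCD", "PNCD"),
         "HC")
}

#' Full group-comparison report for a table of metric values
#'
#' Runs the whole statistical flow for each metric column: normality gate,
#' omnibus test, and (when the omnibus is significant at `alpha`)
#' covariate-adjusted pairwise post hocs with Bonferroni correction over the
#' family `m` (default: the number of metric columns tested).
#'
#' @param data data.frame of subjects; must contain `group` plus the metric
#'   columns named in `metrics`.
#' @param metrics character vector of metric column names.
#' @param covariates optional character vector of covariate column names in
#'   `data` (e.g. `c("age", "sex", "education_years")`).
#' @param alpha significance level (default 0.05).
#' @param m Bonferroni family size (default `length(metrics)`).
#' @return An object of class `group_comparison_report`: list with `omnibus`
#'   (data.frame: metric, test, statistic, p, p_adjusted, significant) and
#'   `posthoc` (data.frame of pairwise rows for significant metrics).
#' @export
compare_groups <- function(data, metrics, covariates = NULL, alpha = 0.05,
                           m = length(metrics)) {
  stopifnot(is.data.frame(data), "group" %in% names(data),
            all(metrics %in% names(data)))
  omni <- do.call(rbind, lapply(metrics, function(mm) {
    res <- omnibus_compare(data[[mm]], data$group)
    data.frame(metric = mm, test = res$test, statistic = res$statistic,
               p = res$p, stringsAsFactors = FALSE)
  }))
  adj <- bonferroni_adjust(omni$p, alpha = alpha, m = m)
  omni$p_adjusted <- adj$p_adjusted
  omni$significant <- adj$significant
  ph <- NULL
  cov_df <- if (!is.null(covariates)) data[, covariates, drop = FALSE]
  for (mm in metrics[omni$p < alpha]) {
    rows <- pairwise_posthoc(data[[mm]], data$group, covariates = cov_df)
    rows <- cbind(metric = mm, rows)
    ph <- rbind(ph, rows)
  }
  structure(list(omnibus = omni, posthoc = ph, alpha = alpha, family_size = m,
                 covariates = covariates %||% character(0)),
            class = "group_comparison_report")
}

#' @export
print.group_comparison_report <- function(x, ...) {
  cat(sprintf("<group_comparison_report> %d metrics, alpha = %g, m = %d\n",
              nrow(x$omnibus), x$alpha, x$family_size))
  print(x$omnibus, digits = 3)
  if (!is.null(x$posthoc)) {
    cat("post hoc (covariates:",
        if (length(x$covariates)) paste(x$covariates, collapse = ", ")
        else "none", "):\n")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}
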