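# Downstream statistics: covariate-adjusted group comparisons (GLM),
# paired OFF-ON tests with a normality gate, demographic tables,
# mixed-model group x medication-status interaction, partial correlation,
# Bonferroni thresholds, and network-level summaries against controls.

test_result <- function(test, statistic, p_value, df = NA_real_,
                        estimate = NA_real_, alpha = 0.05, m = 1L,
                        branch = NA_character_) {
  thr <- bonferroni_threshold(alpha, m)
  tibble::tibble(
    test = test,
    estimate = unname(estimate),
    statistic = unname(statistic),
    df = unname(df),
    p_value = unname(p_value),
    threshold = thr,
    significant = p_value < thr,
    branch = branch
  )
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 2)  # 0.025
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  check_prob(alpha, "alpha")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    abort_config("`m` must be a single integer >= 1")
  }
  alpha / m
}

# Lilliefors-style normality gate (Kolmogorov-Smirnov with estimated
# parameters).  Small or degenerate samples fail the gate (treated as
# non-normal) since the test is undefined there.
is_normal <- function(x, alpha = 0.05) {
  if (length(x) < 5L || stats::sd(x) == 0) return(FALSE)
  nortest::lillie.test(x)$p.value > alpha
}

#' Covariate-adjusted group comparison (general linear model)
#'
#' Fits `outcome ~ group + age + gender + education` (or any covariate set)
#' by least squares and reports the two-sided test of the group
#' coefficient, i.e. the group difference with the covariates regressed
#' out.  Zero-variance covariates are dropped (with a message), so with no
#' informative covariates the test reduces to the pooled-variance
#' two-sample t-test.
#'
#' @param data Data frame, one row per subject.
#' @param outcome Name of the outcome column.
#' @param group Name of the two-level group column.
#' @param covariates Character vector of covariate columns (default
#'   `c("age", "gender", "education")`); two-level categorical covariates
#'   are encoded as 0/1 indicators.
#' @param alpha,m Significance level and number of comparisons for the
#'   Bonferroni-adjusted threshold.
#' @return One-row test-result tibble (`test`, `estimate`, `statistic`,
#'   `df`, `p_value`, `threshold`, `significant`, `branch`).
#' @export
adjusted_group_comparison <- function(data, outcome, group = "group",
                                      covariates = c("age", "gender", "education"),
                                      alpha = 0.05, m = 1L) {
  for (col in c(outcome, group, covariates)) {
    if (!col %in% names(data)) abort_data(sprintf("column `%s` not found", col))
  }
  g <- data[[group]]
  if (!is.factor(g)) g <- factor(g)
  g <- droplevels(g)
  if (nlevels(g) != 2L) abort_data("`group` must have exactly 2 levels")

  covs <- list()
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    if (stats::sd(v) == 0) {
      rlang::inform(sprintf("dropping zero-variance covariate `%s`", cv))
      next
    }
    covs[[cv]] <- v
  }
  df_fit <- data.frame(.outcome = data[[outcome]], .group = g)
  for (nm in names(covs)) df_fit[[nm]] <- covs[[nm]]
  if (nrow(df_fit) < length(covs) + 4L) abort_data("too few subjects for the adjusted model")
  fit <- stats::lm(.outcome ~ ., data = df_fit)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    abort_numeric(sprintf("collinear design: aliased column(s) %s",
                          paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  row <- grep("^\\.group", rownames(sm))
  test_result(
    test = sprintf("GLM group effect on %s", outcome),
    estimate = sm[row, "Estimate"],
    statistic = sm[row, "t value"],
    df = fit$df.residual,
    p_value = sm[row, "Pr(>|t|)"],
    alpha = alpha, m = m,
    branch = sprintf("lm adjusted for %s", paste(names(covs), collapse = "+"))
  )
}

#' Paired OFF-ON comparison with a normality gate
#'
#' Paired t-test when the paired differences pass the Lilliefors normality
#' gate, Wilcoxon signed-rank otherwise.  All-zero differences make both
#' tests degenerate; that case reports `p = 1` with branch `"degenerate"`.
#'
#' @param off,on Paired numeric vectors (same subjects, same order).
#' @param alpha Significance level.
#' @return One-row test-result tibble; `branch` records which test ran.
#' @export
paired_comparison <- function(off, on, alpha = 0.05) {
  if (length(off) != length(on)) abort_data("`off` and `on` lengths differ")
  d <- on - off
  if (all(d == 0)) {
    return(test_result("paired OFF-ON", statistic = 0, p_value = 1,
                       alpha = alpha, branch = "degenerate"))
  }
  if (is_normal(d, alpha = 0.05)) {
    tt <- stats::t.test(on, off, paired = TRUE)
    test_result("paired OFF-ON", estimate = mean(d), statistic = tt$statistic,
                df = tt$parameter, p_value = tt$p.value, alpha = alpha,
                branch = "paired t-test")
  } else {
    wt <- stats::wilcox.test(on, off, paired = TRUE, exact = FALSE, correct = TRUE)
    test_result("paired OFF-ON", estimate = mean(d), statistic = wt$statistic,
                p_value = wt$p.value, alpha = alpha,
                branch = "Wilcoxon signed-rank")
  }
}

#' Demographic / clinical group comparison
#'
#' Continuous variables: pooled two-sample t-test when both groups pass the
#' Lilliefors gate, Mann-Whitney U otherwise; three or more groups use
#' Kruskal-Wallis.  Categorical variables: Pearson chi-square without
#' continuity correction.
#'
#' @param data Data frame, one row per subject.
#' @param variable Column to compare.
#' @param group Grouping column (>= 2 non-empty groups).
#' @param kind `"continuous"` or `"categorical"`.
#' @param alpha Significance level.
#' @return One-row test-result tibble.
#' @export
demographic_comparison <- function(data, variable, group = "group",
                                   kind = c("continuous", "categorical"),
                                   alpha = 0.05) {
  kind <- match.arg(kind)
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2L || any(table(g) == 0L)) abort_data("need >= 2 non-empty groups")
  v <- data[[variable]]
  name <- sprintf("%s by %s", variable, group)

  if (kind == "categorical") {
    ct <- stats::chisq.test(table(g, v), correct = FALSE)
    return(test_result(name, statistic = ct$statistic, df = ct$parameter,
                       p_value = ct$p.value, alpha = alpha,
                       branch = "Pearson chi-square"))
  }
  if (nlevels(g) > 2L) {
    kw <- stats::kruskal.test(v, g)
    return(test_result(name, statistic = kw$statistic, df = kw$parameter,
                       p_value = kw$p.value, alpha = alpha,
                       branch = "Kruskal-Wallis"))
  }
  split_v <- split(v, g)
  if (all(vapply(split_v, is_normal, logical(1)))) {
    tt <- stats::t.test(split_v[[1]], split_v[[2]], var.equal = TRUE)
    test_result(name, estimate = diff(rev(tt$estimate)), statistic = tt$statistic,
                df = tt$parameter, p_value = tt$p.value, alpha = alpha,
                branch = "two-sample t-test")
  } else {
    wt <- stats::wilcox.test(split_v[[1]], split_v[[2]], exact = FALSE)
    test_result(name, statistic = wt$statistic, p_value = wt$p.value,
                alpha = alpha, branch = "Mann-Whitney U")
  }
}

#' Group x medication-status interaction (linear mixed model)
#'
#' The outcome (one value per subject-session) is first residualized
#' against the covariates, then modeled with fixed effects for group,
#' status and their interaction plus a per-subject random intercept (REML);
#' the reported test is the Satterthwaite-df t-test of the interaction
#' coefficient.  A singular random-effects fit falls back to a two-sample
#' t-test on the per-subject ON-OFF differences (branch flagged).
#'
#' @param data Long data frame: exactly 2 rows (OFF and ON) per subject.
#' @param outcome,group,status,subject Column names.
#' @param covariates Covariate columns to residualize on (`NULL` for none).
#' @param alpha Significance level.
#' @return One-row test-result tibble; `estimate` is the interaction
#'   coefficient, i.e. the difference between the groups' mean ON-OFF
#'   changes.
#' @export
mixed_interaction <- function(data, outcome, group = "group", status = "session",
                              subject = "subject_id", covariates = NULL,
                              alpha = 0.05) {
  y <- data[[outcome]]
  g <- droplevels(factor(data[[group]]))
  s <- droplevels(factor(data[[status]]))
  id <- factor(data[[subject]])
  if (nlevels(g) != 2L || nlevels(s) != 2L) abort_data("`group` and `status` must each have 2 levels")
  if (any(table(id) != 2L)) abort_data("each subject needs exactly 2 rows (OFF and ON)")

  if (!is.null(covariates)) {
    covs <- lapply(data[covariates], function(v) {
      if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1 else v
    })
    keep <- vapply(covs, function(v) stats::sd(v) > 0, logical(1))
    if (any(keep)) {
      y <- stats::resid(stats::lm(y ~ ., data = data.frame(covs[keep])))
    }
  }

  dd <- data.frame(y = y, g = g, s = s, id = id)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ g * s + (1 | id), data = dd, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  if (lme4::isSingular(fit, tol = 1e-6)) {
    # per-subject ON-OFF delta, then a two-sample t-test between groups
    ord <- order(dd$id, dd$s)
    yo <- dd$y[ord]
    delta <- yo[seq(2, length(yo), by = 2)] - yo[seq(1, length(yo), by = 2)]
    gid <- dd$g[ord][seq(1, length(yo), by = 2)]
    tt <- stats::t.test(delta ~ gid, var.equal = TRUE)
    return(test_result("group x status interaction",
                       estimate = diff(tt$estimate), statistic = tt$statistic,
                       df = tt$parameter, p_value = tt$p.value, alpha = alpha,
                       branch = "singular fit: two-sample t on ON-OFF deltas"))
  }
  cf <- summary(fit)$coefficients
  row <- grep(":", rownames(cf))
  test_result("group x status interaction",
              estimate = cf[row, "Estimate"], statistic = cf[row, "t value"],
              df = cf[row, "df"], p_value = cf[row, "Pr(>|t|)"], alpha = alpha,
              branch = "mixed model, Satterthwaite t")
}

#' Partial correlation with covariates regressed out
#'
#' Residualizes `x` and `y` on the covariates by least squares, correlates
#' the residuals, and tests with `n - 2 - k` degrees of freedom.
#'
#' @param data Data frame, one row per subject.
#' @param x,y Column names of the two variables.
#' @param covariates Covariate columns (`NULL` reduces to plain Pearson).
#' @param alpha Significance level.
#' @return One-row tibble: `estimate` (partial r), `statistic`, `df`,
#'   `p_value`, `threshold`, `significant`.
#' @export
partial_correlation <- function(data, x, y, covariates = NULL, alpha = 0.05) {
  xv <- data[[x]]
  yv <- data[[y]]
  k <- length(covariates)
  n <- length(xv)
  if (n <= k + 3L) abort_data("need n > k + 3 observations for partial correlation")
  if (k > 0) {
    covs <- lapply(data[covariates], function(v) {
      if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1 else v
    })
    cd <- data.frame(covs)
    xv <- stats::resid(stats::lm(xv ~ ., data = cd))
    yv <- stats::resid(stats::lm(yv ~ ., data = cd))
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) abort_numeric("zero residual variance")
  r <- stats::cor(xv, yv)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, 1e-300))
  test_result(sprintf("partial correlation %s ~ %s", x, y),
              estimate = r, statistic = tstat, df = df,
              p_value = 2 * stats::pt(-abs(tstat), df), alpha = alpha,
              branch = if (k > 0) sprintf("adjusted for %s", paste(covariates, collapse = "+"))
                       else "plain Pearson")
}

#' Network-level summary comparisons against controls
#'
#' For each session, compares patients with controls on mean dopaminergic
#' connectivity and mean cholinergic connectivity (each at the Bonferroni
#' threshold for two tests) and on their difference (relative
#' cholinergic-dopaminergic activity, at the raw level); optionally also
#' compares each patient subgroup with controls on given selected edges
#' (Bonferroni for two subgroups).  All comparisons are covariate-adjusted
#' ([adjusted_group_comparison()]).
#'
#' @param connectivity Long connectivity tibble containing patients and
#'   controls.
#' @param clinical Clinical tibble with `subject_id`, `cohort`
#'   (`"patient"`/`"control"`), covariates, and (for subgroup comparisons)
#'   `group`.
#' @param selected_edges Optional character vector of edge labels for
#'   subgroup-vs-control comparisons.
#' @param covariates Covariates for adjustment.
#' @param alpha Significance level.
#' @return A test-result tibble with one row per comparison, plus columns
#'   `session` and `measure`.  With no controls present, warns and returns
#'   an empty tibble.
#' @export
network_summary_report <- function(connectivity, clinical,
                                   selected_edges = NULL,
                                   covariates = c("age", "gender", "education"),
                                   alpha = 0.05) {
  if (!"cohort" %in% names(clinical) || !any(clinical$cohort == "control")) {
    rlang::warn("no controls available; skipping network summary comparisons")
    return(tibble::tibble())
  }
  summ <- mean_network_strength(connectivity) |>
    tidyr::pivot_wider(names_from = "system", values_from = "mean_z") |>
    dplyr::mutate(ach_minus_da = .data$ach - .data$da) |>
    dplyr::inner_join(clinical, by = "subject_id")

  rows <- list()
  for (sess in sort(unique(summ$session))) {
    ds <- dplyr::filter(summ, .data$session == sess)
    for (spec in list(list(col = "da", m = 2L, lab = "mean DA-FC"),
                      list(col = "ach", m = 2L, lab = "mean ACh-FC"),
                      list(col = "ach_minus_da", m = 1L, lab = "ACh-DA difference"))) {
      res <- adjusted_group_comparison(ds, spec$col, group = "cohort",
                                       covariates = covariates,
                                       alpha = alpha, m = spec$m)
      rows[[length(rows) + 1L]] <- dplyr::mutate(res, session = sess,
                                                 measure = spec$lab, .before = 1L)
    }
  }

  if (!is.null(selected_edges) && "group" %in% names(clinical)) {
    edge_z <- connectivity |>
      dplyr::filter(.data$edge %in% selected_edges) |>
      dplyr::inner_join(clinical, by = "subject_id")
    subgroups <- setdiff(unique(clinical$group[clinical$cohort == "patient"]), NA)
    for (e in selected_edges) {
      for (sess in sort(unique(edge_z$session))) {
        for (sg in subgroups) {
          ds <- edge_z |>
            dplyr::filter(.data$edge == e, .data$session == sess,
                          .data$cohort == "control" | .data$group == sg) |>
            dplyr::mutate(.cmp = ifelse(.data$cohort == "control", "control", sg))
          if (length(unique(ds$.cmp)) < 2L) next
          res <- adjusted_group_comparison(ds, "z", group = ".cmp",
                                           covariates = covariates,
                                           alpha = alpha, m = 2L)
          rows[[length(rows) + 1L]] <- dplyr::mutate(
            res, session = sess, measure = sprintf("%s: %s vs control", e, sg),
            .before = 1L
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
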