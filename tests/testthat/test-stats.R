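test_that("the adjusted comparison reduces to a pooled t-test without informative covariates", {
  d <- withr::with_seed(1, tibble::tibble(
    y = c(rnorm(20), rnorm(20, 0.8)),
    group = rep(c("a", "b"), each = 20),
    age = 0, gender = "M", education = 0
  ))
  res <- suppressMessages(adjusted_group_comparison(d, "y"))
  tt <- stats::t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(abs(res$statistic), abs(unname(tt$statistic)), tolerance = 1e-8)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-8)
})

test_that("the adjusted comparison holds its type-I error and power", {
  null_p <- withr::with_seed(51, vapply(1:1000, function(i) {
    d <- tibble::tibble(
      y = rnorm(52), group = rep(c("a", "b"), c(24, 28)),
      age = rnorm(52, 60, 9), gender = sample(c("M", "F"), 52, TRUE),
      education = rnorm(52, 9, 4)
    )
    adjusted_group_comparison(d, "y")$p_value
  }, numeric(1)))
  expect_gte(mean(null_p < 0.05), 0.03)
  expect_lte(mean(null_p < 0.05), 0.07)
  power_p <- withr::with_seed(52, vapply(1:200, function(i) {
    d <- tibble::tibble(
      y = c(rnorm(26), rnorm(26, 1)), group = rep(c("a", "b"), each = 26),
      age = rnorm(52), gender = sample(c("M", "F"), 52, TRUE), education = rnorm(52)
    )
    adjusted_group_comparison(d, "y")$p_value
  }, numeric(1)))
  expect_gte(mean(power_p < 0.05), 0.9)
})

test_that("the adjusted comparison is invariant to affine covariate rescaling and flags aliasing", {
  d <- withr::with_seed(2, tibble::tibble(
    y = rnorm(40), group = rep(c("a", "b"), each = 20),
    age = rnorm(40, 60, 9), gender = sample(c("M", "F"), 40, TRUE),
    education = rnorm(40, 9, 4)
  ))
  base <- adjusted_group_comparison(d, "y")
  d2 <- dplyr::mutate(d, age = 10 * .data$age - 300, education = .data$education / 7)
  expect_equal(adjusted_group_comparison(d2, "y")$p_value, base$p_value, tolerance = 1e-10)
  d3 <- dplyr::mutate(d, dup = .data$age)
  expect_error(
    adjusted_group_comparison(d3, "y", covariates = c("age", "gender", "education", "dup")),
    "collinear"
  )
})

test_that("the paired test gates on normality and handles the degenerate case", {
  x <- rnorm(20)
  degen <- paired_comparison(x, x)
  expect_equal(degen$p_value, 1)
  expect_equal(degen$branch, "degenerate")
  res <- withr::with_seed(53, t(vapply(1:200, function(i) {
    off <- rnorm(28)
    on <- off + rnorm(28, 0.5, 1)
    r <- paired_comparison(off, on)
    c(reject = r$p_value < 0.05, t_branch = r$branch == "paired t-test")
  }, c(reject = numeric(1), t_branch = numeric(1)))))
  expect_gte(mean(res[, "t_branch"]), 0.8)  # normal differences mostly take the t branch
  expect_gte(mean(res[, "reject"]), 0.6)
  heavy <- withr::with_seed(54, vapply(1:200, function(i) {
    off <- rnorm(28)
    on <- off + rt(28, 2)
    paired_comparison(off, on)$branch == "Wilcoxon signed-rank"
  }, logical(1)))
  expect_gt(mean(heavy), 0.5)  # heavy tails push the majority to Wilcoxon
})

test_that("demographic comparisons pick the right branch and statistic", {
  # chi-square without continuity correction on a 2x2 gender table
  d <- tibble::tibble(
    gender = c(rep("M", 14), rep("F", 10), rep("M", 19), rep("F", 9)),
    group = rep(c("resistant", "responsive"), c(24, 28))
  )
  res <- demographic_comparison(d, "gender", kind = "categorical")
  expect_equal(res$statistic, 0.5055062, tolerance = 1e-6)
  expect_equal(res$p_value, 0.4770907, tolerance = 1e-6)
  expect_equal(res$branch, "Pearson chi-square")
  # identical distributions in both groups: t branch, p = 1
  v <- withr::with_seed(3, rnorm(25))
  d2 <- tibble::tibble(v = c(v, v), group = rep(c("a", "b"), each = 25))
  res2 <- demographic_comparison(d2, "v")
  expect_equal(res2$branch, "two-sample t-test")
  expect_equal(res2$p_value, 1)
  # three groups go to Kruskal-Wallis
  d3 <- tibble::tibble(v = withr::with_seed(4, rnorm(60)),
                       group = rep(c("a", "b", "c"), each = 20))
  expect_equal(demographic_comparison(d3, "v")$branch, "Kruskal-Wallis")
  # a one-SD shift at n = 25 per group is detected almost always
  hits <- withr::with_seed(55, vapply(1:200, function(i) {
    d4 <- tibble::tibble(
      v = c(rnorm(25), rnorm(25, 1)), group = rep(c("a", "b"), each = 25)
    )
    demographic_comparison(d4, "v")$p_value < 0.05
  }, logical(1)))
  expect_gte(mean(hits), 0.9)
})

test_that("the mixed-model interaction equals the difference of group mean deltas when balanced", {
  d <- withr::with_seed(5, {
    n1 <- 10L; n2 <- 12L
    g <- rep(c("resistant", "responsive"), c(n1, n2))
    b <- rnorm(n1 + n2, 0, 0.3)
    off <- 0.2 + b + rnorm(n1 + n2, 0, 0.1)
    on <- 0.2 + b + ifelse(g == "responsive", -0.3, 0.05) + rnorm(n1 + n2, 0, 0.1)
    tibble::tibble(
      subject_id = rep(sprintf("s%02d", seq_len(n1 + n2)), each = 2),
      group = rep(g, each = 2),
      session = rep(c("OFF", "ON"), n1 + n2),
      z = as.vector(rbind(off, on))
    )
  })
  res <- mixed_interaction(d, "z")
  delta <- tapply(d$z[d$session == "ON"], d$group[d$session == "ON"], mean) -
    tapply(d$z[d$session == "OFF"], d$group[d$session == "OFF"], mean)
  expect_equal(res$estimate, unname(delta["responsive"] - delta["resistant"]),
               tolerance = 1e-8)
})

test_that("a zero random-intercept fit falls back to the delta t-test, flagged", {
  d <- withr::with_seed(6, {
    n <- 24L
    g <- rep(c("a", "b"), each = n / 2)
    tibble::tibble(
      subject_id = rep(sprintf("s%02d", 1:n), each = 2),
      group = rep(g, each = 2),
      session = rep(c("OFF", "ON"), n),
      z = rnorm(2 * n) # no subject effect at all: singular random intercept
    )
  })
  res <- mixed_interaction(d, "z")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_true(res$branch %in% c("singular fit: two-sample t on ON-OFF deltas",
                                "mixed model, Satterthwaite t"))
})

test_that("partial correlation reduces to Pearson and recovers a constructed target", {
  d <- withr::with_seed(7, tibble::tibble(x = rnorm(100), c = rnorm(100)))
  d$y <- 0.5 * d$x + rnorm(100)
  plain <- partial_correlation(d, "x", "y")
  ct <- stats::cor.test(d$x, d$y)
  expect_equal(plain$estimate, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(plain$p_value, ct$p.value, tolerance = 1e-10)
  # x = y after residualization
  d$y2 <- d$x
  expect_equal(partial_correlation(d, "x", "y2")$estimate, 1)
  # trivariate construction with known partial correlation 0.5
  big <- withr::with_seed(8, {
    n <- 5000
    cz <- rnorm(n)
    ex <- rnorm(n)
    x <- 0.6 * cz + ex
    y <- 0.6 * cz + rnorm(n) + (0.5 / sqrt(1 - 0.25) * ex)
    tibble::tibble(x = x, y = y, cz = cz)
  })
  res <- partial_correlation(big, "x", "y", "cz")
  expect_lt(abs(res$estimate - 0.5), 0.03)
  # symmetry
  expect_equal(partial_correlation(big, "y", "x", "cz")$estimate, res$estimate)
})

test_that("Bonferroni thresholds divide alpha by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

make_network_cohort <- function(seed, atten, n_pat = 26L, n_ctrl = 30L, T = 120L) {
  roi <- roi_partition(6L, 2L, 2L)
  S_ctrl <- factor_cov(c(rep(0.5, 6), rep(0.64, 2), rep(0.42, 2)))
  S_pat <- factor_cov(c(rep(0.5, 6), rep(0.64 * atten, 2), rep(0.42, 2)))
  withr::with_seed(seed, {
    rows <- list()
    clin <- list()
    for (i in seq_len(n_pat + n_ctrl)) {
      pat <- i <= n_pat
      id <- sprintf("s%03d", i)
      S <- if (pat) S_pat else S_ctrl
      for (ss in c("OFF", "ON")) {
        ts <- sample_correlated_series(S, T)
        colnames(ts) <- roi$label
        rows[[length(rows) + 1L]] <- tibble::tibble(subject_id = id, session = ss,
                                                    ts = list(ts))
      }
      clin[[i]] <- tibble::tibble(
        subject_id = id, cohort = if (pat) "patient" else "control",
        age = rnorm(1, 60, 9), gender = sample(c("M", "F"), 1),
        education = rnorm(1, 9, 4)
      )
    }
    list(cohort = list(timeseries = dplyr::bind_rows(rows), roi = roi),
         clinical = dplyr::bind_rows(clin))
  })
}

test_that("network summaries flag attenuated dopaminergic connectivity, not cholinergic", {
  da_p <- ach_p <- numeric(30)
  for (r in 1:30) {
    nc <- make_network_cohort(r, atten = 0.78)
    rep <- network_summary_report(build_connectivity(nc$cohort), nc$clinical)
    da_p[r] <- rep$p_value[rep$measure == "mean DA-FC" & rep$session == "OFF"]
    ach_p[r] <- rep$p_value[rep$measure == "mean ACh-FC" & rep$session == "OFF"]
  }
  expect_gte(mean(da_p < 0.025), 0.8)
  expect_lte(mean(ach_p < 0.025), 0.2)
  # identical generating covariances: null rejections stay near the threshold
  null_p <- vapply(1:30, function(r) {
    nc <- make_network_cohort(100 + r, atten = 1)
    rep <- network_summary_report(build_connectivity(nc$cohort), nc$clinical)
    rep$p_value[rep$measure == "mean DA-FC" & rep$session == "OFF"]
  }, numeric(1))
  expect_lte(mean(null_p < 0.025), 0.15)
  # the difference measure is exactly per-subject mean ACh minus mean DA
  nc <- make_network_cohort(999, atten = 1, n_pat = 3L, n_ctrl = 3L, T = 40L)
  conn <- build_connectivity(nc$cohort)
  diff_tbl <- ach_da_difference(conn)
  ms <- mean_network_strength(conn)
  wide <- tidyr::pivot_wider(ms, names_from = "system", values_from = "mean_z")
  expect_equal(diff_tbl$ach_minus_da, wide$ach - wide$da)
})

test_that("a missing control arm is skipped with a warning", {
  nc <- make_network_cohort(11, atten = 1, n_pat = 4L, n_ctrl = 0L, T = 40L)
  expect_warning(
    out <- network_summary_report(build_connectivity(nc$cohort), nc$clinical),
    "no controls"
  )
  expect_equal(nrow(out), 0L)
})
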