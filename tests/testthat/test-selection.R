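make_logistic_problem <- function(n = 40, p = 3, beta = c(0.5, 0, 0), seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, stats::plogis(X %*% beta))
  })
  list(X = X, y = as.integer(y))
}

test_that("the penalty dominates at and above lambda_max (exact zero slopes)", {
  pr <- make_logistic_problem()
  lmax <- fcreact:::lambda_grid(pr$X, pr$y)[1]
  path <- penalized_logistic_path(pr$X, pr$y, lambdas = c(10 * lmax, lmax))
  expect_true(all(path$beta == 0))
})

test_that("the path approaches the unpenalized MLE as the penalty vanishes", {
  pr <- make_logistic_problem()
  grid <- exp(seq(log(0.5), log(1e-7), length.out = 100))
  path <- penalized_logistic_path(pr$X, pr$y, lambdas = grid)
  # oracle: iteratively reweighted least squares via glm
  mle <- stats::glm(pr$y ~ pr$X, family = stats::binomial())
  expect_lt(max(abs(path$beta[, 100] - stats::coef(mle)[-1])), 1e-4)
})

test_that("duplicated features share the L1 weight of the original", {
  pr <- make_logistic_problem()
  lam <- fcreact:::lambda_grid(pr$X, pr$y)[30]
  single <- penalized_logistic_path(pr$X, pr$y, lambdas = c(4 * lam, lam))
  dup <- penalized_logistic_path(cbind(pr$X, pr$X[, 1]), pr$y, lambdas = c(4 * lam, lam))
  expect_equal(dup$beta[1, 2] + dup$beta[4, 2], single$beta[1, 2], tolerance = 0.02)
})

test_that("degenerate designs are rejected or flagged", {
  pr <- make_logistic_problem()
  expect_error(penalized_logistic_path(pr$X, rep(1L, 40)), "single class")
  Xc <- pr$X
  Xc[, 2] <- 1
  colnames(Xc) <- c("a", "b", "c")
  expect_warning(penalized_logistic_path(Xc, pr$y), "constant feature")
})

test_that("stratified subsampling draws floor(fraction * class size) per class", {
  labels <- rep(c("resistant", "responsive"), c(24, 28))
  idx <- stratified_subsample(labels, 0.8, seed = 1)
  expect_equal(length(idx), 41L) # 19 + 22
  expect_equal(sum(labels[idx] == "resistant"), 19L)
  expect_equal(sum(labels[idx] == "responsive"), 22L)
  expect_false(any(duplicated(idx)))
  # exact-multiple class sizes land exactly on fraction * size
  idx2 <- stratified_subsample(rep(c("a", "b"), c(5, 10)), 0.8, seed = 2)
  expect_equal(length(idx2), 12L)
  # same counts, generally different members across seeds
  idx3 <- stratified_subsample(labels, 0.8, seed = 99)
  expect_equal(length(idx3), 41L)
  expect_false(identical(idx, idx3))
  expect_identical(idx, stratified_subsample(labels, 0.8, seed = 1))
  expect_error(stratified_subsample(rep(c("a", "b"), c(2, 30)), 0.8), "fewer than 2")
})

test_that("cross-validated penalty choice is seeded and favors the null under noise", {
  pr <- make_logistic_problem(n = 40, p = 10, beta = rep(0, 10), seed = 2)
  grid <- fcreact:::lambda_grid(pr$X, pr$y)
  expect_identical(choose_lambda_cv(pr$X, pr$y, lambdas = grid, seed = 5),
                   choose_lambda_cv(pr$X, pr$y, lambdas = grid, seed = 5))
  upper <- 0L
  for (r in 1:50) {
    prn <- withr::with_seed(2000 + r,
      list(X = matrix(rnorm(400), 40, 10), y = rep(0:1, each = 20)))
    g <- fcreact:::lambda_grid(prn$X, prn$y)
    lam <- choose_lambda_cv(prn$X, prn$y, folds = 10, lambdas = g, seed = 3000 + r)
    upper <- upper + (which.min(abs(g - lam)) <= 50L)
  }
  expect_gte(upper / 50, 0.8)
})

test_that("a strongly separating feature survives the cross-validated penalty", {
  admitted <- 0L
  for (r in 1:50) {
    pr <- withr::with_seed(4000 + r, {
      X <- matrix(rnorm(200), 40, 5)
      y <- rep(0:1, each = 20)
      X[, 1] <- ifelse(y == 1, 3, -3) + rnorm(40, 0, 0.3)
      list(X = X, y = y)
    })
    g <- fcreact:::lambda_grid(pr$X, pr$y)
    lam <- choose_lambda_cv(pr$X, pr$y, folds = 10, lambdas = g, seed = 5000 + r)
    path <- penalized_logistic_path(pr$X, pr$y, lambdas = g)
    admitted <- admitted + (path$beta[1, which.min(abs(g - lam))] != 0)
  }
  expect_gte(admitted / 50, 0.95)
})

test_that("stability selection tallies and thresholds frequencies reproducibly", {
  subjects <- sprintf("s%02d", 1:52)
  groups <- tibble::tibble(subject_id = subjects,
                           group = rep(c("resistant", "responsive"), c(24, 28)))
  X <- withr::with_seed(9, matrix(rnorm(52 * 64), 52, 64,
        dimnames = list(subjects, sprintf("S-E%02d", 1:64))))
  X[, 1] <- X[, 1] + ifelse(groups$group == "responsive", 1.5, 0)
  rt <- synthetic_reactivity(X)
  cfg <- selection_config(n_iter = 30L, seed = 2L)
  sel <- stability_select(rt, groups, cfg, system = "ach")
  ranked <- tidy(sel)
  # a planted d = 1.5 edge among 63 noise edges is found first, above threshold
  expect_equal(ranked$edge[1], "S-E01")
  expect_gte(ranked$frequency[1], 0.6)
  expect_true(ranked$selected[1])
  # bitwise reproducibility under the master seed
  sel2 <- stability_select(rt, groups, cfg, system = "ach")
  expect_identical(sel$frequencies, sel2$frequencies)
  expect_identical(sel$iterations$lambda, sel2$iterations$lambda)
  # glance summarises the run
  g <- glance(sel)
  expect_equal(g$n_edges, 64L)
  expect_equal(g$n_iter, 30L)
  expect_equal(g$max_frequency, ranked$frequency[1])
})

test_that("frequencies live in {0, 1} for a single iteration and 1 for p = 1 signal", {
  subjects <- sprintf("s%02d", 1:52)
  groups <- tibble::tibble(subject_id = subjects,
                           group = rep(c("resistant", "responsive"), c(24, 28)))
  X <- withr::with_seed(10, matrix(rnorm(52 * 5), 52, 5,
        dimnames = list(subjects, sprintf("S-E%02d", 1:5))))
  sel1 <- stability_select(synthetic_reactivity(X), groups,
                           selection_config(n_iter = 1L, seed = 4L), system = "ach")
  expect_true(all(sel1$frequencies$frequency %in% c(0, 1)))
  X1 <- matrix(ifelse(groups$group == "responsive", 2, -2) + withr::with_seed(12, rnorm(52, 0, 0.3)),
               dimnames = list(subjects, "S-E01"), ncol = 1)
  sel2 <- stability_select(synthetic_reactivity(X1), groups,
                           selection_config(n_iter = 10L, seed = 4L), system = "ach")
  expect_equal(sel2$frequencies$frequency, 1)
})

test_that("frequencies are invariant to edge order and to rescaling a feature", {
  subjects <- sprintf("s%02d", 1:40)
  groups <- tibble::tibble(subject_id = subjects,
                           group = rep(c("resistant", "responsive"), each = 20))
  X <- withr::with_seed(13, matrix(rnorm(40 * 8), 40, 8,
        dimnames = list(subjects, sprintf("S-E%02d", 1:8))))
  X[, 3] <- X[, 3] + ifelse(groups$group == "responsive", 1.5, 0)
  cfg <- selection_config(n_iter = 15L, seed = 6L)
  base <- stability_select(synthetic_reactivity(X), groups, cfg, system = "ach")
  perm <- withr::with_seed(14, sample(8))
  shuf <- stability_select(synthetic_reactivity(X[, perm]), groups, cfg, system = "ach")
  merged <- dplyr::inner_join(base$frequencies, shuf$frequencies, by = "edge")
  expect_equal(merged$frequency.x, merged$frequency.y)
  Xr <- X
  Xr[, 3] <- X[, 3] * 37 # standardization removes uniform rescaling
  resc <- stability_select(synthetic_reactivity(Xr), groups, cfg, system = "ach")
  expect_equal(base$frequencies$frequency, resc$frequencies$frequency)
})

test_that("selection results render as a frequency lollipop plot", {
  subjects <- sprintf("s%02d", 1:20)
  groups <- tibble::tibble(subject_id = subjects,
                           group = rep(c("resistant", "responsive"), each = 10))
  X <- withr::with_seed(15, matrix(rnorm(20 * 6), 20, 6,
        dimnames = list(subjects, sprintf("S-E%02d", 1:6))))
  sel <- stability_select(synthetic_reactivity(X), groups,
                          selection_config(n_iter = 3L, seed = 1L), system = "ach")
  p <- autoplot(sel, top_n = 5)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[2]]), 5L)
})

test_that("the canonical driver runs the three feature sets of the design", {
  run <- tiny_run()
  runs <- stability_select_all(run$reactivity, run$groups,
                               selection_config(n_iter = 2L, seed = 3L))
  expect_named(runs, c("da", "ach", "combined"))
  p <- run$cohort$params
  expect_equal(nrow(runs$da$frequencies), p$n_cortical * p$n_da_rois)
  expect_equal(nrow(runs$ach$frequencies), p$n_cortical * p$n_ach_rois)
  expect_equal(nrow(runs$combined$frequencies),
               p$n_cortical * (p$n_da_rois + p$n_ach_rois))
})
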