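# Stability selection: repeated stratified subsampling of a cross-validated
# L1-penalized logistic model; an edge's selection frequency is the fraction
# of resamples in which its coefficient is nonzero at the CV-chosen penalty.
# The penalized path and CV deviance are computed by glmnet; the resampling
# driver, seed derivation and frequency tallying live here.

#' Stability-selection configuration
#'
#' @param n_iter Number of resampling iterations (default 500).
#' @param subsample_fraction Per-class subsample fraction, without
#'   replacement (default 0.8; per-class size is
#'   `floor(fraction * class_size)`).
#' @param stratified Draw the subsample per class (default `TRUE`).
#' @param cv_folds Folds of the inner cross-validation (default 10).
#' @param frequency_threshold Selection-frequency cutoff declaring an edge
#'   discriminating (default 0.60).
#' @param lambda_grid_size Number of penalty values (default 100,
#'   log-spaced from the all-zero penalty `lambda_max` downwards).
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.001).
#' @param standardize Standardize features within each training subsample
#'   (default `TRUE`).
#' @param seed Master seed; per-iteration seeds are derived from it
#'   deterministically (see [stability_select()]).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_iter = 500L,
                             subsample_fraction = 0.8,
                             stratified = TRUE,
                             cv_folds = 10L,
                             frequency_threshold = 0.60,
                             lambda_grid_size = 100L,
                             lambda_min_ratio = 0.001,
                             standardize = TRUE,
                             seed = 1L) {
  cfg <- list(
    n_iter = check_count(n_iter, "n_iter"),
    subsample_fraction = check_prob(subsample_fraction, "subsample_fraction"),
    stratified = isTRUE(stratified),
    cv_folds = check_count(cv_folds, "cv_folds", min = 2L),
    frequency_threshold = check_prob(frequency_threshold, "frequency_threshold",
                                     0, 1, open_hi = FALSE),
    lambda_grid_size = check_count(lambda_grid_size, "lambda_grid_size", min = 2L),
    lambda_min_ratio = check_prob(lambda_min_ratio, "lambda_min_ratio"),
    standardize = isTRUE(standardize),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "selection_config")
}

#' Stratified subsample without replacement
#'
#' Draws `floor(fraction * class_size)` indices per class, without
#' replacement, and returns their union.
#'
#' @param labels Two-class vector (factor or character), each class with
#'   at least 2 members.
#' @param fraction Sampling fraction in (0, 1).
#' @param seed Optional seed for this draw.
#' @return Sorted integer index vector into `labels`, without duplicates.
#' @examples
#' idx <- stratified_subsample(rep(c("a", "b"), c(24, 28)), 0.8, seed = 1)
#' length(idx)  # 19 + 22 = 41
#' @export
stratified_subsample <- function(labels, fraction, seed = NULL) {
  fraction <- check_prob(fraction, "fraction")
  classes <- unique(labels)
  if (length(classes) != 2L) abort_data("`labels` must contain exactly 2 classes")
  if (any(table(labels) < 2L)) abort_data("each class needs at least 2 members")
  with_seed_(seed, {
    idx <- unlist(lapply(classes, function(cl) {
      pool <- which(labels == cl)
      n_take <- floor(fraction * length(pool))
      if (n_take < 2L) {
        abort_data(sprintf("subsample leaves class '%s' with fewer than 2 members", cl))
      }
      sample(pool, n_take)
    }), use.names = FALSE)
    sort(idx)
  })
}

# glmnet-convention lambda grid: lambda_max is the smallest penalty with an
# all-zero slope solution (closed form from the standardized score at the
# null model), then lambda_grid_size log-spaced values down to
# lambda_min_ratio * lambda_max.
lambda_grid <- function(X, y, size = 100L, min_ratio = 0.001, standardize = TRUE) {
  n <- nrow(X)
  yc <- y - mean(y)
  Xs <- if (standardize) {
    sds <- apply(X, 2L, function(v) sqrt(mean((v - mean(v))^2)))
    sds[sds == 0] <- Inf # constant features contribute nothing
    scale(X, center = TRUE, scale = sds)
  } else {
    X
  }
  lmax <- max(abs(crossprod(Xs, yc))) / n
  if (!is.finite(lmax) || lmax <= 0) abort_numeric("cannot compute lambda_max (degenerate design)")
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = size))
}

#' L1-penalized logistic regression path
#'
#' Coefficients of the lasso-penalized logistic model (unpenalized
#' intercept) along a descending penalty grid, computed by coordinate
#' descent ([glmnet::glmnet()]).  At penalties at or above `lambda_max` all
#' slopes are exactly zero; as the penalty approaches zero the fit
#' approaches the unpenalized maximum-likelihood solution.
#'
#' @param X Numeric matrix, subjects x features (no missing values).
#' @param y Binary response (0/1, logical, or two-level factor).
#' @param lambdas Descending penalty grid; defaults to the glmnet-convention
#'   grid (see [selection_config()]).
#' @param standardize Standardize features internally (training statistics
#'   only); coefficients are always returned on the original scale.
#' @return A list with `lambda` (the grid), `beta` (features x lambdas
#'   coefficient matrix) and `a0` (intercepts).
#' @export
penalized_logistic_path <- function(X, y, lambdas = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as_binary(y)
  if (length(unique(y)) < 2L) abort_data("response has a single class")
  if (anyNA(X)) abort_data("missing values in feature matrix")
  sds <- apply(X, 2L, stats::sd)
  if (standardize && any(sds == 0)) {
    rlang::warn(sprintf("dropping constant feature(s) with zero scale: %s",
                        paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  if (is.null(lambdas)) lambdas <- lambda_grid(X, y, standardize = standardize)
  pad <- pad_single(X)
  fit <- glmnet::glmnet(pad$X, y, family = "binomial", alpha = 1, lambda = lambdas,
                        standardize = standardize, thresh = 1e-10, maxit = 1e6)
  beta <- as.matrix(fit$beta)
  if (pad$padded) beta <- beta[1L, , drop = FALSE]
  beta[abs(beta) < 1e-8] <- 0 # coordinate-descent dust is not a selection
  # glmnet may stop early on degenerate grids; pad with the last solution
  if (ncol(beta) < length(lambdas)) {
    pad <- length(lambdas) - ncol(beta)
    beta <- cbind(beta, beta[, rep(ncol(beta), pad), drop = FALSE])
    a0 <- c(fit$a0, rep(fit$a0[length(fit$a0)], pad))
  } else {
    a0 <- fit$a0
  }
  list(lambda = lambdas, beta = beta, a0 = unname(a0))
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) y <- as.integer(factor(y)) - 1L
  if (!all(y %in% c(0L, 1L))) abort_data("`y` must be binary")
  y
}

# glmnet requires >= 2 feature columns; a single-feature problem is padded
# with an all-zero dummy whose coefficient is always zero and is dropped
# from every result.
pad_single <- function(X) {
  if (ncol(X) >= 2L) return(list(X = X, padded = FALSE))
  Xp <- cbind(X, 0)
  colnames(Xp) <- c(colnames(X), ".pad")
  list(X = Xp, padded = TRUE)
}

# glmnet emits advisory warnings on small classes/folds that are routine at
# subsample sizes; muffle those two, let anything else through.
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    msg <- conditionMessage(w)
    if (grepl("fewer than 8\\s+observations|grouped=FALSE enforced", msg)) {
      invokeRestart("muffleWarning")
    }
  })
}

# Stratified fold ids; redraws (up to 10 times) if some fold misses a class.
stratified_folds <- function(y, folds) {
  for (attempt in 1:10) {
    fid <- integer(length(y))
    for (cl in unique(y)) {
      members <- which(y == cl)
      fid[members] <- sample(rep_len(seq_len(folds), length(members)))
    }
    ok <- all(vapply(seq_len(folds), function(f) length(unique(y[fid == f])) == 2L, logical(1)))
    if (ok) return(fid)
  }
  abort_data("could not build stratified folds with both classes in every fold")
}

#' Choose the penalty by cross-validated deviance
#'
#' Stratified k-fold cross-validation of the penalized logistic path; the
#' returned penalty minimizes the mean held-out binomial deviance
#' (the "lambda.min" convention).  Fold assignment is seeded, so the choice
#' is deterministic given the seed.
#'
#' @inheritParams penalized_logistic_path
#' @param folds Number of folds (each must contain both classes; folds are
#'   redrawn up to 10 times otherwise).
#' @param seed Optional seed for the fold assignment.
#' @return The chosen penalty (a value of the grid).
#' @export
choose_lambda_cv <- function(X, y, folds = 10L, lambdas = NULL, seed = NULL,
                             standardize = TRUE) {
  X <- as.matrix(X)
  y <- as_binary(y)
  folds <- check_count(folds, "folds", min = 2L)
  if (min(table(y)) < folds) folds <- max(2L, min(table(y)))
  if (is.null(lambdas)) lambdas <- lambda_grid(X, y, standardize = standardize)
  with_seed_(seed, {
    fid <- stratified_folds(y, folds)
    cv <- quiet_glmnet(
      glmnet::cv.glmnet(pad_single(X)$X, y, family = "binomial", alpha = 1,
                        lambda = lambdas, foldid = fid,
                        type.measure = "deviance", standardize = standardize)
    )
    cv$lambda.min
  })
}

#' Stability selection of discriminating edges
#'
#' Runs `n_iter` iterations of: stratified subsample of the patients ->
#' inner cross-validated penalty choice -> L1-penalized logistic fit of
#' group on edge reactivities -> record which edges have nonzero
#' coefficients.  An edge's selection frequency is the fraction of
#' iterations in which it was chosen; edges at or above
#' `frequency_threshold` form the selected set.
#'
#' Per-iteration seeds are drawn once from the master seed
#' (`sample.int(.Machine$integer.max, n_iter)` under `config$seed`), so
#' results are bitwise reproducible and single iterations can be re-run in
#' isolation.
#'
#' @param reactivity Reactivity tibble from [reactivity_table()], patients
#'   only (inner join with `groups` restricts it).
#' @param groups Data frame with `subject_id` and `group` (two levels),
#'   e.g. from [median_split()].
#' @param config A [selection_config()].
#' @param system Feature set: `"combined"` (all edges), `"da"`, or `"ach"`.
#' @return An object of class `stability_selection`: list with
#'   `frequencies` (tibble: `edge`, `system`, `subcortical`, `cortical`,
#'   `frequency`, `selected`), `iterations` (tibble: `iter`, `seed`,
#'   `lambda`, `n_nonzero`, `subsample` list column of subject ids),
#'   `config`, and `system`.
#' @seealso [tidy.stability_selection()], [autoplot.stability_selection()]
#' @export
stability_select <- function(reactivity, groups, config = selection_config(),
                             system = c("combined", "da", "ach")) {
  system <- match.arg(system)
  if (!inherits(config, "selection_config")) abort_config("`config` must come from selection_config()")
  groups <- dplyr::distinct(dplyr::select(groups, "subject_id", "group"))
  reactivity <- dplyr::semi_join(reactivity, groups, by = "subject_id")
  X <- reactivity_matrix(reactivity, system = system)
  y_lab <- groups$group[match(rownames(X), groups$subject_id)]
  if (anyNA(y_lab)) abort_data("group labels missing for some subjects")
  if (length(unique(y_lab)) != 2L) abort_data("`groups` must contain exactly 2 groups")
  if (any(table(y_lab) < 2L)) abort_data("each group needs at least 2 subjects")
  y <- as_binary(factor(y_lab))

  ei <- dplyr::distinct(reactivity, .data$edge, .data$system, .data$subcortical, .data$cortical)
  ei <- ei[match(colnames(X), ei$edge), ]

  iter_seeds <- seeds_from(config$seed, config$n_iter)
  counts <- numeric(ncol(X))
  iter_rows <- vector("list", config$n_iter)

  for (i in seq_len(config$n_iter)) {
    seed_i <- iter_seeds[i]
    done <- FALSE
    for (redraw in 0:5) {
      # redraws perturb the iteration seed while staying a valid integer
      seed_use <- ((seed_i - 1L + redraw) %% (.Machine$integer.max - 1L)) + 1L
      res <- tryCatch({
        with_seed_(seed_use, {
          idx <- if (config$stratified) {
            stratified_subsample(y, config$subsample_fraction)
          } else {
            sort(sample(length(y), floor(config$subsample_fraction * length(y))))
          }
          Xs <- X[idx, , drop = FALSE]
          ys <- y[idx]
          lam <- lambda_grid(Xs, ys, config$lambda_grid_size, config$lambda_min_ratio,
                             config$standardize)
          fid <- stratified_folds(ys, min(config$cv_folds, min(table(ys))))
          cv <- quiet_glmnet(
            glmnet::cv.glmnet(pad_single(Xs)$X, ys, family = "binomial", alpha = 1,
                              lambda = lam, foldid = fid,
                              type.measure = "deviance",
                              standardize = config$standardize)
          )
          nz <- abs(as.numeric(glmnet::coef.glmnet(cv, s = "lambda.min"))[-1]) > 1e-8
          nz <- nz[seq_len(ncol(Xs))]
          list(idx = idx, lambda = cv$lambda.min, nz = nz)
        })
      }, error = function(e) e)
      if (!inherits(res, "error")) { done <- TRUE; break }
    }
    if (!done) {
      abort_numeric(sprintf("iteration %d failed after 5 redraws: %s", i, conditionMessage(res)))
    }
    counts <- counts + res$nz
    iter_rows[[i]] <- tibble::tibble(
      iter = i, seed = seed_i, lambda = res$lambda, n_nonzero = sum(res$nz),
      subsample = list(rownames(X)[res$idx])
    )
  }

  freq <- counts / config$n_iter
  structure(list(
    frequencies = tibble::tibble(
      edge = colnames(X),
      system = ei$system,
      subcortical = ei$subcortical,
      cortical = ei$cortical,
      frequency = freq,
      selected = freq >= config$frequency_threshold
    ),
    iterations = dplyr::bind_rows(iter_rows),
    config = config,
    system = system
  ), class = "stability_selection")
}

#' Run the canonical selection designs
#'
#' Convenience driver mirroring the study design: dopaminergic-only (768
#' edges), cholinergic-only (384 edges), and combined (1152 edges)
#' selection runs on the same cohort.
#'
#' @inheritParams stability_select
#' @param systems Which runs to perform (default all three).
#' @return Named list of `stability_selection` objects.
#' @export
stability_select_all <- function(reactivity, groups, config = selection_config(),
                                 systems = c("da", "ach", "combined")) {
  systems <- match.arg(systems, c("da", "ach", "combined"), several.ok = TRUE)
  stats::setNames(
    lapply(systems, function(s) stability_select(reactivity, groups, config, system = s)),
    systems
  )
}

#' @export
print.stability_selection <- function(x, ...) {
  sel <- x$frequencies[x$frequencies$selected, ]
  cat(sprintf("<stability_selection> %s features: %d edges, %d iterations\n",
              x$system, nrow(x$frequencies), x$config$n_iter))
  cat(sprintf("  threshold %.2f: %d edge(s) selected\n",
              x$config$frequency_threshold, nrow(sel)))
  if (nrow(sel)) {
    top <- sel[order(-sel$frequency), ]
    for (i in seq_len(min(5L, nrow(top)))) {
      cat(sprintf("    %s (%.1f%%)\n", top$edge[i], 100 * top$frequency[i]))
    }
  }
  invisible(x)
}

#' Tidy a stability-selection result
#'
#' @param x A `stability_selection` object.
#' @param ... Unused.
#' @return The per-edge frequency tibble, ordered by decreasing frequency.
#' @export
tidy.stability_selection <- function(x, ...) {
  dplyr::arrange(x$frequencies, dplyr::desc(.data$frequency))
}

#' Glance at a stability-selection result
#'
#' @inheritParams tidy.stability_selection
#' @return One-row tibble: feature-set name, numbers of edges and
#'   iterations, threshold, number selected, and the top frequency.
#' @export
glance.stability_selection <- function(x, ...) {
  tibble::tibble(
    system = x$system,
    n_edges = nrow(x$frequencies),
    n_iter = x$config$n_iter,
    threshold = x$config$frequency_threshold,
    n_selected = sum(x$frequencies$selected),
    max_frequency = max(x$frequencies$frequency)
  )
}

#' Plot selection frequencies
#'
#' Lollipop plot of per-edge selection frequencies with the decision
#' threshold; selected edges are labeled.
#'
#' @param object A `stability_selection` object.
#' @param top_n Show only the `top_n` highest-frequency edges (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_selection <- function(object, top_n = 40L, ...) {
  df <- tidy(object)
  df <- df[seq_len(min(top_n, nrow(df))), ]
  df$edge <- factor(df$edge, levels = rev(df$edge))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$edge,
                                   colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$frequency,
                                       yend = .data$edge), linewidth = 0.3) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_vline(xintercept = object$config$frequency_threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "#c0392b"),
                                 guide = "none") +
    ggplot2::labs(
      x = "selection frequency",
      y = NULL,
      title = sprintf("Stability selection (%s edges, %d resamples)",
                      object$system, object$config$n_iter)
    ) +
    ggplot2::theme_minimal(base_size = 9)
}
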