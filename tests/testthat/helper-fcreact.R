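# Shared fixtures, all generated in code.

# Small cohort parameters for fast structural tests.
tiny_params <- function(...) {
  defaults <- list(
    n_resistant = 8L, n_responsive = 8L, n_timepoints = 60L,
    n_cortical = 8L, n_da_rois = 2L, n_ach_rois = 2L,
    planted_edge = c("ach", "ACh01", "Cortex01"), seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# Memoized default-condition run (full-size cohort + connectivity +
# reactivity + median split), shared across test files.
.fixture_env <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.fixture_env$default)) {
    cohort <- simulate_cohort(sim_params(seed = 1L))
    connectivity <- build_connectivity(cohort)
    clin <- dplyr::rename(cohort$clinical, group_planted = group)
    groups <- median_split(clin)
    reactivity <- reactivity_table(connectivity)
    .fixture_env$default <- list(cohort = cohort, connectivity = connectivity,
                                 groups = groups, reactivity = reactivity)
  }
  .fixture_env$default
}

tiny_run <- function() {
  if (is.null(.fixture_env$tiny)) {
    cohort <- simulate_cohort(tiny_params())
    connectivity <- build_connectivity(cohort)
    groups <- median_split(dplyr::rename(cohort$clinical, group_planted = group))
    reactivity <- reactivity_table(connectivity)
    .fixture_env$tiny <- list(cohort = cohort, connectivity = connectivity,
                              groups = groups, reactivity = reactivity)
  }
  .fixture_env$tiny
}

# Wrap an arbitrary subjects x features matrix as a reactivity table so the
# selection machinery can be exercised on constructed designs.
synthetic_reactivity <- function(X) {
  subjects <- rownames(X)
  edges <- colnames(X)
  tibble::tibble(
    subject_id = rep(subjects, times = ncol(X)),
    edge = rep(edges, each = nrow(X)),
    system = "ach",
    subcortical = "S",
    cortical = rep(edges, each = nrow(X)),
    z_off = 1, z_on = 1,
    reactivity = as.vector(X),
    denom_floored = FALSE
  )
}

# One-factor covariance: corr(i, j) = loading_i * loading_j; always PD.
factor_cov <- function(loadings) {
  S <- outer(loadings, loadings)
  diag(S) <- 1
  S
}
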