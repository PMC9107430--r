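# Synthetic cohort generator: levodopa-challenge study with two patient
# groups (dopamine-resistant / dopamine-responsive tremor), optional normal
# controls, and one planted subcortico-cortical edge whose ON-session
# connectivity drops only in the responsive group.

#' Simulation parameters for a synthetic levodopa-challenge cohort
#'
#' Defaults encode the study design the pipeline targets: 24 dopamine-
#' resistant and 28 dopamine-responsive tremor patients, 96 cortical + 8
#' dopaminergic + 4 cholinergic ROIs, 200 volumes per session, a cholinergic
#' planted edge (`R.BF123-R.PO`) with OFF correlation 0.16 in both groups
#' and ON correlation 0.17 (resistant) vs 0.01 (responsive), and tremor
#' change rates centred at 0.27 (resistant) vs 0.92 (responsive).
#'
#' @param n_resistant,n_responsive Patients per tremor group (each >= 2).
#' @param n_controls Normal controls (0 disables control generation).
#' @param n_timepoints Volumes per session (>= 10).
#' @param n_cortical,n_da_rois,n_ach_rois ROI counts per class.
#' @param rho_background Population correlation of every non-planted
#'   subcortico-cortical pair, strictly inside (-1, 1).  Implemented as an
#'   equicorrelation structure across all ROI pairs so the joint covariance
#'   is positive definite by construction.
#' @param planted_edge Character vector `c(system, subcortical, cortical)`
#'   naming the planted edge; system is `"da"` or `"ach"`.
#' @param rho_off Planted-edge OFF-session correlation (both groups).
#' @param rho_on_resistant,rho_on_responsive Planted-edge ON-session
#'   correlations per group.
#' @param tremor_mu_resistant,tremor_sd_resistant Target mean/sd of the
#'   resistant group's tremor change rate (Beta-matched).
#' @param tremor_mu_responsive,tremor_sd_responsive Same for the responsive
#'   group.
#' @param age_mean,age_sd,education_mean,education_sd,male_prop Covariate
#'   distribution parameters, shared by groups (matched by construction).
#' @param temporal_ar1 Optional AR(1) coefficient in `[0, 1)` for the ROI
#'   time series (0 = i.i.d. timepoints).
#' @param exclusions Named integer vector of extra recruited-but-excluded
#'   patients to plant, with names among `lacunar_infarction`,
#'   `baseline_on_status`, `no_tremor`, `no_mri`, `high_motion`.
#' @param seed Master seed; every draw in [simulate_cohort()] derives from it.
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
sim_params <- function(n_resistant = 24L,
                       n_responsive = 28L,
                       n_controls = 0L,
                       n_timepoints = 200L,
                       n_cortical = 96L,
                       n_da_rois = 8L,
                       n_ach_rois = 4L,
                       rho_background = 0.2,
                       planted_edge = c("ach", "R.BF123", "R.PO"),
                       rho_off = 0.16,
                       rho_on_resistant = 0.17,
                       rho_on_responsive = 0.01,
                       tremor_mu_resistant = 0.27,
                       tremor_sd_resistant = 0.24,
                       tremor_mu_responsive = 0.92,
                       tremor_sd_responsive = 0.13,
                       age_mean = 60, age_sd = 9,
                       education_mean = 9, education_sd = 4.4,
                       male_prop = 0.6,
                       temporal_ar1 = 0,
                       exclusions = c(lacunar_infarction = 0L, baseline_on_status = 0L,
                                      no_tremor = 0L, no_mri = 0L, high_motion = 0L),
                       seed = 1L) {
  p <- list(
    n_resistant = check_count(n_resistant, "n_resistant", min = 2L),
    n_responsive = check_count(n_responsive, "n_responsive", min = 2L),
    n_controls = check_count(n_controls, "n_controls", min = 0L),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 10L),
    n_cortical = check_count(n_cortical, "n_cortical"),
    n_da_rois = check_count(n_da_rois, "n_da_rois"),
    n_ach_rois = check_count(n_ach_rois, "n_ach_rois"),
    rho_background = check_prob(rho_background, "rho_background", -1, 1),
    planted_edge = planted_edge,
    rho_off = check_prob(rho_off, "rho_off", -1, 1),
    rho_on_resistant = check_prob(rho_on_resistant, "rho_on_resistant", -1, 1),
    rho_on_responsive = check_prob(rho_on_responsive, "rho_on_responsive", -1, 1),
    tremor_mu_resistant = check_prob(tremor_mu_resistant, "tremor_mu_resistant"),
    tremor_sd_resistant = check_prob(tremor_sd_resistant, "tremor_sd_resistant"),
    tremor_mu_responsive = check_prob(tremor_mu_responsive, "tremor_mu_responsive"),
    tremor_sd_responsive = check_prob(tremor_sd_responsive, "tremor_sd_responsive"),
    age_mean = age_mean, age_sd = age_sd,
    education_mean = education_mean, education_sd = education_sd,
    male_prop = check_prob(male_prop, "male_prop", 0, 1, open_lo = FALSE, open_hi = FALSE),
    temporal_ar1 = check_prob(temporal_ar1, "temporal_ar1", 0, 1, open_lo = FALSE),
    exclusions = normalize_exclusions(exclusions),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.character(p$planted_edge) || length(p$planted_edge) != 3L ||
      !p$planted_edge[1] %in% c("da", "ach")) {
    abort_config("`planted_edge` must be c(system, subcortical, cortical) with system 'da' or 'ach'")
  }
  # moment-matching must be feasible up front
  beta_moments(p$tremor_mu_resistant, p$tremor_sd_resistant)
  beta_moments(p$tremor_mu_responsive, p$tremor_sd_responsive)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  patients: %d resistant + %d responsive; controls: %d\n",
              x$n_resistant, x$n_responsive, x$n_controls))
  cat(sprintf("  ROIs: %d cortical, %d dopaminergic, %d cholinergic; T = %d, AR(1) = %g\n",
              x$n_cortical, x$n_da_rois, x$n_ach_rois, x$n_timepoints, x$temporal_ar1))
  cat(sprintf("  planted %s edge %s-%s: rho OFF %g, ON %g (resistant) / %g (responsive)\n",
              x$planted_edge[1], x$planted_edge[2], x$planted_edge[3],
              x$rho_off, x$rho_on_resistant, x$rho_on_responsive))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

normalize_exclusions <- function(x) {
  keys <- c("lacunar_infarction", "baseline_on_status", "no_tremor", "no_mri", "high_motion")
  out <- stats::setNames(integer(5L), keys)
  if (length(x)) {
    if (is.null(names(x)) || !all(names(x) %in% keys)) {
      abort_config(sprintf("`exclusions` must be named among: %s", paste(keys, collapse = ", ")))
    }
    out[names(x)] <- vapply(x, function(v) check_count(v, "exclusions", min = 0L), integer(1))
  }
  out
}

# Equicorrelation covariance with one overridden (planted) entry.  If the
# planted override pushes the matrix off the positive-definite cone the
# background correlation is shrunk (x0.9, up to 20 times); a still-failing
# matrix is rejected naming the offending pair.
build_roi_cov <- function(roi, rho_background, planted_idx = NULL, rho_planted = NULL) {
  p <- nrow(roi)
  shrink <- 0L
  rho <- rho_background
  repeat {
    sigma <- matrix(rho, p, p)
    diag(sigma) <- 1
    if (!is.null(planted_idx)) {
      sigma[planted_idx[1], planted_idx[2]] <- rho_planted
      sigma[planted_idx[2], planted_idx[1]] <- rho_planted
    }
    ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min > 1e-8) return(sigma)
    shrink <- shrink + 1L
    rho <- rho * 0.9
    if (shrink > 20L) {
      pair <- if (is.null(planted_idx)) "background structure" else {
        paste(roi$label[planted_idx], collapse = " - ")
      }
      abort_numeric(sprintf(
        "ROI covariance is not positive definite even after rescaling background correlations (offending pair: %s; smallest eigenvalue %.3g)",
        pair, ev_min
      ))
    }
  }
}

#' Draw a multivariate Gaussian time-series matrix
#'
#' Rows are timepoints drawn from a zero-mean Gaussian with the given
#' cross-ROI covariance.  With `ar1 > 0` each ROI additionally carries
#' stationary AR(1) temporal structure (`x_t = ar1 * x_{t-1} +
#' sqrt(1 - ar1^2) * e_t`), which leaves the cross-sectional covariance
#' target unchanged.  The same seed reuses the same innovations, so `ar1`
#' changes only the temporal structure, not the underlying draws.
#'
#' @param cov Positive-definite covariance matrix (ROIs x ROIs).
#' @param n_timepoints Number of rows to draw.
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param seed Optional seed for this draw.
#' @return A `n_timepoints` x `ncol(cov)` numeric matrix.
#' @examples
#' x <- sample_correlated_series(diag(3), 100, seed = 1)
#' @export
sample_correlated_series <- function(cov, n_timepoints, ar1 = 0, seed = NULL) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov)) abort_config("`cov` must be a square matrix")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  ar1 <- check_prob(ar1, "ar1", 0, 1, open_lo = FALSE)
  ch <- tryCatch(chol(cov), error = function(e) {
    ev <- min(eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    abort_numeric(sprintf(
      "Cholesky factorization failed: covariance is not positive definite (smallest eigenvalue %.3g)", ev
    ))
  })
  p <- ncol(cov)
  with_seed_(seed, {
    e <- matrix(stats::rnorm(n_timepoints * p), n_timepoints, p) %*% ch
    if (ar1 > 0) {
      x <- e
      scale <- sqrt(1 - ar1^2)
      for (t in 2:n_timepoints) x[t, ] <- ar1 * x[t - 1L, ] + scale * e[t, ]
      x
    } else {
      e
    }
  })
}

#' Generate a synthetic levodopa-challenge cohort
#'
#' Produces clinical records and OFF/ON ROI time series with the structure
#' the downstream pipeline assumes: equal planted-edge connectivity across
#' groups in the OFF session, a group-specific planted-edge correlation in
#' the ON session, group-specific tremor change rates, and demographically
#' matched covariates.  Controls (if requested) share the OFF covariance in
#' both sessions.  Planted exclusions (see [sim_params()]) add recruited
#' patients that carry exclusion flags and no imaging.
#'
#' Identical parameters (including `seed`) reproduce the cohort bitwise.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `fc_cohort`: a list with
#'   \describe{
#'     \item{clinical}{tibble of per-subject clinical records (covariates,
#'       UPDRS-III totals and sub-scores OFF/ON, tremor responsiveness,
#'       group label, exclusion flags).}
#'     \item{timeseries}{tibble with columns `subject_id`, `session`
#'       (`"OFF"`/`"ON"`) and `ts` (list column of timepoints x ROIs
#'       matrices with ROI labels as column names).}
#'     \item{roi}{ROI partition tibble.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' co <- simulate_cohort(sim_params(n_resistant = 3, n_responsive = 3,
#'                                  n_timepoints = 30, n_cortical = 6,
#'                                  n_da_rois = 2, n_ach_rois = 2,
#'                                  planted_edge = c("ach", "ACh01", "Cortex01"),
#'                                  seed = 7))
#' co$clinical
#' @export
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) abort_config("`params` must come from sim_params()")
  roi <- roi_partition(params$n_cortical, params$n_da_rois, params$n_ach_rois)
  planted_idx <- resolve_planted_edge(roi, params$planted_edge)

  cov_off <- build_roi_cov(roi, params$rho_background, planted_idx, params$rho_off)
  cov_on_res <- build_roi_cov(roi, params$rho_background, planted_idx, params$rho_on_resistant)
  cov_on_resp <- build_roi_cov(roi, params$rho_background, planted_idx, params$rho_on_responsive)

  with_seed_(params$seed, {
    clinical <- simulate_clinical(params)
    analyzable <- clinical$subject_id[clinical$cohort == "patient" & !clinical$excluded_any]
    controls <- clinical$subject_id[clinical$cohort == "control"]
    need_ts <- c(analyzable, controls)
    ts_seeds <- matrix(sample.int(.Machine$integer.max, 2L * length(need_ts)), ncol = 2L)

    rows <- purrr::imap(need_ts, function(sid, i) {
      grp <- clinical$group[clinical$subject_id == sid]
      cov_on <- switch(grp,
        resistant = cov_on_res,
        responsive = cov_on_resp,
        cov_off # controls: no session effect
      )
      list(
        tibble::tibble(subject_id = sid, session = "OFF",
          ts = list(label_ts(sample_correlated_series(cov_off, params$n_timepoints,
                                                      params$temporal_ar1, ts_seeds[i, 1]), roi))),
        tibble::tibble(subject_id = sid, session = "ON",
          ts = list(label_ts(sample_correlated_series(cov_on, params$n_timepoints,
                                                      params$temporal_ar1, ts_seeds[i, 2]), roi)))
      )
    })
    timeseries <- dplyr::bind_rows(purrr::flatten(rows))

    structure(
      list(clinical = clinical, timeseries = timeseries, roi = roi, params = params),
      class = "fc_cohort"
    )
  })
}

label_ts <- function(x, roi) {
  colnames(x) <- roi$label
  x
}

resolve_planted_edge <- function(roi, planted_edge) {
  cls <- if (planted_edge[1] == "da") "dopaminergic" else "cholinergic"
  sub_i <- which(roi$label == planted_edge[2] & roi$class == cls)
  cort_i <- which(roi$label == planted_edge[3] & roi$class == "cortical")
  if (length(sub_i) != 1L || length(cort_i) != 1L) {
    abort_config(sprintf(
      "planted edge %s-%s (%s) does not match the ROI set",
      planted_edge[2], planted_edge[3], planted_edge[1]
    ))
  }
  c(cort_i, sub_i)
}

# Clinical record generation.  Covariates are drawn from one shared
# distribution (groups matched by construction); tremor change rates come
# from group-specific moment-matched Beta distributions; other sub-scores
# improve with group-independent Beta change rates.
simulate_clinical <- function(params) {
  n_res <- params$n_resistant
  n_resp <- params$n_responsive
  n_excl <- params$exclusions
  n_pat <- n_res + n_resp + sum(n_excl)
  n_all <- n_pat + params$n_controls

  group <- c(rep("resistant", n_res), rep("responsive", n_resp),
             rep("unassigned", sum(n_excl)), rep("control", params$n_controls))
  cohort <- c(rep("patient", n_pat), rep("control", params$n_controls))

  flags <- matrix(FALSE, n_all, 5L,
                  dimnames = list(NULL, names(n_excl)))
  at <- n_res + n_resp
  for (k in names(n_excl)) {
    if (n_excl[[k]] > 0L) {
      flags[at + seq_len(n_excl[[k]]), k] <- TRUE
      at <- at + n_excl[[k]]
    }
  }

  age <- round(stats::rnorm(n_all, params$age_mean, params$age_sd), 1)
  gender <- ifelse(stats::runif(n_all) < params$male_prop, "M", "F")
  education <- pmax(0, round(stats::rnorm(n_all, params$education_mean, params$education_sd)))
  duration <- ifelse(cohort == "patient",
                     round(stats::rgamma(n_all, shape = 1.8, rate = 0.384), 1), NA_real_)
  led <- ifelse(cohort == "patient",
                round(stats::rgamma(n_all, shape = 1.52, rate = 0.0032)), NA_real_)

  tremor_off <- pmax(1, round(stats::rnorm(n_all, 4, 3)))
  bm_res <- beta_moments(params$tremor_mu_resistant, params$tremor_sd_resistant)
  bm_resp <- beta_moments(params$tremor_mu_responsive, params$tremor_sd_responsive)
  change <- numeric(n_all)
  change[group == "resistant"] <- stats::rbeta(n_res, bm_res[1], bm_res[2])
  change[group == "responsive"] <- stats::rbeta(n_resp, bm_resp[1], bm_resp[2])
  change[!group %in% c("resistant", "responsive")] <-
    stats::rbeta(sum(!group %in% c("resistant", "responsive")), bm_res[1], bm_res[2])
  change <- pmin(pmax(change, 0), 1)
  tremor_on <- pmax(0, round(tremor_off * (1 - change)))

  rigidity_off <- pmax(0, round(stats::rnorm(n_all, 5.4, 4.3)))
  brady_off <- pmax(0, round(stats::rnorm(n_all, 9, 6.9)))
  other_off <- pmax(0, round(stats::rnorm(n_all, 4, 3)))
  bm_rig <- beta_moments(0.40, 0.20)
  bm_brady <- beta_moments(0.35, 0.18)
  bm_other <- beta_moments(0.30, 0.15)
  rigidity_on <- pmax(0, round(rigidity_off * (1 - stats::rbeta(n_all, bm_rig[1], bm_rig[2]))))
  brady_on <- pmax(0, round(brady_off * (1 - stats::rbeta(n_all, bm_brady[1], bm_brady[2]))))
  other_on <- pmax(0, round(other_off * (1 - stats::rbeta(n_all, bm_other[1], bm_other[2]))))

  # planted "no tremor" subjects have no baseline tremor by definition
  tremor_off[flags[, "no_tremor"]] <- 0L
  tremor_on[flags[, "no_tremor"]] <- 0L

  is_pat <- cohort == "patient"
  updrs3_off <- ifelse(is_pat, tremor_off + rigidity_off + brady_off + other_off, NA_integer_)
  updrs3_on <- ifelse(is_pat, tremor_on + rigidity_on + brady_on + other_on, NA_integer_)

  responsiveness <- ifelse(is_pat & tremor_off > 0,
                           (tremor_off - tremor_on) / tremor_off, NA_real_)

  tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n_all)),
    cohort = cohort,
    group = group,
    age = age,
    gender = gender,
    education = as.numeric(education),
    disease_duration = duration,
    led = led,
    updrs3_off = as.integer(ifelse(is_pat, updrs3_off, NA)),
    updrs3_on = as.integer(ifelse(is_pat, updrs3_on, NA)),
    tremor_off = as.integer(ifelse(is_pat, tremor_off, NA)),
    tremor_on = as.integer(ifelse(is_pat, tremor_on, NA)),
    rigidity_off = as.integer(ifelse(is_pat, rigidity_off, NA)),
    rigidity_on = as.integer(ifelse(is_pat, rigidity_on, NA)),
    bradykinesia_off = as.integer(ifelse(is_pat, brady_off, NA)),
    bradykinesia_on = as.integer(ifelse(is_pat, brady_on, NA)),
    tremor_responsiveness = responsiveness,
    lacunar_infarction = flags[, "lacunar_infarction"],
    baseline_on_status = flags[, "baseline_on_status"],
    no_tremor = flags[, "no_tremor"],
    no_mri = flags[, "no_mri"],
    high_motion = flags[, "high_motion"],
    excluded_any = rowSums(flags) > 0
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  cl <- x$clinical
  cat("<fc_cohort>\n")
  cat(sprintf("  %d subjects (%d patients, %d controls), %d with imaging\n",
              nrow(cl), sum(cl$cohort == "patient"), sum(cl$cohort == "control"),
              length(unique(x$timeseries$subject_id))))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(cl$group)), table(cl$group)), collapse = ", ")))
  cat(sprintf("  ROIs: %d (%s)\n", nrow(x$roi),
              paste(sprintf("%s=%d", names(table(x$roi$class)), table(x$roi$class)), collapse = ", ")))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes one `<subject>_<session>_ts.tsv` per
#' subject-session (header = ROI labels, rows = timepoints),
#' `participants.csv` (clinical records), `roi_partition.tsv` and a
#' `sim_params.json` sidecar.  `read_cohort()` reads the same layout back
#' into an `fc_cohort`.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` an
#'   `fc_cohort` (with `params = NULL` if no sidecar is present).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$clinical, file.path(dir, "participants.csv"))
  readr::write_tsv(cohort$roi, file.path(dir, "roi_partition.tsv"))
  purrr::pwalk(cohort$timeseries, function(subject_id, session, ts) {
    df <- tibble::as_tibble(ts, .name_repair = "minimal")
    readr::write_tsv(df, file.path(dir, sprintf("%s_%s_ts.tsv", subject_id, session)))
  })
  if (!is.null(cohort$params)) {
    jsonlite::write_json(unclass(cohort$params), file.path(dir, "sim_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "participants.csv")
  rfile <- file.path(dir, "roi_partition.tsv")
  if (!file.exists(pfile) || !file.exists(rfile)) {
    abort_data(sprintf("`%s` does not contain participants.csv and roi_partition.tsv", dir))
  }
  clinical <- readr::read_csv(pfile, show_col_types = FALSE)
  roi <- readr::read_tsv(rfile, show_col_types = FALSE)
  validate_roi(roi)
  files <- sort(list.files(dir, pattern = "_(OFF|ON)_ts\\.tsv$"))
  timeseries <- purrr::map_dfr(files, function(f) {
    m <- regmatches(f, regexec("^(.*)_(OFF|ON)_ts\\.tsv$", f))[[1]]
    ts <- as.matrix(readr::read_tsv(file.path(dir, f), show_col_types = FALSE))
    if (!identical(colnames(ts), roi$label)) {
      abort_data(sprintf("ROI columns of %s do not match roi_partition.tsv", f))
    }
    tibble::tibble(subject_id = m[2], session = m[3], ts = list(ts))
  })
  params <- NULL
  jfile <- file.path(dir, "sim_params.json")
  if (file.exists(jfile)) {
    pj <- jsonlite::read_json(jfile, simplifyVector = TRUE)
    params <- tryCatch(
      do.call(sim_params, pj[setdiff(names(pj), character())]),
      error = function(e) NULL
    )
  }
  structure(list(clinical = clinical, timeseries = timeseries, roi = roi, params = params),
            class = "fc_cohort")
}
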