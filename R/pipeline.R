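# End-to-end orchestration: simulate/load -> subject filters ->
# connectivity -> reactivity + median split -> stability selection ->
# group statistics; deterministic under one master seed, with a file
# bundle and manifest for reproduction.

#' Pipeline configuration
#'
#' @param input_dir Directory with an existing cohort (layout of
#'   [write_cohort()]); `NULL` simulates in place from `sim`.
#' @param sim [sim_params()] used when simulating (its seed is replaced by
#'   a stream derived from `seed`).
#' @param selection [selection_config()] for the feature-selection stage
#'   (its seed is likewise derived from `seed`).
#' @param systems Feature sets to run selection on (subset of
#'   `c("da", "ach", "combined")`).
#' @param out_dir Where to write the result bundle (`NULL`: no files).
#' @param seed Master seed; the simulation and selection streams are
#'   derived from it deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            sim = sim_params(),
                            selection = selection_config(),
                            systems = c("da", "ach", "combined"),
                            out_dir = NULL,
                            seed = 1L) {
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort_config(sprintf("input_dir `%s` does not exist", input_dir))
  }
  if (!inherits(sim, "sim_params")) abort_config("`sim` must come from sim_params()")
  if (!inherits(selection, "selection_config")) {
    abort_config("`selection` must come from selection_config()")
  }
  systems <- match.arg(systems, c("da", "ach", "combined"), several.ok = TRUE)
  structure(list(input_dir = input_dir, sim = sim, selection = selection,
                 systems = systems, out_dir = out_dir,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

#' Apply the subject-flow exclusion filters
#'
#' Filters patients in the study's recruitment order: lacunar infarction,
#' ON-medication status at baseline, no baseline tremor (OFF tremor score
#' 0), refused MRI, high head motion.  Controls pass through untouched.
#'
#' @param clinical Clinical tibble; exclusion flag columns
#'   (`lacunar_infarction`, `baseline_on_status`, `no_tremor`, `no_mri`,
#'   `high_motion`) are honored when present, and `no_tremor` is also
#'   derived from `tremor_off == 0`.
#' @return List with `clinical` (the filtered tibble) and `log`, a tibble
#'   of `(filter, n_before, n_removed, n_after, removed)` whose arithmetic
#'   chains end to end.  Errors if fewer than 4 patients remain.
#' @export
apply_subject_filters <- function(clinical) {
  is_pat <- clinical$cohort == "patient"
  keep <- rep(TRUE, nrow(clinical))
  steps <- list(
    lacunar_infarction = function(d) isTRUE_col(d, "lacunar_infarction"),
    baseline_on_status = function(d) isTRUE_col(d, "baseline_on_status"),
    no_tremor = function(d) {
      isTRUE_col(d, "no_tremor") |
        (!is.na(d$tremor_off) & d$tremor_off == 0)
    },
    no_mri = function(d) isTRUE_col(d, "no_mri"),
    high_motion = function(d) isTRUE_col(d, "high_motion")
  )
  log_rows <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    n_before <- sum(keep & is_pat)
    hit <- steps[[i]](clinical) & keep & is_pat
    keep <- keep & !hit
    log_rows[[i]] <- tibble::tibble(
      filter = names(steps)[i],
      n_before = n_before,
      n_removed = sum(hit),
      n_after = n_before - sum(hit),
      removed = paste(clinical$subject_id[hit], collapse = ";")
    )
  }
  out <- clinical[keep, ]
  if (sum(out$cohort == "patient") < 4L) {
    abort_data("fewer than 4 analyzable patients remain after exclusion filters")
  }
  list(clinical = out, log = dplyr::bind_rows(log_rows))
}

isTRUE_col <- function(d, col) {
  if (col %in% names(d)) !is.na(d[[col]]) & d[[col]] else rep(FALSE, nrow(d))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, applies the exclusion filters, builds
#' connectivity, computes reactivity and tremor responsiveness, splits the
#' patients at the cohort median, runs stability selection per requested
#' feature set, and produces the downstream statistics.  Reruns with an
#' identical configuration reproduce every output bitwise.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list): `clinical`, `exclusion_log`,
#'   `connectivity`, `reactivity`, `groups`, `selection` (named list of
#'   `stability_selection` objects), `stats` (list of test-result tibbles),
#'   and `manifest`.  If `config$out_dir` is set the bundle is also written
#'   there as CSV/JSON plus `manifest.json` with per-file checksums.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) abort_config("`config` must come from pipeline_config()")
  derived <- seeds_from(config$seed, 2L)
  stage <- "simulate"
  on_fail <- function(e) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
    }
    rlang::abort(sprintf("pipeline failed at stage `%s`: %s", stage, conditionMessage(e)),
                 parent = e, class = class(e)[1])
  }
  withCallingHandlers({
    cohort <- if (is.null(config$input_dir)) {
      sim <- config$sim
      sim$seed <- derived[1]
      simulate_cohort(sim)
    } else {
      read_cohort(config$input_dir)
    }

    stage <- "subject_filters"
    flt <- apply_subject_filters(cohort$clinical)
    clinical <- flt$clinical
    cohort$timeseries <- dplyr::semi_join(cohort$timeseries,
                                          clinical["subject_id"], by = "subject_id")

    stage <- "connectivity"
    connectivity <- build_connectivity(cohort)

    stage <- "reactivity"
    patients <- dplyr::filter(clinical, .data$cohort == "patient")
    patients$tremor_responsiveness <-
      tremor_responsiveness(patients$tremor_off, patients$tremor_on)
    if ("group" %in% names(patients)) {
      patients <- dplyr::rename(patients, group_planted = "group")
    }
    groups <- median_split(patients) |>
      dplyr::select("subject_id", "tremor_responsiveness", "group", "cohort_median")
    pat_conn <- dplyr::semi_join(connectivity, groups["subject_id"], by = "subject_id")
    reactivity <- reactivity_table(pat_conn)

    stage <- "selection"
    sel_cfg <- config$selection
    sel_cfg$seed <- derived[2]
    selection <- stability_select_all(reactivity, groups, sel_cfg,
                                      systems = config$systems)

    stage <- "stats"
    stats_out <- pipeline_stats(clinical, connectivity, reactivity, groups, selection)

    manifest <- list(
      package = "fcreact",
      version = as.character(utils::packageVersion("fcreact")),
      seed = config$seed,
      derived_seeds = list(simulation = derived[1], selection = derived[2]),
      systems = config$systems,
      sim_params = if (is.null(config$input_dir)) unclass(config$sim) else NULL,
      input_dir = config$input_dir,
      selection_config = unclass(sel_cfg)
    )

    bundle <- list(clinical = clinical, exclusion_log = flt$log,
                   connectivity = connectivity, reactivity = reactivity,
                   groups = groups, selection = selection, stats = stats_out,
                   manifest = manifest)
    if (!is.null(config$out_dir)) {
      stage <- "write"
      write_bundle(bundle, config$out_dir)
    }
    bundle
  }, error = on_fail)
}

# Downstream statistics of the study design on whatever the selection
# found: reactivity group comparisons for selected edges, OFF/ON FC
# comparisons, paired tests, interaction, partial correlation with tremor
# responsiveness, demographics, and (with controls) network summaries.
pipeline_stats <- function(clinical, connectivity, reactivity, groups, selection) {
  out <- list()
  covars <- c("age", "gender", "education")
  clinical <- dplyr::select(clinical,
                            -dplyr::any_of(c("group", "group_planted",
                                             "tremor_responsiveness", "cohort_median")))
  pats <- dplyr::inner_join(groups, clinical, by = "subject_id")

  out$demographics <- dplyr::bind_rows(
    demographic_comparison(pats, "age", kind = "continuous"),
    demographic_comparison(pats, "gender", kind = "categorical"),
    demographic_comparison(pats, "education", kind = "continuous"),
    demographic_comparison(pats, "updrs3_off", kind = "continuous"),
    demographic_comparison(pats, "tremor_responsiveness", kind = "continuous")
  )

  selected <- unique(unlist(lapply(selection, function(s) {
    s$frequencies$edge[s$frequencies$selected]
  })))
  m_sel <- max(1L, length(selected))

  if (length(selected)) {
    react_sel <- dplyr::filter(reactivity, .data$edge %in% selected) |>
      dplyr::inner_join(pats, by = "subject_id")
    out$reactivity_comparisons <- purrr::map_dfr(selected, function(e) {
      dplyr::mutate(
        adjusted_group_comparison(dplyr::filter(react_sel, .data$edge == e),
                                  "reactivity", covariates = covars, m = m_sel),
        edge = e, .before = 1L
      )
    })

    conn_sel <- dplyr::filter(connectivity, .data$edge %in% selected) |>
      dplyr::inner_join(pats, by = "subject_id")
    out$fc_comparisons <- purrr::map_dfr(selected, function(e) {
      de <- dplyr::filter(conn_sel, .data$edge == e)
      per_session <- purrr::map_dfr(sort(unique(de$session)), function(ss) {
        dplyr::mutate(
          adjusted_group_comparison(dplyr::filter(de, .data$session == ss),
                                    "z", covariates = covars),
          edge = e, session = ss, .before = 1L
        )
      })
      paired <- purrr::map_dfr(levels(factor(de$group)), function(gg) {
        dg <- dplyr::filter(de, .data$group == gg) |>
          dplyr::arrange(.data$subject_id, .data$session)
        off <- dg$z[dg$session == "OFF"][order(dg$subject_id[dg$session == "OFF"])]
        on <- dg$z[dg$session == "ON"][order(dg$subject_id[dg$session == "ON"])]
        dplyr::mutate(paired_comparison(off, on), edge = e,
                      session = sprintf("ON vs OFF (%s)", gg), .before = 1L)
      })
      dplyr::bind_rows(per_session, paired)
    })

    out$interaction <- purrr::map_dfr(selected, function(e) {
      de <- dplyr::filter(conn_sel, .data$edge == e)
      dplyr::mutate(
        mixed_interaction(de, "z", covariates = covars),
        edge = e, .before = 1L
      )
    })

    out$correlation <- purrr::map_dfr(selected, function(e) {
      dr <- dplyr::filter(react_sel, .data$edge == e)
      dplyr::mutate(
        partial_correlation(dr, "reactivity", "tremor_responsiveness",
                            covariates = covars),
        edge = e, .before = 1L
      )
    })
  }

  if (any(clinical$cohort == "control")) {
    ctrl_clin <- dplyr::bind_rows(
      dplyr::select(pats, "subject_id", "cohort", "group", "age", "gender", "education"),
      clinical |>
        dplyr::filter(.data$cohort == "control") |>
        dplyr::mutate(group = "control") |>
        dplyr::select("subject_id", "cohort", "group", "age", "gender", "education")
    )
    out$network_summary <- network_summary_report(
      connectivity, ctrl_clin,
      selected_edges = if (length(selected)) selected else NULL
    )
  }
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$clinical, file.path(out_dir, "participants.csv"))
  readr::write_csv(bundle$exclusion_log, file.path(out_dir, "exclusion_log.csv"))
  readr::write_csv(bundle$connectivity, file.path(out_dir, "connectivity.csv"))
  readr::write_csv(bundle$reactivity, file.path(out_dir, "reactivity.csv"))
  readr::write_csv(bundle$groups, file.path(out_dir, "groups.csv"))

  freq <- purrr::imap_dfr(bundle$selection, function(s, run) {
    dplyr::mutate(s$frequencies, run = run, .before = 1L)
  })
  readr::write_csv(freq, file.path(out_dir, "selection_frequencies.csv"))
  log_lines <- unlist(purrr::imap(bundle$selection, function(s, run) {
    purrr::pmap_chr(s$iterations, function(iter, seed, lambda, n_nonzero, subsample) {
      jsonlite::toJSON(list(run = run, iter = iter, seed = seed, lambda = lambda,
                            n_nonzero = n_nonzero, subsample = subsample),
                       auto_unbox = TRUE, digits = NA)
    })
  }))
  writeLines(log_lines, file.path(out_dir, "selection_log.jsonl"))

  stats_json <- lapply(bundle$stats, function(tb) {
    if (is.data.frame(tb)) unclass(as.list(tb)) else tb
  })
  jsonlite::write_json(stats_json, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(render_report(bundle), file.path(out_dir, "report.md"))

  files <- c("participants.csv", "exclusion_log.csv", "connectivity.csv",
             "reactivity.csv", "groups.csv", "selection_frequencies.csv",
             "selection_log.jsonl", "stats_report.json", "report.md")
  manifest <- bundle$manifest
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

render_report <- function(bundle) {
  sel_lines <- unlist(purrr::imap(bundle$selection, function(s, run) {
    sel <- s$frequencies[s$frequencies$selected, ]
    top <- sel[order(-sel$frequency), ]
    c(sprintf("- `%s` (%d edges, %d iterations): %d selected at >= %.0f%%",
              run, nrow(s$frequencies), s$config$n_iter, nrow(sel),
              100 * s$config$frequency_threshold),
      if (nrow(top)) sprintf("    - %s: %.1f%%", top$edge, 100 * top$frequency))
  }))
  tab <- function(tb) {
    if (is.null(tb) || !nrow(tb)) return("(none)")
    cols <- intersect(c("edge", "session", "measure", "test", "estimate",
                        "statistic", "p_value", "threshold", "significant", "branch"),
                      names(tb))
    tb <- tb[cols]
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], function(v) sprintf("%.4g", v))
    header <- paste0("| ", paste(cols, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
    body <- apply(tb, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, body)
  }
  c("# Pipeline report", "",
    sprintf("%d analyzable patients (%s), %d controls.",
            sum(bundle$clinical$cohort == "patient"),
            paste(sprintf("%s = %d", names(table(bundle$groups$group)),
                          table(bundle$groups$group)), collapse = ", "),
            sum(bundle$clinical$cohort == "control")),
    "", "## Subject flow", "", tab_log(bundle$exclusion_log),
    "", "## Stability selection", "", sel_lines,
    "", "## Demographics", "", tab(bundle$stats$demographics),
    "", "## Selected-edge reactivity comparisons", "",
    tab(bundle$stats$reactivity_comparisons),
    "", "## Selected-edge FC comparisons", "", tab(bundle$stats$fc_comparisons),
    "", "## Group x status interaction", "", tab(bundle$stats$interaction),
    "", "## Reactivity vs tremor responsiveness", "", tab(bundle$stats$correlation),
    "", "## Network summary vs controls", "", tab(bundle$stats$network_summary))
}

tab_log <- function(log) {
  header <- "| filter | n_before | n_removed | n_after |"
  sep <- "|---|---|---|---|"
  body <- sprintf("| %s | %d | %d | %d |", log$filter, log$n_before,
                  log$n_removed, log$n_after)
  c(header, sep, body)
}
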