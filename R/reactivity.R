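# Change-rate statistics: edge functional reactivity, tremor
# responsiveness, UPDRS-III sub-score composition, and the median-split
# assignment into dopamine-resistant / dopamine-responsive tremor groups.

#' Edge functional reactivity (connectivity change rate)
#'
#' `(z_on - z_off) / max(|z_off|, floor)`.  Positive values mean the edge's
#' connectivity strengthened after levodopa, negative that it weakened; the
#' absolute-value denominator preserves the direction of the raw change
#' whatever the sign of the baseline.  Near-zero baselines are floored (and
#' flagged via the `"floored"` attribute) so the design matrix fed to
#' feature selection stays finite for all edges.
#'
#' @param z_on,z_off Finite Fisher-z values (vectorized).
#' @param floor Denominator floor (default `1e-6`).
#' @return Numeric vector of change rates with a logical attribute
#'   `"floored"` marking entries whose denominator hit the floor.
#' @examples
#' edge_reactivity(0.1, 0.2)   # -0.5
#' edge_reactivity(-0.3, -0.2) # -0.5
#' @export
edge_reactivity <- function(z_on, z_off, floor = 1e-6) {
  if (length(z_on) != length(z_off)) abort_data("`z_on` and `z_off` lengths differ")
  if (!all(is.finite(z_on)) || !all(is.finite(z_off))) {
    abort_data("non-finite connectivity value in reactivity computation")
  }
  floored <- abs(z_off) < floor
  out <- (z_on - z_off) / pmax(abs(z_off), floor)
  attr(out, "floored") <- floored
  out
}

#' Tremor responsiveness (tremor change rate)
#'
#' `(off - on) / off` on the UPDRS-III tremor sub-score (items 20 + 21).
#' Equals 1 when tremor resolves completely and 0 when unchanged; subjects
#' with no baseline tremor have no defined responsiveness and must be
#' excluded upstream.
#'
#' @param off_score,on_score Non-negative tremor sub-scores (vectorized).
#' @return Numeric change rates, each `<= 1` whenever `on_score >= 0`.
#' @examples
#' tremor_responsiveness(4, 1)  # 0.75
#' @export
tremor_responsiveness <- function(off_score, on_score) {
  if (length(off_score) != length(on_score)) abort_data("score lengths differ")
  if (anyNA(off_score) || anyNA(on_score)) abort_data("missing tremor scores")
  if (any(off_score <= 0)) {
    abort_data("no baseline tremor (OFF tremor score = 0) - subject must be excluded")
  }
  (off_score - on_score) / off_score
}

#' Compose UPDRS-III sub-scores
#'
#' Tremor = items 20 + 21; rigidity = item 22; bradykinesia = items
#' 23 + 24 + 25 + 26 + 27 + 31.
#'
#' @param items A data frame with one row per subject(-session) and integer
#'   columns `item20`, `item21`, `item22`, `item23`, ..., `item27`,
#'   `item31`; or a named numeric vector for a single subject.
#' @return A tibble with columns `tremor`, `rigidity`, `bradykinesia`.
#' @examples
#' compose_subscores(c(item20 = 2, item21 = 3, item22 = 4, item23 = 1,
#'                     item24 = 1, item25 = 1, item26 = 1, item27 = 1,
#'                     item31 = 2))
#' @export
compose_subscores <- function(items) {
  if (is.numeric(items)) items <- tibble::as_tibble(as.list(items))
  needed <- paste0("item", c(20:27, 31))
  missing <- setdiff(needed, names(items))
  if (length(missing)) {
    abort_data(sprintf("missing UPDRS-III item(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(vapply(items[needed], function(v) any(v < 0 | is.na(v)), logical(1)))) {
    abort_data("UPDRS-III items must be non-negative and non-missing")
  }
  tibble::tibble(
    tremor = items$item20 + items$item21,
    rigidity = items$item22,
    bradykinesia = items$item23 + items$item24 + items$item25 +
      items$item26 + items$item27 + items$item31
  )
}

#' Reactivity table: per-subject, per-edge connectivity change rates
#'
#' Joins each subject's OFF and ON Fisher-z values edge by edge and applies
#' [edge_reactivity()].
#'
#' @param connectivity Long connectivity tibble from [build_connectivity()]
#'   containing both sessions of each subject.
#' @param floor Denominator floor passed to [edge_reactivity()].
#' @return A tibble with columns `subject_id`, `edge`, `system`,
#'   `subcortical`, `cortical`, `z_off`, `z_on`, `reactivity`,
#'   `denom_floored`, edges in canonical order within subject.
#' @export
reactivity_table <- function(connectivity, floor = 1e-6) {
  wide <- connectivity |>
    dplyr::select("subject_id", "edge", "system", "subcortical", "cortical",
                  "session", "z") |>
    tidyr::pivot_wider(names_from = "session", values_from = "z",
                       names_prefix = "z_")
  names(wide) <- sub("^z_OFF$", "z_off", sub("^z_ON$", "z_on", names(wide)))
  if (!all(c("z_off", "z_on") %in% names(wide)) || anyNA(wide$z_off) || anyNA(wide$z_on)) {
    abort_data("each subject needs both an OFF and an ON session")
  }
  react <- edge_reactivity(wide$z_on, wide$z_off, floor = floor)
  wide |>
    dplyr::mutate(reactivity = as.numeric(react),
                  denom_floored = attr(react, "floored"))
}

#' Widen a reactivity table into a subjects x edges matrix
#'
#' @param reactivity Tibble from [reactivity_table()].
#' @param system Restrict to `"da"` or `"ach"` edges, or `"combined"`
#'   (default) for all, in canonical order.
#' @return Numeric matrix, rownames = subject ids, colnames = edge labels.
#' @export
reactivity_matrix <- function(reactivity, system = c("combined", "da", "ach")) {
  system <- match.arg(system)
  if (system != "combined") {
    reactivity <- dplyr::filter(reactivity, .data$system == !!system)
  }
  edges <- unique(reactivity$edge)
  subjects <- unique(reactivity$subject_id)
  m <- matrix(NA_real_, length(subjects), length(edges),
              dimnames = list(subjects, edges))
  m[cbind(match(reactivity$subject_id, subjects), match(reactivity$edge, edges))] <-
    reactivity$reactivity
  if (anyNA(m)) abort_data("reactivity table is not complete over subjects x edges")
  m
}

#' Median split into resistant and responsive tremor groups
#'
#' Splits patients at the cohort median of tremor responsiveness: subjects
#' at or above the median are labeled `responsive`, below it `resistant`.
#' For even n the median is the midpoint of the two central order
#' statistics; ties at the median all go to the responsive group, by the
#' "above or equal" rule.
#'
#' @param data Data frame with one row per patient.
#' @param responsiveness Column with tremor responsiveness values
#'   (default `tremor_responsiveness`).
#' @return The input tibble with added columns `group` (factor
#'   `resistant`/`responsive`) and `cohort_median`.  Warns when a resulting
#'   group has fewer than 2 members (stratified resampling needs >= 2 per
#'   class).
#' @examples
#' median_split(tibble::tibble(tremor_responsiveness = c(.1, .3, .8, .9)))
#' @export
median_split <- function(data, responsiveness = "tremor_responsiveness") {
  vals <- data[[responsiveness]]
  if (is.null(vals)) abort_data(sprintf("column `%s` not found", responsiveness))
  if (length(vals) < 4L) abort_data("median split needs at least 4 subjects")
  if (!all(is.finite(vals))) abort_data("non-finite responsiveness values")
  med <- stats::median(vals)
  grp <- factor(ifelse(vals >= med, "responsive", "resistant"),
                levels = c("resistant", "responsive"))
  if (any(table(grp) < 2L)) {
    rlang::warn("median split left a group with fewer than 2 subjects; stratified resampling will fail downstream")
  }
  dplyr::mutate(data, group = grp, cohort_median = med)
}
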