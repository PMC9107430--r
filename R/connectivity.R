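# Subcortico-cortical Fisher-z connectivity: dopaminergic (basal ganglia ->
# cortex) and cholinergic (basal forebrain -> cortex) edge sets per
# subject-session, plus network-level summaries.

#' Fisher-z functional connectivity of one ROI pair
#'
#' Pearson correlation of two equal-length time courses, clipped to
#' `|r| <= 1 - 1e-12` and mapped through the Fisher r-to-z transform
#' (`atanh`).  The clip keeps perfectly correlated pairs finite so that
#' downstream change-rate arithmetic and model fitting stay well defined.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return A single Fisher-z value with the sign of the correlation.
#' @examples
#' edge_fc(c(1, 2, 3, 4), c(1, 2, 3, 5))  # ~2.371
#' @export
edge_fc <- function(x, y) {
  if (length(x) != length(y)) abort_data("time series lengths differ")
  if (length(x) < 3L) abort_data("time series must have length >= 3")
  if (anyNA(x) || anyNA(y)) abort_data("time series contain missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort_data("zero-variance ROI")
  fisher_z(stats::cor(x, y))
}

# atanh with the documented clip; vectorized.
fisher_z <- function(r, clip = 1 - 1e-12) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Build dopaminergic and cholinergic connectivity for a cohort
#'
#' Maps every (cortical, dopaminergic) and (cortical, cholinergic) ROI pair
#' of every subject-session through [edge_fc()].  No cortico-cortical or
#' subcortico-subcortical edges are formed.  Rows follow the canonical edge
#' order of [edge_index()] within each subject-session, so the flattening is
#' identical across subjects and sessions.
#'
#' @param cohort An `fc_cohort` (or any list with `timeseries` and `roi`
#'   shaped like one; see [simulate_cohort()]).
#' @return A tibble with columns `subject_id`, `session`, `edge`, `system`,
#'   `subcortical`, `cortical`, `r`, `z` — at default ROI sizes 768
#'   dopaminergic + 384 cholinergic = 1152 rows per subject-session.
#' @export
build_connectivity <- function(cohort) {
  roi <- validate_roi(cohort$roi)
  ei <- edge_index(roi)
  cort <- roi$label[roi$class == "cortical"]
  sub_all <- c(roi$label[roi$class == "dopaminergic"], roi$label[roi$class == "cholinergic"])

  purrr::pmap_dfr(cohort$timeseries, function(subject_id, session, ts) {
    if (anyNA(ts)) {
      abort_data(sprintf("missing values in time series of %s %s", subject_id, session))
    }
    sds <- apply(ts, 2L, stats::sd)
    if (any(sds == 0)) {
      abort_data(sprintf(
        "zero-variance ROI in %s %s: %s", subject_id, session,
        paste(colnames(ts)[sds == 0], collapse = ", ")
      ))
    }
    rmat <- stats::cor(ts[, cort, drop = FALSE], ts[, sub_all, drop = FALSE])
    # column-major flattening of (cortical x subcortical) = subcortical-major,
    # cortical-minor: exactly the edge_index order
    rvec <- as.vector(rmat)
    dplyr::mutate(ei, subject_id = subject_id, session = session,
                  r = rvec, z = fisher_z(rvec), .before = 1L)
  })
}

#' Mean network connectivity strength
#'
#' Arithmetic mean of all Fisher-z values of one network (dopaminergic or
#' cholinergic) per subject-session.
#'
#' @param connectivity Long connectivity tibble from [build_connectivity()].
#' @param system `"da"`, `"ach"`, or both (default).
#' @return Tibble `subject_id`, `session`, `system`, `mean_z`.
#' @export
mean_network_strength <- function(connectivity, system = c("da", "ach")) {
  system <- match.arg(system, several.ok = TRUE)
  connectivity |>
    dplyr::filter(.data$system %in% !!system) |>
    dplyr::group_by(.data$subject_id, .data$session, .data$system) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop")
}

#' Cholinergic-dopaminergic network difference
#'
#' The relative activity of the two networks: mean cholinergic z minus mean
#' dopaminergic z, per subject-session.
#'
#' @inheritParams mean_network_strength
#' @return Tibble `subject_id`, `session`, `ach_minus_da`.
#' @export
ach_da_difference <- function(connectivity) {
  mean_network_strength(connectivity) |>
    tidyr::pivot_wider(names_from = "system", values_from = "mean_z") |>
    dplyr::mutate(ach_minus_da = .data$ach - .data$da) |>
    dplyr::select("subject_id", "session", "ach_minus_da")
}
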