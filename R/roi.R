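# ROI label sets.  Regions are abstract labeled columns here: the voxel-level
# parcellation (Harvard-Oxford cortical/subcortical atlases, probabilistic
# basal-forebrain maps) happens upstream of this package.

# Short codes for the 48 bilateral Harvard-Oxford cortical parcels, expanded
# to 96 by hemisphere.  "PO" is the parietal operculum, "PHp" the posterior
# parahippocampal gyrus.
ho_cortical_codes <- c(
  "FP", "INS", "SFG", "MFG", "IFGtri", "IFGop", "PreCG", "TP",
  "STGa", "STGp", "MTGa", "MTGp", "MTGto", "ITGa", "ITGp", "ITGto",
  "PostCG", "SPL", "SMGa", "SMGp", "AG", "LOCs", "LOCi", "ICC",
  "FMC", "SMA", "SubCalC", "PaCiG", "CiGa", "CiGp", "Precuneous", "CunealC",
  "FOrb", "PHa", "PHp", "LG", "TFa", "TFp", "TOF", "OF",
  "FO", "CO", "PO", "PP", "HG", "PT", "SCC", "OcP"
)

da_roi_labels_default <- c(
  "L.Thalamus", "R.Thalamus", "L.Caudate", "R.Caudate",
  "L.Putamen", "R.Putamen", "L.Pallidum", "R.Pallidum"
)

ach_roi_labels_default <- c("L.BF123", "R.BF123", "L.BF4", "R.BF4")

#' ROI partition table
#'
#' Builds the ordered ROI label set used throughout the pipeline: cortical
#' parcels first, then dopaminergic subcortical seeds (bilateral thalamus,
#' caudate, putamen, pallidum), then cholinergic basal-forebrain seeds
#' (bilateral BF123 and BF4).  At the default sizes the labels follow the
#' Harvard-Oxford cortical parcellation (96 = 48 regions x 2 hemispheres);
#' non-default sizes get generic labels.
#'
#' @param n_cortical Number of cortical parcels (default 96).
#' @param n_da Number of dopaminergic subcortical ROIs (default 8).
#' @param n_ach Number of cholinergic basal-forebrain ROIs (default 4).
#' @return A tibble with columns `label` and `class`
#'   (`cortical`/`dopaminergic`/`cholinergic`), one row per ROI, in the
#'   canonical column order of the time-series matrices.
#' @examples
#' roi_partition()
#' roi_partition(n_cortical = 10, n_da = 3, n_ach = 2)
#' @export
roi_partition <- function(n_cortical = 96L, n_da = 8L, n_ach = 4L) {
  n_cortical <- check_count(n_cortical, "n_cortical")
  n_da <- check_count(n_da, "n_da")
  n_ach <- check_count(n_ach, "n_ach")

  cort <- if (n_cortical == 96L) {
    paste0(rep(c("L.", "R."), each = 48L), rep(ho_cortical_codes, times = 2L))
  } else {
    sprintf("Cortex%02d", seq_len(n_cortical))
  }
  da <- if (n_da == 8L) da_roi_labels_default else sprintf("DA%02d", seq_len(n_da))
  ach <- if (n_ach == 4L) ach_roi_labels_default else sprintf("ACh%02d", seq_len(n_ach))

  tibble::tibble(
    label = c(cort, da, ach),
    class = rep(c("cortical", "dopaminergic", "cholinergic"), c(n_cortical, n_da, n_ach))
  )
}

#' Canonical edge index
#'
#' Enumerates all subcortico-cortical edges in the canonical flattening
#' order used by every stage: dopaminergic edges first, then cholinergic,
#' each block in subcortical-major / cortical-minor order.  At the default
#' ROI sizes this yields 768 dopaminergic + 384 cholinergic = 1152 edges.
#'
#' @param roi ROI partition tibble from [roi_partition()].
#' @return A tibble with columns `edge` (e.g. `"R.BF123-R.PO"`), `system`
#'   (`"da"`/`"ach"`), `subcortical`, `cortical`, in canonical order.
#' @examples
#' nrow(edge_index(roi_partition()))  # 1152
#' @export
edge_index <- function(roi = roi_partition()) {
  validate_roi(roi)
  cort <- roi$label[roi$class == "cortical"]
  blocks <- lapply(c(da = "dopaminergic", ach = "cholinergic"), function(cl) {
    sub <- roi$label[roi$class == cl]
    tibble::tibble(
      subcortical = rep(sub, each = length(cort)),
      cortical = rep(cort, times = length(sub))
    )
  })
  out <- dplyr::bind_rows(blocks, .id = "system")
  dplyr::mutate(out,
    edge = paste(.data$subcortical, .data$cortical, sep = "-"),
    .before = "system"
  )
}

validate_roi <- function(roi) {
  if (!is.data.frame(roi) || !all(c("label", "class") %in% names(roi))) {
    abort_data("`roi` must be a data frame with columns `label` and `class`")
  }
  if (anyDuplicated(roi$label)) {
    abort_data("ROI labels must be unique")
  }
  bad <- setdiff(unique(roi$class), c("cortical", "dopaminergic", "cholinergic"))
  if (length(bad)) {
    abort_data(sprintf("unknown ROI class: %s", paste(bad, collapse = ", ")))
  }
  invisible(roi)
}
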