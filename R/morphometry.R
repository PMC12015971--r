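#' Per-slice cross-sectional areas of nerve structures
#'
#' Computes, on each axial slice, the cross-sectional area of the whole
#' nerve and of each sub-structure by voxel counting:
#' `area = n_voxels * dx * dy`, with no smoothing or sub-voxel
#' correction (matching manual ROI exports at this resolution). Because
#' the labels partition the nerve, fascicular and epineurial areas sum
#' exactly to the whole-nerve area on every slice.
#'
#' @param mask A [nerve_label_map()].
#' @param structures Character vector of structures to report
#'   (`"nerve"`, `"fascicle"`, `"epineurium"`).
#' @return Long tibble: `slice`, `structure`, `area_mm2`.
#' @examples
#' lab <- array(0L, c(4, 4, 3)); lab[2:3, 2:3, ] <- 2L
#' csa_per_slice(nerve_label_map(lab, c(0.6, 0.6, 5)))
#' @export
csa_per_slice <- function(mask, structures = c("nerve", "fascicle", "epineurium")) {
  stopifnot(inherits(mask, "nerve_label_map"))
  vox_area <- mask$voxdim[1] * mask$voxdim[2]
  nsl <- dim(mask$labels)[3]
  purrr::map(structures, function(st) {
    labels <- structure_labels(st)
    counts <- vapply(seq_len(nsl),
                     function(s) sum(mask$labels[, , s] %in% labels),
                     numeric(1))
    tibble(slice = seq_len(nsl), structure = st, area_mm2 = counts * vox_area)
  }) |>
    purrr::list_rbind()
}

#' Aggregate per-slice areas over the analysis slices
#'
#' Reduces a per-slice area profile to one value per structure, the
#' arithmetic mean over the analysis slices (the same reduction used for
#' ROI pT2*; first and last slices are excluded upstream by
#' [select_analysis_slices()]).
#'
#' @param profile Long tibble from [csa_per_slice()].
#' @param slices Slice indices to aggregate over.
#' @return Tibble: `structure`, `area_mm2`, `n_slices`.
#' @examples
#' lab <- array(0L, c(4, 4, 4)); lab[2:3, 2:3, ] <- 2L
#' mask <- nerve_label_map(lab, c(0.6, 0.6, 5))
#' aggregate_areas(csa_per_slice(mask), select_analysis_slices(4))
#' @export
aggregate_areas <- function(profile, slices) {
  if (!length(slices)) abort("The analysis slice set is empty.")
  if (!all(slices %in% profile$slice)) {
    abort("`slices` refers to slices missing from the area profile.")
  }
  profile |>
    dplyr::filter(.data$slice %in% slices) |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(area_mm2 = mean(.data$area_mm2),
                     n_slices = dplyr::n(), .groups = "drop")
}
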