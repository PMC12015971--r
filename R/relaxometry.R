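#' Voxelwise pseudo-T2* from a dual-echo volume
#'
#' Computes the two-point pseudo-T2* estimate at every voxel:
#' `pT2* = -dTE / ln(iTE2 / iTE1)`, where `iTE1`, `iTE2` are the signal
#' intensities of the first and second echo and `dTE = te2 - te1`. A
#' voxel is valid when `iTE1 > 0` and `0 < iTE2 < iTE1` (a decaying,
#' positive signal); elsewhere the value is `NA` and the validity mask is
#' `FALSE`. The estimate depends only on the intensity ratio, so scaling
#' both echoes by any positive constant leaves the map unchanged.
#'
#' @param vol An [echo_pair()].
#' @return A list of class `"pt2star_map"` with `values` (ms, `NA` where
#'   invalid), `valid` (logical array), `delta_te` and `voxdim`.
#' @examples
#' e1 <- array(100, c(2, 2, 3)); e2 <- array(50, c(2, 2, 3))
#' m <- compute_pt2star(echo_pair(e1, e2, 1.05, 5.37, c(0.6, 0.6, 5)))
#' m$values[1, 1, 1] # 4.32 / log(2)
#' @export
compute_pt2star <- function(vol) {
  stopifnot(inherits(vol, "echo_pair"))
  valid <- vol$echo1 > 0 & vol$echo2 > 0 & vol$echo2 < vol$echo1
  delta_te <- vol$te2 - vol$te1
  values <- array(NA_real_, dim = dim(vol$echo1))
  values[valid] <- -delta_te / log(vol$echo2[valid] / vol$echo1[valid])
  structure(list(values = values, valid = valid, delta_te = delta_te,
                 voxdim = vol$voxdim),
            class = "pt2star_map")
}

#' Analysis slices after excluding the first and last slice
#'
#' The first and last slices of the slab are excluded to avoid signal
#' changes from field inhomogeneities at the slab edges, so a 12-slice
#' acquisition retains its central 10 slices. Indices are 1-based along
#' the third (slice) axis of the volume.
#'
#' @param nslices Total slice count, at least 3.
#' @return Integer vector `2:(nslices - 1)` of retained slice indices.
#' @examples
#' select_analysis_slices(12) # the central 10 slices
#' @export
select_analysis_slices <- function(nslices) {
  if (nslices < 3) abort("Need at least 3 slices to exclude the first and last.")
  seq.int(2L, nslices - 1L)
}

#' ROI summary of a pseudo-T2* map
#'
#' Summarizes a pT2* map over a labelled structure restricted to the
#' analysis slices. With `method = "voxelwise"` (default) the summary is
#' the mean of the per-voxel pT2* values over valid ROI voxels; with
#' `method = "roi_signal"` the two echo intensities are averaged over the
#' ROI first and the estimator applied to the mean signals (the two
#' agree in the noiseless limit). The fraction of ROI voxels that were
#' valid is always reported, so silently excluded voxels are visible.
#'
#' @param map A `"pt2star_map"` from [compute_pt2star()].
#' @param mask A [nerve_label_map()] of the same dimensions.
#' @param structure `"fascicle"`, `"epineurium"`, `"nerve"` (labels
#'   `{1,2}`), or an integer label set.
#' @param slices Retained slice indices, e.g.
#'   [select_analysis_slices()]; defaults to excluding first and last.
#' @param method `"voxelwise"` or `"roi_signal"`.
#' @param vol The [echo_pair()]; required for `method = "roi_signal"`.
#' @return One-row tibble: `structure`, `mean_pt2star_ms`, `n_voxels`,
#'   `n_valid`, `valid_fraction`.
#' @export
roi_mean_pt2star <- function(map, mask, structure = "fascicle",
                             slices = select_analysis_slices(dim(map$values)[3]),
                             method = c("voxelwise", "roi_signal"),
                             vol = NULL) {
  stopifnot(inherits(map, "pt2star_map"), inherits(mask, "nerve_label_map"))
  method <- match.arg(method)
  if (!identical(dim(map$values), dim(mask$labels))) {
    abort("pT2* map and label map dimensions differ.")
  }
  if (!length(slices)) abort("The analysis slice set is empty.")
  labels <- structure_labels(structure)
  roi <- array(FALSE, dim = dim(mask$labels))
  roi[, , slices] <- mask$labels[, , slices, drop = FALSE] %in% labels
  n_roi <- sum(roi)
  if (n_roi == 0) {
    abort(sprintf("Empty ROI for structure '%s' on the analysis slices.",
                  paste(structure, collapse = ",")))
  }
  ok <- roi & map$valid
  n_valid <- sum(ok)
  mean_val <- if (n_valid == 0) {
    NA_real_
  } else if (method == "voxelwise") {
    mean(map$values[ok])
  } else {
    if (is.null(vol)) abort("`vol` (the echo pair) is required for method = 'roi_signal'.")
    ratio <- mean(vol$echo2[ok]) / mean(vol$echo1[ok])
    if (ratio <= 0 || ratio >= 1) NA_real_ else -map$delta_te / log(ratio)
  }
  tibble(
    structure = paste(if (is.numeric(structure)) paste0("label", structure) else structure,
                      collapse = "+"),
    mean_pt2star_ms = mean_val,
    n_voxels = n_roi,
    n_valid = n_valid,
    valid_fraction = n_valid / n_roi
  )
}
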