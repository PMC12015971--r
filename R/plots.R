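#' Plot one axial slice of a volume or label map
#'
#' Raster view of a single slice: echo intensity (first echo), the pT2*
#' map, or the structure labels, with square pixels scaled by the voxel
#' dimensions.
#'
#' @param x An [echo_pair()], `"pt2star_map"` or [nerve_label_map()].
#' @param slice Slice index (third axis), default the middle slice.
#' @return A ggplot object.
#' @export
plot_slice <- function(x, slice = NULL) {
  if (inherits(x, "echo_pair")) {
    arr <- x$echo1; voxdim <- x$voxdim; lab <- "echo 1 intensity"
  } else if (inherits(x, "pt2star_map")) {
    arr <- x$values; voxdim <- x$voxdim; lab <- "pT2* (ms)"
  } else if (inherits(x, "nerve_label_map")) {
    arr <- x$labels; voxdim <- x$voxdim; lab <- "label"
  } else {
    abort("Don't know how to plot this object.")
  }
  slice <- slice %||% ceiling(dim(arr)[3] / 2)
  m <- arr[, , slice]
  d <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  d$x_mm <- d$i * voxdim[1]
  d$y_mm <- d$j * voxdim[2]
  d$value <- m[cbind(d$i, d$j)]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Slice %d", slice))
  if (inherits(x, "nerve_label_map")) {
    d$value <- factor(d$value, levels = 0:2,
                      labels = c("background", "epineurium", "fascicle"))
    p + ggplot2::geom_raster(data = d, ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_manual(
        values = c(background = "grey20", epineurium = "steelblue4",
                   fascicle = "goldenrod1"), name = lab)
  } else {
    p + ggplot2::geom_raster(data = d, ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = lab, na.value = "grey10")
  }
}

#' Group comparison plot for a cohort measure
#'
#' Jittered points with group mean and standard deviation for one
#' derived measure, by group or severity stratum.
#'
#' @param cohort Cohort tibble (e.g. `run_cohort(...)$cohort`).
#' @param measure Measure column (bare name or string).
#' @param by `"group"` or `"severity"` (computed from NIS-LL if absent).
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(cohort, measure, by = c("group", "severity")) {
  by <- match.arg(by)
  measure <- as_string(ensym(measure))
  if (by == "severity" && !"severity" %in% names(cohort)) {
    cohort$severity <- severity_stratum(cohort$group, cohort$nis_ll)
  }
  ggplot2::ggplot(cohort,
                  ggplot2::aes(.data[[by]], .data[[measure]],
                               colour = .data[[by]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "pointrange", colour = "black") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = measure)
}

#' Scatter plot of a correlation pair
#'
#' @param cohort Cohort tibble.
#' @param x,y Columns (bare names or strings).
#' @param colour_by Optional grouping column for colour.
#' @return A ggplot object.
#' @export
plot_correlation <- function(cohort, x, y, colour_by = "group") {
  x <- as_string(ensym(x)); y <- as_string(ensym(y))
  p <- ggplot2::ggplot(cohort, ggplot2::aes(.data[[x]], .data[[y]]))
  if (!is.null(colour_by) && colour_by %in% names(cohort)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                           se = FALSE, colour = "grey30") +
    ggplot2::labs(x = x, y = y)
}

#' @rdname plot_group_comparison
#' @param object A `"nerve_cohort"`.
#' @param ... Passed on as the measure, default fascicle pT2*.
#' @export
autoplot.nerve_cohort <- function(object, ...) {
  args <- list(...)
  measure <- args$measure %||% "fascicle_pt2star_ms"
  plot_group_comparison(object$cohort, !!rlang::sym(measure))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
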