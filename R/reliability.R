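#' Dice similarity coefficient between two segmentations
#'
#' Overlap of a structure's voxel sets in two label maps:
#' `2 |A intersect B| / (|A| + |B|)`. When both sets are empty the
#' coefficient is defined as 1 (two raters agreeing the structure is
#' absent), a documented convention that avoids failures on structures
#' missing from a slice.
#'
#' @param mask_a,mask_b Two [nerve_label_map()]s (or plain integer
#'   arrays) of identical dimensions.
#' @param structure Structure name or integer label set (see
#'   [roi_mean_pt2star()]).
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' a <- array(0L, c(4, 4, 1)); a[1:2, 1:2, 1] <- 2L
#' b <- a
#' dice_coefficient(nerve_label_map(a, c(1, 1, 1)),
#'                  nerve_label_map(b, c(1, 1, 1)), "fascicle")
#' @export
dice_coefficient <- function(mask_a, mask_b, structure = "nerve") {
  la <- if (inherits(mask_a, "nerve_label_map")) mask_a$labels else mask_a
  lb <- if (inherits(mask_b, "nerve_label_map")) mask_b$labels else mask_b
  if (!identical(dim(la), dim(lb))) abort("The two masks have different dimensions.")
  labels <- structure_labels(structure)
  in_a <- la %in% labels
  in_b <- lb %in% labels
  na <- sum(in_a); nb <- sum(in_b)
  if (na + nb == 0) return(1)
  2 * sum(in_a & in_b) / (na + nb)
}

#' Intraclass correlation coefficient for two raters
#'
#' Computes the single-measurement ICC from the two-way ANOVA mean
#' squares of an n-subject by 2-rater table. The default `"agreement"`
#' form is ICC(2,1) (two-way random effects, absolute agreement), which
#' penalizes systematic between-rater bias and answers whether the two
#' raters' absolute measurements are interchangeable;
#' `"consistency"` gives ICC(3,1). A constant table has no subject
#' variance to apportion and is flagged as degenerate (`icc = NA`).
#'
#' @param data Data frame holding the two raters' measurements.
#' @param rater1,rater2 Columns (bare names or strings) with each
#'   rater's measurement per subject; at least 2 complete subjects.
#' @param type `"agreement"` (ICC(2,1)) or `"consistency"` (ICC(3,1)).
#' @return Object of class `"icc_fit"`: the estimate, the mean squares
#'   (`msr` subjects, `msc` raters, `mse` error) for auditability, `n`,
#'   and a `degenerate` flag. [tidy()] and [glance()] methods return
#'   tibbles.
#' @examples
#' d <- data.frame(r1 = c(1, 2, 3, 4), r2 = c(2, 3, 4, 5))
#' icc_two_rater(d, r1, r2)
#' @export
icc_two_rater <- function(data, rater1, rater2,
                          type = c("agreement", "consistency")) {
  type <- match.arg(type)
  x <- data[[as_string(ensym(rater1))]]
  y <- data[[as_string(ensym(rater2))]]
  keep <- complete.cases(x, y)
  if (any(!keep)) abort("The rater table must have no missing cells.")
  m <- cbind(x, y)
  n <- nrow(m)
  if (n < 2) abort("ICC needs at least 2 subjects.")
  k <- 2
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- isTRUE(all.equal(var(as.vector(m)), 0))
  icc <- if (degenerate) {
    NA_real_
  } else if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  if (degenerate) warn("Constant rater table: ICC is undefined (degenerate).")
  structure(list(icc = icc, type = type,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 n = n, k = k, degenerate = degenerate),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  variant <- if (x$type == "agreement") "ICC(2,1) absolute agreement" else "ICC(3,1) consistency"
  cat(sprintf("%s: %.4f  (n = %d subjects, 2 raters)\n", variant, x$icc, x$n))
  invisible(x)
}

#' @rdname icc_two_rater
#' @param x An `"icc_fit"`.
#' @param ... Unused.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble(term = c("subjects", "raters", "error"),
         mean_square = unname(x$ms))
}

#' @rdname icc_two_rater
#' @export
glance.icc_fit <- function(x, ...) {
  tibble(icc = x$icc, icc_variant = if (x$type == "agreement") "ICC(2,1)" else "ICC(3,1)",
         n = x$n, k = x$k, degenerate = x$degenerate)
}
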