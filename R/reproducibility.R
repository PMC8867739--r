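#' Intersection over union of two masks
#'
#' Voxelwise overlap `|A intersect B| / |A union B|` of the nonzero voxels of
#' two masks on the same grid. When both masks are empty the IoU is defined
#' as 1.0 (degenerate perfect agreement; a warning is raised).
#'
#' @param a,b `mask_volume`s on the same grid.
#' @return Fraction in `[0, 1]`.
#' @export
intersection_over_union <- function(a, b) {
  stopifnot(inherits(a, "mask_volume"), inherits(b, "mask_volume"))
  stop_if_grid_mismatch(a, b, "masks")
  ba <- a$labels != 0L
  bb <- b$labels != 0L
  uni <- sum(ba | bb)
  if (uni == 0L) {
    warning("both masks empty; IoU defined as 1.0")
    return(1.0)
  }
  sum(ba & bb) / uni
}

#' Intraclass correlation coefficient for repeated measurements
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1)) computed from the ANOVA mean-squares decomposition of a
#' subjects x repeats matrix:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' with `MS_R` the between-subjects, `MS_C` the between-repeats and `MS_E`
#' the residual mean square. This is the standard test-retest form for a
#' single reader measuring each subject in repeated sessions.
#'
#' @param measurements Numeric matrix, subjects in rows, repeats in columns;
#'   no missing cells; at least 2 subjects and 2 repeats.
#' @return List of class `icc_result` with `icc`, `icc_model`, and the mean
#'   squares.
#' @export
icc_single_rater <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 repeats")
  if (anyNA(m)) stop("missing cells are not supported")
  gm <- mean(m)
  if (sum((m - gm)^2) == 0) stop("degenerate: zero total variance")
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc,
                 icc_model = "ICC(A,1): two-way mixed, absolute agreement, single measurement",
                 ms_subjects = msr, ms_repeats = msc, ms_error = mse,
                 n_subjects = n, n_repeats = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.4f  (%s; n = %d, k = %d)\n",
              x$icc, x$icc_model, x$n_subjects, x$n_repeats))
  invisible(x)
}

#' Segmentation and measurement reproducibility across two sessions
#'
#' Convenience wrapper: per-subject IoU of paired masks plus the ICC of the
#' paired continuous measurements (typically the marrow SUL mean).
#'
#' @param masks_a,masks_b Lists of `mask_volume`s (same subjects, two
#'   sessions).
#' @param values_a,values_b Numeric vectors of the per-subject measurement in
#'   each session.
#' @return List of class `repro_result` with `iou` (mean), `iou_per_subject`,
#'   `icc`, `icc_model`.
#' @export
assess_reproducibility <- function(masks_a, masks_b, values_a, values_b) {
  stopifnot(length(masks_a) == length(masks_b),
            length(values_a) == length(values_b))
  ious <- mapply(intersection_over_union, masks_a, masks_b)
  icc <- icc_single_rater(cbind(values_a, values_b))
  structure(list(iou = mean(ious), iou_per_subject = as.numeric(ious),
                 icc = icc$icc, icc_model = icc$icc_model),
            class = "repro_result")
}

#' @export
print.repro_result <- function(x, ...) {
  cat(sprintf("<repro_result> mean IoU = %.4f (n = %d), ICC = %.4f\n",
              x$iou, length(x$iou_per_subject), x$icc))
  invisible(x)
}
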