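#' @useDynLib bmpet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov chisq.test coef confint cor.test fisher.test lm
#'   pf rbinom rnorm runif sd t.test wilcox.test var
#' @importFrom utils read.csv write.csv
"_PACKAGE"

#' Label dictionary shared by all masks
#'
#' Integer codes used in labeled mask volumes throughout the pipeline.
#' `marrow` and `th11_marrow` are both marrow tissue; `th11_marrow` marks the
#' sub-region belonging to the eleventh thoracic vertebra, kept as a separate
#' code so the labels stay pairwise disjoint.
#'
#' @return Named integer vector mapping structure names to label codes.
#' @export
bm_label_map <- function() {
  c(background = 0L, bone = 1L, marrow = 2L, th11_marrow = 3L,
    mediastinum = 4L, liver = 5L, exclusion = 6L)
}

.modalities <- c("CT_HU", "PET_BQML", "PET_SUL")

#' 3D image volume
#'
#' A scalar 3D grid with voxel spacing. Arrays are indexed `[z, y, x]`
#' (0-based axial slice = fixed `z` in the underlying C code; in R, `values[k, , ]`
#' is the k-th axial slice). Negative PET values (reconstruction artifacts in
#' real data) are clamped to zero at construction and the clamp count recorded,
#' so SUL values stay non-negative.
#'
#' @param values 3D numeric array, axes (z, y, x).
#' @param spacing_mm Positive voxel spacing `(sz, sy, sx)` in millimetres.
#' @param modality One of `"CT_HU"`, `"PET_BQML"`, `"PET_SUL"`.
#' @param origin_mm Physical coordinate of voxel (1,1,1); 3-vector, mm.
#' @param allow_na Permit `NA` voxels (used for masked volumes whose values
#'   are undefined outside the mask).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm = c(5, 4.11, 4.11),
                         modality = c("CT_HU", "PET_BQML", "PET_SUL"),
                         origin_mm = c(0, 0, 0), allow_na = FALSE) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a non-3D-degenerate 3D array (axes z, y, x); got non-3D input")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite numbers")
  storage.mode(values) <- "double"
  n_clamped <- 0L
  if (allow_na) {
    if (any(is.nan(values) | is.infinite(values)))
      stop("non-finite values (NaN/Inf) in volume")
  } else if (any(!is.finite(values))) {
    stop("non-finite values in volume")
  }
  if (modality != "CT_HU") {
    neg <- !is.na(values) & values < 0
    n_clamped <- sum(neg)
    if (n_clamped > 0) values[neg] <- 0
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, modality = modality,
         origin_mm = as.numeric(origin_mm), n_clamped = n_clamped),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %s  %d x %d x %d (z,y,x)  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  v <- x$values[!is.na(x$values)]
  cat(sprintf("  range [%.4g, %.4g], %d defined voxels", min(v), max(v), length(v)))
  if (x$n_clamped > 0) cat(sprintf(", %d negative voxels clamped to 0", x$n_clamped))
  cat("\n")
  invisible(x)
}

#' Labeled mask volume
#'
#' Integer-labeled grid aligned to an [image_volume()]. Labels must be drawn
#' from `label_map`. A binary mask of a single structure uses codes
#' `{0, code(structure)}`.
#'
#' @param labels 3D integer array, axes (z, y, x).
#' @param spacing_mm Voxel spacing `(sz, sy, sx)` in mm.
#' @param label_map Named integer vector; defaults to [bm_label_map()].
#' @param origin_mm Physical coordinate of voxel (1,1,1).
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(labels, spacing_mm = c(5, 4.11, 4.11),
                        label_map = bm_label_map(), origin_mm = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array (axes z, y, x); got non-3D input")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite numbers")
  if (any(!is.finite(labels))) stop("non-finite labels in mask")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(label_map))
  if (length(bad))
    stop("labels not present in label_map: ", paste(bad, collapse = ", "))
  structure(
    list(labels = labels, spacing_mm = spacing_mm,
         label_map = label_map, origin_mm = as.numeric(origin_mm)),
    class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<mask_volume> %d x %d x %d (z,y,x)  spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  tab <- table(factor(x$labels, levels = unname(x$label_map),
                      labels = names(x$label_map)))
  tab <- tab[tab > 0]
  cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a binary (logical) array for one or more structures
#'
#' @param mask A `mask_volume`.
#' @param structures Character vector of structure names from the mask's
#'   label map. `"marrow"` conventionally means marrow tissue including the
#'   Th11 sub-label; pass `include_th11 = FALSE` to exclude it.
#' @param include_th11 When `"marrow"` is requested, also include
#'   `"th11_marrow"` voxels (they are marrow).
#' @return Logical 3D array.
#' @export
mask_binary <- function(mask, structures, include_th11 = TRUE) {
  stopifnot(inherits(mask, "mask_volume"))
  if (include_th11 && "marrow" %in% structures)
    structures <- union(structures, "th11_marrow")
  codes <- mask$label_map[structures]
  if (anyNA(codes))
    stop("unknown structure(s): ",
         paste(structures[is.na(codes)], collapse = ", "))
  array(mask$labels %in% codes, dim = dim(mask$labels))
}

#' Construct a binary mask_volume from a logical array
#' @param bin Logical 3D array.
#' @param structure Structure name the TRUE voxels represent.
#' @param spacing_mm Voxel spacing.
#' @param origin_mm Origin.
#' @return A `mask_volume` with labels in `{0, code(structure)}`.
#' @export
binary_mask_volume <- function(bin, structure = "marrow",
                               spacing_mm = c(5, 4.11, 4.11),
                               origin_mm = c(0, 0, 0)) {
  code <- bm_label_map()[[structure]]
  mask_volume(array(as.integer(bin) * code, dim = dim(bin)),
              spacing_mm = spacing_mm, origin_mm = origin_mm)
}

#' Run configuration for segmentation and quantification
#'
#' @param hu_threshold CT threshold (HU) for bone extraction. Default 150 HU,
#'   a conventional cortical-bone threshold.
#' @param erosion_pixels Number of one-pixel cortex erosions applied to the
#'   filled bone mask (default 2, matching the two-pixel margin removal of the
#'   reference procedure).
#' @param erosion_3d Erode in 3D (6-connected ball) instead of slice-wise 2D.
#'   Default `FALSE`: with anisotropic voxels (4.11 mm in-plane vs 5 mm axial)
#'   3D erosion removes disproportionate axial extent.
#' @param entropy_bins Number of equal-width histogram bins for the entropy
#'   feature (default 64).
#' @param min_component_voxels Connected components (26-connectivity) smaller
#'   than this are discarded from the bone mask (default 50).
#' @param seed Integer seed recorded with the run.
#' @param spacing_mm Default voxel spacing, mm.
#' @return An object of class `run_config`.
#' @export
run_config <- function(hu_threshold = 150, erosion_pixels = 2L,
                       erosion_3d = FALSE, entropy_bins = 64L,
                       min_component_voxels = 50L, seed = 1L,
                       spacing_mm = c(5, 4.11, 4.11)) {
  erosion_pixels <- as.integer(erosion_pixels)
  entropy_bins <- as.integer(entropy_bins)
  if (erosion_pixels < 0) stop("erosion_pixels must be >= 0")
  if (entropy_bins < 2) stop("entropy_bins must be >= 2")
  structure(list(hu_threshold = hu_threshold,
                 erosion_pixels = erosion_pixels,
                 erosion_3d = isTRUE(erosion_3d),
                 entropy_bins = entropy_bins,
                 min_component_voxels = as.integer(min_component_voxels),
                 seed = as.integer(seed),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "run_config")
}

# internal: check two grids agree (shape + spacing)
same_grid <- function(a, b) {
  da <- if (inherits(a, "mask_volume")) dim(a$labels) else dim(a$values)
  db <- if (inherits(b, "mask_volume")) dim(b$labels) else dim(b$values)
  # float32 NIfTI headers: compare spacing at header precision
  identical(da, db) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm, tolerance = 1e-6))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
}
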