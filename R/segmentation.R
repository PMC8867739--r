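#' Extract the bone envelope from CT
#'
#' Classical whole-bone extraction: voxels at or above `hu_threshold` are
#' kept, the result is morphologically closed with a one-voxel ball to seal
#' cortex gaps, holes enclosed by cortex are filled slice-wise (so the mask
#' is the filled bone envelope including the marrow cavity, as a whole-bone
#' organ segmenter would return), and connected components (26-connectivity)
#' smaller than `min_component_voxels` are discarded.
#'
#' @param ct CT [image_volume()] (modality `CT_HU`).
#' @param config A [run_config()].
#' @return A binary `mask_volume` (label `bone`) with attributes recorded in
#'   `provenance` (number of discarded components).
#' @export
segment_bone <- function(ct, config = run_config()) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$modality != "CT_HU") stop("segment_bone expects a CT_HU volume")
  bw <- ct$values >= config$hu_threshold
  if (!any(bw)) stop("no bone above threshold (", config$hu_threshold, " HU)")
  bw <- close3d(bw)
  bw <- fill_holes_slicewise(bw)
  lab <- label_components(bw, connectivity = 26L)
  n_comp <- attr(lab, "n_components")
  sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
  keep <- which(sizes >= config$min_component_voxels)
  n_removed <- n_comp - length(keep)
  bw <- array(lab %in% keep & lab > 0L, dim = dim(lab))
  if (!any(bw)) stop("no bone above threshold (all components below size cutoff)")
  out <- binary_mask_volume(bw, "bone", ct$spacing_mm, ct$origin_mm)
  out$provenance <- list(hu_threshold = config$hu_threshold,
                         n_components_removed = n_removed)
  out
}

#' Erode the cortical margin from a bone mask
#'
#' Applies `erosion_pixels` one-pixel binary erosions with a 4-connected
#' cross element on each axial slice (or a 6-connected 3D ball when
#' `three_d = TRUE`), removing the cortical margin so that the marrow cavity
#' remains. The result is always a subset of the input; an empty result is
#' allowed and flagged.
#'
#' @param bone A binary `mask_volume` from [segment_bone()].
#' @param erosion_pixels Number of erosion passes (>= 0; 0 returns the input
#'   relabeled as marrow).
#' @param three_d Use 3D erosion instead of the slice-wise default.
#' @return A binary `mask_volume` with label `marrow`.
#' @export
erode_cortex <- function(bone, erosion_pixels = 2L, three_d = FALSE) {
  stopifnot(inherits(bone, "mask_volume"))
  if (erosion_pixels < 0) stop("erosion_pixels must be >= 0")
  m <- mask_binary(bone, c("bone", "marrow"))
  axes <- if (three_d) 1:3 else c(2L, 3L)
  k <- as.integer(erosion_pixels)
  while (k > 0L) {
    m <- erode_step(m, axes = axes)
    k <- k - 1L
  }
  out <- binary_mask_volume(m, "marrow", bone$spacing_mm, bone$origin_mm)
  out$provenance <- list(erosion_pixels = as.integer(erosion_pixels),
                         three_d = isTRUE(three_d), empty = !any(m))
  out
}

#' Remove exclusion regions from a mask
#'
#' Emulates the manual correction step of the reference procedure (removal of
#' thyroid, dental metal, vascular calcifications, ...) without a GUI:
#' exclusion regions are supplied as labeled masks or axis-aligned boxes.
#'
#' @param mask A binary `mask_volume`.
#' @param exclusions List of exclusion regions; each element is either a
#'   `mask_volume` (nonzero voxels are removed) or a list
#'   `list(z = c(lo, hi), y = c(lo, hi), x = c(lo, hi))` in voxel indices.
#' @return The mask minus the union of exclusions; the number of removed
#'   voxels is recorded in `provenance$n_excluded_voxels`.
#' @export
apply_exclusions <- function(mask, exclusions = list()) {
  stopifnot(inherits(mask, "mask_volume"))
  m <- mask$labels != 0L
  excl <- array(FALSE, dim = dim(m))
  for (e in exclusions) {
    if (inherits(e, "mask_volume")) {
      stop_if_grid_mismatch(mask, e, "mask and exclusion")
      excl <- excl | (e$labels != 0L)
    } else if (is.list(e) && all(c("z", "y", "x") %in% names(e))) {
      cl <- function(r, n) c(max(1L, r[1]), min(n, r[2]))
      d <- dim(m)
      z <- cl(as.integer(e$z), d[1]); y <- cl(as.integer(e$y), d[2])
      x <- cl(as.integer(e$x), d[3])
      if (z[1] <= z[2] && y[1] <= y[2] && x[1] <= x[2])
        excl[z[1]:z[2], y[1]:y[2], x[1]:x[2]] <- TRUE
    } else stop("exclusion must be a mask_volume or a z/y/x box")
  }
  removed <- sum(m & excl)
  keep <- m & !excl
  lab <- mask$labels
  lab[!keep] <- 0L
  out <- mask_volume(lab, mask$spacing_mm, mask$label_map, mask$origin_mm)
  out$provenance <- c(mask$provenance, list(n_excluded_voxels = removed))
  out
}

#' Isolate the Th11 marrow from the marrow mask
#'
#' Intersects the segmented marrow with a Th11 label source (phantom ground
#' truth, or a user-supplied vertebra label volume for real data).
#'
#' @param marrow Binary marrow `mask_volume`.
#' @param labels A labeled `mask_volume` containing a `th11_marrow` label.
#' @return Binary `mask_volume` with label `th11_marrow`.
#' @export
extract_th11 <- function(marrow, labels) {
  stopifnot(inherits(marrow, "mask_volume"), inherits(labels, "mask_volume"))
  stop_if_grid_mismatch(marrow, labels, "marrow mask and Th11 label volume")
  sel <- (marrow$labels != 0L) & mask_binary(labels, "th11_marrow",
                                             include_th11 = FALSE)
  if (!any(sel)) stop("Th11 not represented in marrow mask")
  binary_mask_volume(sel, "th11_marrow", marrow$spacing_mm, marrow$origin_mm)
}

#' Mask the PET volume with the marrow mask
#'
#' Returns the "BM PET": PET values at marrow voxels, `NA` (undefined)
#' elsewhere.
#'
#' @param pet PET [image_volume()].
#' @param marrow Binary marrow `mask_volume` on the same grid.
#' @return An [image_volume()] with `NA` outside the mask.
#' @export
mask_pet <- function(pet, marrow) {
  stopifnot(inherits(pet, "image_volume"), inherits(marrow, "mask_volume"))
  stop_if_grid_mismatch(pet, marrow, "PET and marrow mask")
  vals <- pet$values
  vals[marrow$labels == 0L] <- NA_real_
  image_volume(vals, pet$spacing_mm, pet$modality, pet$origin_mm,
               allow_na = TRUE)
}

#' Segment one subject: bone, marrow, Th11 and BM PET
#'
#' Chains [segment_bone()], [erode_cortex()], [apply_exclusions()],
#' [extract_th11()] and [mask_pet()].
#'
#' @param ct CT [image_volume()].
#' @param pet PET [image_volume()] on the same grid.
#' @param th11_labels Labeled `mask_volume` providing the `th11_marrow`
#'   label (phantom truth or user-supplied).
#' @param config A [run_config()].
#' @param exclusions Exclusion regions for [apply_exclusions()].
#' @return A list of class `segmentation_result`: `bone_mask`, `marrow_mask`,
#'   `th11_mask`, `bm_pet`, `provenance`.
#' @export
segment_subject <- function(ct, pet, th11_labels, config = run_config(),
                            exclusions = list()) {
  stop_if_grid_mismatch(ct, pet, "CT and PET")
  bone <- segment_bone(ct, config)
  marrow <- erode_cortex(bone, config$erosion_pixels, config$erosion_3d)
  marrow <- apply_exclusions(marrow, exclusions)
  if (!any(marrow$labels != 0L)) stop("marrow mask empty after exclusions")
  th11 <- extract_th11(marrow, th11_labels)
  structure(list(
    bone_mask = bone,
    marrow_mask = marrow,
    th11_mask = th11,
    bm_pet = mask_pet(pet, marrow),
    provenance = list(config = config,
                      n_components_removed = bone$provenance$n_components_removed,
                      n_excluded_voxels = marrow$provenance$n_excluded_voxels)),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> bone %d, marrow %d, Th11 %d voxels\n",
              sum(x$bone_mask$labels != 0L), sum(x$marrow_mask$labels != 0L),
              sum(x$th11_mask$labels != 0L)))
  cat(sprintf("  %d small component(s) removed, %d voxel(s) excluded\n",
              x$provenance$n_components_removed,
              x$provenance$n_excluded_voxels))
  invisible(x)
}
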