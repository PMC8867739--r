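#' Read a 3D volume from NIfTI-1
#'
#' Volumes written by [write_volume()] store the array exactly as indexed in
#' this package, axes `(z, y, x)`, with the voxel spacing in `pixdim`, the
#' origin in the sform translation and the modality tag in `intent_name`.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param modality Modality to assume when the file carries no tag.
#' @param as_mask Read as a labeled [mask_volume()] instead of an image.
#' @param label_map Label dictionary for `as_mask = TRUE`.
#' @return An [image_volume()] or [mask_volume()].
#' @export
read_volume <- function(path, modality = NULL, as_mask = FALSE,
                        label_map = bm_label_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L)
    stop("non-3D image (", length(dim(arr)), " dimensions): ", path)
  spacing <- abs(hdr$pixdim[2:4])
  if (any(spacing <= 0)) stop("non-positive voxel spacing in ", path)
  origin <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
  if (as_mask)
    return(mask_volume(arr, spacing_mm = spacing, label_map = label_map,
                       origin_mm = origin))
  tag <- hdr$intent_name
  if (is.null(modality)) {
    modality <- if (is.character(tag) && tag %in% .modalities) tag else "CT_HU"
  }
  image_volume(arr, spacing_mm = spacing, modality = modality,
               origin_mm = origin)
}

#' Write a volume or mask to NIfTI-1
#'
#' Images are stored as 64-bit floats (lossless round trip), masks as 32-bit
#' integers. Non-finite voxel values are rejected; for masked volumes whose
#' undefined voxels are `NA`, supply `na_fill`.
#'
#' @param vol An [image_volume()] or [mask_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param na_fill Optional value replacing `NA` voxels before writing.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, na_fill = NULL) {
  UseMethod("write_volume")
}

.nifti_prepare <- function(arr, spacing_mm, origin_mm, intent = "") {
  img <- RNifti::asNifti(arr)
  xf <- diag(4)
  diag(xf)[1:3] <- spacing_mm
  xf[1:3, 4] <- origin_mm
  RNifti::`sform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::`pixdim<-`(img, spacing_mm) -> img
  img$intent_name <- intent
  img
}

#' @export
write_volume.image_volume <- function(vol, path, na_fill = NULL) {
  values <- vol$values
  if (!is.null(na_fill)) values[is.na(values)] <- na_fill
  if (any(!is.finite(values)))
    stop("non-finite values in volume; refusing to write (use `na_fill` for masked volumes)")
  img <- .nifti_prepare(values, vol$spacing_mm, vol$origin_mm, vol$modality)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @export
write_volume.mask_volume <- function(vol, path, na_fill = NULL) {
  img <- .nifti_prepare(vol$labels, vol$spacing_mm, vol$origin_mm, "LABELS")
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

.cohort_required <- c("subject_id", "sex", "age_y", "weight_kg", "height_m",
                      "injected_dose_bq", "wbc_1e3_per_ul", "hb_g_dl",
                      "smoking")

#' Read / write a cohort metadata table
#'
#' CSV with one row per subject. Units are encoded in the column names
#' (height in metres, weight in kg, injected dose in Bq) to prevent unit
#' drift. `sex` must be `M`/`F`; `smoking` must be `current` or
#' `former_or_non`.
#'
#' @param path CSV path.
#' @return A `data.frame` with validated, typed columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  validate_cohort(tab)
}

validate_cohort <- function(tab) {
  bad_sex <- which(!tab$sex %in% c("M", "F"))
  if (length(bad_sex))
    stop("invalid sex value '", tab$sex[bad_sex[1]], "' in row ", bad_sex[1])
  bad_smoke <- which(!tab$smoking %in% c("current", "former_or_non"))
  if (length(bad_smoke))
    stop("invalid smoking value '", tab$smoking[bad_smoke[1]], "' in row ",
         bad_smoke[1])
  num_cols <- c("age_y", "weight_kg", "height_m", "injected_dose_bq",
                "wbc_1e3_per_ul", "hb_g_dl")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v))
      stop("unparseable value in column '", cc, "' at row ", which(is.na(v))[1])
    tab[[cc]] <- v
  }
  if (anyDuplicated(tab$subject_id))
    stop("duplicated subject_id: ", tab$subject_id[duplicated(tab$subject_id)][1])
  tab
}

#' @rdname read_cohort
#' @param tab Cohort `data.frame`.
#' @export
write_cohort <- function(tab, path) {
  validate_cohort(tab[, union(.cohort_required, names(tab))])
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration as JSON
#' @param path JSON path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
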