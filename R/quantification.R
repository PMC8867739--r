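#' Body composition: BMI and lean body mass
#'
#' Lean body mass from sex, weight and height via the standard closed forms
#' used in PET SUL normalization:
#' \deqn{LBM_{man} = 9270 \cdot BW / (6680 + 216 \cdot BMI)}
#' \deqn{LBM_{woman} = 9270 \cdot BW / (8780 + 244 \cdot BMI)}
#' with \eqn{BMI = BW / height^2} (kg, m).
#'
#' @param sex `"M"` or `"F"`.
#' @param weight_kg Body weight in kg (> 0).
#' @param height_m Height in metres (> 0).
#' @return A list of class `body_composition` with `sex`, `weight_kg`,
#'   `height_m`, `bmi`, `lbm_kg`.
#' @examples
#' compute_lbm("M", 70, 1.75)$lbm_kg  # ~55.86
#' @export
compute_lbm <- function(sex, weight_kg, height_m) {
  sex <- match.arg(sex, c("M", "F"))
  if (!is.finite(weight_kg) || weight_kg <= 0 ||
      !is.finite(height_m) || height_m <= 0)
    stop("weight and height must be positive")
  bmi <- weight_kg / height_m^2
  lbm <- if (sex == "M") 9270 * weight_kg / (6680 + 216 * bmi)
         else 9270 * weight_kg / (8780 + 244 * bmi)
  structure(list(sex = sex, weight_kg = weight_kg, height_m = height_m,
                 bmi = bmi, lbm_kg = lbm),
            class = "body_composition")
}

#' @export
print.body_composition <- function(x, ...) {
  cat(sprintf("<body_composition> %s  %.1f kg, %.2f m, BMI %.1f, LBM %.2f kg\n",
              x$sex, x$weight_kg, x$height_m, x$bmi, x$lbm_kg))
  invisible(x)
}

#' Convert a PET activity volume to SUL
#'
#' Voxelwise \eqn{SUL = C \cdot LBM(g) / D} where `C` is the activity
#' concentration (Bq/ml), `D` the injected dose (Bq) and LBM the lean body
#' mass in grams. Doubling the dose at a fixed image halves every SUL; scaling
#' image and dose together leaves SUL unchanged.
#'
#' @param pet An [image_volume()] with modality `PET_BQML` (NA allowed for
#'   masked volumes).
#' @param meta A one-row subject metadata record (list or data.frame row) with
#'   `sex`, `weight_kg`, `height_m`, `injected_dose_bq`.
#' @return An [image_volume()] with modality `PET_SUL`.
#' @export
convert_to_sul <- function(pet, meta) {
  stopifnot(inherits(pet, "image_volume"))
  if (pet$modality != "PET_BQML")
    stop("convert_to_sul expects modality PET_BQML, got ", pet$modality)
  dose <- as.numeric(meta$injected_dose_bq)
  if (!is.finite(dose) || dose <= 0) stop("injected dose must be positive")
  bc <- compute_lbm(as.character(meta$sex), as.numeric(meta$weight_kg),
                    as.numeric(meta$height_m))
  vals <- pet$values * (bc$lbm_kg * 1000) / dose
  image_volume(vals, spacing_mm = pet$spacing_mm, modality = "PET_SUL",
               origin_mm = pet$origin_mm, allow_na = anyNA(vals))
}

#' Marrow volume and SUL summary statistics
#'
#' @param sul An [image_volume()] with modality `PET_SUL`.
#' @param marrow A `mask_volume` (marrow voxels; Th11 sub-label counts as
#'   marrow) on the same grid.
#' @return List with `volume_cm3` (voxel count times exact voxel volume),
#'   `sul_max`, `sul_mean`, `n_voxels`.
#' @export
bm_statistics <- function(sul, marrow) {
  stopifnot(inherits(sul, "image_volume"), inherits(marrow, "mask_volume"))
  stop_if_grid_mismatch(sul, marrow, "SUL volume and marrow mask")
  sel <- mask_binary(marrow, "marrow")
  v <- sul$values[sel]
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty marrow mask")
  voxel_cm3 <- prod(sul$spacing_mm) / 1000
  list(volume_cm3 = length(v) * voxel_cm3,
       sul_max = max(v), sul_mean = mean(v), n_voxels = length(v))
}

#' First-order histogram entropy (bits)
#'
#' Shannon entropy of the grayscale histogram of the masked voxel values:
#' `entropy_bins` equal-width bins spanning `[0, max(values)]` (last bin
#' right-closed), \eqn{H = -\sum p_i \log_2 p_i} over occupied bins. Constant
#' input gives 0 bits; the value is bounded by `log2(entropy_bins)`.
#'
#' @param values Numeric vector of masked SUL samples (>= 1 value).
#' @param entropy_bins Number of bins (default 64).
#' @return Entropy in bits.
#' @export
histogram_entropy <- function(values, entropy_bins = 64L) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input to histogram_entropy")
  if (any(values < 0)) stop("SUL values must be non-negative")
  counts <- sul_histogram(values, entropy_bins)$counts
  p <- counts[counts > 0] / length(values)
  -sum(p * log2(p))
}

# histogram over [0, max] with equal-width bins; bin i covers
# ((i-1)w, iw] except bin 1 which also includes 0
sul_histogram <- function(values, entropy_bins) {
  mx <- max(values)
  if (mx <= 0) {
    counts <- c(length(values), rep(0L, entropy_bins - 1L))
    return(list(bin_edges = seq(0, 1, length.out = entropy_bins + 1L),
                counts = counts))
  }
  idx <- pmin(floor(values / mx * entropy_bins) + 1L, entropy_bins)
  list(bin_edges = seq(0, mx, length.out = entropy_bins + 1L),
       counts = tabulate(idx, nbins = entropy_bins))
}

#' Mean SUL of the reference regions
#'
#' @param sul SUL [image_volume()].
#' @param mediastinum,liver `mask_volume`s of the reference structures.
#' @return List of class `reference_suls` with `mediastinum_sul_mean`,
#'   `liver_sul_mean`.
#' @export
reference_suls <- function(sul, mediastinum, liver) {
  one <- function(m, name) {
    stop_if_grid_mismatch(sul, m, paste("SUL volume and", name, "mask"))
    sel <- mask_binary(m, name, include_th11 = FALSE)
    v <- sul$values[sel]
    v <- v[!is.na(v)]
    if (!length(v)) stop("empty ", name, " reference mask")
    mean(v)
  }
  structure(list(mediastinum_sul_mean = one(mediastinum, "mediastinum"),
                 liver_sul_mean = one(liver, "liver")),
            class = "reference_suls")
}

#' Percentage of marrow volume above the mediastinal reference
#'
#' Strict inequality: `100 * #\{v > mediastinal mean\} / N`.
#'
#' @param marrow_suls Numeric vector of marrow SUL samples.
#' @param ref A [reference_suls()] (or list with `mediastinum_sul_mean`).
#' @return Percent in `[0, 100]`.
#' @export
pct_higher_volume <- function(marrow_suls, ref) {
  marrow_suls <- marrow_suls[!is.na(marrow_suls)]
  if (!length(marrow_suls)) stop("empty marrow sample")
  100 * sum(marrow_suls > ref$mediastinum_sul_mean) / length(marrow_suls)
}

#' Deauville-style reference-region score for Th11 marrow
#'
#' 2 = at or below the mediastinal mean; 3 = above the mediastinum and at or
#' below the liver; 4 = above the liver. Equality with a reference assigns
#' the lower score ("above" read strictly). Scores 1 and 5 are not emitted.
#'
#' @param th11_sul_mean Mean SUL of the Th11 marrow.
#' @param ref A [reference_suls()]; mediastinum must not exceed liver.
#' @return Integer score in `{2, 3, 4}`.
#' @export
deauville_score <- function(th11_sul_mean, ref) {
  med <- ref$mediastinum_sul_mean
  liv <- ref$liver_sul_mean
  if (liv < med) stop("inverted references: liver SUL below mediastinal SUL")
  if (th11_sul_mean <= med) 2L
  else if (th11_sul_mean <= liv) 3L
  else 4L
}

#' Quantify one subject: full per-subject readout
#'
#' Runs SUL conversion, marrow statistics, histogram entropy, reference
#' SULs, percent-higher volume and the Th11 reference-region score.
#'
#' @param pet Whole-body PET [image_volume()] (`PET_BQML`).
#' @param seg A `segmentation_result` from [segment_subject()].
#' @param meta Subject metadata row (`sex`, `age_y`, `weight_kg`, `height_m`,
#'   `injected_dose_bq`, ...).
#' @param ref_masks A labeled `mask_volume` containing `mediastinum` and
#'   `liver` labels (e.g. phantom ground truth).
#' @param config A [run_config()].
#' @return A list of class `bm_quant` with `volume_cm3`, `sul_max`,
#'   `sul_mean`, `entropy_bits`, `pct_higher_volume`, `deauville_score`,
#'   `th11_sul_mean`, reference means, `n_voxels` and the histogram.
#' @export
quantify_subject <- function(pet, seg, meta, ref_masks, config = run_config()) {
  stopifnot(inherits(seg, "segmentation_result"))
  sul <- convert_to_sul(pet, meta)
  stats <- bm_statistics(sul, seg$marrow_mask)
  marrow_vals <- sul$values[mask_binary(seg$marrow_mask, "marrow")]
  marrow_vals <- marrow_vals[!is.na(marrow_vals)]
  ent <- histogram_entropy(marrow_vals, config$entropy_bins)
  hist <- sul_histogram(marrow_vals, config$entropy_bins)
  refs <- reference_suls(sul, ref_masks, ref_masks)
  pct <- pct_higher_volume(marrow_vals, refs)
  th11_vals <- sul$values[mask_binary(seg$th11_mask, "th11_marrow")]
  th11_vals <- th11_vals[!is.na(th11_vals)]
  if (!length(th11_vals)) stop("empty Th11 mask at quantification")
  th11_mean <- mean(th11_vals)
  structure(list(
    volume_cm3 = stats$volume_cm3,
    sul_max = stats$sul_max,
    sul_mean = stats$sul_mean,
    entropy_bits = ent,
    pct_higher_volume = pct,
    deauville_score = deauville_score(th11_mean, refs),
    th11_sul_mean = th11_mean,
    mediastinum_sul_mean = refs$mediastinum_sul_mean,
    liver_sul_mean = refs$liver_sul_mean,
    n_voxels = stats$n_voxels,
    entropy_bins = config$entropy_bins,
    histogram = hist), class = "bm_quant")
}

#' @export
print.bm_quant <- function(x, ...) {
  cat("<bm_quant>\n")
  cat(sprintf("  volume     %9.2f cm^3 (%d voxels)\n", x$volume_cm3, x$n_voxels))
  cat(sprintf("  SUL_max    %9.3f\n  SUL_mean   %9.3f\n", x$sul_max, x$sul_mean))
  cat(sprintf("  entropy    %9.3f bits (%d bins)\n", x$entropy_bits, x$entropy_bins))
  cat(sprintf("  %%Higher    %9.3f %% (mediastinum %.3f)\n",
              x$pct_higher_volume, x$mediastinum_sul_mean))
  cat(sprintf("  Deauville  %9d (Th11 %.3f, liver %.3f)\n",
              x$deauville_score, x$th11_sul_mean, x$liver_sul_mean))
  invisible(x)
}
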