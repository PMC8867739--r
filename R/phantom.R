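#' Parameters of the digital torso phantom
#'
#' The phantom is deliberately blocky and parametric: a stack of
#' `n_vertebrae` contiguous vertebral cuboids plus two pelvic blocks, each
#' with an in-plane cortical shell (`cortical_thickness_vox` voxels) around a
#' marrow core, and cuboidal mediastinal and liver reference structures in
#' soft tissue. Ground-truth labels are exact pre-blur geometry. Marrow
#' uptake follows a linear age model with sex-specific intercepts
#' (see [expected_marrow_sul()]); within-marrow dispersion declines linearly
#' with age, encoding that younger marrow is more heterogeneous.
#'
#' @param shape Grid shape `(nz, ny, nx)`.
#' @param spacing_mm Voxel spacing `(sz, sy, sx)` in mm; default
#'   `(5, 4.11, 4.11)`, a typical reconstructed PET/CT grid.
#' @param n_vertebrae Number of stacked vertebral segments (default 12). The
#'   most caudal segment (0-based index `n_vertebrae - 1`) is labeled as the
#'   Th11 sub-region.
#' @param vertebra_marrow_yx In-plane marrow extent of a vertebra, voxels.
#' @param vertebra_height_vox Axial extent of one vertebra, voxels.
#' @param pelvis_marrow_zyx Marrow extent `(z, y, x)` of each pelvic block.
#' @param cortical_thickness_vox In-plane cortical shell thickness (>= 1).
#' @param hu_bone,hu_marrow,hu_soft CT values (HU) of cortical bone, marrow
#'   and soft tissue.
#' @param a_sex Baseline marrow SUL mean per sex at `age_center`.
#' @param b_age Marrow SUL change per year of age (negative: uptake declines
#'   with age).
#' @param age_center Age (years) at which `a_sex` applies.
#' @param heterogeneity_sd Within-marrow SUL standard deviation at
#'   `age_center`.
#' @param heterogeneity_age_slope Change of the within-marrow SD per year of
#'   age (negative default: younger marrow more heterogeneous).
#' @param mediastinum_sul,liver_sul True mean SUL of the reference regions.
#' @param background_sul,bone_sul True SUL of soft tissue and cortical bone.
#' @param noise_sd Reconstruction-like noise scale: additive Gaussian with
#'   SD `noise_sd * sqrt(signal)`, applied after smoothing, clamped at 0.
#' @param psf_fwhm_mm Gaussian post-smoothing FWHM in mm (0 disables).
#' @param size_scale Linear skeleton scale per sex (women smaller).
#' @param size_jitter_sd SD of the per-subject log-normal size jitter.
#' @param seed Integer seed; phantom generation is deterministic given the
#'   seed.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(80L, 64L, 96L),
                           spacing_mm = c(5, 4.11, 4.11),
                           n_vertebrae = 12L,
                           vertebra_marrow_yx = c(9L, 9L),
                           vertebra_height_vox = 5L,
                           pelvis_marrow_zyx = c(10L, 16L, 27L),
                           cortical_thickness_vox = 2L,
                           hu_bone = 800, hu_marrow = 100, hu_soft = 40,
                           a_sex = c(M = 0.79, F = 0.75),
                           b_age = -0.004,
                           age_center = 55,
                           heterogeneity_sd = 0.12,
                           heterogeneity_age_slope = -0.0015,
                           mediastinum_sul = 0.95, liver_sul = 1.30,
                           background_sul = 0.20, bone_sul = 0.10,
                           noise_sd = 0.05, psf_fwhm_mm = 5,
                           size_scale = c(M = 1.0, F = 0.888),
                           size_jitter_sd = 0.04,
                           seed = 1L) {
  p <- as.list(environment())
  if (p$cortical_thickness_vox < 1) stop("cortical_thickness_vox must be >= 1")
  if (any(c(p$a_sex, p$mediastinum_sul, p$liver_sul, p$background_sul,
            p$bone_sul) < 0))
    stop("uptake levels must be >= 0")
  structure(p, class = "phantom_params")
}

#' Expected (true) marrow SUL mean for a subject
#'
#' Linear age model with sex-specific intercept:
#' `a_sex[sex] + b_age * (age - age_center)`, clamped at 0.05. With the
#' defaults, marrow uptake declines with age and men exceed women, matching
#' the direction of the reference cohort findings.
#'
#' @param meta Subject metadata (list or one-row data.frame with `sex`,
#'   `age_y`).
#' @param params A [phantom_params()].
#' @return True marrow SUL mean (unitless).
#' @export
expected_marrow_sul <- function(meta, params = phantom_params()) {
  sex <- match.arg(as.character(meta$sex), c("M", "F"))
  mu <- unname(params$a_sex[[sex]]) +
    params$b_age * (as.numeric(meta$age_y) - params$age_center)
  max(mu, 0.05)
}

# internal: box = list(z = c(lo, hi), y = ..., x = ...) in 1-based voxel index
paint_box <- function(arr, box, value) {
  arr[box$z[1]:box$z[2], box$y[1]:box$y[2], box$x[1]:box$x[2]] <- value
  arr
}

box_inside <- function(box, shape) {
  all(box$z >= 1, box$z[2] <= shape[1], box$y >= 1, box$y[2] <= shape[2],
      box$x >= 1, box$x[2] <= shape[3]) && all(
        box$z[1] <= box$z[2], box$y[1] <= box$y[2], box$x[1] <= box$x[2])
}

centered <- function(center, width) {
  lo <- center - (width - 1L) %/% 2L
  c(lo, lo + width - 1L)
}

# phantom geometry at a given linear scale; all boxes in voxel indices
phantom_geometry <- function(params, scale) {
  shp <- params$shape
  ct <- params$cortical_thickness_vox
  sw <- function(v) pmax(2L, as.integer(round(v * scale)))
  vy <- sw(params$vertebra_marrow_yx[1])
  vx <- sw(params$vertebra_marrow_yx[2])
  vh <- sw(params$vertebra_height_vox)
  pz <- sw(params$pelvis_marrow_zyx[1])
  py <- sw(params$pelvis_marrow_zyx[2])
  px <- sw(params$pelvis_marrow_zyx[3])
  nv <- params$n_vertebrae
  spine_z0 <- 7L
  y_c <- as.integer(round(shp[2] * 0.56))
  x_c <- as.integer(round(shp[3] * 0.50))
  spine <- list(
    marrow = list(z = c(spine_z0, spine_z0 + nv * vh - 1L),
                  y = centered(y_c, vy), x = centered(x_c, vx)),
    bone = list(z = c(spine_z0, spine_z0 + nv * vh - 1L),
                y = centered(y_c, vy + 2L * ct), x = centered(x_c, vx + 2L * ct)))
  th11_z <- c(spine_z0 + (nv - 1L) * vh, spine_z0 + nv * vh - 1L)
  pelvis_z0 <- spine$bone$z[2] + 4L
  pelvis <- lapply(c(-1, 1), function(side) {
    xc <- x_c + as.integer(side * round((px + 2L * ct + 8L) / 2 + 6L))
    list(marrow = list(z = c(pelvis_z0, pelvis_z0 + pz - 1L),
                       y = centered(y_c, py), x = centered(xc, px)),
         bone = list(z = c(pelvis_z0, pelvis_z0 + pz - 1L),
                     y = centered(y_c, py + 2L * ct),
                     x = centered(xc, px + 2L * ct)))
  })
  # reference boxes scale with spine length and sit anterior (lower y) of it
  L <- nv * vh
  mediastinum <- list(z = c(spine_z0 + as.integer(round(0.08 * L)),
                            spine_z0 + as.integer(round(0.38 * L))),
                      y = c(max(2L, spine$bone$y[1] - 14L), spine$bone$y[1] - 4L),
                      x = centered(x_c, 17L))
  liver <- list(z = c(spine_z0 + as.integer(round(0.63 * L)),
                      spine_z0 + as.integer(round(0.92 * L))),
                y = c(max(2L, spine$bone$y[1] - 16L), spine$bone$y[1] - 1L),
                x = c(spine$bone$x[2] + 6L, min(shp[3] - 4L, spine$bone$x[2] + 32L)))
  list(spine = spine, th11_z = th11_z, pelvis = pelvis,
       mediastinum = mediastinum, liver = liver)
}

#' Generate one synthetic CT/PET subject with ground truth
#'
#' Builds the CT (HU), the PET volume (stored in Bq/ml via the inverse SUL
#' relation using the subject's injected dose and lean body mass), and the
#' exact ground-truth label volume. The PET signal is the true SUL map
#' (marrow mean from [expected_marrow_sul()] with Gaussian within-marrow
#' heterogeneity), optionally smoothed with a Gaussian point-spread function
#' and corrupted with signal-dependent Gaussian noise. Deterministic given
#' `params$seed`.
#'
#' @param meta Subject metadata (needs `sex`, `age_y`, `weight_kg`,
#'   `height_m`, `injected_dose_bq`).
#' @param params A [phantom_params()].
#' @return A list of class `phantom_subject` with elements `ct`, `pet`
#'   ([image_volume()]s), `truth` ([mask_volume()] with bone / marrow /
#'   th11_marrow / mediastinum / liver labels), `meta`, and `expected`
#'   (true per-structure mean SUL).
#' @export
generate_phantom <- function(meta, params = phantom_params()) {
  set.seed(params$seed)
  shp <- as.integer(params$shape)
  lm <- bm_label_map()
  scale <- unname(params$size_scale[[as.character(meta$sex)]]) *
    exp(rnorm(1, 0, params$size_jitter_sd))
  # keep the jittered skeleton inside the default grid
  scale <- min(max(scale, 0.75), 1.08)
  geo <- phantom_geometry(params, scale)

  boxes <- c(list(geo$spine$bone), lapply(geo$pelvis, `[[`, "bone"),
             list(geo$mediastinum, geo$liver))
  for (b in boxes) {
    if (!box_inside(b, shp))
      stop("phantom structure does not fit inside the grid; enlarge `shape`")
  }

  # paint labels; painting into nonzero voxels means structures overlap
  labels <- array(0L, dim = shp)
  paint_checked <- function(labels, box, code) {
    cur <- labels[box$z[1]:box$z[2], box$y[1]:box$y[2], box$x[1]:box$x[2]]
    if (any(cur != 0L & cur != code))
      stop("phantom structures would overlap; adjust geometry parameters")
    paint_box(labels, box, code)
  }
  labels <- paint_checked(labels, geo$spine$bone, lm[["bone"]])
  labels <- paint_box(labels, geo$spine$marrow, lm[["marrow"]])
  th11_box <- geo$spine$marrow
  th11_box$z <- geo$th11_z
  labels <- paint_box(labels, th11_box, lm[["th11_marrow"]])
  for (p in geo$pelvis) {
    labels <- paint_checked(labels, p$bone, lm[["bone"]])
    labels <- paint_box(labels, p$marrow, lm[["marrow"]])
  }
  labels <- paint_checked(labels, geo$mediastinum, lm[["mediastinum"]])
  labels <- paint_checked(labels, geo$liver, lm[["liver"]])

  is_bone <- labels == lm[["bone"]]
  is_marrow <- labels == lm[["marrow"]] | labels == lm[["th11_marrow"]]

  ct_vals <- array(params$hu_soft, dim = shp)
  ct_vals[is_bone] <- params$hu_bone
  ct_vals[is_marrow] <- params$hu_marrow
  ct_vals[labels == lm[["liver"]]] <- 60
  ct_vals[labels == lm[["mediastinum"]]] <- 45

  mu <- expected_marrow_sul(meta, params)
  het <- max(params$heterogeneity_sd + params$heterogeneity_age_slope *
               (as.numeric(meta$age_y) - params$age_center), 0.02)
  sul <- array(params$background_sul, dim = shp)
  sul[is_bone] <- params$bone_sul
  n_marrow <- sum(is_marrow)
  if (params$heterogeneity_sd > 0) {
    sul[is_marrow] <- rnorm(n_marrow, mu, het)
  } else {
    sul[is_marrow] <- mu
  }
  sul[labels == lm[["mediastinum"]]] <- params$mediastinum_sul
  sul[labels == lm[["liver"]]] <- params$liver_sul
  sul <- pmax(sul, 0)
  if (params$psf_fwhm_mm > 0)
    sul <- gaussian_blur(sul, params$psf_fwhm_mm, params$spacing_mm)
  if (params$noise_sd > 0) {
    sul <- sul + rnorm(length(sul), 0, params$noise_sd * sqrt(pmax(sul, 0)))
    sul <- pmax(sul, 0)
  }

  dose <- as.numeric(meta$injected_dose_bq)
  bc <- compute_lbm(as.character(meta$sex), as.numeric(meta$weight_kg),
                    as.numeric(meta$height_m))
  pet_bqml <- sul * dose / (bc$lbm_kg * 1000)

  structure(list(
    ct = image_volume(ct_vals, params$spacing_mm, "CT_HU"),
    pet = image_volume(pet_bqml, params$spacing_mm, "PET_BQML"),
    truth = mask_volume(labels, params$spacing_mm),
    meta = meta,
    expected = list(marrow_sul = mu,
                    mediastinum_sul = params$mediastinum_sul,
                    liver_sul = params$liver_sul,
                    heterogeneity_sd = het,
                    size_scale = scale)),
    class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> %s, age %.0f: true marrow SUL %.3f, %d marrow voxels\n",
              x$meta$sex, as.numeric(x$meta$age_y), x$expected$marrow_sul,
              sum(mask_binary(x$truth, "marrow"))))
  invisible(x)
}

#' Simulate a cohort metadata table
#'
#' Draws `n` subjects with the demographic structure of a healthy adult
#' FDG-PET screening cohort: sexes ~57:41 male:female; per-sex Gaussian ages
#' (men 55.5 +/- 14.2 y, women 56.3 +/- 18.9 y) limited to the enrollment
#' range 20-80 y by boundary clamping; heights and BMI drawn so the implied
#' lean body mass (via [compute_lbm()]) has per-sex means near 52.6 kg (men)
#' and 34.7 kg (women); injected dose 3 MBq/kg; WBC and hemoglobin Gaussian
#' within their normal ranges; current-smoking prevalence 30% (men) / 12%
#' (women). Deterministic given `seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @return A cohort `data.frame` (see [read_cohort()] for the columns).
#' @export
generate_cohort <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  sex <- ifelse(runif(n) < 57 / 98, "M", "F")
  m <- sex == "M"
  age <- numeric(n)
  age[m] <- clamp(rnorm(sum(m), 55.5, 14.2), 20, 80)
  age[!m] <- clamp(rnorm(sum(!m), 56.3, 18.9), 20, 80)
  height <- numeric(n)
  height[m] <- clamp(rnorm(sum(m), 1.70, 0.06), 1.45, 1.95)
  height[!m] <- clamp(rnorm(sum(!m), 1.57, 0.055), 1.35, 1.85)
  bmi <- numeric(n)
  bmi[m] <- clamp(rnorm(sum(m), 23.2, 2.5), 16, 35)
  bmi[!m] <- clamp(rnorm(sum(!m), 21.5, 2.8), 16, 35)
  weight <- bmi * height^2
  wbc <- numeric(n)
  wbc[m] <- clamp(rnorm(sum(m), 6.0, 1.6), 3.5, 9.7)
  wbc[!m] <- clamp(rnorm(sum(!m), 5.3, 1.1), 3.5, 9.7)
  hb <- numeric(n)
  hb[m] <- clamp(rnorm(sum(m), 15.0, 1.1), 12.6, 17.6)
  hb[!m] <- clamp(rnorm(sum(!m), 13.0, 0.9), 10.6, 15.2)
  smoking <- ifelse(runif(n) < ifelse(m, 0.30, 0.12), "current", "former_or_non")
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex, age_y = age, weight_kg = weight, height_m = height,
    injected_dose_bq = 3e6 * weight,
    wbc_1e3_per_ul = wbc, hb_g_dl = hb, smoking = smoking,
    stringsAsFactors = FALSE)
}
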