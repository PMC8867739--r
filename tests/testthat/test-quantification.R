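test_that("lean body mass matches hand evaluation of the closed forms", {
  # man 70 kg, 1.75 m: BMI = 70/1.75^2; LBM = 9270*70 / (6680 + 216*BMI)
  bmi_m <- 70 / 1.75^2
  expect_equal(compute_lbm("M", 70, 1.75)$lbm_kg,
               9270 * 70 / (6680 + 216 * bmi_m), tolerance = 1e-12)
  expect_lt(abs(compute_lbm("M", 70, 1.75)$lbm_kg - 55.85), 0.01)
  # woman 60 kg at BMI 24 (height sqrt(60/24)): LBM = 556200 / 14636
  h <- sqrt(60 / 24)
  expect_lt(abs(compute_lbm("F", 60, h)$lbm_kg - 556200 / 14636), 1e-9)
  expect_lt(abs(compute_lbm("F", 60, h)$lbm_kg - 38.00), 0.01)
  # monotone increasing in body weight at fixed BMI
  lbm_at <- function(w, bmi) compute_lbm("M", w, sqrt(w / bmi))$lbm_kg
  w <- seq(50, 110, by = 5)
  expect_true(all(diff(vapply(w, lbm_at, numeric(1), bmi = 24)) > 0))
  expect_error(compute_lbm("M", -1, 1.7), "positive")
  expect_error(compute_lbm("F", 60, 0), "positive")
})

test_that("SUL conversion has the right identity point, homogeneity and scale", {
  meta <- test_meta()
  bc <- compute_lbm(meta$sex, meta$weight_kg, meta$height_m)
  conc0 <- meta$injected_dose_bq / (bc$lbm_kg * 1000)
  pet <- image_volume(array(conc0, dim = c(4, 4, 4)), modality = "PET_BQML")
  sul <- convert_to_sul(pet, meta)
  expect_equal(as.vector(sul$values), rep(1, 64), tolerance = 1e-12)
  expect_identical(sul$modality, "PET_SUL")

  meta2 <- meta; meta2$injected_dose_bq <- 2 * meta$injected_dose_bq
  expect_equal(convert_to_sul(pet, meta2)$values, sul$values / 2,
               tolerance = 1e-12)

  # worked value: 5000 Bq/ml, 210 MBq, LBM from the closed form
  meta3 <- test_meta(weight = 70, height = 1.75)
  meta3$injected_dose_bq <- 2.1e8
  pet3 <- image_volume(array(5000, dim = c(2, 2, 2)), modality = "PET_BQML")
  lbm_g <- compute_lbm("M", 70, 1.75)$lbm_kg * 1000
  expect_equal(convert_to_sul(pet3, meta3)$values[1], 5000 * lbm_g / 2.1e8,
               tolerance = 1e-12)
  expect_lt(abs(convert_to_sul(pet3, meta3)$values[1] - 1.3298), 2e-3)

  expect_error(convert_to_sul(sul, meta), "PET_BQML")
  meta4 <- meta; meta4$injected_dose_bq <- 0
  expect_error(convert_to_sul(pet, meta4), "dose")
})

test_that("scaling PET and dose together leaves every SUL unchanged", {
  meta <- test_meta()
  set.seed(12)
  pet <- image_volume(array(runif(64, 0, 9000), dim = c(4, 4, 4)),
                      modality = "PET_BQML")
  for (k in c(0.5, 3, 10)) {
    meta_k <- meta; meta_k$injected_dose_bq <- k * meta$injected_dose_bq
    pet_k <- image_volume(k * pet$values, spacing_mm = pet$spacing_mm,
                          modality = "PET_BQML")
    expect_equal(convert_to_sul(pet_k, meta_k)$values,
                 convert_to_sul(pet, meta)$values, tolerance = 1e-12)
  }
})

test_that("marrow statistics use the exact voxel volume", {
  vals <- array(0.5, dim = c(10, 10, 10))
  sel <- array(TRUE, dim = dim(vals))   # 1000 masked voxels
  sul <- image_volume(vals, spacing_mm = c(5, 4.11, 4.11), modality = "PET_SUL")
  m <- binary_mask_volume(sel, "marrow", c(5, 4.11, 4.11))
  st <- bm_statistics(sul, m)
  expect_identical(st$volume_cm3, 1000 * (5 * 4.11 * 4.11) / 1000)
  expect_equal(st$sul_max, 0.5)
  expect_equal(st$sul_mean, 0.5)

  vals3 <- array(0, dim = c(1, 1, 3)); vals3[1, 1, ] <- c(0.5, 1.0, 1.5)
  sul3 <- image_volume(vals3, c(1, 1, 1), "PET_SUL")
  m3 <- binary_mask_volume(array(TRUE, dim(vals3)), "marrow", c(1, 1, 1))
  st3 <- bm_statistics(sul3, m3)
  expect_equal(st3$sul_max, 1.5)
  expect_equal(st3$sul_mean, 1.0)

  empty <- binary_mask_volume(array(FALSE, dim(vals3)), "marrow", c(1, 1, 1))
  expect_error(bm_statistics(sul3, empty), "empty marrow mask")
})

test_that("histogram entropy reproduces the analytic cases", {
  expect_equal(histogram_entropy(rep(0.8, 500), 64), 0)
  # one sample per bin over 64 bins: bin centres (i - 0.5) * max/64
  centres <- (seq_len(64) - 0.5)
  expect_equal(histogram_entropy(centres, 64), 6)
  # occupancy (1/2, 1/4, 1/4) -> 1.5 bits
  expect_equal(histogram_entropy(c(0.1, 0.1, 0.5, 0.9), 64), 1.5)
  expect_error(histogram_entropy(numeric(0)), "empty")
})

test_that("entropy is permutation invariant and bounded by log2(bins)", {
  set.seed(21)
  for (i in 1:20) {
    v <- rgamma(400, shape = 3, rate = 4)
    bins <- sample(c(16, 64, 128), 1)
    h <- histogram_entropy(v, bins)
    expect_equal(histogram_entropy(sample(v), bins), h)
    expect_lte(h, log2(bins))
    expect_gte(h, 0)
  }
})

test_that("reference SULs are plain means over the reference masks", {
  vals <- array(0, dim = c(2, 2, 2))
  vals[1, 1, 1] <- 0.6; vals[2, 1, 1] <- 0.8
  vals[1, 2, 1] <- 1.0; vals[2, 2, 1] <- 1.0
  sul <- image_volume(vals, c(1, 1, 1), "PET_SUL")
  lmap <- bm_label_map()
  lab <- array(0L, dim = c(2, 2, 2))
  lab[1:2, 1, 1] <- lmap[["mediastinum"]]
  lab[1:2, 2, 1] <- lmap[["liver"]]
  m <- mask_volume(lab, c(1, 1, 1))
  refs <- reference_suls(sul, m, m)
  expect_equal(refs$mediastinum_sul_mean, 0.7)
  expect_equal(refs$liver_sul_mean, 1.0)

  empty <- mask_volume(array(0L, dim = c(2, 2, 2)), c(1, 1, 1))
  expect_error(reference_suls(sul, empty, m), "empty mediastinum")
})

test_that("clean phantom reference regions recover their configured levels", {
  ph <- generate_phantom(test_meta(), clean_params())
  sul <- convert_to_sul(ph$pet, test_meta())
  refs <- reference_suls(sul, ph$truth, ph$truth)
  expect_equal(refs$mediastinum_sul_mean, ph$expected$mediastinum_sul,
               tolerance = 1e-6)
  expect_equal(refs$liver_sul_mean, ph$expected$liver_sul, tolerance = 1e-6)
})

test_that("percent-higher volume is an exact strict-threshold count", {
  ref <- function(x) list(mediastinum_sul_mean = x)
  expect_equal(pct_higher_volume(c(0.2, 0.5, 1.3), ref(0)), 100)
  expect_equal(pct_higher_volume(c(0.2, 0.5, 1.3), ref(2)), 0)
  eight <- c(0.5, 0.9, 1.1, 1.3, 0.2, 0.4, 0.6, 0.7)
  expect_equal(pct_higher_volume(eight, ref(0.8)), 37.5)
  # strictness at the boundary
  expect_equal(pct_higher_volume(c(0.8, 0.8, 0.9), ref(0.8)), 100 / 3)
})

test_that("raising all marrow SULs never lowers percent-higher or the score", {
  set.seed(33)
  ref <- list(mediastinum_sul_mean = 0.9, liver_sul_mean = 1.3)
  for (i in 1:25) {
    v <- runif(200, 0, 1.6)
    p0 <- pct_higher_volume(v, ref)
    s0 <- deauville_score(mean(v), ref)
    d <- runif(1, 0, 0.5)
    expect_gte(pct_higher_volume(v + d, ref), p0)
    expect_gte(deauville_score(mean(v) + d, ref), s0)
  }
})

test_that("the Th11 reference-region score follows the footnote rules", {
  ref <- list(mediastinum_sul_mean = 0.7, liver_sul_mean = 1.0)
  expect_identical(deauville_score(0.5, ref), 2L)
  expect_identical(deauville_score(0.8, ref), 3L)
  expect_identical(deauville_score(1.2, ref), 4L)
  # equality assigns the lower score
  expect_identical(deauville_score(0.7, ref), 2L)
  expect_identical(deauville_score(1.0, ref), 3L)
  expect_error(deauville_score(0.8, list(mediastinum_sul_mean = 1.1,
                                         liver_sul_mean = 1.0)),
               "inverted references")
})

test_that("subject quantification composes the pipeline faithfully", {
  meta <- test_meta()
  ph <- generate_phantom(meta, clean_params())
  seg <- segment_subject(ph$ct, ph$pet, ph$truth)
  q <- quantify_subject(ph$pet, seg, meta, ph$truth)
  expect_equal(q$sul_mean, ph$expected$marrow_sul, tolerance = 1e-6)
  expect_equal(q$volume_cm3, q$n_voxels * prod(ph$pet$spacing_mm) / 1000)
  expect_true(q$sul_max >= q$sul_mean)
  expect_true(q$deauville_score %in% 2:4)

  # mediastinum configured above all marrow: nothing higher, score 2
  ph2 <- generate_phantom(meta, clean_params(mediastinum_sul = 2.0,
                                             liver_sul = 2.5))
  seg2 <- segment_subject(ph2$ct, ph2$pet, ph2$truth)
  q2 <- quantify_subject(ph2$pet, seg2, meta, ph2$truth)
  expect_equal(q2$pct_higher_volume, 0)
  expect_identical(q2$deauville_score, 2L)

  # with default noise and smoothing, the measured mean stays close to truth
  ph3 <- generate_phantom(meta, tiny_params())
  seg3 <- segment_subject(ph3$ct, ph3$pet, ph3$truth)
  q3 <- quantify_subject(ph3$pet, seg3, meta, ph3$truth)
  expect_lt(abs(q3$sul_mean - ph3$expected$marrow_sul), 0.05)
})
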