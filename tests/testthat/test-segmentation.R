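test_that("bone extraction covers the cortical shell and rejects boneless CT", {
  ph <- generate_phantom(test_meta(), clean_params())
  bone <- segment_bone(ph$ct, run_config())
  truth_bone <- mask_binary(ph$truth, "bone", include_th11 = FALSE)
  expect_true(all(bone$labels[truth_bone] != 0L))

  soft <- image_volume(array(40, dim = c(8, 8, 8)), modality = "CT_HU")
  expect_error(segment_bone(soft, run_config()), "no bone above threshold")
})

test_that("small isolated components are discarded from the bone mask", {
  ct_arr <- array(40, dim = c(20, 20, 20))
  ct_arr[5:15, 5:15, 5:15] <- 800          # one solid block, 1331 voxels
  ct_arr[2, 2, 2:4] <- 800                 # isolated 3-voxel calcification
  ct <- image_volume(ct_arr, spacing_mm = c(1, 1, 1), modality = "CT_HU")
  bone <- segment_bone(ct, run_config(min_component_voxels = 10))
  expect_true(all(bone$labels[2, 2, 2:4] == 0L))
  expect_true(all(bone$labels[5:15, 5:15, 5:15] != 0L))
  expect_identical(bone$provenance$n_components_removed, 1L)
})

test_that("cortex erosion follows 2D cross morphology", {
  # single axial slice holding a 5x5 solid square
  lab <- array(0L, dim = c(1, 9, 9))
  lab[1, 3:7, 3:7] <- 1L
  m <- mask_volume(lab, spacing_mm = c(1, 1, 1))
  e0 <- erode_cortex(m, 0)
  expect_equal(sum(e0$labels != 0L), 25)
  e2 <- erode_cortex(m, 2)
  # exactly the centre voxel (z=1, y=5, x=5) survives two cross erosions
  expect_equal(which(e2$labels != 0L), 1L + (5L - 1L) * 1L + (5L - 1L) * 9L)
  expect_equal(sum(e2$labels != 0L), 1)

  # anti-extensivity on random masks
  set.seed(99)
  for (i in 1:100) {
    r <- array(runif(6 * 12 * 12) < 0.45, dim = c(6, 12, 12))
    rm <- binary_mask_volume(r, "bone", c(1, 1, 1))
    er <- erode_cortex(rm, sample(0:3, 1))
    expect_true(all(which(er$labels != 0L) %in% which(r)))
  }
})

test_that("3D erosion shrinks across slices while 2D does not", {
  lab <- array(0L, dim = c(5, 7, 7))
  lab[1:5, 2:6, 2:6] <- 1L
  m <- mask_volume(lab, c(1, 1, 1))
  e2d <- erode_cortex(m, 1, three_d = FALSE)
  e3d <- erode_cortex(m, 1, three_d = TRUE)
  expect_equal(sum(e2d$labels != 0L), 5 * 9)   # 3x3 core kept on all 5 slices
  expect_equal(sum(e3d$labels != 0L), 3 * 9)   # axial faces eroded too
})

test_that("exclusion removal is exact set arithmetic with provenance", {
  lab <- array(0L, dim = c(4, 10, 10))
  lab[1:4, 1:5, 1:5] <- 2L                     # 100 marrow voxels
  m <- mask_volume(lab, c(1, 1, 1))
  same <- apply_exclusions(m, list())
  expect_identical(same$labels, m$labels)

  all_gone <- apply_exclusions(m, list(list(z = c(1, 4), y = c(1, 10),
                                            x = c(1, 10))))
  expect_equal(sum(all_gone$labels != 0L), 0)
  expect_equal(all_gone$provenance$n_excluded_voxels, 100)

  # box overlapping exactly 17 mask voxels: 4 z-slices x 4 y x 1 x = 16, plus 1
  part <- apply_exclusions(m, list(list(z = c(1, 4), y = c(2, 5), x = c(1, 1)),
                                   list(z = c(1, 1), y = c(1, 1), x = c(2, 2))))
  expect_equal(part$provenance$n_excluded_voxels, 17)
  expect_equal(sum(part$labels != 0L), 83)
})

test_that("Th11 isolation intersects the marrow with the vertebra label", {
  ph <- generate_phantom(test_meta(), clean_params())
  seg <- segment_subject(ph$ct, ph$pet, ph$truth)
  expect_gt(sum(seg$th11_mask$labels != 0L), 0)
  expect_true(all(which(seg$th11_mask$labels != 0L) %in%
                    which(seg$marrow_mask$labels != 0L)))

  # toy two-band marrow column against a Th11 label: hand-counted overlap
  marrow <- array(0L, dim = c(8, 4, 4))
  marrow[1:6, 2:3, 2:3] <- 2L
  th11 <- array(0L, dim = c(8, 4, 4))
  th11[5:8, 2:3, 2:3] <- 3L
  got <- extract_th11(mask_volume(marrow, c(1, 1, 1)),
                      mask_volume(th11, c(1, 1, 1)))
  expect_equal(sum(got$labels != 0L), 2 * 2 * 2)  # z 5:6 overlap only

  # marrow missing the Th11 vertebra -> explicit error
  bone <- segment_bone(ph$ct, run_config())
  marrow_full <- erode_cortex(bone, 2)
  lmap <- bm_label_map()
  th11_box <- which(ph$truth$labels == lmap[["th11_marrow"]], arr.ind = TRUE)
  cut <- apply_exclusions(marrow_full, list(list(
    z = range(th11_box[, 1]), y = range(th11_box[, 2]),
    x = range(th11_box[, 3]))))
  expect_error(extract_th11(cut, ph$truth), "Th11 not represented")
})

test_that("PET masking keeps exactly the masked values", {
  ph <- generate_phantom(test_meta(), clean_params())
  d <- dim(ph$pet$values)
  full <- binary_mask_volume(array(TRUE, d), "marrow", ph$pet$spacing_mm)
  expect_identical(mask_pet(ph$pet, full)$values, ph$pet$values)

  none <- binary_mask_volume(array(FALSE, d), "marrow", ph$pet$spacing_mm)
  expect_true(all(is.na(mask_pet(ph$pet, none)$values)))

  set.seed(4)
  idx <- sample(prod(d), 10)
  sel <- array(FALSE, d); sel[idx] <- TRUE
  sparse <- binary_mask_volume(sel, "marrow", ph$pet$spacing_mm)
  bm <- mask_pet(ph$pet, sparse)
  expect_identical(bm$values[idx], ph$pet$values[idx])
  expect_equal(sum(!is.na(bm$values)), 10)

  wrong <- binary_mask_volume(array(TRUE, c(2, 2, 2)), "marrow", c(1, 1, 1))
  expect_error(mask_pet(ph$pet, wrong), "grid mismatch")
})

test_that("segmentation nests th11 in marrow in bone and is deterministic", {
  ph <- generate_phantom(test_meta("F", age = 40), tiny_params())
  a <- segment_subject(ph$ct, ph$pet, ph$truth)
  b <- segment_subject(ph$ct, ph$pet, ph$truth)
  expect_identical(a$marrow_mask$labels, b$marrow_mask$labels)
  in_mask <- function(m) which(m$labels != 0L)
  expect_true(all(in_mask(a$th11_mask) %in% in_mask(a$marrow_mask)))
  expect_true(all(in_mask(a$marrow_mask) %in% in_mask(a$bone_mask)))
})

test_that("marrow recovery on clean phantoms is essentially exact", {
  ph <- generate_phantom(test_meta(), clean_params())
  seg <- segment_subject(ph$ct, ph$pet, ph$truth)
  iou <- intersection_over_union(seg$marrow_mask, truth_marrow_mask(ph))
  expect_gte(iou, 0.90)
})
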