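# Small fixtures built in code: a reduced phantom grid keeps unit tests fast;
# acceptance checks use the full default geometry.

tiny_params <- function(..., seed = 42L) {
  phantom_params(shape = c(48L, 48L, 64L), n_vertebrae = 6L,
                 pelvis_marrow_zyx = c(6L, 10L, 16L), seed = seed, ...)
}

test_meta <- function(sex = "M", age = 55, weight = 67, height = 1.70,
                      id = "S0001") {
  list(subject_id = id, sex = sex, age_y = age, weight_kg = weight,
       height_m = height, injected_dose_bq = 3e6 * weight,
       wbc_1e3_per_ul = 6, hb_g_dl = 15, smoking = "former_or_non")
}

# clean phantom: no noise, no smoothing, no heterogeneity, no size jitter
clean_params <- function(...) {
  tiny_params(noise_sd = 0, psf_fwhm_mm = 0, heterogeneity_sd = 0,
              heterogeneity_age_slope = 0, size_jitter_sd = 0, ...)
}

truth_marrow_mask <- function(ph) {
  binary_mask_volume(mask_binary(ph$truth, "marrow"), "marrow",
                     ph$truth$spacing_mm)
}
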