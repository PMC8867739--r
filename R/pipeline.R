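# Orchestration: phantom -> segmentation -> quantification -> (repro) -> stats.

stage_try <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] subject %s: %s", stage, subject_id,
                 conditionMessage(e)), call. = FALSE)
  })
}

# small random exclusion box centred on a marrow voxel; emulates the
# variability of a human reader's manual correction between sessions
random_exclusion_box <- function(truth, half = c(1L, 2L, 2L)) {
  sel <- which(mask_binary(truth, "marrow"))
  if (!length(sel)) return(list())
  d <- dim(truth$labels)
  idx <- sel[sample.int(length(sel), 1L)]
  z <- (idx - 1L) %% d[1] + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  list(list(z = c(z - half[1], z + half[1]),
            y = c(y - half[2], y + half[2]),
            x = c(x - half[3], x + half[3])))
}

quant_as_row <- function(q) {
  data.frame(volume_cm3 = q$volume_cm3, sul_max = q$sul_max,
             sul_mean = q$sul_mean, entropy_bits = q$entropy_bits,
             pct_higher_volume = q$pct_higher_volume,
             deauville_score = q$deauville_score,
             th11_sul_mean = q$th11_sul_mean,
             mediastinum_sul_mean = q$mediastinum_sul_mean,
             liver_sul_mean = q$liver_sul_mean,
             n_voxels = q$n_voxels)
}

#' Run the full quantification pipeline on a synthetic or file-based cohort
#'
#' Demo mode (`inputs = NULL`): simulates `n` subjects with
#' [generate_cohort()] and [generate_phantom()], segments and quantifies
#' each, and (optionally) re-reads every subject in a second session with a
#' small perturbed exclusion region to measure reproducibility. File mode:
#' `inputs` is a `data.frame` with columns `subject_id`, `ct_path`,
#' `pet_path`, `truth_path` and `cohort` the matching metadata table. The
#' run is deterministic given `seed`; any stage error aborts with the stage
#' name and subject id.
#'
#' @param n Number of simulated subjects (demo mode).
#' @param seed Integer master seed for cohort, phantoms and perturbations.
#' @param out_dir Output directory; created if needed. Writes `results.csv`,
#'   `manifest.json` and (if `repro_sessions`) `repro.json`.
#' @param config A [run_config()].
#' @param params A [phantom_params()] (demo mode).
#' @param inputs Optional file-mode input table (see above).
#' @param cohort Cohort metadata `data.frame` (file mode).
#' @param repro_sessions Also run a perturbed second read of every subject
#'   and report mean IoU and the SUL-mean ICC.
#' @param write_volumes Write per-subject NIfTI volumes (ct, pet, truth)
#'   under `out_dir` (demo mode only).
#' @return A list of class `pipeline_manifest`: `results` (cohort +
#'   per-subject quantification), `repro` (or `NULL`), `config`, `seed`,
#'   `paths`, `timings_s`, `version`.
#' @export
run_pipeline <- function(n = 10L, seed = 1L, out_dir = NULL,
                         config = run_config(), params = phantom_params(),
                         inputs = NULL, cohort = NULL,
                         repro_sessions = FALSE, write_volumes = FALSE) {
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function() proc.time()[["elapsed"]]

  t0 <- tick()
  if (is.null(inputs)) {
    cohort <- generate_cohort(n, seed = seed)
  } else {
    needed <- c("subject_id", "ct_path", "pet_path", "truth_path")
    if (!all(needed %in% names(inputs)))
      stop("[stage: io] inputs must have columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    if (is.null(cohort)) stop("[stage: io] file mode requires `cohort`",
                              call. = FALSE)
    cohort <- validate_cohort(cohort)
    n <- nrow(inputs)
  }
  set.seed(seed)
  subject_seeds <- sample.int(2147483646L, n)
  timings["cohort"] <- tick() - t0

  rows <- vector("list", n)
  repro_rows <- vector("list", n)
  n_corrected <- 0L
  t_seg <- 0; t_quant <- 0; t_phantom <- 0
  for (i in seq_len(n)) {
    meta <- cohort[i, ]
    sid <- meta$subject_id
    t0 <- tick()
    if (is.null(inputs)) {
      pp <- params
      pp$seed <- subject_seeds[i]
      ph <- stage_try("phantom", sid, generate_phantom(meta, pp))
      ct <- ph$ct; pet <- ph$pet; truth <- ph$truth
      if (write_volumes && !is.null(out_dir)) {
        dir.create(file.path(out_dir, "volumes"), recursive = TRUE,
                   showWarnings = FALSE)
        write_volume(ct, file.path(out_dir, "volumes", paste0(sid, "_ct.nii.gz")))
        write_volume(pet, file.path(out_dir, "volumes", paste0(sid, "_pet.nii.gz")))
        write_volume(truth, file.path(out_dir, "volumes", paste0(sid, "_truth.nii.gz")))
      }
    } else {
      ct <- stage_try("segmentation", sid, read_volume(inputs$ct_path[i], "CT_HU"))
      pet <- stage_try("segmentation", sid, read_volume(inputs$pet_path[i], "PET_BQML"))
      truth <- stage_try("segmentation", sid, read_volume(inputs$truth_path[i], as_mask = TRUE))
    }
    t_phantom <- t_phantom + tick() - t0

    t0 <- tick()
    seg <- stage_try("segmentation", sid,
                     segment_subject(ct, pet, truth, config))
    t_seg <- t_seg + tick() - t0

    t0 <- tick()
    quant <- stage_try("quantification", sid,
                       quantify_subject(pet, seg, meta, truth, config))
    t_quant <- t_quant + tick() - t0

    rows[[i]] <- cbind(meta, quant_as_row(quant), row.names = NULL)

    if (repro_sessions) {
      set.seed(subject_seeds[i] %% 100000L + 17L)
      excl <- random_exclusion_box(truth)
      seg2 <- stage_try("reproducibility", sid,
                        segment_subject(ct, pet, truth, config,
                                        exclusions = excl))
      if (seg2$provenance$n_excluded_voxels > 0) n_corrected <- n_corrected + 1L
      quant2 <- stage_try("reproducibility", sid,
                          quantify_subject(pet, seg2, meta, truth, config))
      repro_rows[[i]] <- list(mask_a = seg$marrow_mask, mask_b = seg2$marrow_mask,
                              v_a = quant$sul_mean, v_b = quant2$sul_mean)
    }
  }
  timings["phantom_or_io"] <- t_phantom
  timings["segmentation"] <- t_seg
  timings["quantification"] <- t_quant

  results <- do.call(rbind, rows)

  repro <- NULL
  if (repro_sessions) {
    t0 <- tick()
    repro <- stage_try("reproducibility", "(cohort)", assess_reproducibility(
      lapply(repro_rows, `[[`, "mask_a"), lapply(repro_rows, `[[`, "mask_b"),
      vapply(repro_rows, `[[`, numeric(1), "v_a"),
      vapply(repro_rows, `[[`, numeric(1), "v_b")))
    repro$n_manual_corrections <- n_corrected
    timings["reproducibility"] <- tick() - t0
  }

  t0 <- tick()
  stats_report <- tryCatch(cohort_report(results), error = function(e) NULL)
  timings["stats"] <- tick() - t0

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$results_csv <- file.path(out_dir, "results.csv")
    write.csv(results, paths$results_csv, row.names = FALSE)
    if (!is.null(repro)) {
      paths$repro_json <- file.path(out_dir, "repro.json")
      jsonlite::write_json(repro[c("iou", "iou_per_subject", "icc",
                                   "icc_model", "n_manual_corrections")],
                           paths$repro_json, auto_unbox = TRUE, digits = NA)
    }
  }

  manifest <- structure(list(
    results = results, repro = repro, stats = stats_report,
    config = config, seed = as.integer(seed), n = n,
    mode = if (is.null(inputs)) "demo" else "files",
    paths = paths, timings_s = as.list(round(timings, 3)),
    total_s = round(tick() - t_all, 3),
    version = as.character(utils::packageVersion("bmpet"))),
    class = "pipeline_manifest")

  if (!is.null(out_dir)) {
    paths$manifest_json <- file.path(out_dir, "manifest.json")
    manifest$paths <- paths
    jsonlite::write_json(
      manifest[c("seed", "n", "mode", "timings_s", "total_s", "version")],
      paths$manifest_json, auto_unbox = TRUE, digits = NA)
  }
  manifest
}

# per-sex correlations and sex comparisons over the joined results table
cohort_report <- function(results) {
  by_sex <- function(sex) {
    sub <- results[results$sex == sex, ]
    if (nrow(sub) < 3) return(NULL)
    lapply(c(sul_mean = "sul_mean", sul_max = "sul_max",
             entropy = "entropy_bits"), function(v) {
      r <- tryCatch(correlate(sub, "age_y", v), error = function(e) NULL)
      if (is.null(r)) NULL else list(r = r$estimate$r, p = r$p_value)
    })
  }
  comp <- function(v, method) {
    r <- tryCatch(compare_sexes(results, v, method), error = function(e) NULL)
    if (is.null(r)) NULL else list(p = r$p_value,
                                   mean_difference = r$estimate$mean_difference)
  }
  list(age_correlations = list(M = by_sex("M"), F = by_sex("F")),
       sex_comparisons = list(
         volume_cm3 = comp("volume_cm3", "mann_whitney"),
         sul_mean = comp("sul_mean", "mann_whitney"),
         wbc = comp("wbc_1e3_per_ul", "t_test"),
         hb = comp("hb_g_dl", "t_test")))
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> %s mode, n = %d, seed = %d, %.1f s total\n",
              x$mode, x$n, x$seed, x$total_s))
  if (!is.null(x$repro))
    cat(sprintf("  reproducibility: mean IoU %.4f, ICC %.4f\n",
                x$repro$iou, x$repro$icc))
  invisible(x)
}
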