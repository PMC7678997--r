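# End-to-end orchestration: generate -> fit -> aggregate -> slopes ->
# associate, from a single serializable config with reproducible seeding.

#' Build a pipeline configuration
#'
#' Collects every tunable constant of the end-to-end run. Per-subject phantoms
#' vary the planted bundle tissue MD and free-water mean around the cohort
#' means; `effect_mdt_slope` plants a standardized effect of the subject's
#' bundle MDt on the IST15 slope (0 gives a null cohort). All randomness is
#' derived from `seed`.
#'
#' @param n_subjects cohort size.
#' @param shape phantom grid.
#' @param bundle_radius tube radius, voxels.
#' @param wmh_overlap bundle fraction covered by WMH.
#' @param bundle_md,bundle_fa planted bundle tissue scalars (population mean).
#' @param bundle_md_sd between-subject SD of planted bundle MD, mm^2/s.
#' @param fw_mean,fw_sd population mean and between-subject SD of the planted
#'   free-water fraction.
#' @param snr b0 SNR for Rician noise, or `NULL` for noise-free signals.
#' @param n_dirs_half,bvalue,n_series gradient scheme parameters.
#' @param visit_times,mean_slope,sd_intercept,sd_slope,resid_sd longitudinal
#'   generator parameters (see [simulate_longitudinal_scores()]).
#' @param effect_mdt_slope planted standardized MDt -> IST15-slope effect.
#' @param fdr_q FDR level.
#' @param adjust_wmh add the WMH burden covariate to the regression tables.
#' @param seed master integer seed.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 4, shape = c(16, 16, 10),
                            bundle_radius = 1.5, wmh_overlap = 0.032,
                            bundle_md = 0.755e-3, bundle_fa = 0.567,
                            bundle_md_sd = 0.03e-3,
                            fw_mean = 0.141, fw_sd = 0.017,
                            snr = NULL, n_dirs_half = 21, bvalue = 1000,
                            n_series = 2,
                            visit_times = c(0, 2, 4, 7, 10, 12),
                            mean_slope = -0.489, sd_intercept = 2,
                            sd_slope = 0.15, resid_sd = 1,
                            effect_mdt_slope = 0,
                            fdr_q = 0.05, adjust_wmh = FALSE,
                            seed = 1L, out_dir = tempfile("fwetract_run_")) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 2, length(cfg$shape) == 3, all(cfg$shape <= 64),
            cfg$wmh_overlap >= 0, cfg$wmh_overlap <= 1,
            cfg$fdr_q > 0, cfg$fdr_q < 1,
            abs(cfg$effect_mdt_slope) <= 1,
            length(cfg$visit_times) >= 3)
  invisible(cfg)
}

#' Write / read a pipeline config as JSON
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return the path (write) or the config (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$snr) && length(cfg$snr) == 0) cfg$snr <- NULL
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Run the pipeline end to end (or selected stages)
#'
#' Stages: `simulate` (phantoms + longitudinal scores + screening table),
#' `fit` (conventional tensor and free-water maps per subject, written as
#' NIfTI), `tract_metrics` (per-subject summary CSV), `slopes` (mixed-model
#' slope CSV), `associate` (comparison and regression tables). Later stages
#' read only the CSV outputs of earlier stages, so any suffix of the stage
#' list can be rerun from cached files and reproduces its outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("simulate", "fit", "tract_metrics", "slopes", "associate")`, in order.
#' @param write_nifti_maps write phantom signals and fitted maps as NIfTI
#'   (slower; tables alone are enough for the statistics stages).
#' @return the output directory, invisibly; a manifest (config, seeds,
#'   package version, per-stage wall time) is written as
#'   `manifest_<stage>.json` entries inside `manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit", "tract_metrics",
                                    "slopes", "associate"),
                         write_nifti_maps = FALSE) {
  validate_config(config)
  out <- config$out_dir
  dir.create(file.path(out, "tables"), recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(package_version = as.character(utils::packageVersion("fwetract")),
         r_version = as.character(getRversion()),
         seed = config$seed, stage_seconds = list())
  }
  manifest$config <- unclass(config)

  timed <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    fn()
    manifest$stage_seconds[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  for (st in stages) {
    switch(st,
      simulate = timed(st, function() stage_simulate(config, out, write_nifti_maps)),
      fit = timed(st, function() stage_fit(config, out, write_nifti_maps)),
      tract_metrics = timed(st, function() stage_tract_metrics(config, out)),
      slopes = timed(st, function() stage_slopes(config, out)),
      associate = timed(st, function() stage_associate(config, out)),
      stop("run_pipeline: unknown stage '", st, "'")
    )
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  write_config(config, file.path(out, "config.json"))
  invisible(out)
}

# per-subject planted parameters, all derived from the master seed
subject_params <- function(config) {
  withr_seed(config$seed + 7919L, function() {
    n <- config$n_subjects
    md <- stats::rnorm(n, config$bundle_md, config$bundle_md_sd)
    fw <- pmin(pmax(stats::rnorm(n, config$fw_mean, config$fw_sd), 0.03), 0.5)
    data.frame(subject = seq_len(n), bundle_md = md, fw_mean = fw)
  })
}

phantom_for_subject <- function(config, params, i) {
  make_phantom(shape = config$shape, bundle_radius = config$bundle_radius,
               bundle_fa = config$bundle_fa, bundle_md = params$bundle_md[i],
               wmh_overlap = config$wmh_overlap,
               fw_mean = params$fw_mean[i], fw_sd = 0.02,
               snr = config$snr,
               scheme = make_gradient_scheme(config$n_dirs_half, config$bvalue,
                                             config$n_series),
               seed = config$seed + 1000L + i)
}

stage_simulate <- function(config, out, write_nifti_maps) {
  params <- subject_params(config)
  utils::write.csv(params, file.path(out, "tables", "subject_params.csv"),
                   row.names = FALSE)
  if (write_nifti_maps) {
    for (i in seq_len(config$n_subjects)) {
      ph <- phantom_for_subject(config, params, i)
      write_phantom(ph, file.path(out, "subjects", sprintf("sub-%03d", i)))
    }
  }
  # longitudinal scores: covariate = z-scored planted bundle MD
  beta <- config$effect_mdt_slope
  covz <- as.vector(scale(params$bundle_md))
  sim <- simulate_longitudinal_scores(
    n_subjects = config$n_subjects, visit_times = config$visit_times,
    mean_slope = config$mean_slope, sd_intercept = config$sd_intercept,
    sd_slope = config$sd_slope * sqrt(1 - beta^2), resid_sd = config$resid_sd,
    covariate = covz, covariate_link = config$sd_slope * beta,
    seed = config$seed + 2000L)
  utils::write.csv(sim$data, file.path(out, "tables", "scores_long.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(out, "tables", "scores_truth.csv"),
                   row.names = FALSE)
  screening <- simulate_screening_records(seed = config$seed + 3000L)
  utils::write.csv(screening, file.path(out, "tables", "screening.csv"),
                   row.names = FALSE)
}

stage_fit <- function(config, out, write_nifti_maps) {
  params <- utils::read.csv(file.path(out, "tables", "subject_params.csv"))
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    ph <- phantom_for_subject(config, params, i)
    mask <- ph$masks$left_bundle | ph$masks$right_bundle
    dti <- fit_dti_volume(ph, mask)
    fw <- fit_fw_volume(ph, mask)
    if (write_nifti_maps) {
      sdir <- file.path(out, "subjects", sprintf("sub-%03d", i))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      px <- rep(ph$voxel_size, 3)
      for (m in c("fa", "md", "rd", "ad")) {
        write_nifti(replace_na(dti[[m]]), file.path(sdir, paste0(m, ".nii")), px)
      }
      for (m in c("fw", "fat", "mdt", "rdt", "adt")) {
        write_nifti(replace_na(fw[[m]]), file.path(sdir, paste0(m, ".nii")), px)
      }
      write_nifti(fw$flags, file.path(sdir, "flags.nii"), px, datatype = "uint8")
    }
    rows[[i]] <- cbind(data.frame(subject = i), tract_summary(dti, fw, ph))
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out, "tables", "tract_measures.csv"),
                   row.names = FALSE)
}

replace_na <- function(x, value = 0) { x[is.na(x)] <- value; x }

stage_tract_metrics <- function(config, out) {
  # tract summaries are produced voxel-adjacent in stage_fit; this stage
  # derives the cohort-level percent-change summary from the cached CSV
  tm <- utils::read.csv(file.path(out, "tables", "tract_measures.csv"))
  pc <- data.frame(measure = c("fa", "md", "rd", "ad"))
  pc$pct_change_mean <- vapply(pc$measure, function(m) {
    mean(tm[[paste0("pct_change_", m)]])
  }, numeric(1))
  pc$pct_change_sd <- vapply(pc$measure, function(m) {
    stats::sd(tm[[paste0("pct_change_", m)]])
  }, numeric(1))
  utils::write.csv(pc, file.path(out, "tables", "pct_change_summary.csv"),
                   row.names = FALSE)
}

stage_slopes <- function(config, out) {
  scores <- utils::read.csv(file.path(out, "tables", "scores_long.csv"))
  if (length(unique(scores$subject)) >= 10) {
    fit <- fit_lmm_slopes(scores)
    write_slopes(fit, file.path(out, "tables"))
  } else {
    # mixed models need a cohort; tiny smoke runs fall back to per-subject OLS
    slopes <- ols_slopes(scores)
    utils::write.csv(slopes, file.path(out, "tables", "subject_slopes.csv"),
                     row.names = FALSE)
    writeLines("per-subject OLS fallback (cohort smaller than 10 subjects)",
               file.path(out, "tables", "slope_model_summary.txt"))
  }
}

ols_slopes <- function(scores, score_cols = c("ist15", "ist30", "ist60")) {
  subjects <- sort(unique(scores$subject))
  out <- data.frame(subject = subjects)
  for (sc in score_cols) {
    sl <- vapply(subjects, function(s) {
      d <- scores[scores$subject == s & !is.na(scores[[sc]]), ]
      unname(stats::coef(stats::lm(d[[sc]] ~ d$time_years))[2])
    }, numeric(1))
    out[[sc]] <- sl
    out[[paste0(sc, "_ols")]] <- sl
  }
  out
}

stage_associate <- function(config, out) {
  tm <- utils::read.csv(file.path(out, "tables", "tract_measures.csv"))
  sl <- utils::read.csv(file.path(out, "tables", "subject_slopes.csv"))
  screening <- utils::read.csv(file.path(out, "tables", "screening.csv"))
  cohort <- merge(tm, sl, by = "subject")
  names(cohort)[names(cohort) == "ist15"] <- "slope_ist15"
  names(cohort)[names(cohort) == "ist30"] <- "slope_ist30"
  names(cohort)[names(cohort) == "ist60"] <- "slope_ist60"
  cohort$age <- screening$age[seq_len(nrow(cohort))]
  utils::write.csv(cohort, file.path(out, "tables", "cohort.csv"),
                   row.names = FALSE)
  t2 <- table_compare_measures(cohort, q = config$fdr_q)
  utils::write.csv(t2, file.path(out, "tables", "measure_comparison.csv"),
                   row.names = FALSE)
  # tiny smoke cohorts cannot support the covariate-adjusted design; constant
  # covariates (e.g. identical phantom geometry) carry no adjustment and would
  # make the design collinear
  covariates <- if (nrow(cohort) >= 8) c("age", "bundle_pctiv") else character(0)
  covariates <- covariates[vapply(covariates,
                                  function(cv) stats::sd(cohort[[cv]]) > 0,
                                  logical(1))]
  t3 <- table_regressions(cohort, adjust_wmh = config$adjust_wmh,
                          covariates = covariates, q = config$fdr_q)
  utils::write.csv(t3, file.path(out, "tables", "slope_regressions.csv"),
                   row.names = FALSE)
  jm <- tryCatch(
    joint_fw_mdt_model(cohort, adjust_wmh = config$adjust_wmh,
                       covariates = covariates)$coefficients,
    error = function(e) data.frame(predictor = c("fw", "mdt"), beta = NA_real_,
                                   raw_beta = NA_real_, se = NA_real_,
                                   p_value = NA_real_))
  utils::write.csv(jm, file.path(out, "tables", "joint_fw_mdt.csv"),
                   row.names = FALSE)
}
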