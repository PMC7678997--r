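# Synthetic cohort: longitudinal verbal-fluency trajectories, screening
# records with staged exclusions, and table-level association cohorts.

#' Simulate nested longitudinal verbal-fluency scores
#'
#' Generates per-subject Isaacs Set Test (IST) trajectories under the linear
#' mixed model the estimation layer assumes:
#' `score(t) = (mu0 + b0_i) + (mu1 + b1_i + gamma * cov_i) * t + eps`,
#' with `b0_i ~ N(0, sd_intercept^2)`, `b1_i ~ N(0, sd_slope^2)` and
#' `eps ~ N(0, resid_sd^2)`. The three scores are cumulative word counts of
#' one fluency trial, so they are generated as the 15 s count plus two
#' non-negative increments (15->30 s and 30->60 s), which enforces
#' `IST15 <= IST30 <= IST60` at every visit by construction. Increment
#' trajectories have their own mixed-model structure with random-effect and
#' residual SDs scaled from the main arguments (factors 0.3 and 0.5), so the
#' fully deterministic limit (`sd_slope = resid_sd = 0`) stays deterministic
#' for all three scores.
#'
#' Defaults are the cohort's reported 12-year decline: mean annual slopes
#' -0.489 (IST15), -0.697 (IST30), -0.924 (IST60) words/year, visits at
#' 0, 2, 4, 7, 10, 12 years.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param visit_times visit times in years, strictly increasing, >= 3 visits.
#' @param mean_intercept population IST15 intercept, words.
#' @param mean_slope population IST15 annual slope, words/year.
#' @param sd_intercept,sd_slope random-effect standard deviations.
#' @param resid_sd residual standard deviation, words.
#' @param covariate per-subject covariate vector entering the slope, or
#'   `NULL` for standard-normal draws (only used when `covariate_link != 0`).
#' @param covariate_link effect `gamma` of the covariate on the IST15 slope,
#'   words/year per covariate unit.
#' @param increment_slopes mean annual slopes of the two increments
#'   (15->30 s, 30->60 s), words/year.
#' @param increment_intercepts mean increments at baseline, words.
#' @param seed integer seed.
#' @return object of class `longitudinal_scores`: `data` (long data.frame
#'   with `subject`, `time_years`, `ist15`, `ist30`, `ist60`), `truth`
#'   (per-subject planted intercepts/slopes for each score, pre-truncation,
#'   and the covariate), and `visit_times`.
#' @export
simulate_longitudinal_scores <- function(n_subjects, visit_times = c(0, 2, 4, 7, 10, 12),
                                         mean_intercept = 18, mean_slope = -0.489,
                                         sd_intercept = 2, sd_slope = 0.15,
                                         resid_sd = 1,
                                         covariate = NULL, covariate_link = 0,
                                         increment_slopes = c(-0.208, -0.227),
                                         increment_intercepts = c(10, 10),
                                         seed = 1L) {
  if (n_subjects < 2) stop("simulate_longitudinal_scores: need at least 2 subjects")
  if (length(visit_times) < 3 || any(diff(visit_times) <= 0)) {
    stop("simulate_longitudinal_scores: need >= 3 strictly increasing visit times")
  }
  if (sd_intercept < 0 || sd_slope < 0 || resid_sd < 0) {
    stop("simulate_longitudinal_scores: variance components must be non-negative")
  }
  if (is.null(covariate)) {
    covariate <- if (covariate_link != 0) {
      withr_seed(seed + 104729L, function() stats::rnorm(n_subjects))
    } else {
      rep(0, n_subjects)
    }
  }
  stopifnot(length(covariate) == n_subjects)

  res <- withr_seed(seed, function() {
    nv <- length(visit_times)
    b0 <- stats::rnorm(n_subjects, 0, sd_intercept)
    b1 <- stats::rnorm(n_subjects, 0, sd_slope)
    slope15 <- mean_slope + b1 + covariate_link * covariate
    int15 <- mean_intercept + b0

    inc_b0 <- matrix(stats::rnorm(2 * n_subjects, 0, sd_intercept * 0.3), n_subjects, 2)
    inc_b1 <- matrix(stats::rnorm(2 * n_subjects, 0, sd_slope * 0.3), n_subjects, 2)
    inc_int <- sweep(inc_b0, 2, increment_intercepts, "+")
    inc_slope <- sweep(inc_b1, 2, increment_slopes, "+")

    tgrid <- rep(visit_times, times = n_subjects)
    sid <- rep(seq_len(n_subjects), each = nv)
    eps15 <- stats::rnorm(n_subjects * nv, 0, resid_sd)
    eps_inc1 <- stats::rnorm(n_subjects * nv, 0, resid_sd * 0.5)
    eps_inc2 <- stats::rnorm(n_subjects * nv, 0, resid_sd * 0.5)

    ist15 <- pmax(0, int15[sid] + slope15[sid] * tgrid + eps15)
    inc1 <- pmax(0, inc_int[sid, 1] + inc_slope[sid, 1] * tgrid + eps_inc1)
    inc2 <- pmax(0, inc_int[sid, 2] + inc_slope[sid, 2] * tgrid + eps_inc2)

    list(
      data = data.frame(subject = sid, time_years = tgrid,
                        ist15 = ist15, ist30 = ist15 + inc1,
                        ist60 = ist15 + inc1 + inc2),
      truth = data.frame(subject = seq_len(n_subjects),
                         covariate = covariate,
                         intercept_ist15 = int15, slope_ist15 = slope15,
                         intercept_ist30 = int15 + inc_int[, 1],
                         slope_ist30 = slope15 + inc_slope[, 1],
                         intercept_ist60 = int15 + inc_int[, 1] + inc_int[, 2],
                         slope_ist60 = slope15 + inc_slope[, 1] + inc_slope[, 2])
    )
  })
  structure(c(res, list(visit_times = visit_times)), class = "longitudinal_scores")
}

#' Default screening stages and their cohort attrition counts
#'
#' Ordered exclusion stages applied to the 239 screened subjects, with the
#' number attributed to each stage; 68 subjects survive all stages.
#' @export
SCREENING_STAGES <- c(dementia = 8L, brain_pathology = 27L,
                      mri_unavailable = 62L, mri_artefacts = 24L,
                      preprocessing_failure = 15L,
                      cingulum_reconstruction_failure = 16L,
                      tractography_qc_failure = 19L)

#' Simulate a screening table with staged exclusion flags
#'
#' Produces `n` subject records with boolean exclusion flags planted so that
#' sequential application of the stages in order attributes exactly
#' `stage_counts[k]` subjects to stage `k`. Subjects already excluded at an
#' earlier stage may additionally carry later flags (with probability
#' `extra_flag_prob`), which exercises first-stage attribution. Covariates
#' (age, sex, education, MMSE, CES-D, BMI, diabetes, hypertension) are drawn
#' around the included cohort's reported characteristics.
#'
#' @param n number screened.
#' @param stage_counts named integer vector, per-stage exclusion counts in
#'   application order.
#' @param extra_flag_prob probability of a redundant later-stage flag on an
#'   already-excluded subject.
#' @param seed integer seed.
#' @return data.frame with `subject`, one logical column per stage, and
#'   covariate columns.
#' @export
simulate_screening_records <- function(n = 239, stage_counts = SCREENING_STAGES,
                                       extra_flag_prob = 0.1, seed = 1L) {
  if (sum(stage_counts) > n) stop("simulate_screening_records: stage counts exceed n")
  withr_seed(seed, function() {
    stages <- names(stage_counts)
    ord <- sample.int(n)
    flags <- matrix(FALSE, n, length(stages), dimnames = list(NULL, stages))
    pos <- 1L
    for (k in seq_along(stages)) {
      if (stage_counts[k] > 0) {
        flags[ord[pos:(pos + stage_counts[k] - 1L)], k] <- TRUE
        pos <- pos + stage_counts[k]
      }
    }
    excluded_at <- apply(flags, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
    for (i in which(!is.na(excluded_at))) {
      later <- seq_along(stages) > excluded_at[i]
      flags[i, later] <- stats::runif(sum(later)) < extra_flag_prob
    }
    mmse <- round(pmin(pmax(stats::rnorm(n, 27.3, 2.5), 0), 30))
    data.frame(subject = seq_len(n), flags,
               age = stats::rnorm(n, 81.2, 4.0),
               male = stats::runif(n) < 0.368,
               high_education = stats::runif(n) < 0.37,
               mmse = mmse,
               cesd = pmax(round(stats::rnorm(n, 8.3, 7)), 0),
               bmi = stats::rnorm(n, 25.2, 4),
               diabetes = stats::runif(n) < 0.103,
               hypertension = stats::runif(n) < 0.353)
  })
}

#' Apply staged exclusions sequentially
#'
#' Walks the stages in order; a subject is attributed to the first stage whose
#' flag excludes them and is never recounted at a later stage.
#'
#' @param records data.frame with one logical column per stage.
#' @param stage_order character vector of flag column names, in application
#'   order.
#' @return list with `included` (surviving rows of `records`), `attrition`
#'   (named integer, count per stage), `n_screened`, `n_included`.
#' @examples
#' rec <- simulate_screening_records(seed = 7)
#' apply_exclusions(rec)$n_included  # 68
#' @export
apply_exclusions <- function(records, stage_order = names(SCREENING_STAGES)) {
  missing_cols <- setdiff(stage_order, names(records))
  if (length(missing_cols)) {
    stop("apply_exclusions: unknown stage flag(s): ", paste(missing_cols, collapse = ", "))
  }
  alive <- rep(TRUE, nrow(records))
  attrition <- stats::setNames(integer(length(stage_order)), stage_order)
  for (st in stage_order) {
    hit <- alive & records[[st]]
    attrition[st] <- sum(hit)
    alive <- alive & !hit
  }
  list(included = records[alive, , drop = FALSE], attrition = attrition,
       n_screened = nrow(records), n_included = sum(alive))
}

#' Simulate a per-subject association cohort at the table level
#'
#' Generates the per-subject summary table the association layer consumes —
#' bilateral conventional and free-water-corrected cingulum diffusion
#' measures, free-water content, WMH volumetrics, covariates, and annual
#' verbal-fluency slopes — without running the imaging stages. Measure means
#' and SDs follow the reported cohort table; the between-measure correlation
#' structure is driven by two latent factors (tissue state and free-water
#' contamination). A diffusion-cognition link is planted as a standardized
#' effect of the corrected mean diffusivity (MDt) on the IST15 slope:
#' `slope_z = beta_mdt * z(MDt) + sqrt(1 - beta_mdt^2) * noise`; IST30/60
#' slopes share the subject's slope deviation with correlation 0.9.
#' `beta_mdt = 0` gives an exact null cohort.
#'
#' @param n subjects.
#' @param beta_mdt planted standardized effect of MDt on the IST15 slope.
#' @param seed integer seed.
#' @return data.frame, one row per subject, with measure, volumetric,
#'   covariate and slope columns; the planted effect is stored in
#'   `attr(, "beta_mdt")`.
#' @export
simulate_association_cohort <- function(n = 68, beta_mdt = 0, seed = 1L) {
  if (abs(beta_mdt) > 1) stop("simulate_association_cohort: |beta_mdt| must be <= 1")
  withr_seed(seed, function() {
    tissue <- stats::rnorm(n)        # latent tissue state (drives MDt etc.)
    contam <- stats::rnorm(n)        # latent free-water contamination
    mix <- function(a, x, y) a * x + sqrt(1 - a^2) * y
    mdt_z <- tissue
    rdt_z <- mix(0.8, tissue, stats::rnorm(n))
    adt_z <- mix(0.7, tissue, stats::rnorm(n))
    fat_z <- mix(-0.6, tissue, stats::rnorm(n))
    fw_z <- mix(0.5, contam, stats::rnorm(n))
    # conventional = corrected pulled toward the contamination axis
    conv <- function(zt, sgn) {
      z <- 0.85 * zt + sgn * 0.5 * fw_z
      z / sqrt(0.85^2 + 0.5^2)
    }
    md_z <- conv(mdt_z, +1); rd_z <- conv(rdt_z, +1); ad_z <- conv(adt_z, +1)
    fa_z <- conv(fat_z, -1)

    dev <- beta_mdt * mdt_z + sqrt(1 - beta_mdt^2) * stats::rnorm(n)
    slope_dev <- function() mix(0.9, dev, stats::rnorm(n))

    out <- data.frame(
      subject = seq_len(n),
      age = stats::rnorm(n, 81.2, 4.0),
      male = stats::runif(n) < 0.368,
      bundle_pctiv = stats::rnorm(n, 0.46, 0.06),
      wmh_total_ml = exp(stats::rnorm(n, log(15.9), 0.6)),
      wmh_cingulum_pct = pmax(stats::rnorm(n, 3.2, 0.65), 0),
      fa = 0.543 + 0.049 * fa_z,
      md = (0.768 + 0.0041 * md_z) * 1e-3,
      rd = (0.506 + 0.0047 * rd_z) * 1e-3,
      ad = (1.29 + 0.0683 * ad_z) * 1e-3,
      fat = 0.567 + 0.054 * fat_z,
      mdt = (0.755 + 0.0034 * mdt_z) * 1e-3,
      rdt = (0.493 + 0.0049 * rdt_z) * 1e-3,
      adt = (1.27 + 0.0638 * adt_z) * 1e-3,
      fw = 0.141 + 0.017 * fw_z,
      slope_ist15 = -0.489 + 0.15 * dev,
      slope_ist30 = -0.697 + 0.17 * slope_dev(),
      slope_ist60 = -0.924 + 0.20 * slope_dev()
    )
    out$wmh_log <- log(out$wmh_total_ml / 470)   # ~WM volume ml, fixed for scale
    attr(out, "beta_mdt") <- beta_mdt
    out
  })
}
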