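# Subject-specific annual cognitive slopes via linear mixed models.

#' Fit random intercept-and-slope mixed models and extract subject slopes
#'
#' For each score column, fits `score ~ time + (time | subject)` by REML with
#' correlated random intercept and slope. The subject-specific slope is the
#' fixed-effect slope plus the subject's best linear unbiased prediction
#' (BLUP) of the random slope. Per-subject ordinary least-squares slopes are
#' returned alongside as a two-stage cross-check. A singular correlated fit
#' falls back to independent random effects and is flagged. Subjects with all
#' scores missing for a column are dropped from that column's fit.
#'
#' @param scores a `longitudinal_scores` object, or a long data.frame with
#'   columns `subject`, `time_years` and the score columns.
#' @param score_cols score column names to fit.
#' @return object of class `slope_estimates`: `slopes` (data.frame: `subject`
#'   then `<score>` BLUP slope and `<score>_ols` columns, words/year),
#'   `fixed` (per score: intercept, slope), `varcomp` (per score: intercept
#'   SD, slope SD, their correlation, residual SD), `logLik`, `singular`
#'   (logical per score), `converged`.
#' @examples
#' sim <- simulate_longitudinal_scores(50, seed = 3)
#' fit <- fit_lmm_slopes(sim)
#' head(fit$slopes)
#' @export
fit_lmm_slopes <- function(scores, score_cols = c("ist15", "ist30", "ist60")) {
  df <- if (inherits(scores, "longitudinal_scores")) scores$data else scores
  need <- c("subject", "time_years", score_cols)
  if (!all(need %in% names(df))) {
    stop("fit_lmm_slopes: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  n_sub <- length(unique(df$subject))
  if (n_sub < 10) stop("fit_lmm_slopes: at least 10 subjects are required")
  visits_per <- table(df$subject[!is.na(df[[score_cols[1]]])])
  if (stats::median(visits_per) < 3) {
    stop("fit_lmm_slopes: a majority of subjects need >= 3 visits")
  }

  subjects <- sort(unique(df$subject))
  slopes <- data.frame(subject = subjects)
  fixed <- list(); varcomp <- list(); ll <- c(); singular <- c(); converged <- c()

  for (sc in score_cols) {
    d <- df[!is.na(df[[sc]]), c("subject", "time_years", sc)]
    names(d)[3] <- "y"
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ time_years + (time_years | subject), data = d, REML = TRUE)
    ))
    fell_back <- FALSE
    if (lme4::isSingular(fit, tol = 1e-5)) {
      fit2 <- suppressWarnings(suppressMessages(
        lme4::lmer(y ~ time_years + (time_years || subject), data = d, REML = TRUE)
      ))
      # keep the fallback only if it is itself usable
      if (!inherits(fit2, "try-error")) { fit <- fit2; fell_back <- TRUE }
    }
    fe <- lme4::fixef(fit)
    cf <- stats::coef(fit)$subject     # fixed + BLUP per subject
    blup_slope <- cf[match(as.character(subjects), rownames(cf)), "time_years"]
    ols <- vapply(subjects, function(s) {
      dd <- d[d$subject == s, ]
      if (nrow(dd) < 2) return(NA_real_)
      unname(stats::coef(stats::lm(y ~ time_years, dd))[2])
    }, numeric(1))
    slopes[[sc]] <- blup_slope
    slopes[[paste0(sc, "_ols")]] <- ols

    vc <- as.data.frame(lme4::VarCorr(fit))
    get_vc <- function(v1, v2 = NA) {
      i <- which(vc$grp %in% c("subject", "subject.1") &
                   (vc$var1 %in% v1 | (is.na(vc$var1) & is.na(v1))) &
                   ((is.na(v2) & is.na(vc$var2)) | (!is.na(v2) & vc$var2 %in% v2)))
      if (length(i)) vc$sdcor[i[1]] else NA_real_
    }
    fixed[[sc]] <- c(intercept = unname(fe[1]), slope = unname(fe[2]))
    varcomp[[sc]] <- c(sd_intercept = get_vc("(Intercept)"),
                       sd_slope = get_vc("time_years"),
                       cor_int_slope = if (fell_back) 0 else get_vc("(Intercept)", "time_years"),
                       sd_resid = vc$sdcor[vc$grp == "Residual"][1])
    ll[sc] <- as.numeric(stats::logLik(fit))
    singular[sc] <- fell_back
    converged[sc] <- length(fit@optinfo$conv$lme4) == 0
  }
  structure(list(slopes = slopes, fixed = fixed, varcomp = varcomp,
                 logLik = ll, singular = singular, converged = converged),
            class = "slope_estimates")
}

#' @export
print.slope_estimates <- function(x, ...) {
  for (sc in names(x$fixed)) {
    cat(sprintf("%s: fixed slope %.4f words/year (intercept %.2f)%s\n",
                sc, x$fixed[[sc]]["slope"], x$fixed[[sc]]["intercept"],
                if (x$singular[sc]) " [independent-RE fallback]" else ""))
  }
  invisible(x)
}

#' Write slope estimates and a model summary log
#'
#' @param fit a `slope_estimates` object.
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
write_slopes <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "subject_slopes.csv")
  utils::write.csv(fit$slopes, csv, row.names = FALSE)
  log <- file.path(dir, "slope_model_summary.txt")
  lines <- unlist(lapply(names(fit$fixed), function(sc) {
    c(sprintf("score %s", sc),
      sprintf("  fixed intercept %.6f  fixed slope %.6f", fit$fixed[[sc]]["intercept"],
              fit$fixed[[sc]]["slope"]),
      sprintf("  sd_intercept %.6f  sd_slope %.6f  cor %.4f  sd_resid %.6f",
              fit$varcomp[[sc]]["sd_intercept"], fit$varcomp[[sc]]["sd_slope"],
              fit$varcomp[[sc]]["cor_int_slope"], fit$varcomp[[sc]]["sd_resid"]),
      sprintf("  logLik %.3f  singular_fallback %s  converged %s",
              fit$logLik[sc], fit$singular[sc], fit$converged[sc]))
  }))
  writeLines(lines, log)
  invisible(c(csv = csv, log = log))
}
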