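# Association layer: bivariate screens, paired comparisons, standardized-beta
# regressions, and Benjamini-Hochberg FDR control.

#' Bivariate screen: Spearman correlation or Mann-Whitney U
#'
#' Spearman's rank correlation (average ranks for ties; exact p for n <= 10
#' without ties, t-approximation otherwise) for continuous pairs, or the
#' Mann-Whitney U test (exact enumeration up to group sizes of 20 without
#' ties, normal approximation with continuity and tie correction above) for a
#' continuous variable against a two-level grouping.
#'
#' @param x numeric vector.
#' @param y numeric vector (spearman) or group labels with two levels
#'   (mannwhitney).
#' @param kind `"spearman"` or `"mannwhitney"`.
#' @return object of class `assoc_test`: `statistic`, `p_value`, `n` (or
#'   `n1`, `n2`), `test`, `direction` (sign of the effect).
#' @export
bivariate_screen <- function(x, y, kind = c("spearman", "mannwhitney")) {
  kind <- match.arg(kind)
  if (kind == "spearman") {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4) stop("bivariate_screen: need n >= 4")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("bivariate_screen: Spearman correlation undefined for constant input")
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = n <= 10))
    structure(list(statistic = unname(ct$estimate), p_value = ct$p.value,
                   n = n, test = "spearman",
                   direction = sign(unname(ct$estimate))),
              class = "assoc_test")
  } else {
    g <- factor(y)
    if (nlevels(g) != 2L) stop("bivariate_screen: mannwhitney needs exactly two groups")
    x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
    if (!length(x1) || !length(x2)) stop("bivariate_screen: both groups must be nonempty")
    exact <- max(length(x1), length(x2)) <= 20 && !any(duplicated(c(x1, x2)))
    wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = exact,
                                              correct = TRUE))
    structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                   n1 = length(x1), n2 = length(x2), test = "mannwhitney",
                   direction = sign(stats::median(x1) - stats::median(x2))),
              class = "assoc_test")
  }
}

#' Paired t-test between conventional and corrected measures
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the per-subject differences
#' `d = after - before`, two-sided p on `n - 1` degrees of freedom.
#'
#' @param before,after equal-length numeric vectors (n >= 3).
#' @return an `assoc_test` with `statistic` (t), `p_value`, `n`, `direction`.
#' @export
paired_compare <- function(before, after) {
  if (length(before) != length(after)) stop("paired_compare: unequal lengths")
  n <- length(before)
  if (n < 3) stop("paired_compare: need n >= 3")
  d <- after - before
  if (all(d == 0)) {
    # identical vectors carry no evidence either way
    return(structure(list(statistic = 0, p_value = 1, n = n,
                          test = "paired_t", direction = 0),
                     class = "assoc_test"))
  }
  if (stats::sd(d) == 0) stop("paired_compare: zero-variance differences, test degenerate")
  tt <- stats::t.test(after, before, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 n = n, test = "paired_t", direction = sign(mean(d))),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, p = %.4g\n", x$test, x$statistic, x$p_value))
  invisible(x)
}

#' Standardized-coefficient regression with covariate adjustment
#'
#' Ordinary least squares of the z-scored outcome on z-scored predictors of
#' interest, with covariates entered on their raw scale. The reported beta for
#' each predictor is its coefficient in this standardized fit (for a single
#' predictor without covariates this equals the Pearson correlation); R^2 and
#' adjusted R^2 come from the full model. Supports several simultaneous
#' predictors (e.g. the joint free-water + MDt model) and any covariate set.
#'
#' @param outcome numeric vector.
#' @param predictors named list (or single vector) of predictor vectors.
#' @param covariates named list of covariate vectors, may be empty.
#' @return object of class `regression_result`: `coefficients` (data.frame
#'   per predictor: `beta`, `raw_beta`, `se`, `p_value`), `r_squared`,
#'   `adj_r_squared`, `n`, `covariates`, `outcome_sd`.
#' @export
adjusted_regression <- function(outcome, predictors, covariates = list()) {
  if (!is.list(predictors)) predictors <- list(predictor = predictors)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  cols <- c(list(.y = outcome), predictors, covariates)
  dat <- do.call(data.frame, c(cols, list(check.names = FALSE)))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p_total <- length(predictors) + length(covariates)
  if (n <= p_total + 2) stop("adjusted_regression: too few observations for the design")
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  sd_y <- stats::sd(dat$.y)
  dz <- dat
  dz$.y <- zs(dat$.y)
  raw_sds <- vapply(names(predictors), function(nm) stats::sd(dat[[nm]]), numeric(1))
  for (nm in names(predictors)) dz[[nm]] <- zs(dat[[nm]])
  X <- stats::model.matrix(~ ., dz[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    bad <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    stop("adjusted_regression: collinear design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = dz)
  sm <- summary(fit)
  co <- sm$coefficients
  rows <- co[names(predictors), , drop = FALSE]
  coefs <- data.frame(predictor = names(predictors),
                      beta = rows[, "Estimate"],
                      raw_beta = rows[, "Estimate"] * sd_y / raw_sds,
                      se = rows[, "Std. Error"],
                      p_value = rows[, "Pr(>|t|)"],
                      row.names = NULL)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, n = n,
                 covariates = names(covariates), outcome_sd = sd_y),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("standardized regression (n = %d, R^2 = %.3f)\n", x$n, x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up control of the false discovery rate at level `q`; returns monotone
#' adjusted p-values and the rejection flags.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR level.
#' @return list with `adjusted` (BH-adjusted p-values, input order),
#'   `significant` (logical), `q`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("fdr_adjust: p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = adj <= q, q = q)
}

#' Conventional-versus-corrected comparison table
#'
#' For each tensor scalar (FA, MD, RD, AD), compares the conventional and
#' free-water-corrected cohort columns: means and SDs, paired t statistic,
#' BH-adjusted p over the four comparisons (one family), and the cohort mean
#' and SD of per-subject percent change. Also reports the free-water mean.
#'
#' @param cohort per-subject data.frame with columns `fa`, `md`, `rd`, `ad`,
#'   `fat`, `mdt`, `rdt`, `adt`, `fw`.
#' @param q FDR level for the family of paired tests.
#' @return data.frame, one row per measure.
#' @export
table_compare_measures <- function(cohort, q = 0.05) {
  measures <- c("fa", "md", "rd", "ad")
  rows <- lapply(measures, function(m) {
    conv <- cohort[[m]]; corr <- cohort[[paste0(m, "t")]]
    tt <- paired_compare(conv, corr)
    pc <- percent_change(conv, corr)
    data.frame(measure = toupper(m),
               dti_mean = mean(conv), dti_sd = stats::sd(conv),
               fwcorr_mean = mean(corr), fwcorr_sd = stats::sd(corr),
               t = tt$statistic, p = tt$p_value,
               pct_change_mean = mean(pc), pct_change_sd = stats::sd(pc))
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_adjust(out$p, q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$significant
  out <- rbind(out, data.frame(measure = "FW", dti_mean = NA, dti_sd = NA,
                               fwcorr_mean = mean(cohort$fw),
                               fwcorr_sd = stats::sd(cohort$fw),
                               t = NA, p = NA, pct_change_mean = NA,
                               pct_change_sd = NA, p_fdr = NA, significant = NA))
  out
}

#' Measure-by-slope standardized regression table
#'
#' Runs, for every diffusion measure and every verbal-fluency slope,
#' [adjusted_regression()] of the slope on the measure adjusted for age and
#' cingulum bundle volume (as % of intracranial volume), optionally adding the
#' log-transformed WM-normalized WMH burden, with one BH family per measure
#' block (conventional measures; corrected measures + free water).
#'
#' @param cohort per-subject data.frame from the tract-metrics stage merged
#'   with slopes and covariates (`age`, `bundle_pctiv`, optionally `wmh_log`).
#' @param slopes slope column names.
#' @param adjust_wmh add `wmh_log` as a covariate.
#' @param covariates names of the adjustment covariate columns; empty for
#'   unadjusted models.
#' @param q FDR level per family.
#' @return data.frame: `family`, `measure`, `slope`, `beta`, `r_squared`,
#'   `p`, `p_fdr`, `significant`.
#' @export
table_regressions <- function(cohort, slopes = c("slope_ist15", "slope_ist30", "slope_ist60"),
                              adjust_wmh = FALSE,
                              covariates = c("age", "bundle_pctiv"), q = 0.05) {
  families <- list(conventional = c("fa", "md", "ad", "rd"),
                   fw_corrected = c("fat", "mdt", "adt", "rdt", "fw"))
  covs <- stats::setNames(lapply(covariates, function(cv) cohort[[cv]]), covariates)
  if (adjust_wmh) covs$wmh_log <- cohort$wmh_log
  out <- list()
  for (fam in names(families)) {
    rows <- list()
    for (m in families[[fam]]) {
      for (sl in slopes) {
        rr <- adjusted_regression(cohort[[sl]],
                                  stats::setNames(list(cohort[[m]]), m), covs)
        rows[[paste(m, sl)]] <- data.frame(
          family = fam, measure = m, slope = sl,
          beta = rr$coefficients$beta[1], r_squared = rr$r_squared,
          p = rr$coefficients$p_value[1])
      }
    }
    fam_df <- do.call(rbind, rows)
    fdr <- fdr_adjust(fam_df$p, q)
    fam_df$p_fdr <- fdr$adjusted
    fam_df$significant <- fdr$significant
    out[[fam]] <- fam_df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Joint free-water and corrected-MD model
#'
#' Enters the free-water content and MDt simultaneously as standardized
#' predictors of a verbal-fluency slope, adjusted for age and bundle volume,
#' to assess whether the two carry independent information.
#'
#' @param cohort per-subject data.frame.
#' @param slope slope column name.
#' @param adjust_wmh add `wmh_log` as a covariate.
#' @param covariates names of the adjustment covariate columns.
#' @return a `regression_result` with rows for `fw` and `mdt`.
#' @export
joint_fw_mdt_model <- function(cohort, slope = "slope_ist15", adjust_wmh = FALSE,
                               covariates = c("age", "bundle_pctiv")) {
  covs <- stats::setNames(lapply(covariates, function(cv) cohort[[cv]]), covariates)
  if (adjust_wmh) covs$wmh_log <- cohort$wmh_log
  adjusted_regression(cohort[[slope]],
                      list(fw = cohort$fw, mdt = cohort$mdt), covs)
}
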