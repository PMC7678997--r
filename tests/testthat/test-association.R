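# Bivariate screens, paired tests, standardized regressions, FDR control.

test_that("Spearman screen: perfect monotone association and exhaustive-permutation p", {
  x <- c(0.3, 1.1, 2.2, 2.9, 4.5, 5.0, 7.1)
  r <- bivariate_screen(x, exp(x), "spearman")
  expect_equal(r$statistic, 1)
  set.seed(6)
  xs <- rnorm(7); ys <- rnorm(7)
  res <- bivariate_screen(xs, ys, "spearman")
  rx <- rank(xs); ry <- rank(ys)
  rhos <- vapply(all_perms(7), function(p) cor(rx, ry[p]), numeric(1))
  p_perm <- mean(abs(rhos) >= abs(cor(rx, ry)) - 1e-12)
  expect_equal(res$p_value, p_perm, tolerance = 1e-12)
  expect_error(bivariate_screen(rep(1, 8), rnorm(8), "spearman"), "constant")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(13)
  x <- rnorm(30); y <- rnorm(30)
  base <- bivariate_screen(x, y, "spearman")
  for (tf in list(function(v) exp(v), function(v) v^3, function(v) atan(v))) {
    r <- bivariate_screen(tf(x), y, "spearman")
    expect_equal(r$statistic, base$statistic, tolerance = 1e-12)
    expect_equal(r$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney screen: symmetry null value and enumeration oracle", {
  # identical multisets => U = n1 n2 / 2
  v <- c(1.2, 3.4, 0.7, 5.5, 2.2)
  g <- rep(c("a", "b"), each = 5)
  r <- bivariate_screen(c(v, v), g, "mannwhitney")
  expect_equal(unname(r$statistic), length(v)^2 / 2)
  # exact p equals brute force over all group assignments
  set.seed(9)
  a <- rnorm(5); b <- rnorm(5) + 0.8
  res <- bivariate_screen(c(a, b), g, "mannwhitney")
  pool <- c(a, b)
  mu <- 25 / 2
  Us <- apply(combn(10, 5), 2, function(idx) sum(outer(pool[idx], pool[-idx], ">")))
  U_obs <- sum(outer(a, b, ">"))
  p_enum <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
  expect_equal(res$p_value, p_enum, tolerance = 1e-12)
  expect_error(bivariate_screen(rnorm(4), rep("a", 4), "mannwhitney"), "two groups")
})

test_that("paired comparison matches the closed-form t formula", {
  expect_equal(paired_compare(1:5, 1:5)$p_value, 1)
  expect_equal(paired_compare(1:5, 1:5)$statistic, 0)
  set.seed(2)
  before <- rnorm(10); after <- before + 0.5 + rnorm(10, sd = 0.01)
  r <- paired_compare(before, after)
  d <- after - before
  t_oracle <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_oracle), 9), tolerance = 1e-12)
  expect_lt(paired_compare(before, before + 0.5 + rnorm(10, sd = 1e-4))$p_value, 1e-6)
  expect_error(paired_compare(1:5, 2:6), "degenerate")
})

test_that("standardized regression reproduces a normal-equations oracle", {
  # identity and orthogonality limits
  set.seed(20)
  y <- rnorm(30)
  r1 <- suppressWarnings(adjusted_regression(y, list(x = y)))  # perfect-fit warning
  expect_equal(r1$coefficients$beta, 1, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  x <- rnorm(30)
  x_orth <- residuals(lm(x ~ y))
  r0 <- adjusted_regression(y, list(x = x_orth))
  expect_lt(abs(r0$coefficients$beta), 1e-10)
  # n = 20, two covariates: explicit (X'X)^-1 X'y oracle on z-scored data
  set.seed(21)
  n <- 20
  pred <- rnorm(n); c1 <- rnorm(n); c2 <- rnorm(n)
  out <- 0.6 * pred + 0.3 * c1 + rnorm(n)
  rr <- adjusted_regression(out, list(p = pred), list(c1 = c1, c2 = c2))
  z <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, z(pred), c1, c2)
  beta_or <- solve(t(X) %*% X, t(X) %*% z(out))
  expect_equal(rr$coefficients$beta, beta_or[2], tolerance = 1e-10)
  yhat <- X %*% beta_or
  r2_or <- 1 - sum((z(out) - yhat)^2) / sum(z(out)^2)
  expect_equal(rr$r_squared, r2_or, tolerance = 1e-10)
  expect_error(adjusted_regression(out, list(p = pred), list(p2 = pred * 2)),
               "collinear")
})

test_that("single standardized predictor equals the Pearson correlation", {
  set.seed(30)
  for (i in 1:10) {
    x <- rnorm(25); y <- 0.4 * x + rnorm(25)
    rr <- adjusted_regression(y, list(x = x))
    expect_equal(rr$coefficients$beta, cor(x, y), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up rule", {
  expect_false(any(fdr_adjust(rep(1, 6))$significant))
  expect_true(fdr_adjust(0.01)$significant)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  res <- fdr_adjust(p, q = 0.05)
  # direct step-up oracle
  m <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= seq_len(m) / m * 0.05)))
  reject_oracle <- rep(FALSE, m)
  if (k > 0) reject_oracle[ord[seq_len(k)]] <- TRUE
  expect_equal(res$significant, reject_oracle)
  expect_true(all(diff(sort(res$adjusted)) >= -1e-15))
  expect_error(fdr_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("cohort regression tables carry the planted effect with FDR control", {
  co <- simulate_association_cohort(n = 68, beta_mdt = -0.5, seed = 3)
  t3 <- table_regressions(co)
  mdt_row <- t3[t3$measure == "mdt" & t3$slope == "slope_ist15", ]
  expect_lt(mdt_row$beta, -0.25)
  expect_true(mdt_row$significant)
  # null cohort: betas near zero on average
  co0 <- simulate_association_cohort(n = 68, beta_mdt = 0, seed = 4)
  t30 <- table_regressions(co0)
  expect_lt(mean(abs(t30$beta)), 0.25)
  # comparison table reproduces the planted conventional vs corrected gaps
  t2 <- table_compare_measures(co)
  expect_true(all(t2$fwcorr_mean[t2$measure %in% c("MD", "RD", "AD")] <
                    t2$dti_mean[t2$measure %in% c("MD", "RD", "AD")]))
  expect_gt(t2$fwcorr_mean[t2$measure == "FA"], t2$dti_mean[t2$measure == "FA"])
})
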