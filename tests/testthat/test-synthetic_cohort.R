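# Synthetic-input generators: gradient schemes, bi-tensor signals, planted
# tensors, phantoms, longitudinal scores, screening/exclusions.

test_that("gradient scheme has the acquisition layout and unit, antipodal directions", {
  sch <- the_scheme
  expect_equal(length(sch$bvals), 87)        # (1 b0 + 42) + (2 b0 + 42)
  expect_equal(sum(sch$bvals == 0), 3)
  expect_true(all(sch$bvals[sch$bvals > 0] == 1000))
  dw <- sch$bvals > 0
  expect_true(all(abs(sqrt(colSums(sch$bvecs[, dw]^2)) - 1) < 1e-8))
  # per series, each direction's antipode is present
  for (s in 1:2) {
    g <- sch$bvecs[, dw & sch$series == s]
    expect_equal(ncol(g), 42)
    half <- g[, 1:21]; anti <- g[, 22:42]
    expect_equal(anti, -half)
  }
})

test_that("six-direction scheme yields a full-rank log-linear tensor system", {
  sch <- make_gradient_scheme(6, 1000, 1)
  # independent design construction: rows (1, -b gx^2, ..., -2b gy gz)
  g <- sch$bvecs; b <- sch$bvals
  X <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  expect_equal(qr(X)$rank, 7L)
  expect_error(make_gradient_scheme(5, 1000, 1), "identifiability")
})

test_that("bval/bvec files round-trip through the FSL-dialect writer", {
  prefix <- file.path(withr::local_tempdir(), "dwi")
  write_bval_bvec(the_scheme1, prefix)
  back <- read_bval_bvec(prefix)
  expect_equal(back$bvals, the_scheme1$bvals)
  expect_equal(back$bvecs, the_scheme1$bvecs, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("bi-tensor forward model collapses correctly at the mixture endpoints", {
  sch <- the_scheme1
  D <- tensor_from_eigen(tensor_from_scalars(0.6, 0.8e-3), c(0, 1, 0))
  # f = 0: pure tensor attenuation
  s <- simulate_bitensor_signal(voxel_model(D, 0, s0 = 500), sch)
  quad <- colSums(sch$bvecs * (D %*% sch$bvecs))
  expect_equal(s, 500 * exp(-sch$bvals * quad), tolerance = 1e-12)
  # f = 1 at b = 1000: every DW volume equals S0 * exp(-3)
  s1 <- simulate_bitensor_signal(voxel_model(D, 1, s0 = 500), sch)
  expect_equal(unname(s1[sch$bvals > 0]), rep(500 * exp(-3), 42), tolerance = 1e-12)
  expect_error(simulate_bitensor_signal(voxel_model(D, 0.2), sch, snr = -5), "snr")
})

test_that("noise-free signals are antipodally symmetric and seeded noise is reproducible", {
  sch <- the_scheme
  for (seed in 1:3) {
    D <- random_spd_tensor(seed)
    vm <- voxel_model(D, runif(1), s0 = 1000)
    s <- simulate_bitensor_signal(vm, sch)
    dw <- which(sch$bvals > 0 & sch$series == 1)
    half <- dw[1:21]; anti <- dw[22:42]
    expect_true(all(abs(s[half] - s[anti]) <= 1e-12 * 1000))
    n1 <- simulate_bitensor_signal(vm, sch, snr = 20, seed = 11)
    n2 <- simulate_bitensor_signal(vm, sch, snr = 20, seed = 11)
    expect_identical(n1, n2)
    expect_true(all(n1 >= 0))
  }
})

test_that("Rician mean approaches sigma * sqrt(pi/2) as the true signal vanishes", {
  sch <- the_scheme
  D <- diag(3) * 1e-3
  vm <- voxel_model(D, 1, s0 = 1)   # DW signal = exp(-3), tiny vs sigma below
  snr <- 0.001                      # sigma = 1000 * true b0 signal
  sigma <- 1 / snr
  draws <- unlist(lapply(1:120, function(i) {
    s <- simulate_bitensor_signal(vm, sch, snr = snr, seed = i)
    s[sch$bvals > 0]
  }))
  expect_gt(length(draws), 1e4)
  expect_equal(mean(draws), sigma * sqrt(pi / 2), tolerance = 0.05)
})

test_that("tensor_from_scalars inverts the closed-form scalar maps", {
  expect_equal(tensor_from_scalars(0, 1e-3), rep(1e-3, 3))
  for (case in list(c(0.567, 0.755e-3), c(0.3, 1.1e-3), c(0.85, 0.6e-3))) {
    ev <- tensor_from_scalars(case[1], case[2])
    sc <- oracle_scalars(ev)
    expect_equal(unname(sc["fa"]), case[1], tolerance = 1e-10)
    expect_equal(unname(sc["md"]), case[2], tolerance = 1e-10)
    expect_true(ev[1] >= ev[2] && ev[2] == ev[3] && ev[3] >= 0)
  }
  # stick limit: fa -> 1 drives the radial eigenvalue to 0+ and lambda1 to 3 MD
  ev <- tensor_from_scalars(0.99, 1e-3)
  expect_lt(ev[2], 0.05e-3)
  expect_gt(ev[1], 2.8e-3)
  expect_error(tensor_from_scalars(1.2, 1e-3), "fa")
})

test_that("phantom masks nest, overlap is exact, and construction is deterministic", {
  ph <- make_phantom(wmh_overlap = 0.25, seed = 5)
  m <- ph$masks
  bundle <- m$left_bundle | m$right_bundle
  expect_true(all(m$white_matter[bundle]))
  expect_true(all(m$intracranial[m$white_matter]))
  expect_true(all(m$white_matter[m$wmh]))
  expect_true(all(ph$signal >= 0))
  # voxel-count oracle on the requested bundle/WMH overlap
  n_bundle <- sum(bundle)
  n_overlap <- sum(bundle & m$wmh)
  expect_lte(abs(n_overlap - 0.25 * n_bundle), 1)
  # disjoint construction at overlap 0
  ph0 <- make_phantom(wmh_overlap = 0, seed = 5)
  expect_equal(sum((ph0$masks$left_bundle | ph0$masks$right_bundle) & ph0$masks$wmh), 0)
  # bit-for-bit determinism, including under Rician noise
  pha <- make_phantom(shape = c(16, 16, 10), snr = 20, seed = 9)
  phb <- make_phantom(shape = c(16, 16, 10), snr = 20, seed = 9)
  expect_identical(pha$signal, phb$signal)
  expect_error(make_phantom(wmh_overlap = 1.5), "wmh_overlap")
})

test_that("phantom files are written in the declared formats and read back", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(shape = c(12, 12, 8), seed = 2)
  write_phantom(ph, dir)
  dwi <- read_nifti(file.path(dir, "phantom_dwi.nii"))
  expect_equal(dim(dwi$data), c(12, 12, 8, 87))
  expect_equal(dwi$pixdim, rep(2, 3))
  lb <- read_nifti(file.path(dir, "phantom_left_bundle.nii"))
  expect_identical(array(lb$data == 1L, dim(lb$data)), ph$masks$left_bundle)
  truth <- read.csv(file.path(dir, "phantom_truth.csv"))
  expect_true(all(c("voxel", "fw", "s0", "dxx") %in% names(truth)))
  expect_equal(truth$fw, ph$truth$fw[truth$voxel])
})

test_that("longitudinal scores are nested and deterministic lines recover the mean slope", {
  sim <- simulate_longitudinal_scores(40, seed = 21)
  with(sim$data, {
    expect_true(all(ist15 <= ist30 + 1e-12))
    expect_true(all(ist30 <= ist60 + 1e-12))
  })
  # zero random-slope, zero-residual limit: every OLS slope equals mean_slope
  sim0 <- simulate_longitudinal_scores(12, sd_slope = 0, resid_sd = 0,
                                       mean_slope = -0.489, seed = 3)
  for (s in unique(sim0$data$subject)) {
    d <- sim0$data[sim0$data$subject == s, ]
    expect_equal(unname(coef(lm(ist15 ~ time_years, d))[2]), -0.489,
                 tolerance = 1e-10)
  }
  expect_error(simulate_longitudinal_scores(40, sd_slope = -1), "variance")
  expect_error(simulate_longitudinal_scores(1), "subjects")
})

test_that("mean of per-subject OLS slopes matches the generator mean (two-stage oracle)", {
  n <- 2000
  sim <- simulate_longitudinal_scores(n, resid_sd = 1, seed = 77)
  tg <- sim$visit_times
  tc <- tg - mean(tg)
  sxx <- sum(tc^2)
  y <- matrix(sim$data$ist15, nrow = length(tg))   # visits x subjects
  ols <- colSums(tc * y) / sxx                     # closed-form per-subject OLS
  se <- sd(ols) / sqrt(n)
  expect_lt(abs(mean(ols) - (-0.489)), 3 * se)
})

test_that("staged exclusions attribute subjects to the first failing stage", {
  rec <- simulate_screening_records(seed = 7)
  res <- apply_exclusions(rec)
  expect_equal(unname(res$attrition), c(8, 27, 62, 24, 15, 16, 19))
  expect_equal(res$n_included, 68)
  # conservation holds for any seed
  for (seed in c(1, 99)) {
    r <- apply_exclusions(simulate_screening_records(seed = seed))
    expect_equal(r$n_included + sum(r$attrition), r$n_screened)
  }
  # no-op filter
  rec0 <- rec
  rec0[names(SCREENING_STAGES)] <- FALSE
  res0 <- apply_exclusions(rec0)
  expect_equal(res0$n_included, nrow(rec))
  expect_true(all(res0$attrition == 0))
  # double-flagged subject counts only at its first stage
  two <- data.frame(a = c(FALSE, TRUE), b = c(FALSE, TRUE))
  r2 <- apply_exclusions(two, stage_order = c("a", "b"))
  expect_equal(unname(r2$attrition), c(1, 0))
  expect_error(apply_exclusions(rec, stage_order = "nonexistent_flag"), "unknown")
})
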