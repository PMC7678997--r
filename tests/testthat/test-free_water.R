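# Single-shell bi-tensor free-water fit.

test_that("initial free-water fraction interpolates the conventional MD", {
  expect_equal(init_free_water(3e-3), 0.99)        # clamped upper endpoint
  expect_equal(init_free_water(0.6e-3), 0.01)      # clamped lower endpoint
  expect_equal(init_free_water((0.6e-3 + 3e-3) / 2), 0.5)
  expect_error(init_free_water(1e-3, md_tissue_prior = 4e-3), "d_iso")
})

test_that("planted f = 0 makes corrected and conventional scalars coincide", {
  s <- planted_signal(0.6, 0.75e-3, f = 0)
  fw <- fit_bitensor(s, the_scheme)
  conv <- fit_single_tensor(s, the_scheme)
  expect_lt(fw$fw_fraction, 1e-6)
  expect_equal(unname(fw$scalars["fat"]), unname(conv$scalars["fa"]), tolerance = 1e-6)
  expect_equal(unname(fw$scalars["mdt"]), unname(conv$scalars["md"]), tolerance = 1e-6)
})

test_that("fitted parameters reproduce noise-free signals (signal conservation)", {
  for (case in list(c(0.567, 0.755e-3, 0.141), c(0.4, 0.9e-3, 0.3))) {
    s <- planted_signal(case[1], case[2], case[3])
    fw <- fit_bitensor(s, the_scheme)
    quad <- colSums(the_scheme$bvecs * (fw$tissue_tensor %*% the_scheme$bvecs))
    pred <- fw$s0_hat * ((1 - fw$fw_fraction) * exp(-the_scheme$bvals * quad) +
                           fw$fw_fraction * exp(-the_scheme$bvals * D_ISO))
    expect_true(all(abs(pred - s) / s <= 1e-6))
    expect_true(fw$converged)
  }
})

test_that("optimizer beats a coarse brute-force grid on a noise-free voxel", {
  s <- planted_signal(0.55, 0.8e-3, 0.22, axis = c(0, 1, 0))
  fw <- fit_bitensor(s, the_scheme)
  y <- s / mean(s[the_scheme$bvals == 0])
  grid_cost <- Inf
  for (f in seq(0, 0.95, by = 0.05)) {
    for (l1 in seq(0.4e-3, 2.2e-3, length.out = 12)) {
      for (lp in seq(0.1e-3, 1.2e-3, length.out = 12)) {
        if (lp > l1) next
        D <- tensor_from_eigen(c(l1, lp, lp), c(0, 1, 0))
        quad <- colSums(the_scheme$bvecs * (D %*% the_scheme$bvecs))
        m <- (1 - f) * exp(-the_scheme$bvals * quad) +
          f * exp(-the_scheme$bvals * D_ISO)
        grid_cost <- min(grid_cost, sum((y - m)^2))
      }
    }
  }
  expect_lte(fw$residual, grid_cost + 1e-12)
})

test_that("free-water correction moves every scalar in the documented direction", {
  set.seed(10)
  for (i in 1:6) {
    fa <- runif(1, 0.3, 0.8); md <- runif(1, 0.6e-3, 0.9e-3)
    f <- runif(1, 0.08, 0.35)
    ev <- tensor_from_scalars(fa, md)
    if (ev[1] >= D_ISO) next                 # direction property needs lambda < d_iso
    s <- planted_signal(fa, md, f)
    fw <- fit_bitensor(s, the_scheme)
    conv <- fit_single_tensor(s, the_scheme)
    expect_gt(fw$scalars["fat"], conv$scalars["fa"])
    expect_lt(fw$scalars["mdt"], conv$scalars["md"])
    expect_lt(fw$scalars["rdt"], conv$scalars["rd"])
    expect_lt(fw$scalars["adt"], conv$scalars["ad"])
  }
})

test_that("fitted f respects [0,1] on noisy and pure-noise voxels", {
  vm <- voxel_model(tensor_from_eigen(tensor_from_scalars(0.567, 0.755e-3), c(0, 1, 0)),
                    0.141)
  for (seed in 1:10) {
    s <- simulate_bitensor_signal(vm, the_scheme, snr = 20, seed = seed)
    f <- fit_bitensor(s, the_scheme)$fw_fraction
    expect_gte(f, 0); expect_lte(f, 1)
  }
  # pure-noise voxel: signal is essentially Rician noise around zero
  vm0 <- voxel_model(diag(3) * 2.9e-3, 0.99, s0 = 1)
  s0 <- simulate_bitensor_signal(vm0, the_scheme, snr = 0.05, seed = 4)
  fit0 <- fit_bitensor(s0, the_scheme)
  expect_gte(fit0$fw_fraction, 0); expect_lte(fit0$fw_fraction, 1)
})

test_that("noisy recovery at SNR 20: median f within 0.03, RMSE at most 0.06", {
  vm <- voxel_model(tensor_from_eigen(tensor_from_scalars(0.567, 0.755e-3), c(0, 1, 0)),
                    0.141)
  fs <- vapply(1:500, function(i) {
    s <- simulate_bitensor_signal(vm, the_scheme, snr = 20, seed = i)
    fit_bitensor(s, the_scheme)$fw_fraction
  }, numeric(1))
  expect_lt(abs(median(fs) - 0.141), 0.03)
  expect_lte(sqrt(mean((fs - 0.141)^2)), 0.06)
})

test_that("near-isotropic tissue is flagged degenerate, not dropped", {
  s <- planted_signal(0.01, 0.7e-3, 0.2)
  fw <- fit_bitensor(s, the_scheme)
  expect_true(fw$degenerate)
  expect_s3_class(fw, "free_water_fit")
})
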