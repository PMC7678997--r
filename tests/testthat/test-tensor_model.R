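# Conventional single-tensor fitting and scalar maps.

test_that("tensor scalars match the closed-form definitions", {
  s <- tensor_scalars(c(1, 1, 1) * 1e-3)
  expect_equal(unname(s), c(0, 1e-3, 1e-3, 1e-3), tolerance = 1e-14)
  expect_equal(unname(tensor_scalars(c(2e-3, 0, 0))["fa"]), 1, tolerance = 1e-12)
  # hand arithmetic on the corrected-cingulum eigenvalue triple
  s2 <- tensor_scalars(c(1.27, 0.493, 0.493) * 1e-3)
  expect_equal(unname(s2["md"]), (1.27 + 2 * 0.493) / 3 * 1e-3, tolerance = 1e-15)
  expect_equal(unname(s2["rd"]), 0.493e-3)
  expect_equal(unname(s2["ad"]), 1.27e-3)
  expect_error(tensor_scalars(c(0, 0, 0)), "undefined")
})

test_that("FA lies in [0,1] and is invariant under eigenvalue rescaling", {
  set.seed(42)
  for (i in 1:25) {
    l <- sort(runif(3, 0, 2e-3), decreasing = TRUE)
    fa <- tensor_scalars(l)["fa"]
    expect_gte(fa, 0); expect_lte(fa, 1)
    expect_equal(unname(tensor_scalars(l * 3.7)["fa"]), unname(fa), tolerance = 1e-12)
  }
})

test_that("noise-free isotropic free-water signal fits to MD = 3e-3 and FA = 0", {
  s <- simulate_bitensor_signal(voxel_model(diag(3) * 3e-3, 0), the_scheme)
  fit <- fit_single_tensor(s, the_scheme)
  expect_equal(unname(fit$scalars["md"]), 3e-3, tolerance = 1e-9)
  expect_lt(fit$scalars["fa"], 1e-9)
})

test_that("log-linear inversion recovers arbitrary planted SPD tensors exactly", {
  for (seed in 1:5) {
    D <- random_spd_tensor(seed)
    s <- simulate_bitensor_signal(voxel_model(D, 0, s0 = 800), the_scheme)
    fit <- fit_single_tensor(s, the_scheme)
    expect_equal(fit$tensor, D, tolerance = 1e-9)
    expect_equal(fit$s0_hat, 800, tolerance = 1e-9)
    expect_false(fit$clamped)
  }
  expect_error(fit_single_tensor(rep(-1, 87), the_scheme), "b0")
})

test_that("indefinite planted tensors are clamped at zero and flagged", {
  # an indefinite 'tensor' still defines a valid positive signal via exp()
  D <- diag(c(1.2e-3, 0.5e-3, -2e-5))
  X <- cbind(1, -the_scheme$bvals * the_scheme$bvecs[1, ]^2,
             -the_scheme$bvals * the_scheme$bvecs[2, ]^2,
             -the_scheme$bvals * the_scheme$bvecs[3, ]^2,
             -2 * the_scheme$bvals * the_scheme$bvecs[1, ] * the_scheme$bvecs[2, ],
             -2 * the_scheme$bvals * the_scheme$bvecs[1, ] * the_scheme$bvecs[3, ],
             -2 * the_scheme$bvals * the_scheme$bvecs[2, ] * the_scheme$bvecs[3, ])
  s <- exp(as.vector(X %*% c(log(600), D[1, 1], D[2, 2], D[3, 3], 0, 0, 0)))
  fit <- fit_single_tensor(s, the_scheme)
  # unclamped eigen-decomposition oracle on the recovered tensor
  ev_oracle <- sort(eigen(fit$tensor, symmetric = TRUE)$values, decreasing = TRUE)
  expect_lt(ev_oracle[3], 0)
  expect_true(fit$clamped)
  expect_equal(fit$eigenvalues[3], 0)
  expect_equal(fit$eigenvalues[1:2], ev_oracle[1:2], tolerance = 1e-9)
})

test_that("scalars are rotation invariant", {
  th <- 0.7; ax <- c(1, 2, 0.5) / sqrt(5.25)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K   # Rodrigues
  D <- tensor_from_eigen(tensor_from_scalars(0.6, 0.8e-3), c(0, 1, 0))
  sch_rot <- the_scheme
  sch_rot$bvecs <- R %*% the_scheme$bvecs
  f1 <- fit_single_tensor(simulate_bitensor_signal(voxel_model(D, 0), the_scheme),
                          the_scheme)
  f2 <- fit_single_tensor(
    simulate_bitensor_signal(voxel_model(R %*% D %*% t(R), 0), sch_rot), sch_rot)
  expect_equal(f1$scalars, f2$scalars, tolerance = 1e-10)
})

test_that("free-water contamination inflates conventional MD monotonically", {
  D <- tensor_from_eigen(tensor_from_scalars(0.567, 0.755e-3), c(0, 1, 0))
  md <- vapply(seq(0, 0.9, by = 0.1), function(f) {
    s <- simulate_bitensor_signal(voxel_model(D, f), the_scheme)
    unname(fit_single_tensor(s, the_scheme)$scalars["md"])
  }, numeric(1))
  expect_true(all(diff(md) > 0))
})
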