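# Forward bi-tensor signal model and planted-tensor construction.

#' Fixed free-water diffusivity (mm^2/s)
#'
#' Diffusivity of free water at body temperature, the fixed isotropic
#' compartment of the bi-tensor model.
#' @export
D_ISO <- 3e-3

#' Construct a voxel model for simulation
#'
#' Bundles the ground-truth ingredients of one voxel of the two-compartment
#' forward model: a symmetric positive-semidefinite tissue tensor, a
#' free-water volume fraction, and the non-diffusion-weighted amplitude.
#'
#' @param tissue_tensor symmetric positive-semidefinite 3x3 matrix, mm^2/s.
#' @param fw_fraction free-water volume fraction in `[0, 1]`.
#' @param s0 non-DW signal amplitude (> 0, arbitrary units).
#' @return an object of class `voxel_model`.
#' @export
voxel_model <- function(tissue_tensor, fw_fraction, s0 = 1000) {
  tissue_tensor <- (tissue_tensor + t(tissue_tensor)) / 2
  ev <- eigen(tissue_tensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1e-30)) {
    stop("voxel_model: tissue tensor must be positive semi-definite")
  }
  if (fw_fraction < 0 || fw_fraction > 1) stop("voxel_model: fw_fraction must lie in [0, 1]")
  if (s0 <= 0) stop("voxel_model: s0 must be positive")
  structure(list(tissue_tensor = tissue_tensor, fw_fraction = fw_fraction, s0 = s0),
            class = "voxel_model")
}

#' Axially symmetric tensor eigenvalues from target FA and MD
#'
#' Inverts the closed-form scalar maps for a prolate (cigar-shaped) tensor:
#' returns eigenvalues `(lambda1, lambda_perp, lambda_perp)` whose fractional
#' anisotropy and mean diffusivity reproduce the requested values. Used to
#' plant tissue tensors matching reported cohort means.
#'
#' With `a = fa / sqrt(3 - 2 fa^2)`, the solution is
#' `lambda1 = md (1 + 2a)`, `lambda_perp = md (1 - a)`.
#'
#' @param fa target fractional anisotropy, `0 <= fa < 1`.
#' @param md target mean diffusivity, mm^2/s, > 0.
#' @return numeric length-3 vector of eigenvalues, decreasing.
#' @examples
#' tensor_from_scalars(0.567, 0.755e-3)
#' @export
tensor_from_scalars <- function(fa, md) {
  if (fa < 0 || fa >= 1) stop("tensor_from_scalars: fa must lie in [0, 1)")
  if (md <= 0) stop("tensor_from_scalars: md must be positive")
  a <- fa / sqrt(3 - 2 * fa^2)
  ev <- c(md * (1 + 2 * a), md * (1 - a), md * (1 - a))
  if (ev[2] < 0) stop("tensor_from_scalars: infeasible (fa, md): radial eigenvalue < 0")
  ev
}

#' Build a 3x3 tensor from eigenvalues and a principal axis
#'
#' @param eigenvalues length-3, `(lambda1, lambda2, lambda3)`.
#' @param axis principal direction for `lambda1`; normalized internally.
#'   The two transverse axes are an arbitrary orthonormal completion.
#' @return symmetric 3x3 matrix.
#' @export
tensor_from_eigen <- function(eigenvalues, axis = c(1, 0, 0)) {
  e1 <- axis / sqrt(sum(axis^2))
  helper <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- helper - sum(helper * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  v <- cbind(e1, e2, e3)
  v %*% diag(eigenvalues) %*% t(v)
}

#' Simulate single-shell signals from the bi-tensor forward model
#'
#' Noise-free signal per volume is
#' `S0 * ((1 - f) * exp(-b g' D g) + f * exp(-b d_iso))`
#' with the free-water diffusivity `d_iso` fixed at `3e-3` mm^2/s. When `snr`
#' is given, Rician noise is applied: the noise-free value is treated as the
#' real channel and Gaussian noise with `sigma = S0 / snr` is added to both
#' quadrature channels before taking the magnitude.
#'
#' @param model a [voxel_model()].
#' @param scheme a [make_gradient_scheme()] scheme.
#' @param snr signal-to-noise ratio `S0 / sigma` on the b0 signal, or `NULL`
#'   for noise-free simulation.
#' @param seed integer seed making the Rician draw reproducible; ignored when
#'   `snr` is `NULL`.
#' @return numeric vector of signal values, one per volume of the scheme.
#' @export
simulate_bitensor_signal <- function(model, scheme, snr = NULL, seed = 1L) {
  stopifnot(inherits(model, "voxel_model"), inherits(scheme, "gradient_scheme"))
  if (!is.null(snr) && snr <= 0) stop("simulate_bitensor_signal: snr must be positive")
  s <- bitensor_predict(model$s0, model$fw_fraction, model$tissue_tensor,
                        scheme$bvals, scheme$bvecs)
  if (!is.null(snr)) {
    sigma <- model$s0 / snr
    s <- withr_seed(seed, function() {
      n <- length(s)
      sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
    })
  }
  s
}

# Noise-free forward model; vectorized over volumes.
bitensor_predict <- function(s0, f, tensor, bvals, bvecs) {
  quad <- colSums(bvecs * (tensor %*% bvecs))
  s0 * ((1 - f) * exp(-bvals * quad) + f * exp(-bvals * D_ISO))
}

# Run fn under a local RNG state so simulation never disturbs the caller's.
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}
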