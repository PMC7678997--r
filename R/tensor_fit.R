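# Conventional single diffusion tensor fit and scalar maps.

#' Scalar measures from tensor eigenvalues
#'
#' Standard DTI scalars: mean diffusivity `MD = (l1 + l2 + l3) / 3`, axial
#' diffusivity `AD = l1`, radial diffusivity `RD = (l2 + l3) / 2`, and
#' fractional anisotropy
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||`.
#'
#' @param eigenvalues length-3 numeric, ordered `l1 >= l2 >= l3 >= 0`, mm^2/s.
#' @return named numeric vector with `fa`, `md`, `rd`, `ad`.
#' @examples
#' tensor_scalars(c(1.27e-3, 0.493e-3, 0.493e-3))
#' @export
tensor_scalars <- function(eigenvalues) {
  l <- eigenvalues
  if (length(l) != 3L) stop("tensor_scalars: three eigenvalues required")
  if (any(l < -1e-15)) stop("tensor_scalars: eigenvalues must be non-negative")
  if (all(l == 0)) stop("tensor_scalars: FA undefined for an all-zero tensor")
  md <- mean(l)
  fa <- sqrt(3 / 2) * sqrt(sum((l - md)^2)) / sqrt(sum(l^2))
  c(fa = fa, md = md, rd = (l[2] + l[3]) / 2, ad = l[1])
}

#' Fit the single diffusion tensor to one voxel's signals
#'
#' Weighted log-linear least squares on `ln S = ln S0 - b g' D g`: an ordinary
#' least-squares pass on the log signal followed by one refinement pass with
#' weights equal to the squared predicted signal (the classic WLS estimator).
#' `S0` is estimated jointly as the intercept of the log-linear system.
#' Negative eigenvalues are clamped to zero and flagged.
#'
#' @param signals numeric vector, one positive value per volume.
#' @param scheme the matching `gradient_scheme`.
#' @return an object of class `tensor_fit`: list with `tensor` (3x3, mm^2/s),
#'   `eigenvalues` (decreasing, clamped at 0), `eigenvectors` (columns),
#'   `s0_hat`, `scalars` (`fa`, `md`, `rd`, `ad`) and `clamped` (logical).
#' @export
fit_single_tensor <- function(signals, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b0 <- scheme$bvals == 0
  if (!any(b0)) stop("fit_single_tensor: at least one b0 volume is required")
  if (any(signals[b0] <= 0)) stop("fit_single_tensor: non-positive b0 signal")
  X <- tensor_design(scheme)
  if (qr(X)$rank < 7L) stop("fit_single_tensor: rank-deficient design (non-collinear directions needed)")
  y <- log(pmax(signals, .Machine$double.xmin))
  beta <- stats::lm.fit(X, y)$coefficients
  # one WLS refinement: weights = squared predicted signal
  w <- exp(as.vector(X %*% beta))^2
  beta <- stats::lm.wfit(X, y, w)$coefficients
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  es <- eigen(D, symmetric = TRUE)
  ev <- es$values[order(es$values, decreasing = TRUE)]
  vec <- es$vectors[, order(es$values, decreasing = TRUE), drop = FALSE]
  clamped <- any(ev < 0)
  ev <- pmax(ev, 0)
  structure(list(tensor = D, eigenvalues = ev, eigenvectors = vec,
                 s0_hat = unname(exp(beta[1])), scalars = tensor_scalars(ev),
                 clamped = clamped),
            class = "tensor_fit")
}

# Design matrix of the log-linear tensor system: columns
# (1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz)
# for parameters (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("tensor_fit: FA %.4g  MD %.4g mm^2/s%s\n",
              x$scalars["fa"], x$scalars["md"],
              if (x$clamped) "  [clamped]" else ""))
  invisible(x)
}

#' Fit the single tensor over every voxel of a phantom
#'
#' @param phantom a [make_phantom()] volume.
#' @param mask optional logical volume restricting the fit (defaults to the
#'   intracranial mask).
#' @return list of 3D arrays `fa`, `md`, `rd`, `ad`, `s0`, plus `clamped`
#'   (logical array); voxels outside the mask are `NA`.
#' @export
fit_dti_volume <- function(phantom, mask = NULL) {
  stopifnot(inherits(phantom, "phantom_volume"))
  if (is.null(mask)) mask <- phantom$masks$intracranial
  shape <- phantom$shape
  out <- list(fa = array(NA_real_, shape), md = array(NA_real_, shape),
              rd = array(NA_real_, shape), ad = array(NA_real_, shape),
              s0 = array(NA_real_, shape), clamped = array(FALSE, shape))
  idx <- which(mask)
  for (v in idx) {
    fit <- fit_single_tensor(phantom$signal[v, ], phantom$scheme)
    out$fa[v] <- fit$scalars["fa"]; out$md[v] <- fit$scalars["md"]
    out$rd[v] <- fit$scalars["rd"]; out$ad[v] <- fit$scalars["ad"]
    out$s0[v] <- fit$s0_hat; out$clamped[v] <- fit$clamped
  }
  out
}
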