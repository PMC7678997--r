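# Bundle-shaped digital phantom: nested masks, planted bi-tensor ground truth,
# simulated single-shell signals.

#' Build a synthetic bundle phantom with planted ground truth
#'
#' Constructs, on a small 3D grid, the nested anatomy the pipeline consumes —
#' an intracranial box, a white-matter slab inside it, left and right
#' tube-shaped bundles running anterior-posterior inside the slab, and a
#' white-matter-hyperintensity (WMH) region overlapping the bundle by a
#' requested fraction — then plants a tissue tensor and free-water fraction in
#' every intracranial voxel and simulates single-shell signals through the
#' bi-tensor forward model, optionally with Rician noise.
#'
#' Planted defaults are the cohort means this package's recovery tests target:
#' bundle tissue FA 0.567 and MD 0.755e-3 mm^2/s, free-water fraction drawn
#' around 0.141, bundle-in-WMH fraction 3.2%. Bundle voxels are oriented along
#' the tube axis (y); background white matter is mildly anisotropic; WMH
#' voxels get a more isotropic, more diffusive tissue tensor and elevated free
#' water. Voxels inside the intracranial mask but outside white matter are
#' free-water dominated (CSF-like). All ground truth is retained in `$truth`.
#'
#' @param shape grid dimensions, length 3 (kept small; <= 64 per axis).
#' @param bundle_radius tube radius in voxels.
#' @param bundle_fa,bundle_md planted tissue FA and MD (mm^2/s) in the bundle.
#' @param wm_fa,wm_md planted tissue scalars in background white matter.
#' @param wmh_overlap fraction of bundle voxels covered by the WMH mask, in
#'   `[0, 1]`.
#' @param fw_mean,fw_sd mean and spatial SD of the planted free-water fraction
#'   in white matter (clamped to `[0.02, 0.6]`).
#' @param snr b0 signal-to-noise ratio for Rician noise, or `NULL` for
#'   noise-free signals.
#' @param scheme gradient scheme; defaults to
#'   `make_gradient_scheme(21, 1000, 2)`.
#' @param voxel_size isotropic voxel edge, mm.
#' @param seed integer seed; the whole construction is reproducible.
#' @return object of class `phantom_volume`: `signal` (n_voxels x n_volumes,
#'   linear voxel index in rows), `shape`, `scheme`, `voxel_size`, `masks`
#'   (logical arrays `left_bundle`, `right_bundle`, `white_matter`, `wmh`,
#'   `intracranial`), `truth` (list: `fw`, `s0` 3D arrays; `tensors`
#'   n_voxels x 6 packed upper-triangle xx,yy,zz,xy,xz,yz), `seed`.
#' @export
make_phantom <- function(shape = c(24, 24, 12), bundle_radius = 2,
                         bundle_fa = 0.567, bundle_md = 0.755e-3,
                         wm_fa = 0.35, wm_md = 0.75e-3,
                         wmh_overlap = 0.032,
                         fw_mean = 0.141, fw_sd = 0.03,
                         snr = NULL, scheme = NULL, voxel_size = 2,
                         seed = 1L) {
  if (any(shape > 64)) stop("make_phantom: grid limited to 64 voxels per axis")
  if (wmh_overlap < 0 || wmh_overlap > 1) stop("make_phantom: wmh_overlap must lie in [0, 1]")
  if (is.null(scheme)) scheme <- make_gradient_scheme(21, 1000, 2)

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ix <- slice.index(array(0, shape), 1)
  iy <- slice.index(array(0, shape), 2)
  iz <- slice.index(array(0, shape), 3)

  icv <- ix > 1 & ix < nx & iy > 1 & iy < ny & iz > 1 & iz < nz
  wm <- ix > 2 & ix < nx - 1 & iy > 2 & iy < ny - 1 &
    iz >= max(3, floor(nz / 2) - 2) & iz <= min(nz - 2, floor(nz / 2) + 3)
  zc <- floor(nz / 2)
  xl <- round(nx / 2 - nx / 5)
  xr <- round(nx / 2 + nx / 5)
  tube <- function(xc) {
    (ix - xc)^2 + (iz - zc)^2 <= bundle_radius^2 & iy > 2 & iy < ny - 1
  }
  left <- tube(xl) & wm
  right <- tube(xr) & wm

  bundle <- left | right
  n_bundle <- sum(bundle)
  n_in <- round(wmh_overlap * n_bundle)
  wmh <- array(FALSE, shape)
  if (n_in > 0) {
    # anterior (low-y) end of the bundle, deterministically ordered
    bidx <- which(bundle)
    bidx <- bidx[order(iy[bidx], ix[bidx], iz[bidx])]
    wmh[bidx[seq_len(n_in)]] <- TRUE
  }
  # extra WMH tissue between the bundles, never touching them
  blob <- wm & !bundle & abs(ix - round((xl + xr) / 2)) <= 2 &
    iy > 2 & iy <= 2 + max(2, round(ny / 6))
  wmh <- wmh | blob

  truth_fw <- array(NA_real_, shape)
  truth_s0 <- array(NA_real_, shape)
  tensors <- matrix(NA_real_, prod(shape), 6)
  colnames(tensors) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  signal <- matrix(0, prod(shape), length(scheme$bvals))

  ev_bundle <- tensor_from_scalars(bundle_fa, bundle_md)
  ev_wm <- tensor_from_scalars(wm_fa, wm_md)
  ev_wmh <- tensor_from_scalars(max(wm_fa - 0.1, 0.05), wm_md * 1.2)
  ev_csf <- rep(1.0e-3, 3)  # residual non-free tissue in CSF-dominated voxels

  build <- function() {
    idx <- which(icv)
    fw_draw <- pmin(pmax(stats::rnorm(length(idx), fw_mean, fw_sd), 0.02), 0.6)
    noise1 <- NULL; noise2 <- NULL
    if (!is.null(snr)) {
      nvol <- length(scheme$bvals)
      noise1 <- matrix(stats::rnorm(length(idx) * nvol), length(idx), nvol)
      noise2 <- matrix(stats::rnorm(length(idx) * nvol), length(idx), nvol)
    }
    for (k in seq_along(idx)) {
      v <- idx[k]
      if (bundle[v]) {
        D <- tensor_from_eigen(ev_bundle, axis = c(0, 1, 0))
        f <- fw_draw[k]
      } else if (wmh[v]) {
        D <- tensor_from_eigen(ev_wmh, axis = c(0, 1, 0))
        f <- pmin(fw_draw[k] + 0.1, 0.8)
      } else if (wm[v]) {
        D <- tensor_from_eigen(ev_wm, axis = c(1, 0, 0))
        f <- fw_draw[k]
      } else {
        D <- diag(ev_csf)
        f <- 0.9
      }
      if (wmh[v] && bundle[v]) {  # lesioned bundle tissue: keep bundle axis
        D <- tensor_from_eigen(tensor_from_scalars(max(bundle_fa - 0.15, 0.05),
                                                   bundle_md * 1.15),
                               axis = c(0, 1, 0))
        f <- pmin(fw_draw[k] + 0.1, 0.8)
      }
      s0 <- 1000
      truth_fw[v] <<- f
      truth_s0[v] <<- s0
      tensors[v, ] <<- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
      s <- bitensor_predict(s0, f, D, scheme$bvals, scheme$bvecs)
      if (!is.null(snr)) {
        sigma <- s0 / snr
        s <- sqrt((s + sigma * noise1[k, ])^2 + (sigma * noise2[k, ])^2)
      }
      signal[v, ] <<- s
    }
  }
  withr_seed(seed, build)

  structure(list(signal = signal, shape = shape, scheme = scheme,
                 voxel_size = voxel_size,
                 masks = list(left_bundle = left, right_bundle = right,
                              white_matter = wm, wmh = wmh, intracranial = icv),
                 truth = list(fw = truth_fw, s0 = truth_s0, tensors = tensors),
                 seed = as.integer(seed)),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("phantom_volume: grid", paste(x$shape, collapse = "x"),
      "|", sum(x$masks$left_bundle | x$masks$right_bundle), "bundle voxels",
      "|", sum(x$masks$wmh), "WMH voxels",
      "|", length(x$scheme$bvals), "volumes\n")
  invisible(x)
}

#' Write a phantom to disk in the pipeline's file formats
#'
#' Emits the 4D signal and all masks as NIfTI, the gradient table as
#' FSL-dialect bval/bvec, and a per-voxel ground-truth sidecar CSV (linear
#' voxel index, planted free water, packed tensor, s0).
#'
#' @param phantom a `phantom_volume`.
#' @param dir output directory, created if needed.
#' @param prefix file-name prefix.
#' @return named vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- rep(phantom$voxel_size, 3)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  sig <- array(phantom$signal, c(phantom$shape, ncol(phantom$signal)))
  write_nifti(sig, p("dwi.nii"), pixdim = px)
  for (m in names(phantom$masks)) {
    write_nifti(phantom$masks[[m]], p(paste0(m, ".nii")), pixdim = px,
                datatype = "uint8")
  }
  write_bval_bvec(phantom$scheme, file.path(dir, prefix))
  gt <- data.frame(voxel = which(phantom$masks$intracranial))
  gt$fw <- phantom$truth$fw[gt$voxel]
  gt$s0 <- phantom$truth$s0[gt$voxel]
  gt <- cbind(gt, phantom$truth$tensors[gt$voxel, , drop = FALSE])
  utils::write.csv(gt, p("truth.csv"), row.names = FALSE)
  invisible(c(dwi = p("dwi.nii"), truth = p("truth.csv")))
}
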