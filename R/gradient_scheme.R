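# Single-shell gradient sampling schemes and FSL-dialect bval/bvec I/O.

#' Build a single-shell gradient scheme
#'
#' Constructs the acquisition layout used throughout the package: per series,
#' one or two b=0 volumes followed by `n_dirs_half` diffusion directions spread
#' homogeneously over a half sphere and their antipodes on the opposite half
#' sphere. The first series carries one b0 volume, every later series two
#' (matching a two-run single-shell protocol acquired for SNR).
#'
#' The half-sphere layout is fully deterministic: a Fibonacci-hemisphere seed
#' configuration refined by a fixed number of electrostatic-repulsion steps in
#' which every point interacts with all points and their antipodes, so the
#' final set is well spread for tensor estimation and identical on every call.
#'
#' @param n_dirs_half number of unique (non-antipodal) diffusion directions
#'   per series; at least 6 for tensor identifiability.
#' @param bvalue diffusion weighting of the shell in s/mm^2.
#' @param n_series number of repeated series.
#' @return an object of class `gradient_scheme`: a list with `bvals` (numeric
#'   per volume, s/mm^2), `bvecs` (3 x n_volumes matrix of unit vectors, zero
#'   columns for b0 volumes), and `series` (integer tag per volume).
#' @examples
#' sch <- make_gradient_scheme(21, 1000, 2)
#' table(sch$bvals)
#' @export
make_gradient_scheme <- function(n_dirs_half = 21, bvalue = 1000, n_series = 2) {
  if (n_dirs_half < 6) {
    stop("make_gradient_scheme: at least 6 directions are required for tensor identifiability")
  }
  if (bvalue <= 0) stop("make_gradient_scheme: bvalue must be positive")
  dirs <- half_sphere_directions(n_dirs_half)
  bvals <- c()
  bvecs <- NULL
  series <- c()
  for (s in seq_len(n_series)) {
    n_b0 <- if (s == 1L) 1L else 2L
    g <- cbind(matrix(0, 3, n_b0), dirs, -dirs)
    b <- c(rep(0, n_b0), rep(bvalue, 2L * n_dirs_half))
    bvals <- c(bvals, b)
    bvecs <- cbind(bvecs, g)
    series <- c(series, rep(s, length(b)))
  }
  structure(list(bvals = bvals, bvecs = bvecs, series = as.integer(series)),
            class = "gradient_scheme")
}

# Deterministic homogeneous points on the upper half sphere:
# Fibonacci-hemisphere start + fixed electrostatic-repulsion refinement
# (each point repels all others and all antipodes; projected gradient steps).
half_sphere_directions <- function(n, n_iter = 200L, step = 0.05) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- i / n                       # covers (0, 1): upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i / golden
  p <- rbind(r * cos(phi), r * sin(phi), z)
  for (it in seq_len(n_iter)) {
    q <- cbind(p, -p)
    force <- matrix(0, 3, n)
    for (j in seq_len(n)) {
      d <- p[, j] - q
      dist2 <- colSums(d^2)
      dist2[dist2 < 1e-12] <- Inf   # self term
      force[, j] <- rowSums(sweep(d, 2, dist2^1.5, "/"))
    }
    p <- p + step * force / n
    p <- sweep(p, 2, sqrt(colSums(p^2)), "/")
    p[, p[3, ] < 0] <- -p[, p[3, ] < 0, drop = FALSE]  # keep on upper half
  }
  p
}

#' @export
print.gradient_scheme <- function(x, ...) {
  n_b0 <- sum(x$bvals == 0)
  shells <- sort(unique(x$bvals[x$bvals > 0]))
  cat("gradient_scheme:", length(x$bvals), "volumes,", n_b0, "b0,",
      sum(x$bvals > 0), "DW at b =", paste(shells, collapse = ", "),
      "s/mm^2 over", length(unique(x$series)), "series\n")
  invisible(x)
}

#' Write a gradient scheme as FSL-dialect bval/bvec text files
#'
#' @param scheme a `gradient_scheme`.
#' @param prefix path prefix; writes `<prefix>.bval` (one space-separated row)
#'   and `<prefix>.bvec` (three rows: x, y, z components).
#' @return named character vector of the two paths, invisibly.
#' @export
write_bval_bvec <- function(scheme, prefix) {
  bval_path <- paste0(prefix, ".bval")
  bvec_path <- paste0(prefix, ".bvec")
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(row) {
    paste(format(row, trim = TRUE, digits = 10), collapse = " ")
  }), bvec_path)
  invisible(c(bval = bval_path, bvec = bvec_path))
}

#' Read FSL-dialect bval/bvec files into a gradient scheme
#'
#' @param prefix path prefix as in [write_bval_bvec()].
#' @param series optional integer series tag per volume; defaults to a single
#'   series.
#' @return a `gradient_scheme`.
#' @export
read_bval_bvec <- function(prefix, series = NULL) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  rows <- lapply(readLines(paste0(prefix, ".bvec")), function(l) scan(text = l, quiet = TRUE))
  bvecs <- do.call(rbind, rows)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals)) {
    stop("read_bval_bvec: inconsistent bval/bvec dimensions")
  }
  if (is.null(series)) series <- rep(1L, length(bvals))
  structure(list(bvals = bvals, bvecs = bvecs, series = as.integer(series)),
            class = "gradient_scheme")
}
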