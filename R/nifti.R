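# Minimal NIfTI-1 single-file (.nii) I/O.
#
# Covers exactly what this package emits: little-endian, no extensions,
# datatype float32 (16) for scalar/signal volumes and uint8 (2) for masks,
# 3D or 4D arrays. Not a general NIfTI implementation.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

#' Write an array as a NIfTI-1 volume
#'
#' @param x numeric or logical array, 3 or 4 dimensions.
#' @param path output file path; conventionally ends in `.nii`
#'   (uncompressed only).
#' @param pixdim voxel size in mm per spatial axis, length 3.
#' @param datatype `"float32"` for scalar maps and signals, `"uint8"` for
#'   binary masks.
#' @return `path`, invisibly.
#' @seealso [read_nifti()]
#' @export
write_nifti <- function(x, path, pixdim = c(2, 2, 2), datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  if (is.logical(x)) x <- array(as.integer(x), dim = dim(x))
  nd <- length(dim(x))
  if (nd < 3L || nd > 4L) stop("write_nifti: array must be 3D or 4D")
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(x)
  dims[dims == 0L] <- 1L
  dt_code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(NIFTI_HDR_SIZE, con, size = 4, endian = "little")     # sizeof_hdr
  writeBin(raw(35), con)                                          # unused
  writeBin(as.raw(0L), con)                                       # dim_info
  writeBin(dims, con, size = 2, endian = "little")                # dim[8]
  writeBin(numeric(3), con, size = 4, endian = "little")          # intent_p1..p3
  writeBin(integer(1), con, size = 2, endian = "little")          # intent_code
  writeBin(dt_code, con, size = 2, endian = "little")             # datatype
  writeBin(bitpix, con, size = 2, endian = "little")              # bitpix
  writeBin(integer(1), con, size = 2, endian = "little")          # slice_start
  pd <- c(1, pixdim, 1, 0, 0, 0)                                  # pixdim[8]
  writeBin(pd, con, size = 4, endian = "little")
  writeBin(NIFTI_VOX_OFFSET, con, size = 4, endian = "little")    # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")             # scl_slope, scl_inter
  writeBin(integer(1), con, size = 2, endian = "little")          # slice_end
  writeBin(raw(2), con)                                           # slice_code, xyzt_units
  writeBin(numeric(4), con, size = 4, endian = "little")          # cal_max..toffset
  writeBin(integer(2), con, size = 4, endian = "little")          # glmax, glmin
  writeBin(raw(80 + 24), con)                                     # descrip, aux_file
  writeBin(integer(2), con, size = 2, endian = "little")          # qform, sform = 0
  writeBin(numeric(6), con, size = 4, endian = "little")          # quatern b..z, qoffset x..z... (6 floats)
  writeBin(numeric(12), con, size = 4, endian = "little")         # srow_x/y/z
  writeBin(raw(16), con)                                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)                  # magic
  writeBin(raw(4), con)                                           # extender
  if (datatype == "float32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' @param path file path to an uncompressed `.nii`.
#' @return a list with `data` (array), `pixdim` (length-3 voxel size in mm),
#'   and `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, NIFTI_HDR_SIZE)) stop("read_nifti: not a little-endian NIfTI-1 file")
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = "little")
  seek(con, 70)
  dt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
  seek(con, 76)
  pd <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  seek(con, vox_offset)
  data <- switch(as.character(dt_code),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "2"  = as.integer(readBin(con, "raw", n)),
    stop("read_nifti: unsupported datatype code ", dt_code)
  )
  list(data = array(data, dim = shape),
       pixdim = pd[2:4],
       datatype = if (dt_code == 16L) "float32" else "uint8")
}
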