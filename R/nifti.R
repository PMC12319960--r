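# Minimal NIfTI-1 I/O.
#
# Only the features this pipeline needs: single-file .nii / .nii.gz, the
# 348-byte NIfTI-1 header, dtypes uint8/int16/int32/float32/float64, axis-
# aligned sform built from the voxel size, scl_slope/scl_inter on read, and
# the 80-byte descrip field used to record units. Both byte orders are read;
# files are always written little-endian.

NIFTI_DTYPES <- list(
  uint8  = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16  = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32  = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float  = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  double = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

pad_raw <- function(s, n) {
  r <- charToRaw(as.character(s)[1])
  if (length(r) >= n) r[seq_len(n)] else c(r, raw(n - length(r)))
}

#' Write a volume as NIfTI-1
#'
#' @param x 3D or 4D finite numeric array (echo/time axis last for 4D).
#' @param voxel_size Length-3 voxel dimensions in millimetres.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param dtype Storage type: one of `"double"` (default, lossless for R
#'   numerics), `"float"`, `"int16"`, `"int32"`, `"uint8"`.
#' @param descrip Free-text stored in the header `descrip` field (<= 79
#'   bytes); used to record units such as `"chi ppb"`.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(x, voxel_size, path, dtype = "double", descrip = "") {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("x must be a 3D or 4D array")
  }
  if (any(!is.finite(x))) stop("refusing to write non-finite voxels")
  dt <- NIFTI_DTYPES[[dtype]]
  if (is.null(dt)) stop("unsupported dtype: ", dtype)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L)

  con <- tryCatch(nifti_open(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  w_raw <- function(v) writeBin(v, con)

  ndim <- length(d)
  dim8 <- rep(1L, 8L); dim8[1] <- ndim; dim8[1 + seq_len(ndim)] <- d
  pixdim8 <- c(1, voxel_size, rep(0, 4))

  w_i32(348L)                      # sizeof_hdr
  w_raw(raw(10L + 18L))            # data_type, db_name
  w_i32(0L); w_i16(0L)             # extents, session_error
  w_raw(as.raw(c(114L, 0L)))       # regular 'r', dim_info
  w_i16(dim8)
  w_f32(c(0, 0, 0)); w_i16(0L)     # intent_p1..3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  w_f32(pixdim8)
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); w_raw(raw(1L))        # slice_end, slice_code
  w_raw(as.raw(2L))                # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(pad_raw(descrip, 80L))
  w_raw(raw(24L))                  # aux_file
  w_i16(0L); w_i16(1L)             # qform_code, sform_code
  w_f32(rep(0, 6))                 # quatern b,c,d + qoffset x,y,z
  w_f32(c(voxel_size[1], 0, 0, 0))
  w_f32(c(0, voxel_size[2], 0, 0))
  w_f32(c(0, 0, voxel_size[3], 0))
  w_raw(raw(16L))                  # intent_name
  w_raw(c(charToRaw("n+1"), raw(1L)))  # magic
  w_raw(raw(4L))                   # extension flag

  if (dt$what == "integer") {
    writeBin(as.integer(round(x)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 (`.nii`, `.nii.gz`), returning the data array
#' (echo/time axis last for 4D) together with the voxel geometry. Volumes
#' containing non-finite voxels are rejected with a count of the offending
#' voxels.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list of class `nifti_volume` with elements `data` (3D/4D array),
#'   `voxel_size` (mm), and `descrip`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)

  rd <- function(off, what, n, size, endian, signed = TRUE) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  dim8 <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dim8[1]
  if (!(ndim %in% c(3L, 4L))) stop("only 3D/4D volumes supported, got ndim = ", ndim)
  d <- dim8[1 + seq_len(ndim)]
  dtcode <- rd(70L, "integer", 1L, 2L, endian)
  idx <- which(vapply(NIFTI_DTYPES, function(z) z$code == dtcode, logical(1)))
  if (!length(idx)) stop("unsupported NIfTI datatype code: ", dtcode)
  dt <- NIFTI_DTYPES[[idx]]
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  descrip_raw <- hdr[149:228]
  nz <- which(descrip_raw == as.raw(0))
  descrip <- rawToChar(descrip_raw[seq_len(if (length(nz)) nz[1] - 1L else 80L)])

  skip <- vox_offset - 352L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n) stop("truncated NIfTI data payload: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  nbad <- sum(!is.finite(vals))
  if (nbad > 0) {
    stop(sprintf("volume contains %d non-finite voxel%s: %s",
                 nbad, if (nbad == 1L) "" else "s", path))
  }
  structure(
    list(data = array(vals, dim = d),
         voxel_size = pixdim[2:4],
         descrip = descrip),
    class = "nifti_volume"
  )
}
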