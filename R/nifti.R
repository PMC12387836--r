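#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single-file NIfTI-1 images (`.nii`, `.nii.gz`) carrying a
#' 3D array, voxel spacing and origin. Supports the datatypes this package
#' emits (uint8, int16, int32, float32, float64) and both byte orders on read.
#' Scaling (`scl_slope`/`scl_inter`) is applied on read.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti()` returns a list with `data` (3D array), `spacing`
#'   (numeric length 3, mm) and `origin` (numeric length 3, mm).
#' @keywords internal
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path)
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L)
  endian <- "little"
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[off + seq_len(2L * n)], "integer",
                                     n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[off + seq_len(4L * n)], "double",
                                     n = n, size = 4L, endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "': ", path)
  dim_field <- rd_i16(40L, 8L)
  ndim <- dim_field[1L]
  if (ndim < 3L) stop("expected a 3D NIfTI volume: ", path)
  dims <- dim_field[2:4]
  if (ndim > 3L && any(dim_field[5:(1L + ndim)] > 1L))
    stop("only single-volume 3D NIfTI supported: ", path)
  datatype <- rd_i16(70L, 1L)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  srow_x <- rd_f32(280L, 4L)
  srow_y <- rd_f32(296L, 4L)
  srow_z <- rd_f32(312L, 4L)
  origin <- c(srow_x[4L], srow_y[4L], srow_z[4L])

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n_vox <- prod(dims)
  dt <- switch(as.character(datatype),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "double",  size = 4L, signed = TRUE),
    "64" = list(what = "double",  size = 8L, signed = TRUE),
    stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  )
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data block: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims), spacing = pixdim[2:4], origin = origin)
}

#' @rdname read_nifti
#' @param data 3D numeric/integer array.
#' @param spacing voxel edge lengths in mm (length 3, strictly positive).
#' @param origin physical offset in mm (length 3).
#' @param datatype one of `"float32"`, `"float64"`, `"int32"`, `"int16"`,
#'   `"uint8"`.
#' @return `write_nifti()` returns `path` invisibly.
#' @export
write_nifti <- function(path, data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        datatype = c("float32", "float64", "int32", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, int32 = 32L,
                   float32 = 32L, float64 = 64L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))

  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wr_raw <- function(n) writeBin(raw(n), con)

  wr_i32(348L)                              # sizeof_hdr
  wr_raw(36L)                               # data_type, db_name, extents, session_error, regular, dim_info
  wr_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))  # dim[8]
  wr_f32(c(0, 0, 0)); wr_i16(0L)            # intent_p1..p3, intent_code
  wr_i16(code); wr_i16(bitpix); wr_i16(0L)  # datatype, bitpix, slice_start
  wr_f32(c(1, spacing, 1, 1, 1, 1))         # pixdim[8] (qfac = 1)
  wr_f32(352)                               # vox_offset
  wr_f32(c(1, 0))                           # scl_slope, scl_inter
  wr_i16(0L); writeBin(raw(2L), con)        # slice_end, slice_code, xyzt_units
  wr_f32(c(0, 0, 0, 0))                     # cal_max, cal_min, slice_duration, toffset
  wr_i32(c(0L, 0L))                         # glmax, glmin
  wr_raw(104L)                              # descrip, aux_file
  wr_i16(c(0L, 1L))                         # qform_code = 0, sform_code = 1
  wr_f32(rep(0, 6))                         # quatern_b/c/d, qoffset_x/y/z
  wr_f32(c(spacing[1], 0, 0, origin[1]))    # srow_x
  wr_f32(c(0, spacing[2], 0, origin[2]))    # srow_y
  wr_f32(c(0, 0, spacing[3], origin[3]))    # srow_z
  wr_raw(16L)                               # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)
  wr_raw(4L)                                # extension flag

  vals <- as.vector(data)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(vals)), con, size = bitpix %/% 8L, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}
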