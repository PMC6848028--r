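# Minimal NIfTI-1 reader/writer.
#
# Only what the pipeline needs: single-file .nii (optionally gzipped), 3-D
# payloads (singleton 4th dimension tolerated), datatypes uint8/int16/int32/
# float32/float64, scl_slope/scl_inter honoured, both endiannesses on read.
# No R NIfTI package is available in the deployment environment, hence this
# self-contained implementation.

.nifti_datatypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L),
  name   = c("uint8", "int16", "int32", "float32", "float64"),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

.nifti_open <- function(path, mode) {
  # gzfile transparently reads both plain and gzip streams
  if (grepl("\\.gz$", path) || mode == "rb") gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [volume_image()]. Only 3-D payloads are accepted; a 4-D image with a
#' singleton fourth dimension is squeezed.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `castrr_volume` object.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("unreadable volume: file not found: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("unreadable volume: truncated header in ", path)

  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("unreadable volume: not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)], "double",
                                     n = n, size = 4L, endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unreadable volume: bad magic in ", path)

  dim_field <- rd_i16(40L, 8L)
  ndim <- dim_field[1]
  dims <- dim_field[2:(1 + max(ndim, 1L))]
  if (ndim > 3L) {
    extra <- dims[4:ndim]
    if (any(extra > 1L)) {
      stop("unreadable volume: payload is ", ndim, "-D; split 4-D series before reading")
    }
    dims <- dims[1:3]
  }
  if (length(dims) < 3L) dims <- c(dims, rep(1L, 3L - length(dims)))
  if (any(dims < 1L)) stop("unreadable volume: degenerate dimensions in ", path)

  datatype <- rd_i16(70L, 1L)
  dt <- .nifti_datatypes[.nifti_datatypes$code == datatype, ]
  if (nrow(dt) == 0L) stop("unreadable volume: unsupported datatype code ", datatype)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  descrip <- rawToChar(hdr_raw[149:228])
  descrip <- sub("\\x00.*$", "", descrip, perl = TRUE, useBytes = TRUE)
  sform_code <- rd_i16(254L, 1L)
  srow <- matrix(rd_f32(280L, 12L), nrow = 3L, byrow = TRUE)

  # skip any extension bytes between header end and data start
  to_skip <- as.integer(round(vox_offset)) - 348L
  if (to_skip > 0L) readBin(con, "raw", n = to_skip)

  n_vox <- prod(dims)
  what <- if (dt$name %in% c("float32", "float64")) "double" else "integer"
  signed <- dt$name != "uint8"
  data <- readBin(con, what, n = n_vox, size = dt$bitpix / 8L,
                  signed = signed, endian = endian)
  if (length(data) < n_vox) stop("unreadable volume: truncated data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  arr <- array(as.double(data), dim = dims)

  orientation <- if (sform_code > 0L) .orientation_from_srow(srow) else "RAS"
  units <- if (startsWith(descrip, "units:")) trimws(sub("^units:", "", descrip)) else ""

  volume_image(arr, voxel_size = pixdim[2:4], orientation = orientation, units = units)
}

.orientation_from_srow <- function(srow) {
  codes <- c("R", "A", "S")
  neg <- c("L", "P", "I")
  out <- character(3L)
  for (j in 1:3) {
    i <- which.max(abs(srow[, j]))
    out[j] <- if (srow[i, j] >= 0) codes[i] else neg[i]
  }
  paste(out, collapse = "")
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volume_image()] as a single-file NIfTI-1 image. The volume's
#' `units` tag is stored in the header `descrip` field and round-trips through
#' [read_volume()].
#'
#' @param vol A `castrr_volume`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param datatype Storage type; `"float64"` preserves values exactly,
#'   `"uint8"` suits masks and label volumes.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float64", "float32", "int16", "uint8")) {
  stopifnot(inherits(vol, "castrr_volume"))
  datatype <- match.arg(datatype)
  dt <- .nifti_datatypes[.nifti_datatypes$name == datatype, ]
  dims <- dim(vol$data)
  vs <- vol$voxel_size

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_chr <- function(x, width) {
    raw_x <- charToRaw(x)
    if (length(raw_x) > width) raw_x <- raw_x[1:width]
    writeBin(c(raw_x, raw(width - length(raw_x))), con)
  }

  w_i32(348L)                       # sizeof_hdr
  w_chr("", 10L); w_chr("", 18L)    # data_type, db_name
  w_i32(0L); w_i16(0L)              # extents, session_error
  writeBin(c(charToRaw("r"), as.raw(0L)), con)  # regular, dim_info
  w_i16(c(3L, dims, 1L, 1L, 1L, 1L))            # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)      # intent_p1..p3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix)  # datatype, bitpix
  w_i16(0L)                         # slice_start
  w_f32(c(1, vs, 0, 0, 0, 0))       # pixdim (qfac + voxel sizes)
  w_f32(352)                        # vox_offset
  w_f32(1); w_f32(0)                # scl_slope, scl_inter
  w_i16(0L); writeBin(raw(2L), con) # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_chr(paste0("units:", vol$units), 80L)       # descrip
  w_chr("", 24L)                    # aux_file
  w_i16(0L); w_i16(1L)              # qform_code, sform_code
  w_f32(c(0, 0, 0)); w_f32(c(0, 0, 0))          # quatern, qoffset
  w_f32(c(vs[1], 0, 0, 0)); w_f32(c(0, vs[2], 0, 0)); w_f32(c(0, 0, vs[3], 0))
  w_chr("", 16L)
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  writeBin(raw(4L), con)            # no extensions

  data <- as.vector(vol$data)
  if (datatype %in% c("uint8", "int16")) data <- round(data)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.double(data), con, size = dt$bitpix / 8L, endian = "little")
  } else {
    writeBin(as.integer(data), con, size = dt$bitpix / 8L, endian = "little")
  }
  invisible(path)
}
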