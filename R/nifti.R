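# Minimal NIfTI-1 I/O.
#
# Only what the package needs: single-file .nii / .nii.gz, 3D volumes,
# datatypes uint8 / int16 / int32 / float32 / float64, no scaling
# (scl_slope 0), no extensions on write. Both endiannesses are handled on
# read (detected from sizeof_hdr); files are written little-endian.
# Voxel sizes travel in pixdim[1:3] (micrometres here, by package
# convention recorded in the manifest).

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "numeric", size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "numeric", size = 8L, signed = TRUE,  bitpix = 64L)
)

#' Read a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 reader covering the volumes this package
#' writes and typical converted atlas exports: 3D, datatypes uint8, int16,
#' int32, float32, float64, optional gzip. Scale slopes other than 0/1 are
#' applied.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (numeric/integer 3D array, first axis fastest)
#'   and `voxel_size` (numeric length-3, from `pixdim`).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) ws_stop(sprintf("file not found: %s", path), "io")
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) ws_stop(sprintf("truncated NIfTI header: %s", path), "io")
  parse_hdr <- function(endian) {
    h <- list()
    rc <- rawConnection(hdr_raw)
    on.exit(close(rc))
    h$sizeof_hdr <- readBin(rc, "integer", 1, 4, endian = endian)
    invisible(readBin(rc, "raw", 36L))                      # unused fields
    h$dim <- readBin(rc, "integer", 8, 2, endian = endian)
    invisible(readBin(rc, "raw", 14L))
    h$datatype <- readBin(rc, "integer", 1, 2, endian = endian)
    h$bitpix <- readBin(rc, "integer", 1, 2, endian = endian)
    invisible(readBin(rc, "raw", 2L))                       # slice_start
    h$pixdim <- readBin(rc, "numeric", 8, 4, endian = endian)
    h$vox_offset <- readBin(rc, "numeric", 1, 4, endian = endian)
    h$scl_slope <- readBin(rc, "numeric", 1, 4, endian = endian)
    h$scl_inter <- readBin(rc, "numeric", 1, 4, endian = endian)
    h
  }
  hdr <- parse_hdr("little")
  endian <- "little"
  if (hdr$sizeof_hdr != 348L) {
    hdr <- parse_hdr("big")
    endian <- "big"
    if (hdr$sizeof_hdr != 348L)
      ws_stop(sprintf("not a NIfTI-1 file (bad sizeof_hdr): %s", path), "io")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    ws_stop(sprintf("unsupported NIfTI magic '%s': %s", magic, path), "io")
  ndim <- hdr$dim[1]
  if (ndim < 3L || any(hdr$dim[5:8] > 1))
    ws_stop(sprintf("only 3D volumes supported: %s", path), "io")
  sh <- hdr$dim[2:4]
  dt <- NIFTI_DTYPES[[as.character(hdr$datatype)]]
  if (is.null(dt))
    ws_stop(sprintf("unsupported NIfTI datatype %d: %s", hdr$datatype, path), "io")
  skip <- as.integer(round(hdr$vox_offset)) - 348L
  if (skip > 0L) invisible(readBin(con, "raw", skip))
  n <- prod(sh)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) ws_stop(sprintf("truncated NIfTI data: %s", path), "io")
  if (hdr$scl_slope != 0 && hdr$scl_slope != 1)
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  list(data = array(vals, dim = sh), voxel_size = abs(hdr$pixdim[2:4]))
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D numeric/integer/logical array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size numeric length-3, stored in `pixdim`.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; `"auto"` picks uint8 for logical/0-1 data, int32 for other
#'   integers, float64 otherwise.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1), datatype = "auto") {
  if (length(dim(data)) != 3L) ws_stop("only 3D volumes supported", "io")
  if (identical(datatype, "auto")) {
    datatype <- if (is.logical(data) ||
                    (is.numeric(data) && all(data %in% c(0, 1)))) "uint8"
      else if (is.integer(data) || isTRUE(all(data == round(data)))) "int32"
      else "float64"
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 ws_stop(sprintf("unknown datatype '%s'", datatype), "parameter"))
  dt <- NIFTI_DTYPES[[as.character(code)]]
  sh <- dim(data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x, size) writeBin(as.numeric(x), con, size = size, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36L), con)                       # data_type..dim_info
  wi(c(3L, sh, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wd(c(0, 0, 0), 4)                             # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(code, 2)                                   # datatype
  wi(dt$bitpix, 2)                              # bitpix
  wi(0L, 2)                                     # slice_start
  wd(c(1, voxel_size, 1, 1, 1, 1), 4)           # pixdim[8] (qfac 1)
  wd(352, 4)                                    # vox_offset
  wd(c(0, 0), 4)                                # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1L), con); writeBin(raw(1L), con)  # slice_end/code/xyzt
  wd(c(0, 0), 4)                                # cal_max, cal_min
  wd(c(0, 0), 4)                                # slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80L), con)                       # descrip
  writeBin(raw(24L), con)                       # aux_file
  wi(c(0L, 0L), 2)                              # qform_code, sform_code
  wd(rep(0, 6), 4)                              # quatern b,c,d + offsets x,y,z
  wd(rep(0, 12), 4)                             # srow_x/y/z
  writeBin(raw(16L), con)                       # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)    # magic
  writeBin(raw(4L), con)                        # extension flag
  vals <- if (is.logical(data)) as.integer(data) else as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
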