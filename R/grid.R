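#' Construct a voxel grid
#'
#' A `voxel_grid` is the shared discrete geometry every mask in a catalogue
#' must agree on: the array shape (planes, rows, columns), the physical voxel
#' size in micrometres per axis, and a real-space origin. Two grids are
#' *compatible* when their shapes and voxel sizes are equal elementwise;
#' all set operations in the package require compatible grids.
#'
#' Volumes are stored and indexed `(plane, row, column)`. In R the first
#' index varies fastest, and the NIfTI writer preserves that order, so
#' external viewers can reorient using the manifest metadata.
#'
#' @param shape integer vector of length 3, all entries >= 1.
#' @param voxel_size_um positive numeric vector of length 3 (micrometres
#'   per axis); anisotropic voxels are supported.
#' @param origin_um numeric vector of length 3, real-space origin.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(32, 48, 32), voxel_size_um = c(10, 10, 10))
#' voxel_volume_um3(g)  # 1000
#' @export
voxel_grid <- function(shape, voxel_size_um = c(1, 1, 1), origin_um = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size_um <- as.numeric(voxel_size_um)
  origin_um <- as.numeric(origin_um)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    ws_stop("'shape' must be three integers >= 1", "config")
  if (length(voxel_size_um) != 3L || anyNA(voxel_size_um) || any(voxel_size_um <= 0))
    ws_stop("'voxel_size_um' must be three positive reals", "config")
  if (length(origin_um) != 3L || anyNA(origin_um))
    ws_stop("'origin_um' must be three reals", "config")
  structure(
    list(shape = shape, voxel_size_um = voxel_size_um, origin_um = origin_um),
    class = "voxel_grid"
  )
}

#' Test whether two voxel grids are compatible
#'
#' @param a,b `voxel_grid` objects.
#' @return `TRUE` iff shapes and voxel sizes match elementwise.
#' @export
grids_compatible <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  identical(a$shape, b$shape) && isTRUE(all(a$voxel_size_um == b$voxel_size_um))
}

check_same_grid <- function(a, b, what = "operation") {
  if (!grids_compatible(a, b))
    ws_stop(sprintf("incompatible voxel grids in %s: (%s) vs (%s)",
                    what,
                    paste(a$shape, collapse = "x"),
                    paste(b$shape, collapse = "x")),
            "grid")
  invisible(TRUE)
}

#' Physical volume of one voxel
#'
#' @param grid a `voxel_grid`.
#' @return Voxel volume in cubic micrometres.
#' @export
voxel_volume_um3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$voxel_size_um)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s um/voxel\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$voxel_size_um), collapse = " x ")))
  invisible(x)
}

# classed conditions so callers/tests can discriminate failure modes
ws_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("wntscape_", class, "_error"),
                                     "wntscape_error")))
}

ws_warn <- function(msg) {
  warning(warningCondition(msg, class = "wntscape_warning"))
}
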