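# Small voxel-geometry helpers shared by the phantom generator and the
# occupancy machinery. All coordinates are 1-based (plane, row, column).

# linear index <-> (p, r, c) on a grid of dim `sh`
lin_index <- function(coords, sh) {
  coords[, 1L] + (coords[, 2L] - 1L) * sh[1L] +
    (coords[, 3L] - 1L) * sh[1L] * sh[2L]
}

# voxel coordinates of a Euclidean ball |v - centre| <= radius, clipped to grid
sphere_coords <- function(centre, radius, sh) {
  lo <- pmax(1L, as.integer(floor(centre - radius)))
  hi <- pmin(sh, as.integer(ceiling(centre + radius)))
  if (any(lo > hi)) return(matrix(integer(0), ncol = 3))
  g <- as.matrix(expand.grid(p = lo[1]:hi[1], r = lo[2]:hi[2], c = lo[3]:hi[3]))
  d2 <- (g[, 1] - centre[1])^2 + (g[, 2] - centre[2])^2 + (g[, 3] - centre[3])^2
  g[d2 <= radius^2 + 1e-9, , drop = FALSE]
}

# stamp a sphere into a logical array, returning the modified array
stamp_sphere <- function(mask, centre, radius) {
  co <- sphere_coords(centre, radius, dim(mask))
  if (nrow(co)) mask[lin_index(co, dim(mask))] <- TRUE
  mask
}

# relative offsets for 6/18/26 neighbourhoods
connectivity_offsets <- function(connectivity = c(26L, 18L, 6L)) {
  connectivity <- as.integer(connectivity[1])
  if (!connectivity %in% c(6L, 18L, 26L))
    ws_stop("connectivity must be 6, 18 or 26", "parameter")
  g <- as.matrix(expand.grid(dp = -1:1, dr = -1:1, dc = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

# Morphological dilation of a logical array by a Euclidean ball of integer
# radius. radius 0 is the identity.
dilate_mask <- function(mask, radius) {
  radius <- as.integer(radius)
  if (radius < 0L) ws_stop("dilation radius must be >= 0", "parameter")
  if (radius == 0L || !any(mask)) return(mask)
  sh <- dim(mask)
  offs <- as.matrix(expand.grid(dp = -radius:radius, dr = -radius:radius,
                                dc = -radius:radius))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  co <- which(mask, arr.ind = TRUE)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[i, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= sh[1] &
          nb[, 2] >= 1L & nb[, 2] <= sh[2] &
          nb[, 3] >= 1L & nb[, 3] <= sh[3]
    if (any(ok)) out[lin_index(nb[ok, , drop = FALSE], sh)] <- TRUE
  }
  out
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
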