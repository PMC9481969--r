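# Fixtures and independent per-voxel oracles.
#
# Every oracle here is a deliberately naive triple loop (or per-voxel
# tally) over the raw arrays, kept free of the package's vectorised code
# paths so it can serve as an independent check.

# explicit triple-loop voxel count
oracle_count <- function(mask) {
  n <- 0L
  d <- dim(mask)
  for (p in seq_len(d[1])) for (r in seq_len(d[2])) for (cc in seq_len(d[3]))
    if (mask[p, r, cc]) n <- n + 1L
  n
}

oracle_intersection <- function(a, b) {
  n <- 0L
  d <- dim(a)
  for (p in seq_len(d[1])) for (r in seq_len(d[2])) for (cc in seq_len(d[3]))
    if (a[p, r, cc] && b[p, r, cc]) n <- n + 1L
  n
}

oracle_jaccard <- function(a, b) {
  i <- oracle_intersection(a, b)
  u <- oracle_count(a) + oracle_count(b) - i
  if (u == 0) 0 else i / u
}

# per-voxel occupancy tally over a list of masks
oracle_occupancy <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(0L, dim = d)
  for (p in seq_len(d[1])) for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    s <- 0L
    for (m in masks) if (m[p, r, cc]) s <- s + 1L
    out[p, r, cc] <- s
  }
  out
}

# per-voxel presence-pattern tally inside an embryo mask
oracle_combination_counts <- function(masks, embryo) {
  d <- dim(embryo)
  counts <- list()
  for (p in seq_len(d[1])) for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    if (!embryo[p, r, cc]) next
    key <- paste(vapply(masks, function(m) m[p, r, cc], logical(1)),
                 collapse = "")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random catalogue on a small grid: blobby domains (union of 1-3 random
# spheres plus scattered voxels) inside a random ellipsoidal embryo mask.
# Some domains may come out empty, which is legal.
random_catalog <- function(seed, shape = c(8L, 8L, 8L), n_genes = 6L,
                           voxel_size = c(2, 2, 2), with_anatomy = FALSE) {
  set.seed(seed)
  grid <- wntscape::voxel_grid(shape, voxel_size)
  embryo <- wntscape::make_embryo_mask(grid, seed = seed)
  doms <- lapply(seq_len(n_genes), function(i) {
    m <- array(stats::runif(prod(shape)) < stats::runif(1, 0, 0.35), dim = shape)
    m <- m & embryo$mask
    wntscape::binary_domain(m, grid, label = sprintf("g%02d", i), family = "Wnt",
                            stage = "E10.5")
  })
  anatomy <- NULL
  anames <- NULL
  if (with_anatomy) {
    anatomy <- array(sample(0:3, prod(shape), replace = TRUE), dim = shape)
    anames <- data.frame(value = 1:3, name = c("head", "trunk", "tail"))
  }
  wntscape::domain_catalog(doms, embryo, anatomy = anatomy, anatomy_names = anames)
}
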