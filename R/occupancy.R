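#' Per-voxel occupancy map of a gene family
#'
#' The occupancy of a voxel is the number of family members whose mapped
#' expression domain includes that voxel: one gene mapping to a voxel is
#' occupancy level 1, two genes level 2, and so on. The map is the voxelwise
#' sum of the filtered binary masks, so total occupancy is conserved:
#' `sum(counts)` equals the summed domain volumes.
#'
#' @param catalog a [domain_catalog()].
#' @param family,stage optional filters (see [filter_domains()]).
#' @return An `occupancy_map`: `grid`, integer `counts` array, `family`,
#'   `stage`, `n_genes`, and the contributing `labels`.
#' @export
occupancy_map <- function(catalog, family = NULL, stage = NULL) {
  doms <- filter_domains(catalog, family, stage)
  counts <- array(0L, dim = catalog$grid$shape)
  for (d in doms) counts <- counts + d$mask
  structure(
    list(grid = catalog$grid, counts = counts,
         family = if (is.null(family)) "all" else paste(family, collapse = "+"),
         stage = if (is.null(stage)) "all" else paste(stage, collapse = "+"),
         n_genes = length(doms),
         labels = vapply(doms, `[[`, character(1), "label")),
    class = "occupancy_map"
  )
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %s/%s: %d genes, max occupancy %d\n",
              x$family, x$stage, x$n_genes, max(x$counts)))
  invisible(x)
}

# Label the connected components of a set of candidate voxels (linear
# indices) under 6/18/26 connectivity. Returns an integer membership vector
# parallel to idx (components numbered arbitrarily).
label_components <- function(idx, sh, connectivity = 26L) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  offs <- connectivity_offsets(connectivity)
  co <- arrayInd(idx, sh)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[k, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= sh[1] &
          nb[, 2] >= 1L & nb[, 2] <= sh[2] &
          nb[, 3] >= 1L & nb[, 3] <= sh[3]
    j <- match(lin_index(nb[ok, , drop = FALSE], sh), idx)
    i <- which(ok)[!is.na(j)]
    j <- j[!is.na(j)]
    keep <- i < j                      # each undirected edge once
    edges[[k]] <- rbind(i[keep], j[keep])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(em)) g <- igraph::add_edges(g, as.vector(em))
  igraph::components(g)$membership
}

#' Threshold an occupancy map into regions of high occupancy (ROHOs)
#'
#' Thresholds the occupancy image at `counts >= t` and splits the result
#' into connected components. Components smaller than `min_voxels` are
#' discarded as noise. Region ids are assigned deterministically: decreasing
#' voxel count, ties broken by the lexicographically smallest bounding-box
#' origin.
#'
#' @param occ an [occupancy_map()].
#' @param t integer occupancy threshold (>= 1, <= number of genes summed).
#'   Family/stage defaults used in the reference analysis: Wnt 5 at E9.5 and
#'   E11.5, 4 at E10.5; Fzd 4 at all stages (see [roho_threshold()]).
#' @param connectivity 6, 18 or 26 (default 26, vertex connectivity).
#' @param min_voxels minimum component size retained (default 5).
#' @return A `roho_regions` object: integer `labels` array (0 background),
#'   a `regions` data.frame (id, voxels, volume_um3, peak_occupancy,
#'   centroid_p/r/c, bbox bounds), and the thresholding parameters.
#' @export
threshold_regions <- function(occ, t, connectivity = 26L, min_voxels = 5L) {
  stopifnot(inherits(occ, "occupancy_map"))
  t <- as.integer(t)
  if (t < 1L) ws_stop("threshold t must be >= 1", "threshold")
  if (t > occ$n_genes)
    ws_stop(sprintf("threshold t = %d exceeds the %d genes summed", t, occ$n_genes),
            "threshold")
  min_voxels <- max(1L, as.integer(min_voxels))
  sh <- occ$grid$shape
  idx <- which(occ$counts >= t)
  memb <- label_components(idx, sh, connectivity)
  labels <- array(0L, dim = sh)
  regions <- data.frame()
  if (length(idx)) {
    sizes <- tabulate(memb)
    keep_comp <- which(sizes >= min_voxels)
    if (length(keep_comp)) {
      co <- arrayInd(idx, sh)
      stats <- lapply(keep_comp, function(cmp) {
        sel <- memb == cmp
        cc <- co[sel, , drop = FALSE]
        list(size = sum(sel),
             origin = c(min(cc[, 1]), min(cc[, 2]), min(cc[, 3])),
             bbox_hi = c(max(cc[, 1]), max(cc[, 2]), max(cc[, 3])),
             centroid = colMeans(cc),
             peak = max(occ$counts[idx[sel]]),
             voxel_idx = idx[sel])
      })
      size_v <- vapply(stats, `[[`, numeric(1), "size")
      orig_m <- t(vapply(stats, `[[`, numeric(3), "origin"))
      ord <- order(-size_v, orig_m[, 1], orig_m[, 2], orig_m[, 3])
      stats <- stats[ord]
      for (r in seq_along(stats)) labels[stats[[r]]$voxel_idx] <- r
      regions <- data.frame(
        id = seq_along(stats),
        voxels = vapply(stats, `[[`, numeric(1), "size"),
        volume_um3 = vapply(stats, `[[`, numeric(1), "size") *
          voxel_volume_um3(occ$grid),
        peak_occupancy = vapply(stats, `[[`, numeric(1), "peak"),
        centroid_p = vapply(stats, function(s) s$centroid[1], numeric(1)),
        centroid_r = vapply(stats, function(s) s$centroid[2], numeric(1)),
        centroid_c = vapply(stats, function(s) s$centroid[3], numeric(1)),
        bbox_p0 = vapply(stats, function(s) s$origin[1], numeric(1)),
        bbox_r0 = vapply(stats, function(s) s$origin[2], numeric(1)),
        bbox_c0 = vapply(stats, function(s) s$origin[3], numeric(1)),
        bbox_p1 = vapply(stats, function(s) s$bbox_hi[1], numeric(1)),
        bbox_r1 = vapply(stats, function(s) s$bbox_hi[2], numeric(1)),
        bbox_c1 = vapply(stats, function(s) s$bbox_hi[3], numeric(1))
      )
    }
  }
  structure(
    list(labels = labels, regions = regions, threshold = t,
         connectivity = as.integer(connectivity), min_voxels = min_voxels,
         grid = occ$grid, family = occ$family, stage = occ$stage),
    class = "roho_regions"
  )
}

#' @export
print.roho_regions <- function(x, ...) {
  cat(sprintf("<roho_regions> %s/%s: %d regions at occupancy >= %d (conn %d, min %d vox)\n",
              x$family, x$stage, nrow(x$regions), x$threshold,
              x$connectivity, x$min_voxels))
  invisible(x)
}

#' Default ROHO occupancy thresholds
#'
#' The thresholds used in the reference Wnt/Fzd analysis: five or more Wnts
#' at E9.5 and E11.5, four or more at E10.5; four or more Fzds at every
#' stage. Unknown family/stage combinations fall back to `default`.
#'
#' @param family gene family name.
#' @param stage developmental stage.
#' @param default fallback threshold.
#' @return Integer threshold.
#' @export
roho_threshold <- function(family, stage, default = 4L) {
  if (identical(family, "Wnt"))
    return(switch(stage, E9.5 = 5L, E10.5 = 4L, E11.5 = 5L, default))
  if (identical(family, "Fzd")) return(4L)
  as.integer(default)
}

#' Gene sets and overlap statistics of detected regions
#'
#' For each labelled region, a gene belongs to the region's *gene set* iff
#' its expression domain intersects any voxel of the region. Overlap voxel
#' counts per gene are reported alongside.
#'
#' @param regions a [threshold_regions()] result.
#' @param catalog the [domain_catalog()] the occupancy map came from.
#' @param family,stage filters selecting the domains to test; default the
#'   tags carried by `regions` (pass `NULL` explicitly to test all domains,
#'   e.g. to ask which reporter or partner-family domains hit a region).
#' @return A list of `roho_record`s, one per region, each holding the region
#'   row plus `gene_set` (sorted labels) and `gene_overlap_voxels` (named
#'   integer vector over all tested genes).
#' @export
roho_gene_sets <- function(regions, catalog,
                           family = if (regions$family %in% c("all")) NULL else regions$family,
                           stage = if (regions$stage %in% c("all")) NULL else regions$stage) {
  stopifnot(inherits(regions, "roho_regions"), inherits(catalog, "domain_catalog"))
  check_same_grid(regions$grid, catalog$grid, "roho_gene_sets")
  doms <- filter_domains(catalog, family, stage)
  n_reg <- nrow(regions$regions)
  overlaps <- vapply(doms, function(d) {
    hit <- regions$labels[d$mask]
    tabulate(hit[hit > 0L], nbins = n_reg)
  }, integer(n_reg))
  if (n_reg == 1L) overlaps <- matrix(overlaps, nrow = 1L,
                                      dimnames = list(NULL, names(doms)))
  lapply(seq_len(n_reg), function(r) {
    ov <- overlaps[r, ]
    names(ov) <- vapply(doms, `[[`, character(1), "label")
    structure(
      list(id = regions$regions$id[r],
           family = regions$family, stage = regions$stage,
           threshold = regions$threshold,
           voxel_count = regions$regions$voxels[r],
           volume_um3 = regions$regions$volume_um3[r],
           peak_occupancy = regions$regions$peak_occupancy[r],
           centroid = unlist(regions$regions[r, c("centroid_p", "centroid_r", "centroid_c")]),
           bounding_box = unlist(regions$regions[r, c("bbox_p0", "bbox_r0", "bbox_c0",
                                                      "bbox_p1", "bbox_r1", "bbox_c1")]),
           gene_set = sort(names(ov)[ov >= 1L]),
           gene_overlap_voxels = ov),
      class = "roho_record")
  })
}

#' @export
print.roho_record <- function(x, ...) {
  cat(sprintf("<roho_record> #%d %s/%s: %d voxels, peak %d, gene set {%s}\n",
              x$id, x$family, x$stage, x$voxel_count, x$peak_occupancy,
              paste(x$gene_set, collapse = ", ")))
  invisible(x)
}

#' Occupancy peaks
#'
#' The sub-territory at a higher occupancy cut-off (reference analysis used
#' Wnt occupancy >= 7 and Fzd occupancy >= 6 for peaks). At `peak_t = 1` the
#' peak mask is just the union of all domains; peaks are nested:
#' `peaks(t + 1)` is a subset of `peaks(t)`.
#'
#' @param occ an [occupancy_map()].
#' @param peak_t integer cut-off >= 1.
#' @return A [binary_domain()] mask of voxels with `counts >= peak_t`.
#' @export
occupancy_peaks <- function(occ, peak_t) {
  stopifnot(inherits(occ, "occupancy_map"))
  peak_t <- as.integer(peak_t)
  if (peak_t < 1L) ws_stop("peak_t must be >= 1", "parameter")
  binary_domain(occ$counts >= peak_t, occ$grid,
                label = sprintf("%s_peaks_%d", occ$family, peak_t),
                family = "other", stage = occ$stage)
}

#' Unique single-gene expression territories
#'
#' The unique domain of gene g is the part of its expression territory where
#' no other family member is detected: `domain_g & (occupancy == 1)`. The
#' contribution table reports, per gene, the share of the combined
#' single-gene territory it accounts for and the share of the gene's own
#' domain that is unique -- the two percentages quoted for dominant
#' contributors in the reference analysis.
#'
#' @param catalog a [domain_catalog()].
#' @param family,stage filters; at least two domains must remain.
#' @return A list with `domains` (named list of unique-territory
#'   [binary_domain()]s), `table` (data.frame: label, unique_voxels,
#'   frac_of_single_domain, frac_of_gene_domain) and `single_domain_voxels`
#'   (total occupancy-1 volume).
#' @export
unique_gene_domains <- function(catalog, family = NULL, stage = NULL) {
  doms <- filter_domains(catalog, family, stage)
  if (length(doms) < 2L)
    ws_stop("unique-gene analysis needs at least two domains in the family", "selection")
  occ <- occupancy_map(catalog, family, stage)
  occ1 <- occ$counts == 1L
  total1 <- sum(occ1)
  uniq <- lapply(doms, function(d) {
    binary_domain(d$mask & occ1, catalog$grid,
                  label = paste0(d$label, "_unique"),
                  family = d$family, stage = d$stage)
  })
  uv <- vapply(uniq, function(u) sum(u$mask), numeric(1))
  gv <- vapply(doms, function(d) sum(d$mask), numeric(1))
  tab <- data.frame(
    label = vapply(doms, `[[`, character(1), "label"),
    unique_voxels = as.integer(uv),
    gene_voxels = as.integer(gv),
    frac_of_single_domain = if (total1 > 0) uv / total1 else rep(0, length(uv)),
    frac_of_gene_domain = ifelse(gv > 0, uv / gv, 0),
    row.names = NULL
  )
  list(domains = uniq, table = tab, single_domain_voxels = as.integer(total1))
}

#' Zero-expression territory of a family
#'
#' Embryo-foreground voxels where no member of the filtered family is
#' detected: `embryo_mask & (occupancy == 0)`.
#'
#' @param catalog a [domain_catalog()] with an embryo mask.
#' @param family,stage filters.
#' @return A [binary_domain()].
#' @export
zero_expression_domain <- function(catalog, family = NULL, stage = NULL) {
  occ <- occupancy_map(catalog, family, stage)
  binary_domain(catalog$embryo_mask$mask & occ$counts == 0L, catalog$grid,
                label = sprintf("zero_%s", occ$family),
                family = "other", stage = occ$stage)
}

#' Voxelwise set algebra over domains
#'
#' @param domains list of [binary_domain()]s on one grid. For
#'   `op = "subtract"` the first element is the minuend and all remaining
#'   elements are subtracted from it.
#' @param op `"union"`, `"intersection"` or `"subtract"`.
#' @param label label for the result.
#' @return A [binary_domain()].
#' @export
combine_domains <- function(domains, op = c("union", "intersection", "subtract"),
                            label = NULL) {
  op <- match.arg(op)
  if (length(domains) < 1L) ws_stop("need at least one domain", "parameter")
  grid <- domains[[1]]$grid
  for (d in domains[-1]) check_same_grid(grid, d$grid, "combine_domains")
  masks <- lapply(domains, `[[`, "mask")
  out <- switch(op,
    union = Reduce(`|`, masks),
    intersection = Reduce(`&`, masks),
    subtract = if (length(masks) == 1L) masks[[1]]
               else masks[[1]] & !Reduce(`|`, masks[-1]))
  if (is.null(label))
    label <- paste0(op, "(", paste(vapply(domains, `[[`, character(1), "label"),
                                   collapse = ","), ")")
  binary_domain(out, grid, label = label, family = "other",
                stage = domains[[1]]$stage)
}
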