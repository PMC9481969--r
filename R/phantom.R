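# Synthetic embryo phantoms.
#
# The generator emulates the structure of an integrated per-stage atlas:
# one ellipsoidal embryo foreground, K localized multi-gene hotspots shared
# by several family members (so thresholding the family occupancy map
# recovers them), per-gene private territories, optional speckle noise, an
# exact-Jaccard paralogue pair constructor, and a reporter domain built
# from a subset of hotspots. Euclidean balls in voxel units are the domain
# primitive; anisotropy is ignored during generation.

#' Configuration for a synthetic embryo catalogue
#'
#' Defaults state a catalogue shaped like the integrated Wnt/Fzd atlas at
#' one stage: 19 Wnt-like and 10 Fzd-like genes on a 32 x 48 x 32 grid of
#' 10 um voxels, 4 hotspots each shared by 5 genes per family, 2 private
#' blobs per gene, and no speckle noise.
#'
#' With `strict_recovery = TRUE` (the default) every planted sphere --
#' hotspot or private, any gene -- is pairwise disjoint from every other
#' and fully inside the embryo mask, and the separation inequality
#' `min_hotspot_separation_vox > 2 * (hotspot_radius_vox + private_radius_vox)`
#' is asserted. This guarantees the planted hotspots map to exactly K
#' disjoint connected occupancy components, so detection can be validated
#' against ground truth.
#'
#' @param grid a [voxel_grid()].
#' @param n_genes_per_family named integer vector, family -> gene count.
#' @param n_hotspots number of planted multi-gene hotspots (K >= 0).
#' @param hotspot_radius_vox hotspot sphere radius in voxels.
#' @param min_hotspot_separation_vox minimum centre-to-centre hotspot
#'   distance.
#' @param genes_per_hotspot genes from each family assigned to each hotspot
#'   (integer, or `"all"`).
#' @param n_private_blobs private spheres per gene.
#' @param private_radius_vox private sphere radius.
#' @param speckle_rate probability in `[0, 1)` of flipping each
#'   embryo-foreground voxel of each gene mask (models binarization noise);
#'   default 0.
#' @param stage stage tag applied to all generated domains.
#' @param strict_recovery enforce the disjoint-sphere geometry above.
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid = voxel_grid(c(32L, 48L, 32L), c(10, 10, 10)),
                           n_genes_per_family = c(Wnt = 19L, Fzd = 10L),
                           n_hotspots = 4L,
                           hotspot_radius_vox = 3,
                           min_hotspot_separation_vox = 12,
                           genes_per_hotspot = 5L,
                           n_private_blobs = 2L,
                           private_radius_vox = 2,
                           speckle_rate = 0,
                           stage = "E10.5",
                           strict_recovery = TRUE,
                           seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(names(n_genes_per_family)) || any(n_genes_per_family < 1))
    ws_stop("n_genes_per_family must be a named vector of positive counts", "config")
  if (n_hotspots < 0) ws_stop("n_hotspots must be >= 0", "config")
  if (speckle_rate < 0 || speckle_rate >= 1)
    ws_stop("speckle_rate must be in [0, 1)", "config")
  if (!identical(genes_per_hotspot, "all")) {
    genes_per_hotspot <- as.integer(genes_per_hotspot)
    if (any(genes_per_hotspot > min(n_genes_per_family)))
      ws_stop("genes_per_hotspot exceeds the smallest family", "config")
  }
  if (strict_recovery && n_hotspots > 0 &&
      min_hotspot_separation_vox <= 2 * (hotspot_radius_vox + private_radius_vox))
    ws_stop(paste("strict_recovery requires min_hotspot_separation_vox >",
                  "2 * (hotspot_radius_vox + private_radius_vox)"), "config")
  structure(
    list(grid = grid, n_genes_per_family = n_genes_per_family,
         n_hotspots = as.integer(n_hotspots),
         hotspot_radius_vox = hotspot_radius_vox,
         min_hotspot_separation_vox = min_hotspot_separation_vox,
         genes_per_hotspot = genes_per_hotspot,
         n_private_blobs = as.integer(n_private_blobs),
         private_radius_vox = private_radius_vox,
         speckle_rate = speckle_rate, stage = stage,
         strict_recovery = isTRUE(strict_recovery), seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Synthetic embryo foreground mask
#'
#' A filled ellipsoid centred on the grid with per-axis semi-axes drawn
#' (deterministically from `seed`) between 40% and 47.5% of each extent,
#' giving a single 26-connected component filling 20-60% of the grid.
#'
#' @param grid a [voxel_grid()] with at least 4 voxels per axis.
#' @param seed integer seed.
#' @return A [binary_domain()] labelled `"embryo"`.
#' @export
make_embryo_mask <- function(grid, seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (any(grid$shape < 4L))
    ws_stop("grid too small for an embryo mask (need >= 4 voxels per axis)", "config")
  sh <- grid$shape
  alpha <- with_seed(seed, stats::runif(3, 0.80, 0.95))  # full-axis fractions
  centre <- (sh + 1) / 2
  semi <- alpha * sh / 2
  p <- slice.index(array(0L, sh), 1L)
  r <- slice.index(array(0L, sh), 2L)
  cc <- slice.index(array(0L, sh), 3L)
  mask <- ((p - centre[1]) / semi[1])^2 + ((r - centre[2]) / semi[2])^2 +
    ((cc - centre[3]) / semi[3])^2 <= 1
  binary_domain(mask, grid, label = "embryo", family = "other", stage = "all")
}

# squared distances from point x to rows of matrix m
dist2_to <- function(x, m) {
  if (!nrow(m)) return(numeric(0))
  (m[, 1] - x[1])^2 + (m[, 2] - x[2])^2 + (m[, 3] - x[3])^2
}

# Rejection-sample a sphere centre inside `inside_idx` (linear indices of
# allowed centres) subject to minimum distances from previously placed
# spheres. Returns the centre or NULL after `budget` tries.
place_sphere <- function(inside_coords, radius, placed_centres, placed_radii,
                         min_gap, sh, embryo, budget = 1000L) {
  for (try in seq_len(budget)) {
    i <- sample.int(nrow(inside_coords), 1L)
    ctr <- inside_coords[i, ]
    if (nrow(placed_centres) && is.finite(min_gap)) {
      d2 <- dist2_to(ctr, placed_centres)
      if (any(d2 < (placed_radii + min_gap)^2)) next
    }
    co <- sphere_coords(ctr, radius, sh)
    if (!all(embryo[lin_index(co, sh)])) next  # sphere must fit inside foreground
    return(list(centre = ctr, coords = co))
  }
  NULL
}

#' Generate a synthetic domain catalogue with known ground truth
#'
#' Plants `n_hotspots` sphere centres inside the embryo mask at the
#' configured separation (rejection sampling, 1000 tries per sphere), then
#' builds each gene's mask as the union of the hotspot spheres it is
#' assigned to, its private spheres, and optional speckle flips, all
#' clipped to the embryo mask. Returns the catalogue together with a
#' `phantom_truth` record of everything planted.
#'
#' Under `strict_recovery` all spheres are pairwise disjoint, so per-gene
#' planted volumes equal measured volumes, family occupancy at each hotspot
#' centre equals the number of genes assigned there, and thresholding at
#' `t = genes_per_hotspot` recovers exactly the planted hotspots.
#'
#' @param config a [phantom_config()].
#' @return A list with `catalog` ([domain_catalog()]) and `truth`
#'   (`phantom_truth`: `hotspot_centers` matrix, `hotspot_radius_vox`,
#'   `assignments` data.frame (hotspot, family, label), `hotspot_gene_sets`
#'   per-hotspot label list, `planted_volumes` named per-gene voxel counts,
#'   `config` echo).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  sh <- grid$shape
  embryo <- make_embryo_mask(grid, seed = config$seed)
  with_seed(config$seed + 1L, {
    emb_coords <- which(embryo$mask, arr.ind = TRUE)
    placed_centres <- matrix(numeric(0), ncol = 3)
    placed_radii <- numeric(0)

    # hotspot centres: pairwise separation is always enforced
    hot <- vector("list", config$n_hotspots)
    for (k in seq_len(config$n_hotspots)) {
      res <- NULL
      for (try in seq_len(1000L)) {
        i <- sample.int(nrow(emb_coords), 1L)
        ctr <- emb_coords[i, ]
        if (k > 1L) {
          prev <- do.call(rbind, lapply(hot[seq_len(k - 1L)], `[[`, "centre"))
          if (any(dist2_to(ctr, prev) < config$min_hotspot_separation_vox^2)) next
        }
        co <- sphere_coords(ctr, config$hotspot_radius_vox, sh)
        if (config$strict_recovery && !all(embryo$mask[lin_index(co, sh)])) next
        res <- list(centre = ctr, coords = co)
        break
      }
      if (is.null(res))
        ws_stop(sprintf("could not place hotspot %d of %d at separation %.3g (placed %d)",
                        k, config$n_hotspots, config$min_hotspot_separation_vox, k - 1L),
                "placement")
      hot[[k]] <- res
      placed_centres <- rbind(placed_centres, res$centre)
      placed_radii <- c(placed_radii, config$hotspot_radius_vox)
    }

    # gene labels and hotspot assignments, in label order per family
    families <- names(config$n_genes_per_family)
    labels <- unlist(lapply(families, function(f)
      sprintf("%s%02d", f, seq_len(config$n_genes_per_family[[f]]))))
    fam_of <- rep(families, config$n_genes_per_family)
    assignments <- data.frame(hotspot = integer(0), family = character(0),
                              label = character(0))
    gph <- config$genes_per_hotspot
    for (k in seq_len(config$n_hotspots)) {
      for (f in families) {
        fam_labels <- labels[fam_of == f]
        chosen <- if (identical(gph, "all")) fam_labels
          else sort(sample(fam_labels, gph[1L + (k - 1L) %% length(gph)]))
        assignments <- rbind(assignments,
                             data.frame(hotspot = k, family = f, label = chosen))
      }
    }

    # per-gene masks: assigned hotspot spheres + private spheres (+ speckle)
    domains <- vector("list", length(labels))
    planted <- setNames(integer(length(labels)), labels)
    for (gi in seq_along(labels)) {
      lab <- labels[gi]
      mask <- array(FALSE, dim = sh)
      vol <- 0L
      for (k in assignments$hotspot[assignments$label == lab]) {
        co <- hot[[k]]$coords
        mask[lin_index(co, sh)] <- TRUE
        vol <- vol + nrow(co)
      }
      for (b in seq_len(config$n_private_blobs)) {
        res <- place_sphere(emb_coords, config$private_radius_vox,
                            placed_centres, placed_radii,
                            min_gap = if (config$strict_recovery)
                              config$private_radius_vox + 1e-9 else -Inf,
                            sh = sh, embryo = if (config$strict_recovery)
                              embryo$mask else array(TRUE, sh))
        if (is.null(res))
          ws_stop(sprintf("could not place private blob %d for gene %s", b, lab),
                  "placement")
        mask[lin_index(res$coords, sh)] <- TRUE
        vol <- vol + nrow(res$coords)
        if (config$strict_recovery) {
          placed_centres <- rbind(placed_centres, res$centre)
          placed_radii <- c(placed_radii, config$private_radius_vox)
        }
      }
      if (config$speckle_rate > 0) {
        flips <- stats::runif(nrow(emb_coords)) < config$speckle_rate
        idx <- lin_index(emb_coords[flips, , drop = FALSE], sh)
        mask[idx] <- !mask[idx]
      }
      mask <- mask & embryo$mask
      domains[[gi]] <- binary_domain(mask, grid, label = lab,
                                     family = fam_of[gi], stage = config$stage)
      planted[gi] <- vol
    }

    hotspot_gene_sets <- lapply(seq_len(config$n_hotspots), function(k)
      sort(assignments$label[assignments$hotspot == k]))

    truth <- structure(
      list(hotspot_centers = if (config$n_hotspots)
             do.call(rbind, lapply(hot, `[[`, "centre"))
           else matrix(numeric(0), ncol = 3),
           hotspot_radius_vox = config$hotspot_radius_vox,
           assignments = assignments,
           hotspot_gene_sets = hotspot_gene_sets,
           planted_volumes = planted,
           config = config),
      class = "phantom_truth")
    list(catalog = domain_catalog(domains, embryo), truth = truth)
  })
}

#' Gene set planted at each hotspot, restricted to one family
#'
#' @param truth a `phantom_truth` from [generate_catalog()].
#' @param family family name.
#' @return List (one per hotspot) of sorted gene labels of that family.
#' @export
hotspot_gene_sets <- function(truth, family) {
  stopifnot(inherits(truth, "phantom_truth"))
  a <- truth$assignments
  lapply(seq_len(nrow(truth$hotspot_centers)), function(k)
    sort(a$label[a$hotspot == k & a$family == family]))
}

#' Construct a paralogue pair with an exact Jaccard index
#'
#' Draws three pairwise-disjoint voxel sets of exactly `core_vox`,
#' `private_a_vox` and `private_b_vox` voxels from the embryo foreground
#' and returns masks A = core + private A and B = core + private B, so that
#' JI(A, B) = core / (core + private_a + private_b) holds exactly by
#' construction.
#'
#' @param core_vox,private_a_vox,private_b_vox non-negative voxel counts.
#' @param embryo_mask a [binary_domain()] foreground with enough room.
#' @param seed integer seed.
#' @param labels length-2 character vector of gene labels.
#' @param family,stage metadata for the two domains.
#' @return A list of two [binary_domain()]s `a` and `b`.
#' @export
generate_paralogue_pair <- function(core_vox, private_a_vox, private_b_vox,
                                    embryo_mask, seed = 1L,
                                    labels = c("paralog_a", "paralog_b"),
                                    family = "Wnt", stage = "E10.5") {
  stopifnot(inherits(embryo_mask, "binary_domain"))
  core_vox <- as.integer(core_vox)
  private_a_vox <- as.integer(private_a_vox)
  private_b_vox <- as.integer(private_b_vox)
  if (core_vox < 0L || private_a_vox < 0L || private_b_vox < 0L)
    ws_stop("voxel counts must be >= 0", "parameter")
  need <- core_vox + private_a_vox + private_b_vox
  pool <- which(embryo_mask$mask)
  if (need > length(pool))
    ws_stop(sprintf("embryo mask has %d voxels; %d required", length(pool), need),
            "placement")
  picked <- with_seed(seed, sample(pool, need))
  sh <- embryo_mask$grid$shape
  mk <- function(idx, lab) {
    m <- array(FALSE, dim = sh)
    m[idx] <- TRUE
    binary_domain(m, embryo_mask$grid, label = lab, family = family, stage = stage)
  }
  core <- picked[seq_len(core_vox)]
  pa <- picked[core_vox + seq_len(private_a_vox)]
  pb <- picked[core_vox + private_a_vox + seq_len(private_b_vox)]
  list(a = mk(c(core, pa), labels[1]), b = mk(c(core, pb), labels[2]))
}

#' Synthetic reporter domain from planted hotspots
#'
#' Emulates a pathway-activity read-out: the union of a subset of the
#' planted hotspot spheres, optionally dilated, clipped to the embryo mask.
#'
#' @param truth a `phantom_truth` from [generate_catalog()].
#' @param embryo_mask the catalogue's foreground [binary_domain()].
#' @param subset integer indices of hotspots to include (default all); an
#'   empty subset yields an empty reporter.
#' @param dilation_vox integer dilation radius (Euclidean ball), >= 0.
#' @return A [binary_domain()] with family `"reporter"`.
#' @export
generate_reporter <- function(truth, embryo_mask,
                              subset = seq_len(nrow(truth$hotspot_centers)),
                              dilation_vox = 0L) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(embryo_mask, "binary_domain"))
  n_hot <- nrow(truth$hotspot_centers)
  subset <- as.integer(subset)
  if (length(subset) && (any(subset < 1L) || any(subset > n_hot)))
    ws_stop(sprintf("hotspot subset indices must be in 1..%d", n_hot), "parameter")
  sh <- embryo_mask$grid$shape
  mask <- array(FALSE, dim = sh)
  for (k in subset)
    mask <- stamp_sphere(mask, truth$hotspot_centers[k, ], truth$hotspot_radius_vox)
  mask <- dilate_mask(mask, dilation_vox)
  binary_domain(mask & embryo_mask$mask, embryo_mask$grid,
                label = "reporter", family = "reporter",
                stage = truth$config$stage)
}
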