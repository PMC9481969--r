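test_that("occupancy map equals the per-voxel oracle and conserves volume", {
  for (seed in c(1, 2)) {
    ct <- random_catalog(seed, n_genes = 6L)
    occ <- occupancy_map(ct, "Wnt")
    masks <- lapply(ct$domains, `[[`, "mask")
    expect_identical(occ$counts, oracle_occupancy(masks))
    expect_equal(sum(occ$counts), sum(vapply(masks, sum, integer(1))))
    expect_true(all(occ$counts >= 0 & occ$counts <= occ$n_genes))
  }
  # three masks sharing one voxel count 3 there
  g <- voxel_grid(c(6, 6, 6))
  mk <- function(extra) {
    m <- array(FALSE, c(6, 6, 6)); m[3, 3, 3] <- TRUE; m[extra] <- TRUE; m
  }
  emb <- binary_domain(array(TRUE, c(6, 6, 6)), g, "embryo")
  ct3 <- domain_catalog(list(binary_domain(mk(1), g, "a", "Wnt"),
                             binary_domain(mk(2), g, "b", "Wnt"),
                             binary_domain(mk(4), g, "c", "Wnt")), emb)
  expect_equal(occupancy_map(ct3, "Wnt")$counts[3, 3, 3], 3L)
  # all-empty domains give an all-zero map
  ct0 <- domain_catalog(list(empty_domain(g, "a", "Wnt"),
                             empty_domain(g, "b", "Wnt")), emb)
  expect_true(all(occupancy_map(ct0, "Wnt")$counts == 0L))
  expect_error(occupancy_map(ct0, family = "Fzd"),
               class = "wntscape_selection_error")
})

test_that("threshold_regions separates plateaus and orders labels deterministically", {
  g <- voxel_grid(c(12, 12, 12))
  counts <- array(0L, c(12, 12, 12))
  counts[2:4, 2:4, 2:4] <- 3L        # 27 voxels
  counts[8:11, 8:11, 8:11] <- 3L     # 64 voxels
  occ <- structure(list(grid = g, counts = counts, family = "Wnt",
                        stage = "E10.5", n_genes = 5L, labels = letters[1:5]),
                   class = "occupancy_map")
  reg <- threshold_regions(occ, 3, min_voxels = 1)
  expect_equal(nrow(reg$regions), 2L)
  # larger component gets id 1
  expect_equal(reg$regions$voxels, c(64, 27))
  expect_equal(reg$regions$bbox_p0, c(8, 2))
  # every labelled voxel satisfies counts >= t
  expect_true(all(counts[reg$labels > 0] >= 3L))
  expect_true(all(reg$labels[counts < 3L] == 0L))
  # t above the maximum gives zero regions; t above n_genes errors
  expect_equal(nrow(threshold_regions(occ, 4, min_voxels = 1)$regions), 0L)
  expect_error(threshold_regions(occ, 6), class = "wntscape_threshold_error")
  # min_voxels filters small components
  counts2 <- counts; counts2[12, 1, 1] <- 3L
  occ2 <- occ; occ2$counts <- counts2
  expect_equal(nrow(threshold_regions(occ2, 3, min_voxels = 2)$regions), 2L)
  expect_equal(nrow(threshold_regions(occ2, 3, min_voxels = 1)$regions), 3L)
})

test_that("connectivity choice changes which diagonal touches merge", {
  g <- voxel_grid(c(6, 6, 6))
  counts <- array(0L, c(6, 6, 6))
  counts[2, 2, 2] <- 1L
  counts[3, 3, 3] <- 1L    # vertex-adjacent only
  occ <- structure(list(grid = g, counts = counts, family = "x", stage = "s",
                        n_genes = 1L, labels = "a"), class = "occupancy_map")
  expect_equal(nrow(threshold_regions(occ, 1, connectivity = 26, min_voxels = 1)$regions), 1L)
  expect_equal(nrow(threshold_regions(occ, 1, connectivity = 18, min_voxels = 1)$regions), 2L)
  counts[3, 3, 2] <- 1L    # edge-adjacent to both
  occ$counts <- counts
  expect_equal(nrow(threshold_regions(occ, 1, connectivity = 18, min_voxels = 1)$regions), 1L)
  expect_equal(nrow(threshold_regions(occ, 1, connectivity = 6, min_voxels = 1)$regions), 2L)
})

test_that("ROHO monotonicity: regions at t+1 nest inside regions at t", {
  ct <- random_catalog(8, n_genes = 8L)
  occ <- occupancy_map(ct, "Wnt")
  for (t in seq_len(max(max(occ$counts) - 1L, 1L))) {
    lo <- threshold_regions(occ, t, min_voxels = 1)
    hi <- threshold_regions(occ, t + 1L, min_voxels = 1)
    if (nrow(hi$regions) == 0) next
    for (id in hi$regions$id) {
      parents <- unique(lo$labels[hi$labels == id])
      expect_length(parents, 1L)
      expect_gt(parents, 0L)
    }
  }
})

test_that("gene sets follow the intersect-any-voxel rule", {
  g <- voxel_grid(c(10, 10, 10))
  emb <- binary_domain(array(TRUE, c(10, 10, 10)), g, "embryo")
  base <- array(FALSE, c(10, 10, 10)); base[4:6, 4:6, 4:6] <- TRUE
  # two genes build the region; a third touches it in exactly one voxel,
  # a fourth is disjoint
  touch <- array(FALSE, c(10, 10, 10)); touch[4, 4, 4] <- TRUE; touch[9, 9, 9] <- TRUE
  off <- array(FALSE, c(10, 10, 10)); off[1, 1, 1] <- TRUE
  ct <- domain_catalog(list(binary_domain(base, g, "core1", "Wnt"),
                            binary_domain(base, g, "core2", "Wnt"),
                            binary_domain(touch, g, "toucher", "Wnt"),
                            binary_domain(off, g, "absent", "Wnt")), emb)
  occ <- occupancy_map(ct, "Wnt")
  reg <- threshold_regions(occ, 2, min_voxels = 1)
  recs <- roho_gene_sets(reg, ct)
  expect_length(recs, 1L)
  expect_setequal(recs[[1]]$gene_set, c("core1", "core2", "toucher"))
  expect_equal(unname(recs[[1]]$gene_overlap_voxels["toucher"]), 1L)
  expect_equal(unname(recs[[1]]$gene_overlap_voxels["absent"]), 0L)
  expect_equal(recs[[1]]$peak_occupancy, 3)
  expect_gte(length(recs[[1]]$gene_set), reg$threshold)
})

test_that("occupancy peaks are nested threshold masks", {
  ct <- random_catalog(13, n_genes = 7L)
  occ <- occupancy_map(ct, "Wnt")
  p1 <- occupancy_peaks(occ, 1)
  union_all <- Reduce(`|`, lapply(ct$domains, `[[`, "mask"))
  expect_identical(p1$mask, union_all)
  expect_equal(sum(occupancy_peaks(occ, occ$n_genes + 3L)$mask), 0L)
  for (t in 1:6)
    expect_true(all(occupancy_peaks(occ, t + 1)$mask <= occupancy_peaks(occ, t)$mask))
})

test_that("unique-gene domains partition the single-occupancy territory", {
  ct <- random_catalog(17, n_genes = 6L)
  uq <- unique_gene_domains(ct, "Wnt")
  occ <- occupancy_map(ct, "Wnt")
  total1 <- sum(occ$counts == 1L)
  expect_equal(sum(uq$table$unique_voxels), total1)
  expect_equal(uq$single_domain_voxels, total1)
  # per-gene fractions are consistent
  expect_equal(uq$table$frac_of_single_domain,
               uq$table$unique_voxels / total1)
  expect_equal(uq$table$frac_of_gene_domain,
               ifelse(uq$table$gene_voxels > 0,
                      uq$table$unique_voxels / uq$table$gene_voxels, 0))
  # two identical domains have empty unique territories
  g <- voxel_grid(c(6, 6, 6))
  emb <- binary_domain(array(TRUE, c(6, 6, 6)), g, "embryo")
  m <- array(FALSE, c(6, 6, 6)); m[2:4, 2:4, 2:4] <- TRUE
  ct2 <- domain_catalog(list(binary_domain(m, g, "a", "Wnt"),
                             binary_domain(m, g, "b", "Wnt")), emb)
  uq2 <- unique_gene_domains(ct2, "Wnt")
  expect_true(all(uq2$table$unique_voxels == 0L))
  # an exclusive blob is attributed entirely to its gene
  m2 <- m; m2[6, 6, 1:3] <- TRUE                       # 3 exclusive voxels
  ct3 <- domain_catalog(list(binary_domain(m2, g, "a", "Wnt"),
                             binary_domain(m, g, "b", "Wnt")), emb)
  uq3 <- unique_gene_domains(ct3, "Wnt")
  expect_equal(uq3$table$unique_voxels[uq3$table$label == "a"], 3L)
})

test_that("zero-expression territory completes the embryo partition", {
  ct <- random_catalog(19, n_genes = 5L)
  occ <- occupancy_map(ct, "Wnt")
  z <- zero_expression_domain(ct, "Wnt")
  emb <- ct$embryo_mask$mask
  expect_identical(z$mask, emb & occ$counts == 0L)
  # all domains are clipped to the embryo mask in random_catalog, so:
  expect_equal(sum(z$mask) + sum(emb & occ$counts == 1L) +
                 sum(emb & occ$counts >= 2L), sum(emb))
  # no expression at all -> zero domain is the whole embryo mask
  g <- ct$grid
  ct0 <- domain_catalog(list(empty_domain(g, "a", "Wnt")), ct$embryo_mask)
  expect_identical(zero_expression_domain(ct0, "Wnt")$mask, emb)
})

test_that("combine_domains implements voxelwise set algebra", {
  g <- voxel_grid(c(8, 8, 8))
  set.seed(23)
  A <- binary_domain(array(runif(512) < 0.4, c(8, 8, 8)), g, "A")
  B <- binary_domain(array(runif(512) < 0.4, c(8, 8, 8)), g, "B")
  E <- empty_domain(g)
  expect_identical(combine_domains(list(A, E), "union")$mask, A$mask)
  expect_equal(sum(combine_domains(list(A, A), "subtract")$mask), 0L)
  expect_identical(combine_domains(list(A, B), "intersection")$mask,
                   A$mask & B$mask)
  # De Morgan inside a universe U: U \ (A | B) == (U \ A) & (U \ B)
  U <- binary_domain(array(TRUE, c(8, 8, 8)), g, "U")
  lhs <- combine_domains(list(U, combine_domains(list(A, B), "union")), "subtract")
  rhs <- combine_domains(list(combine_domains(list(U, A), "subtract"),
                              combine_domains(list(U, B), "subtract")),
                         "intersection")
  expect_identical(lhs$mask, rhs$mask)
  g2 <- voxel_grid(c(8, 8, 4))
  expect_error(combine_domains(list(A, empty_domain(g2)), "union"),
               class = "wntscape_grid_error")
})

test_that("stage-specific default ROHO thresholds are the published ones", {
  expect_equal(roho_threshold("Wnt", "E9.5"), 5L)
  expect_equal(roho_threshold("Wnt", "E10.5"), 4L)
  expect_equal(roho_threshold("Wnt", "E11.5"), 5L)
  for (s in c("E9.5", "E10.5", "E11.5")) expect_equal(roho_threshold("Fzd", s), 4L)
})
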