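# a jaccard pairwise_table built directly from a symmetric matrix
make_ji_table <- function(m, volumes = rep(10L, nrow(m))) {
  labels <- paste0("g", seq_len(nrow(m)))
  diag(m) <- 1
  wntscape:::new_pairwise_table(labels, m, "jaccard", volumes, 1)
}

# random symmetric JI matrix with unit diagonal
random_ji <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- round(runif(n * (n - 1) / 2), 3)
  m <- m + t(m)
  diag(m) <- 1
  m
}

test_that("build_network thresholds edges and keeps isolated nodes", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.2
  tb <- make_ji_table(m)
  net <- build_network(tb, 0.3)
  expect_equal(igraph::vcount(net$graph), 4L)     # isolated nodes retained
  expect_equal(igraph::ecount(net$graph), 1L)
  ed <- igraph::as_edgelist(net$graph)
  expect_setequal(as.vector(ed), c("g1", "g2"))
  expect_equal(igraph::E(net$graph)$ji, 0.5)
  expect_equal(net$k_retained, 2L)
  # threshold 0 connects every pair; threshold 1 with distinct domains: none
  expect_equal(igraph::ecount(build_network(tb, 0)$graph), 6L)
  expect_equal(igraph::ecount(build_network(tb, 1)$graph), 0L)
  expect_error(build_network(tb, 1.5), class = "wntscape_parameter_error")
  expect_error(build_network(pairwise_table(random_catalog(1, n_genes = 3),
                                            mode = "row_normalised"), 0.5),
               class = "wntscape_parameter_error")
  # no self-edges, all weights within [threshold, 1]
  netr <- build_network(make_ji_table(random_ji(8, 5)), 0.4)
  expect_equal(sum(igraph::which_loop(netr$graph)), 0L)
  if (igraph::ecount(netr$graph) > 0) {
    expect_true(all(igraph::E(netr$graph)$ji >= 0.4))
    expect_true(all(igraph::E(netr$graph)$ji <= 1))
  }
})

test_that("edge sets are nested under increasing threshold", {
  tb <- make_ji_table(random_ji(10, 7))
  edge_key <- function(net) {
    el <- igraph::as_edgelist(net$graph)
    if (!nrow(el)) return(character(0))
    apply(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), 1, paste,
          collapse = "|")
  }
  thresholds <- seq(0, 1, by = 0.1)
  prev <- NULL
  for (tau in rev(thresholds)) {            # increasing edge sets as tau falls
    cur <- edge_key(build_network(tb, tau))
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("select_topk_threshold matches an exhaustive threshold scan", {
  for (seed in 1:10) {
    n <- 10L
    tb <- make_ji_table(random_ji(n, seed))
    for (k in c(1L, 3L, n)) {
      sel <- select_topk_threshold(tb, k)
      # consistency at the returned threshold
      expect_gte(build_network(tb, sel$threshold)$k_retained, k)
      expect_equal(build_network(tb, sel$threshold)$k_retained, sel$k_retained)
      # exhaustive scan over every distinct off-diagonal JI value
      off <- tb$values[upper.tri(tb$values)]
      cands <- sort(unique(off), decreasing = TRUE)
      best <- NULL
      for (tau in cands) {
        if (build_network(tb, tau)$k_retained >= k) { best <- tau; break }
      }
      expect_equal(sel$threshold, best)
      # any strictly larger representable JI keeps fewer than k genes
      larger <- cands[cands > sel$threshold]
      if (length(larger))
        expect_lt(build_network(tb, min(larger))$k_retained, k)
    }
    # boundaries: k = 1 is the max pairwise JI, k = n the min node score
    m <- tb$values; diag(m) <- -Inf
    expect_equal(select_topk_threshold(tb, 1L)$threshold, max(m))
    expect_equal(select_topk_threshold(tb, n)$threshold, min(apply(m, 1, max)))
  }
  tb <- make_ji_table(random_ji(4, 1))
  expect_error(select_topk_threshold(tb, 0), class = "wntscape_parameter_error")
  expect_error(select_topk_threshold(tb, 5), class = "wntscape_parameter_error")
})

test_that("edge intersection domains agree with the intersection table", {
  ct <- random_catalog(33, n_genes = 4L)
  tb <- pairwise_table(ct, mode = "intersection_voxels")
  doms <- ct$domains
  for (i in 1:3) for (j in (i + 1):4) {
    e <- edge_intersection_domain(doms[[i]], doms[[j]])
    expect_equal(sum(e$mask), unname(tb$values[i, j]))
  }
  a <- doms[[1]]
  expect_identical(edge_intersection_domain(a, a)$mask, a$mask)
})

test_that("similarity networks export to readable GraphML", {
  ct <- random_catalog(35, n_genes = 5L)
  tb <- pairwise_table(ct, mode = "jaccard")
  net <- build_network(tb, 0.05)
  f <- tempfile(fileext = ".graphml")
  write_network_graphml(net, f, family = "Wnt", stage = "E10.5")
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), 5L)
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  expect_setequal(igraph::V(g2)$name, tb$labels)
  if (igraph::ecount(g2) > 0)
    expect_equal(sort(igraph::E(g2)$ji), sort(igraph::E(net$graph)$ji))
  unlink(f)
})

test_that("combination counts tally voxels per gene-presence pattern", {
  ct <- random_catalog(41, n_genes = 3L)
  cc <- combination_counts(ct)
  masks <- lapply(ct$domains, `[[`, "mask")
  oracle <- oracle_combination_counts(masks, ct$embryo_mask$mask)
  # totals partition the embryo mask
  expect_equal(sum(cc$voxels), sum(ct$embryo_mask$mask))
  # every pattern matches the per-voxel tally
  for (i in seq_len(nrow(cc))) {
    bits <- bitwAnd(cc$pattern[i], 2^(0:2)) > 0
    key <- paste(bits, collapse = "")
    expect_equal(cc$voxels[i], oracle[[key]] %||% 0L)
  }
  # marginals: counts where gene g present sum to |domain_g & embryo|
  for (gidx in 1:3) {
    present <- bitwAnd(cc$pattern, 2^(gidx - 1)) > 0
    expect_equal(sum(cc$voxels[present]),
                 sum(masks[[gidx]] & ct$embryo_mask$mask))
  }
  # single-gene catalogue yields at most two patterns
  ct1 <- domain_catalog(ct$domains[1], ct$embryo_mask)
  expect_lte(nrow(combination_counts(ct1)), 2L)
  # width guard
  g <- voxel_grid(c(4, 4, 4))
  emb <- binary_domain(array(TRUE, c(4, 4, 4)), g, "embryo")
  many <- lapply(1:25, function(i) empty_domain(g, paste0("g", i), "Wnt"))
  expect_error(combination_counts(domain_catalog(many, emb)),
               class = "wntscape_parameter_error")
})

test_that("query profiles report per-gene overlap, including zeros", {
  ct <- random_catalog(43, n_genes = 5L)
  g <- ct$grid
  # query inside the first gene's domain (if nonempty)
  d1 <- ct$domains[[1]]
  if (sum(d1$mask) >= 2) {
    idx <- which(d1$mask)[1:2]
    qm <- array(FALSE, g$shape); qm[idx] <- TRUE
    prof <- query_region_profile(binary_domain(qm, g, "q"), ct)
    expect_equal(prof$fraction_of_query[prof$label == d1$label], 1)
  }
  # random query against the oracle
  set.seed(44)
  qm <- array(runif(prod(g$shape)) < 0.2, g$shape)
  q <- binary_domain(qm, g, "q")
  prof <- query_region_profile(q, ct)
  for (i in seq_len(nrow(prof))) {
    d <- ct$domains[[prof$label[i]]]
    ov <- oracle_intersection(d$mask, qm)
    expect_equal(prof$voxels_in_query[i], ov)
    expect_equal(prof$fraction_of_query[i], ov / oracle_count(qm))
  }
  # query disjoint from everything reports zeros for every gene
  far_idx <- which(!ct$embryo_mask$mask)[1]   # one voxel outside the embryo
  far <- array(FALSE, g$shape); far[far_idx] <- TRUE
  prof0 <- query_region_profile(binary_domain(far, g, "far"), ct)
  expect_equal(nrow(prof0), length(ct$domains))
  expect_true(all(prof0$voxels_in_query == 0L))
  expect_error(query_region_profile(empty_domain(g), ct),
               class = "wntscape_stat_error")
})
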