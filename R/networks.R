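#' Build a Jaccard similarity network
#'
#' Nodes are genes; an edge joins every unordered off-diagonal pair whose
#' Jaccard index meets the threshold, weighted by the JI. Isolated genes are
#' kept as degree-0 nodes, so "no similar partner at this threshold" remains
#' visible. Edge sets are nested under increasing threshold.
#'
#' @param table a [pairwise_table()] in `jaccard` mode.
#' @param threshold real in `[0, 1]`.
#' @return A `similarity_network`: an igraph `graph` (node attributes
#'   `name`, `volume_voxels`; edge attribute `ji`), plus `threshold` and
#'   `k_retained` (number of non-isolated nodes).
#' @export
build_network <- function(table, threshold) {
  stopifnot(inherits(table, "pairwise_table"))
  if (!identical(table$mode, "jaccard"))
    ws_stop("build_network requires a jaccard-mode table", "parameter")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    ws_stop("threshold must be a single real in [0, 1]", "parameter")
  n <- length(table$labels)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- table$labels
  igraph::V(g)$volume_voxels <- table$volumes
  edges <- integer(0)
  w <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (table$values[i, j] >= threshold) {
          edges <- c(edges, i, j)
          w <- c(w, table$values[i, j])
        }
      }
    }
  }
  if (length(edges)) {
    g <- igraph::add_edges(g, edges)
    igraph::E(g)$ji <- w
  } else {
    g <- igraph::set_edge_attr(g, "ji", value = numeric(0))
  }
  structure(
    list(graph = g, threshold = threshold,
         k_retained = sum(igraph::degree(g) > 0),
         labels = table$labels),
    class = "similarity_network"
  )
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges at JI >= %.4g (%d connected genes)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, x$k_retained))
  invisible(x)
}

#' Threshold retaining the k most similar genes
#'
#' Scores each gene by its best partner similarity,
#' `s(g) = max_j JI(g, j)` over off-diagonal partners, and returns the k-th
#' largest score: the largest JI threshold at which at least `k` genes still
#' have an edge. Ties keep every tied gene, so the number of connected genes
#' (`k_retained`) may exceed `k`; it is reported.
#'
#' @param table a [pairwise_table()] in `jaccard` mode with >= 2 genes.
#' @param k integer, `1 <= k <=` number of genes. The reference analysis
#'   selected the 15 most similar genes per stage.
#' @return A list: `threshold`, `k_retained`, and per-gene `scores`.
#' @export
select_topk_threshold <- function(table, k) {
  stopifnot(inherits(table, "pairwise_table"))
  if (!identical(table$mode, "jaccard"))
    ws_stop("select_topk_threshold requires a jaccard-mode table", "parameter")
  n <- length(table$labels)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n)
    ws_stop(sprintf("k must be in 1..%d", n), "parameter")
  if (n < 2L)
    ws_stop("top-k selection needs at least two genes", "parameter")
  m <- table$values
  diag(m) <- -Inf
  scores <- apply(m, 1L, max)
  names(scores) <- table$labels
  thr <- sort(scores, decreasing = TRUE)[k]
  list(threshold = unname(thr),
       k_retained = sum(scores >= thr),
       scores = scores)
}

#' Intersection domain of one network edge
#'
#' The voxel territory where two expression patterns intersect -- the mask
#' that illustrates what an edge of the similarity network means spatially.
#'
#' @param a,b [binary_domain()]s on compatible grids.
#' @return A [binary_domain()] holding `a & b`.
#' @export
edge_intersection_domain <- function(a, b) {
  check_same_grid(a$grid, b$grid, "edge_intersection_domain")
  binary_domain(a$mask & b$mask, a$grid,
                label = sprintf("%s&%s", a$label, b$label),
                family = "other", stage = a$stage)
}

#' Export a similarity network as GraphML
#'
#' @param network a [build_network()] result.
#' @param path output `.graphml` path.
#' @param family,stage optional strings stored as graph attributes.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, family = NULL, stage = NULL) {
  stopifnot(inherits(network, "similarity_network"))
  g <- network$graph
  if (!is.null(family)) g <- igraph::set_graph_attr(g, "family", family)
  if (!is.null(stage)) g <- igraph::set_graph_attr(g, "stage", stage)
  g <- igraph::set_graph_attr(g, "ji_threshold", network$threshold)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Per-voxel gene-combination counts
#'
#' For every embryo-foreground voxel, records which of the filtered genes
#' are present, and tallies voxels per distinct presence/absence
#' combination -- the re-formatting used for parallel-coordinate views of
#' co-expression. The all-absent combination is included, so counts sum to
#' the embryo mask volume.
#'
#' @param catalog a [domain_catalog()].
#' @param family,stage filters; at most 24 genes may remain (bit-pattern
#'   width guard; filter to a subset for wider selections).
#' @return A data.frame (`pattern` integer bitmask with bit i = gene i in
#'   filter order, `genes` "+"-joined labels or "(none)", `n_genes`,
#'   `voxels`) sorted by decreasing voxel count, plus attribute `labels`.
#' @export
combination_counts <- function(catalog, family = NULL, stage = NULL) {
  doms <- filter_domains(catalog, family, stage)
  if (length(doms) > 24L)
    ws_stop(sprintf("%d genes selected; combination patterns support at most 24 -- filter to a subset",
                    length(doms)), "parameter")
  labels <- vapply(doms, `[[`, character(1), "label")
  inside <- catalog$embryo_mask$mask
  code <- numeric(sum(inside))
  for (i in seq_along(doms)) code <- code + doms[[i]]$mask[inside] * 2^(i - 1)
  tab <- table(code)
  pattern <- as.numeric(names(tab))
  genes <- vapply(pattern, function(p) {
    on <- labels[bitwAnd(p, 2^(seq_along(labels) - 1)) > 0]
    if (length(on)) paste(on, collapse = "+") else "(none)"
  }, character(1))
  out <- data.frame(pattern = pattern, genes = genes,
                    n_genes = vapply(pattern, function(p)
                      sum(bitwAnd(p, 2^(seq_along(labels) - 1)) > 0), numeric(1)),
                    voxels = as.integer(tab), row.names = NULL)
  if (!0 %in% out$pattern)
    out <- rbind(out, data.frame(pattern = 0, genes = "(none)", n_genes = 0,
                                 voxels = 0L))
  out <- out[order(-out$voxels, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- unname(labels)
  out
}

#' Expression profile of a query region
#'
#' Restricts every catalogue domain to an arbitrary query mask (for example
#' a digitally segmented anatomical territory) and reports per-gene overlap
#' statistics. Genes with zero overlap are included with zeros, so "no
#' family member detected in this region" is a reportable outcome.
#'
#' @param query a nonempty [binary_domain()] on the catalogue grid.
#' @param catalog a [domain_catalog()].
#' @param family,stage optional filters.
#' @return data.frame: `label`, `family`, `voxels_in_query`,
#'   `fraction_of_query`, `fraction_of_domain`.
#' @export
query_region_profile <- function(query, catalog, family = NULL, stage = NULL) {
  stopifnot(inherits(query, "binary_domain"), inherits(catalog, "domain_catalog"))
  check_same_grid(query$grid, catalog$grid, "query_region_profile")
  qv <- sum(query$mask)
  if (qv == 0) ws_stop("query region is empty; profile undefined", "stat")
  doms <- filter_domains(catalog, family, stage)
  rows <- lapply(doms, function(d) {
    ov <- sum(d$mask & query$mask)
    gv <- sum(d$mask)
    data.frame(label = d$label, family = d$family,
               voxels_in_query = as.integer(ov),
               fraction_of_query = ov / qv,
               fraction_of_domain = if (gv > 0) ov / gv else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
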