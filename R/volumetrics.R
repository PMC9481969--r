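#' Volume of a binary domain
#'
#' @param domain a [binary_domain()].
#' @return A list with `voxels` (count of expressed voxels) and `um3`
#'   (count times the physical voxel volume).
#' @examples
#' g <- voxel_grid(c(3, 3, 3), c(2, 2, 2))
#' d <- binary_domain(array(TRUE, c(3, 3, 3)), g, "all")
#' domain_volume(d)  # 27 voxels, 216 um^3
#' @export
domain_volume <- function(domain) {
  stopifnot(inherits(domain, "binary_domain"))
  v <- sum(domain$mask)
  list(voxels = as.integer(v), um3 = v * voxel_volume_um3(domain$grid))
}

#' Jaccard index of two domains
#'
#' JI = volume of intersection / volume of union of the two domains. When
#' both domains are empty the ratio is 0/0; the package defines it as 0 so
#' similarity tables stay finite for undetected genes.
#'
#' @param a,b [binary_domain()] objects on compatible grids.
#' @return JI in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  check_same_grid(a$grid, b$grid, "jaccard")
  inter <- sum(a$mask & b$mask)
  uni <- sum(a$mask) + sum(b$mask) - inter
  if (uni == 0) 0 else inter / uni
}

new_pairwise_table <- function(labels, values, mode, volumes, voxel_volume_um3) {
  dimnames(values) <- list(labels, labels)
  structure(
    list(labels = labels, values = values, mode = mode,
         volumes = as.integer(volumes), voxel_volume_um3 = voxel_volume_um3),
    class = "pairwise_table"
  )
}

#' Pairwise intersection / similarity table over a catalogue
#'
#' Builds a gene-by-gene square table over the filtered domains:
#' * `intersection_voxels` -- raw intersection volumes `|i & j|`; the
#'   diagonal holds per-gene volumes.
#' * `row_normalised` -- `|i & j| / |i|`, the fraction of the row (test)
#'   pattern covered by the column (target) pattern; 0 for empty rows.
#' * `column_normalised` -- `|i & j| / |j|`, the transpose convention.
#' * `jaccard` -- `|i & j| / |i | j|`, with the empty/empty pair defined
#'   as 0.
#'
#' @param catalog a [domain_catalog()].
#' @param family,stage optional filters (see [filter_domains()]).
#' @param mode table mode, one of the four above.
#' @return A `pairwise_table`: labels, square `values` matrix, `mode`,
#'   per-gene `volumes` (voxels) and the voxel volume for um^3 conversion.
#' @export
pairwise_table <- function(catalog, family = NULL, stage = NULL,
                           mode = c("jaccard", "intersection_voxels",
                                    "row_normalised", "column_normalised")) {
  mode <- match.arg(mode)
  doms <- filter_domains(catalog, family, stage)
  labels <- vapply(doms, `[[`, character(1), "label")
  X <- vapply(doms, function(d) as.numeric(d$mask),
              numeric(prod(catalog$grid$shape)))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(doms))
  inter <- crossprod(X)                      # |i & j| for binary columns
  vols <- diag(inter)
  values <- switch(mode,
    intersection_voxels = inter,
    row_normalised = {
      m <- inter / ifelse(vols > 0, vols, 1)  # divide rows by |i|
      m[vols == 0, ] <- 0
      m
    },
    column_normalised = {
      m <- t(inter / ifelse(vols > 0, vols, 1))
      m[, vols == 0] <- 0
      m
    },
    jaccard = {
      uni <- outer(vols, vols, `+`) - inter
      m <- ifelse(uni > 0, inter / uni, 0)
      m
    })
  new_pairwise_table(unname(labels), unname(values), mode, vols,
                     voxel_volume_um3(catalog$grid))
}

#' @export
print.pairwise_table <- function(x, ...) {
  cat(sprintf("<pairwise_table> %d genes, mode '%s'\n", length(x$labels), x$mode))
  print(round(x$values, 4))
  invisible(x)
}

#' Fractions of anatomical structures occupied by each expression domain
#'
#' For every (gene, structure) pair reports
#' `|domain & structure| / |structure|` -- the proportion of the anatomical
#' domain occupied by that gene's expression. A `whole_embryo` row per gene
#' uses the embryo foreground mask as the structure. A structure with zero
#' voxels yields fraction 0 with a warning.
#'
#' @param catalog a [domain_catalog()] with an anatomy label volume.
#' @param family,stage optional filters.
#' @return A long `data.frame(label, structure, structure_voxels,
#'   overlap_voxels, fraction)`.
#' @export
anatomy_proportions <- function(catalog, family = NULL, stage = NULL) {
  stopifnot(inherits(catalog, "domain_catalog"))
  if (is.null(catalog$anatomy))
    ws_stop("catalogue has no anatomy label volume", "validation")
  doms <- filter_domains(catalog, family, stage)
  an <- catalog$anatomy
  nm <- catalog$anatomy_names
  structures <- rbind(
    data.frame(value = NA_integer_, name = "whole_embryo"),
    nm[order(nm$value), c("value", "name")]
  )
  out <- vector("list", length(doms) * nrow(structures))
  k <- 0L
  for (d in doms) {
    for (s in seq_len(nrow(structures))) {
      if (is.na(structures$value[s])) {
        smask <- catalog$embryo_mask$mask
      } else {
        smask <- an == structures$value[s]
      }
      sv <- sum(smask)
      ov <- sum(d$mask & smask)
      if (sv == 0) ws_warn(sprintf("structure '%s' has zero voxels", structures$name[s]))
      k <- k + 1L
      out[[k]] <- data.frame(label = d$label, structure = structures$name[s],
                             structure_voxels = sv, overlap_voxels = ov,
                             fraction = if (sv > 0) ov / sv else 0)
    }
  }
  do.call(rbind, out)
}

#' Fraction of a domain lying outside a set of other domains
#'
#' Generalises statements like "half of one gene's expression domain lies
#' outside any domain of the partner family": returns
#' `|a \ union(others)| / |a|`.
#'
#' @param a a nonempty [binary_domain()].
#' @param others list of `binary_domain`s on the same grid.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_outside <- function(a, others) {
  stopifnot(inherits(a, "binary_domain"))
  va <- sum(a$mask)
  if (va == 0) ws_stop("coverage_outside is undefined for an empty domain", "stat")
  cover <- array(FALSE, dim = a$grid$shape)
  for (o in others) {
    check_same_grid(a$grid, o$grid, "coverage_outside")
    cover <- cover | o$mask
  }
  sum(a$mask & !cover) / va
}
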