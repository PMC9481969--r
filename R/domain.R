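#' Construct a binary expression domain
#'
#' A `binary_domain` is one gene (or reporter) expression territory mapped
#' onto a reference grid: a logical 3D array plus metadata. A zero-volume
#' domain is legal -- a gene may simply not be detected at a stage.
#'
#' @param mask logical (or coercible numeric, binarized by `> 0`) 3D array
#'   whose dimensions equal `grid$shape`.
#' @param grid a [voxel_grid()].
#' @param label gene identifier string.
#' @param family one of `"Wnt"`, `"Fzd"`, `"TcfLef"`, `"Sfrp"`, `"other"`,
#'   `"reporter"`.
#' @param stage developmental stage; the canonical values are `"E9.5"`,
#'   `"E10.5"`, `"E11.5"` but any string is accepted.
#' @return An object of class `binary_domain`.
#' @export
binary_domain <- function(mask, grid, label = "domain",
                          family = c("other", "Wnt", "Fzd", "TcfLef", "Sfrp", "reporter"),
                          stage = "E10.5") {
  stopifnot(inherits(grid, "voxel_grid"))
  family <- match.arg(family)
  if (is.numeric(mask) || is.integer(mask)) mask <- mask > 0
  if (!is.logical(mask)) ws_stop("'mask' must be logical or numeric", "validation")
  if (!identical(dim(mask), grid$shape))
    ws_stop(sprintf("mask shape (%s) does not equal grid shape (%s)",
                    paste(dim(mask), collapse = "x"),
                    paste(grid$shape, collapse = "x")), "grid")
  if (anyNA(mask)) ws_stop("mask contains NA voxels", "validation")
  structure(
    list(mask = mask, grid = grid, label = as.character(label),
         family = family, stage = as.character(stage)),
    class = "binary_domain"
  )
}

#' Empty domain on a grid
#' @param grid a [voxel_grid()].
#' @inheritParams binary_domain
#' @return A `binary_domain` whose mask is all-`FALSE`.
#' @export
empty_domain <- function(grid, label = "empty", family = "other", stage = "E10.5") {
  binary_domain(array(FALSE, dim = grid$shape), grid, label, family, stage)
}

#' @export
print.binary_domain <- function(x, ...) {
  v <- sum(x$mask)
  cat(sprintf("<binary_domain> %s [%s, %s]: %d voxels (%.4g%% of grid)\n",
              x$label, x$family, x$stage, v, 100 * v / length(x$mask)))
  invisible(x)
}

#' Assemble a domain catalogue
#'
#' A `domain_catalog` bundles the co-registered domains of one integrated
#' dataset: the shared grid, an ordered collection of `binary_domain`s, the
#' embryo foreground mask, and optionally an anatomy label volume (non-negative
#' integer labels with a name table). Labels must be unique within each
#' `(family, stage)` pair.
#'
#' @param domains list of [binary_domain()] objects on one common grid.
#' @param embryo_mask a `binary_domain` marking embryo foreground.
#' @param anatomy optional integer 3D array of anatomical labels (0 =
#'   unlabelled background) on the same grid.
#' @param anatomy_names optional `data.frame(value, name)` naming every
#'   nonzero label present in `anatomy`.
#' @return An object of class `domain_catalog`.
#' @export
domain_catalog <- function(domains, embryo_mask, anatomy = NULL, anatomy_names = NULL) {
  if (length(domains) < 1L) ws_stop("catalogue needs at least one domain", "validation")
  if (!all(vapply(domains, inherits, logical(1), "binary_domain")))
    ws_stop("'domains' must be a list of binary_domain objects", "validation")
  stopifnot(inherits(embryo_mask, "binary_domain"))
  grid <- embryo_mask$grid
  for (d in domains) check_same_grid(grid, d$grid, sprintf("domain '%s'", d$label))
  key <- vapply(domains, function(d) paste(d$family, d$stage, d$label, sep = "\r"),
                character(1))
  if (anyDuplicated(key))
    ws_stop(sprintf("duplicate (family, stage, label): %s",
                    gsub("\r", "/", key[duplicated(key)][1])), "validation")
  if (!is.null(anatomy)) {
    anatomy <- array(as.integer(anatomy), dim = dim(anatomy))
    if (!identical(dim(anatomy), grid$shape))
      ws_stop("anatomy volume shape does not match catalogue grid", "grid")
    if (any(anatomy < 0L)) ws_stop("anatomy labels must be non-negative", "validation")
    present <- setdiff(sort(unique(as.vector(anatomy))), 0L)
    if (is.null(anatomy_names))
      anatomy_names <- data.frame(value = present,
                                  name = paste0("structure_", present))
    missing <- setdiff(present, anatomy_names$value)
    if (length(missing))
      ws_stop(sprintf("anatomy labels without a name-table entry: %s",
                      paste(missing, collapse = ", ")), "validation")
  }
  names(domains) <- vapply(domains, `[[`, character(1), "label")
  structure(
    list(grid = grid, domains = domains, embryo_mask = embryo_mask,
         anatomy = anatomy, anatomy_names = anatomy_names),
    class = "domain_catalog"
  )
}

#' Filter catalogue domains by family and stage
#'
#' @param catalog a [domain_catalog()].
#' @param family optional family filter (`NULL` keeps all).
#' @param stage optional stage filter (`NULL` keeps all).
#' @param require_nonempty error (class `wntscape_selection_error`) when the
#'   filter selects nothing -- the default, since downstream statistics are
#'   undefined on an empty selection.
#' @return A list of `binary_domain` objects (possibly empty when
#'   `require_nonempty = FALSE`).
#' @export
filter_domains <- function(catalog, family = NULL, stage = NULL,
                           require_nonempty = TRUE) {
  stopifnot(inherits(catalog, "domain_catalog"))
  keep <- vapply(catalog$domains, function(d) {
    (is.null(family) || d$family %in% family) &&
      (is.null(stage) || d$stage %in% stage)
  }, logical(1))
  out <- catalog$domains[keep]
  if (require_nonempty && length(out) == 0L)
    ws_stop(sprintf("no domains match family=%s stage=%s",
                    if (is.null(family)) "*" else paste(family, collapse = "|"),
                    if (is.null(stage)) "*" else paste(stage, collapse = "|")),
            "selection")
  out
}

#' @export
print.domain_catalog <- function(x, ...) {
  fam <- table(vapply(x$domains, `[[`, character(1), "family"))
  cat(sprintf("<domain_catalog> %d domains on %s grid (%s)\n",
              length(x$domains), paste(x$grid$shape, collapse = "x"),
              paste(sprintf("%s: %d", names(fam), fam), collapse = ", ")))
  cat(sprintf("  embryo mask: %d voxels; anatomy: %s\n",
              sum(x$embryo_mask$mask),
              if (is.null(x$anatomy)) "none"
              else sprintf("%d structures", nrow(x$anatomy_names))))
  invisible(x)
}
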