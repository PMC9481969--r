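# Catalogue and table I/O.
#
# A manifest is a CSV with header `label,family,stage,file` (or an
# equivalent JSON array of records). Two reserved family values carry the
# non-gene volumes: `embryo` (foreground mask) and `anatomy` (integer label
# volume; its name table may sit beside it as <file>.names.csv with columns
# value,name). Volume files are NIfTI-1; input volumes are binarized by the
# fixed rule value > 0 -> TRUE. Native Woolz (.wlz) archives are not parsed:
# convert to NIfTI first.

#' Read a domain catalogue from a manifest
#'
#' @param manifest_path CSV (columns `label,family,stage,file`; `#` comments
#'   allowed) or JSON (array of objects with those fields) manifest. Relative
#'   `file` entries are resolved against the manifest's directory. Rows with
#'   family `embryo` / `anatomy` populate the foreground mask and anatomy
#'   label volume; when no `embryo` row is present the foreground defaults to
#'   the union of all domains, with a warning.
#' @return A [domain_catalog()].
#' @export
read_catalog <- function(manifest_path) {
  if (!file.exists(manifest_path))
    ws_stop(sprintf("manifest not found: %s", manifest_path), "io")
  man <- if (grepl("\\.json$", manifest_path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(manifest_path))
  } else {
    utils::read.csv(manifest_path, comment.char = "#",
                    colClasses = "character", strip.white = TRUE)
  }
  need <- c("label", "family", "stage", "file")
  if (!all(need %in% names(man)))
    ws_stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
            "validation")
  base_dir <- dirname(normalizePath(manifest_path, mustWork = TRUE))
  resolve <- function(f) if (file.exists(f)) f else file.path(base_dir, f)

  grid <- NULL
  domains <- list()
  embryo <- NULL
  anatomy <- NULL
  anatomy_names <- NULL
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    f <- resolve(row$file)
    if (!file.exists(f))
      ws_stop(sprintf("manifest row %d ('%s'): file not found: %s",
                      i, row$label, row$file), "io")
    vol <- read_nifti(f)
    if (is.null(grid)) {
      grid <- voxel_grid(dim(vol$data),
                         voxel_size_um = ifelse(vol$voxel_size > 0, vol$voxel_size, 1))
    } else if (!identical(dim(vol$data), grid$shape)) {
      ws_stop(sprintf("manifest row %d ('%s'): volume shape (%s) incompatible with grid (%s)",
                      i, row$label, paste(dim(vol$data), collapse = "x"),
                      paste(grid$shape, collapse = "x")), "grid")
    }
    if (identical(row$family, "anatomy")) {
      anatomy <- array(as.integer(round(vol$data)), dim = grid$shape)
      names_file <- paste0(f, ".names.csv")
      if (file.exists(names_file)) {
        anatomy_names <- utils::read.csv(names_file)
        anatomy_names$value <- as.integer(anatomy_names$value)
      }
    } else if (identical(row$family, "embryo")) {
      embryo <- binary_domain(vol$data > 0, grid, label = row$label,
                              family = "other", stage = row$stage)
    } else {
      domains[[length(domains) + 1L]] <-
        binary_domain(vol$data > 0, grid, label = row$label,
                      family = row$family, stage = row$stage)
    }
  }
  if (length(domains) == 0L)
    ws_stop("manifest lists no gene domains", "validation")
  warn_union <- is.null(embryo)
  if (warn_union) {
    u <- Reduce(`|`, lapply(domains, `[[`, "mask"))
    embryo <- binary_domain(u, grid, label = "embryo_union", family = "other",
                            stage = domains[[1]]$stage)
  }
  out <- domain_catalog(domains, embryo, anatomy = anatomy,
                        anatomy_names = anatomy_names)
  if (warn_union)
    ws_warn("manifest has no 'embryo' row; using union of domains as foreground")
  out
}

#' Write a domain catalogue to disk
#'
#' Writes one NIfTI-1 file per domain (plus the embryo mask and, when
#' present, the anatomy label volume and its name table) and a CSV manifest
#' readable by [read_catalog()]. Round-tripping preserves every mask
#' bit-exactly.
#'
#' @param catalog a [domain_catalog()].
#' @param out_dir output directory (created if needed).
#' @param format only `"nifti"` is supported (TIFF is not available in this
#'   build).
#' @param gzip compress volumes (`.nii.gz`)? Default `TRUE`.
#' @return The manifest path, invisibly.
#' @export
write_catalog <- function(catalog, out_dir, format = "nifti", gzip = TRUE) {
  stopifnot(inherits(catalog, "domain_catalog"))
  format <- match.arg(format, c("nifti", "tiff"))
  if (format == "tiff")
    ws_stop("TIFF output is not supported in this build; use format = 'nifti'", "parameter")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) ws_stop(sprintf("cannot create %s", out_dir), "io")
  ext <- if (gzip) ".nii.gz" else ".nii"
  vs <- catalog$grid$voxel_size_um
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

  rows <- list()
  for (d in catalog$domains) {
    f <- paste0(safe(paste(d$family, d$stage, d$label, sep = "_")), ext)
    write_nifti(d$mask, file.path(out_dir, f), voxel_size = vs, datatype = "uint8")
    rows[[length(rows) + 1L]] <-
      data.frame(label = d$label, family = d$family, stage = d$stage, file = f)
  }
  f <- paste0("embryo_mask", ext)
  write_nifti(catalog$embryo_mask$mask, file.path(out_dir, f),
              voxel_size = vs, datatype = "uint8")
  rows[[length(rows) + 1L]] <-
    data.frame(label = catalog$embryo_mask$label, family = "embryo",
               stage = catalog$embryo_mask$stage, file = f)
  if (!is.null(catalog$anatomy)) {
    f <- paste0("anatomy", ext)
    write_nifti(catalog$anatomy, file.path(out_dir, f), voxel_size = vs,
                datatype = "int32")
    utils::write.csv(catalog$anatomy_names,
                     file.path(out_dir, paste0(f, ".names.csv")),
                     row.names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(label = "anatomy", family = "anatomy",
                 stage = catalog$domains[[1]]$stage, file = f)
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  con <- file(manifest_path, "w")
  writeLines(c("# wntscape catalogue manifest",
               "# axis_order: plane,row,column (index origin 0 in file space)",
               sprintf("# voxel_size_um: %s", paste(vs, collapse = ",")),
               "# binarization: value > 0"), con)
  utils::write.table(do.call(rbind, rows), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  close(con)
  invisible(manifest_path)
}

#' Export a pairwise table as CSV
#'
#' The CSV carries a comment header recording the normalisation mode, the
#' per-gene total volumes (so absolute voxel counts can be recovered from
#' normalised entries) and the voxel volume for conversion to cubic
#' micrometres. Values are printed with round-trip (17 significant digit)
#' precision.
#'
#' @param table a [pairwise_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path) {
  stopifnot(inherits(table, "pairwise_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# wntscape pairwise table",
               sprintf("# mode: %s", table$mode),
               sprintf("# volumes_voxels: %s",
                       paste(sprintf("%s=%d", table$labels, table$volumes),
                             collapse = ";")),
               sprintf("# voxel_volume_um3: %.17g", table$voxel_volume_um3)),
             con)
  m <- table$values
  writeLines(paste(c("label", table$labels), collapse = ","), con)
  for (i in seq_along(table$labels)) {
    writeLines(paste(c(table$labels[i], sprintf("%.17g", m[i, ])), collapse = ","),
               con)
  }
  invisible(path)
}

#' Read back a pairwise table CSV written by [export_table()]
#'
#' @param path CSV path.
#' @return A `pairwise_table` object.
#' @export
read_pairwise_table <- function(path) {
  if (!file.exists(path)) ws_stop(sprintf("file not found: %s", path), "io")
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  mode <- grab("mode")
  vox_um3 <- as.numeric(grab("voxel_volume_um3"))
  vol_str <- strsplit(grab("volumes_voxels"), ";", fixed = TRUE)[[1]]
  vols <- as.integer(sub(".*=", "", vol_str))
  names(vols) <- sub("=.*", "", vol_str)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  labels <- as.character(df$label)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  new_pairwise_table(labels, m, mode, unname(vols[labels]), vox_um3)
}
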