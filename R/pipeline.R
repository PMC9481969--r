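#' Configuration for a full analysis run
#'
#' Exactly one of `manifest` (path to a catalogue manifest) or `phantom`
#' (a [phantom_config()]) must be given. Defaults encode the thresholds of
#' the reference Wnt/Fzd analysis: ROHO occupancy Wnt 5/4/5 at
#' E9.5/E10.5/E11.5 and Fzd 4 (see [roho_threshold()]), occupancy peaks at
#' Wnt 7 and Fzd 6, 26-connectivity, minimum region size 5 voxels, and
#' similarity networks thresholded to retain the 15 most similar genes.
#'
#' @param manifest optional manifest path for [read_catalog()].
#' @param phantom optional [phantom_config()] for [generate_catalog()].
#' @param families families to analyse (default `c("Wnt", "Fzd")`).
#' @param stages stages to analyse; `NULL` means every stage found.
#' @param roho_thresholds named list family -> (named stage vector or single
#'   integer); missing entries fall back to [roho_threshold()].
#' @param peak_thresholds named integer vector of peak cut-offs per family.
#' @param connectivity 6, 18 or 26.
#' @param min_voxels minimum ROHO size.
#' @param network_k top-k genes retained in similarity networks.
#' @param out_dir output directory.
#' @param seed integer seed (phantom generation).
#' @return A `run_config` list.
#' @export
run_config <- function(manifest = NULL, phantom = NULL,
                       families = c("Wnt", "Fzd"), stages = NULL,
                       roho_thresholds = list(Wnt = c(E9.5 = 5L, E10.5 = 4L, E11.5 = 5L),
                                              Fzd = 4L),
                       peak_thresholds = c(Wnt = 7L, Fzd = 6L),
                       connectivity = 26L, min_voxels = 5L,
                       network_k = 15L, out_dir = tempfile("wntscape_run_"),
                       seed = 1L) {
  structure(
    list(manifest = manifest, phantom = phantom, families = families,
         stages = stages, roho_thresholds = roho_thresholds,
         peak_thresholds = peak_thresholds,
         connectivity = as.integer(connectivity),
         min_voxels = as.integer(min_voxels),
         network_k = as.integer(network_k),
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Lists every problem found without executing anything. Accepts a
#' `run_config` object or a path to a JSON file with the same fields
#' (`phantom` given as a list of [phantom_config()] arguments).
#'
#' @param config a [run_config()] or JSON path.
#' @return Character vector of problems; `character(0)` when valid.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (is.null(config$manifest) && is.null(config$phantom))
    add("exactly one of 'manifest' or 'phantom' must be given (none present)")
  if (!is.null(config$manifest) && !is.null(config$phantom))
    add("exactly one of 'manifest' or 'phantom' must be given (both present)")
  if (!is.null(config$manifest) && !file.exists(config$manifest))
    add(sprintf("manifest file not found: %s", config$manifest))
  if (!is.null(config$phantom) && !inherits(config$phantom, "phantom_config"))
    add("'phantom' is not a phantom_config")
  if (length(config$families) < 1L) add("no families requested")
  if (is.na(config$network_k) || config$network_k < 1L) add("network_k must be >= 1")
  if (!config$connectivity %in% c(6L, 18L, 26L)) add("connectivity must be 6, 18 or 26")
  if (is.na(config$min_voxels) || config$min_voxels < 1L) add("min_voxels must be >= 1")
  thr <- unlist(config$roho_thresholds)
  if (length(thr) && (anyNA(thr) || any(thr < 1) || any(thr != round(thr))))
    add("roho_thresholds must be positive integers")
  pk <- config$peak_thresholds
  if (length(pk) && (anyNA(pk) || any(pk < 1))) add("peak_thresholds must be >= 1")
  problems
}

#' Read a run configuration from JSON
#'
#' @param path JSON file; fields as in [run_config()], with `phantom` given
#'   as a list of [phantom_config()] arguments (its `grid` as
#'   `{shape, voxel_size_um}`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ws_stop(sprintf("config file not found: %s", path), "io")
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    ws_stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                            "config"))
  phantom <- NULL
  if (!is.null(raw$phantom)) {
    ph <- raw$phantom
    if (!is.null(ph$grid))
      ph$grid <- voxel_grid(ph$grid$shape,
                            voxel_size_um = ph$grid$voxel_size_um %||% c(1, 1, 1))
    if (!is.null(ph$n_genes_per_family))
      ph$n_genes_per_family <- unlist(ph$n_genes_per_family)
    phantom <- do.call(phantom_config, ph)
  }
  args <- raw[setdiff(names(raw), "phantom")]
  if (!is.null(args$roho_thresholds))
    args$roho_thresholds <- lapply(args$roho_thresholds, unlist)
  if (!is.null(args$peak_thresholds)) args$peak_thresholds <- unlist(args$peak_thresholds)
  do.call(run_config, c(args, list(phantom = phantom)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lookup_threshold <- function(thresholds, family, stage, fallback) {
  t <- thresholds[[family]]
  if (is.null(t)) return(fallback(family, stage))
  if (length(t) == 1L && is.null(names(t))) return(as.integer(t))
  if (!is.null(names(t)) && stage %in% names(t)) return(as.integer(t[[stage]]))
  if (length(t) == 1L) return(as.integer(t))
  fallback(family, stage)
}

#' Run the full integrated analysis
#'
#' Loads or generates the catalogue, then for every requested
#' (family, stage) combination computes: the four pairwise tables,
#' occupancy map, ROHO regions with gene sets, occupancy peaks, unique-gene
#' and zero-expression territories, the top-k Jaccard network, and
#' per-voxel combination counts. Artefacts are written under
#' `out_dir/tables`, `out_dir/volumes`, `out_dir/networks`, with a
#' machine-readable `summary.json`. Given identical configuration and
#' inputs the artefacts are byte-identical; timestamps live only in the
#' summary.
#'
#' @param config a [run_config()] (or JSON path, see [read_run_config()]).
#' @return The run summary, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  problems <- validate_run_config(config)
  if (length(problems))
    ws_stop(paste("invalid configuration:", paste(problems, collapse = "; ")),
            "config")
  t0 <- Sys.time()
  out_dir <- config$out_dir
  for (d in c("", "tables", "volumes", "networks"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)

  log_msg <- function(...) message("[wntscape] ", sprintf(...))
  if (!is.null(config$phantom)) {
    log_msg("generating phantom catalogue (seed %d)", config$seed)
    ph <- config$phantom
    ph$seed <- config$seed
    gen <- generate_catalog(ph)
    catalog <- gen$catalog
  } else {
    log_msg("reading catalogue from %s", config$manifest)
    catalog <- read_catalog(config$manifest)
  }

  stages <- config$stages %||%
    sort(unique(vapply(catalog$domains, `[[`, character(1), "stage")))
  vs <- catalog$grid$voxel_size_um
  summary <- list(
    package_version = as.character(utils::packageVersion("wntscape")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = list(families = config$families, stages = stages,
                  connectivity = config$connectivity,
                  min_voxels = config$min_voxels,
                  network_k = config$network_k, seed = config$seed),
    grid = list(shape = catalog$grid$shape, voxel_size_um = vs),
    embryo_mask_voxels = sum(catalog$embryo_mask$mask),
    analyses = list()
  )

  for (fam in config$families) {
    fam_hits <- 0L
    for (stg in stages) {
      doms <- filter_domains(catalog, fam, stg, require_nonempty = FALSE)
      if (length(doms) == 0L) {
        if (!is.null(config$stages))
          ws_stop(sprintf("no domains for requested family '%s' at stage '%s'",
                          fam, stg), "selection")
        next
      }
      fam_hits <- fam_hits + 1L
      tag <- sprintf("%s_%s", fam, gsub("[^A-Za-z0-9.]+", "-", stg))
      log_msg("analysing %s (%d genes)", tag, length(doms))
      entry <- list(family = fam, stage = stg, n_genes = length(doms))
      entry$gene_volumes_voxels <-
        as.list(vapply(doms, function(d) sum(d$mask), numeric(1)))

      # pairwise tables, all four modes
      table_files <- list()
      ji_tab <- NULL
      for (mode in c("jaccard", "intersection_voxels", "row_normalised",
                     "column_normalised")) {
        tb <- pairwise_table(catalog, fam, stg, mode = mode)
        if (mode == "jaccard") ji_tab <- tb
        f <- file.path(out_dir, "tables", sprintf("%s_%s.csv", tag, mode))
        export_table(tb, f)
        table_files[[mode]] <- f
      }
      entry$table_files <- table_files

      # occupancy, ROHOs, peaks
      occ <- occupancy_map(catalog, fam, stg)
      occ_file <- file.path(out_dir, "volumes", sprintf("%s_occupancy.nii.gz", tag))
      write_nifti(occ$counts, occ_file, voxel_size = vs, datatype = "int16")
      t_roho <- lookup_threshold(config$roho_thresholds, fam, stg, roho_threshold)
      t_roho <- min(t_roho, occ$n_genes)
      regions <- threshold_regions(occ, t_roho,
                                   connectivity = config$connectivity,
                                   min_voxels = config$min_voxels)
      lab_file <- file.path(out_dir, "volumes", sprintf("%s_roho_labels.nii.gz", tag))
      write_nifti(regions$labels, lab_file, voxel_size = vs, datatype = "int16")
      records <- roho_gene_sets(regions, catalog, fam, stg)
      roho_csv <- file.path(out_dir, "tables", sprintf("%s_rohos.csv", tag))
      roho_df <- if (length(records)) cbind(
        regions$regions,
        gene_set = vapply(records, function(r) paste(r$gene_set, collapse = "+"),
                          character(1))
      ) else data.frame()
      utils::write.csv(roho_df, roho_csv, row.names = FALSE)
      pk_t <- if (fam %in% names(config$peak_thresholds))
        as.integer(config$peak_thresholds[[fam]]) else t_roho + 2L
      peaks <- occupancy_peaks(occ, min(pk_t, occ$n_genes))
      peak_file <- file.path(out_dir, "volumes", sprintf("%s_peaks.nii.gz", tag))
      write_nifti(peaks$mask, peak_file, voxel_size = vs, datatype = "uint8")
      entry$occupancy_file <- occ_file
      entry$roho <- list(threshold = t_roho, count = nrow(regions$regions),
                         labels_file = lab_file, table_file = roho_csv,
                         gene_sets = lapply(records, `[[`, "gene_set"))
      entry$peaks <- list(threshold = min(pk_t, occ$n_genes),
                          voxels = sum(peaks$mask), file = peak_file)

      # unique / zero territories
      zero <- zero_expression_domain(catalog, fam, stg)
      zero_file <- file.path(out_dir, "volumes", sprintf("%s_zero.nii.gz", tag))
      write_nifti(zero$mask, zero_file, voxel_size = vs, datatype = "uint8")
      entry$zero_voxels <- sum(zero$mask)
      entry$zero_file <- zero_file
      if (length(doms) >= 2L) {
        uq <- unique_gene_domains(catalog, fam, stg)
        uniq_csv <- file.path(out_dir, "tables", sprintf("%s_unique.csv", tag))
        utils::write.csv(uq$table, uniq_csv, row.names = FALSE)
        single_file <- file.path(out_dir, "volumes", sprintf("%s_single.nii.gz", tag))
        write_nifti(occ$counts == 1L, single_file, voxel_size = vs,
                    datatype = "uint8")
        entry$unique <- list(single_domain_voxels = uq$single_domain_voxels,
                             table_file = uniq_csv, mask_file = single_file)
      }

      # similarity network at the top-k threshold
      if (length(doms) >= 2L) {
        k <- min(config$network_k, length(doms))
        sel <- select_topk_threshold(ji_tab, k)
        net <- build_network(ji_tab, sel$threshold)
        net_file <- file.path(out_dir, "networks", sprintf("%s.graphml", tag))
        write_network_graphml(net, net_file, family = fam, stage = stg)
        entry$network <- list(k = k, threshold = sel$threshold,
                              k_retained = sel$k_retained,
                              edges = igraph::ecount(net$graph), file = net_file)
      }

      # combination counts (guard the 24-gene pattern width)
      if (length(doms) <= 24L) {
        cc <- combination_counts(catalog, fam, stg)
        cc_file <- file.path(out_dir, "tables", sprintf("%s_combinations.csv", tag))
        utils::write.csv(cc, cc_file, row.names = FALSE)
        entry$combination_counts_file <- cc_file
        entry$combination_patterns <- nrow(cc)
      }

      summary$analyses[[tag]] <- entry
    }
    if (fam_hits == 0L)
      ws_stop(sprintf("no domains found for requested family '%s'", fam),
              "selection")
  }
  summary$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("done in %.1f s; outputs in %s", summary$wall_time_s, out_dir)
  invisible(summary)
}
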