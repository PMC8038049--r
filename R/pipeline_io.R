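## End-to-end orchestration and standard-format I/O.
##
## The pipeline runs simulate -> per-subject network construction -> global
## and local-scale metrics -> cohort statistics, writing NIfTI volumes and
## atlases, TSV edge lists, CSV tables and a JSON manifest. Every stochastic
## stage draws its seed deterministically from the master seed and the
## subject/region identifier, so a fixed configuration reproduces all
## numeric outputs bit for bit.

#' Construct one subject's GM network and small-worldness, end to end
#'
#' Convenience composition of [extract_cube_nodes()],
#' [build_similarity_matrix()], [estimate_null()], [binarize_fdr()] and
#' [small_worldness()] with a single seed.
#'
#' @param volume a [gm_volume()] (resliced to 2 mm first if needed).
#' @param gm_voxel_threshold,min_gm_voxels_per_cube node extraction
#'   parameters.
#' @param n_perm,q permutation-null size and FDR level.
#' @param n_random,swap_attempts_factor reference-ensemble parameters.
#' @param seed integer seed.
#' @return list with `nodes` (`gm_nodeset`), `network` (igraph), `metrics`
#'   (`network_metrics`).
#' @export
construct_gm_network <- function(volume, gm_voxel_threshold = 0.1,
                                 min_gm_voxels_per_cube = 1L,
                                 n_perm = 1e5, q = 0.05, n_random = 20L,
                                 swap_attempts_factor = 10L, seed = 1L) {
  volume <- reslice_to_2mm(volume)
  nodes <- extract_cube_nodes(volume, gm_voxel_threshold,
                              min_gm_voxels_per_cube)
  if (nodes$n_nodes < 3L)
    stop("fewer than 3 cube nodes: cannot construct a network", call. = FALSE)
  sim <- build_similarity_matrix(nodes)
  nul <- estimate_null(nodes, n_perm = n_perm, seed = derive_seed(seed, "null"))
  net <- binarize_fdr(sim, nul, q = q)
  if (igraph::ecount(net) < 1L)
    stop("empty network after FDR thresholding", call. = FALSE)
  metrics <- small_worldness(net, n_random = n_random,
                             swap_attempts_factor = swap_attempts_factor,
                             seed = derive_seed(seed, "sw"))
  list(nodes = nodes, network = net, metrics = metrics)
}

# NIfTI -----------------------------------------------------------------

#' Write a GM volume as NIfTI
#'
#' @param volume a [gm_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_gm_volume <- function(volume, path) {
  stopifnot(inherits(volume, "gm_volume"))
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::asNifti(img, reference = list(pixdim = c(-1, volume$voxel_size,
                                                          rep(1, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a GM partial-volume map from NIfTI
#'
#' Values are validated to lie in \[0, 1\]; non-2 mm grids are routed through
#' [reslice_to_2mm()] unless `reslice = FALSE`.
#'
#' @param path NIfTI file.
#' @param subject_id identifier to attach (default: file name).
#' @param reslice reslice to isotropic 2 mm (default TRUE).
#' @return a [gm_volume()].
#' @export
read_gm_volume <- function(path, subject_id = NULL, reslice = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  dat <- array(as.double(img), dim(img))
  if (min(dat) < -1e-6 || max(dat) > 1 + 1e-6)
    stop(sprintf("%s: GM values outside [0, 1] (range %.3g..%.3g)", path,
                 min(dat), max(dat)), call. = FALSE)
  vol <- gm_volume(pmin(pmax(dat, 0), 1), voxel_size = vs,
                   subject_id = subject_id)
  if (reslice) reslice_to_2mm(vol) else vol
}

#' Write / read an atlas parcellation
#'
#' The label volume goes to NIfTI (integer labels, 0 = background) and the
#' region table to CSV (`region_id`, `name`, `grouping`).
#'
#' @param atlas a `gm_atlas`.
#' @param nii_path,csv_path output paths.
#' @return `nii_path`, invisibly.
#' @export
write_atlas <- function(atlas, nii_path, csv_path) {
  stopifnot(inherits(atlas, "gm_atlas"))
  img <- RNifti::asNifti(atlas$labels + 0L)
  img <- RNifti::asNifti(img, reference = list(pixdim = c(-1, 2, 2, 2,
                                                          rep(1, 4))))
  RNifti::writeNifti(img, nii_path, datatype = "int32")
  utils::write.csv(atlas$region_table, csv_path, row.names = FALSE)
  invisible(nii_path)
}

#' @rdname write_atlas
#' @return `read_atlas`: a `gm_atlas`.
#' @export
read_atlas <- function(nii_path, csv_path) {
  img <- RNifti::readNifti(nii_path)
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "grouping")
  if (!all(need %in% names(tab)))
    stop("atlas region table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(list(labels = array(as.integer(img), dim(img)),
                 region_table = tab[, need]),
            class = "gm_atlas")
}

# edge lists and adjacency ----------------------------------------------

#' Write a binary network as a TSV edge list
#'
#' Two 0-based node indices per line, tab-separated, no header.
#'
#' @param net an undirected [igraph::graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = FALSE) - 1L
  utils::write.table(el, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list into a binary network
#'
#' @param path edge-list TSV (0-based indices).
#' @param n_vertices total vertex count (isolated vertices included).
#' @return an undirected [igraph::graph].
#' @export
read_edge_list <- function(path, n_vertices) {
  n_vertices <- stop_if_not_count(n_vertices, "n_vertices")
  g <- igraph::make_empty_graph(n_vertices, directed = FALSE)
  if (file.size(path) > 0) {
    el <- as.matrix(utils::read.table(path, sep = "\t"))
    if (any(el < 0) || any(el >= n_vertices))
      stop("edge indices out of range", call. = FALSE)
    g <- igraph::add_edges(g, as.vector(t(el + 1L)))
  }
  g
}

#' Write a binary network as MatrixMarket sparse adjacency
#'
#' Coordinate-format MTX of the upper-triangle adjacency pattern.
#'
#' @param net an undirected [igraph::graph].
#' @param path output path (`.mtx`).
#' @return `path`, invisibly.
#' @export
write_adjacency_mtx <- function(net, path) {
  el <- igraph::as_edgelist(net, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  n <- igraph::vcount(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate pattern symmetric",
               sprintf("%d %d %d", n, n, nrow(el))), con)
  if (nrow(el))
    writeLines(sprintf("%d %d", el[, 2], el[, 1]), con)  # lower triangle
  invisible(path)
}

# cohort CSV ------------------------------------------------------------

COHORT_COLUMNS <- c("subject_id", "group", "age", "sex", "education",
                    "gm_volume", "pas", "sas", "duration_illness", "cpz_dose")

#' Write / read a cohort covariate table as CSV
#'
#' The schema is validated on read: all required columns must be present,
#' unknown columns are an error (except per-subject metric columns such as
#' `sigma`, `regularity` and `gm_target`, which round-trip), `group` must be
#' patient/control, PAS must lie in \[0, 61\] and SAS in \[0, 40\] or be
#' missing.
#'
#' @param covariates cohort data frame.
#' @param path CSV path.
#' @return `path` (write) / the validated data frame (read).
#' @export
write_cohort_csv <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  miss <- setdiff(COHORT_COLUMNS, names(dat))
  if (length(miss))
    stop(path, ": missing cohort columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(dat), c(COHORT_COLUMNS, "sigma", "regularity",
                                 "gm_target"))
  if (length(extra))
    stop(path, ": unknown cohort columns: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (!all(dat$group %in% c("patient", "control")))
    stop(path, ": `group` must be 'patient' or 'control'", call. = FALSE)
  if (any(!is.na(dat$pas) & (dat$pas < 0 | dat$pas > 61)))
    stop(path, ": PAS scores must lie in [0, 61]", call. = FALSE)
  if (any(!is.na(dat$sas) & (dat$sas < 0 | dat$sas > 40)))
    stop(path, ": SAS scores must lie in [0, 40]", call. = FALSE)
  dat
}

# run configuration and pipeline ----------------------------------------

#' Pipeline run configuration
#'
#' Bundles the simulation configuration with the network, metric, local-scale
#' and statistics parameters and a master seed. Every stochastic stage
#' derives its own seed from `master_seed` and the subject/region identifier.
#'
#' @param sim a [simulation_config()] describing the synthetic cohort.
#' @param gm_voxel_threshold,min_gm_voxels_per_cube node extraction.
#' @param n_perm,q permutation null size and FDR level for edges.
#' @param n_random,swap_attempts_factor reference ensemble.
#' @param levels local-scale levels to run (subset of `c("icn7",
#'   "regional")`; empty vector skips local scale).
#' @param min_avg_nodes cohort-average node filter for regional statistics.
#' @param fdr_q FDR level for the statistical families.
#' @param master_seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(),
                       gm_voxel_threshold = 0.1, min_gm_voxels_per_cube = 1L,
                       n_perm = 1e5, q = 0.05,
                       n_random = 20L, swap_attempts_factor = 10L,
                       levels = c("icn7", "regional"),
                       min_avg_nodes = 30, fdr_q = 0.05,
                       master_seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            all(levels %in% c("icn7", "regional")))
  structure(list(sim = sim, gm_voxel_threshold = gm_voxel_threshold,
                 min_gm_voxels_per_cube = as.integer(min_gm_voxels_per_cube),
                 n_perm = n_perm, q = q, n_random = as.integer(n_random),
                 swap_attempts_factor = as.integer(swap_attempts_factor),
                 levels = levels, min_avg_nodes = min_avg_nodes,
                 fdr_q = fdr_q, master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param rc a [run_config()].
#' @param path YAML file path.
#' @return `path` (save) / a [run_config()] (load).
#' @export
save_run_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  x <- unclass(rc)
  x$sim <- unclass(x$sim)
  # yaml drops names from named atomic vectors; store them as maps
  for (nm in c("sas_missing_fraction", "sex_female_fraction"))
    x$sim[[nm]] <- as.list(x$sim[[nm]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_args <- x$sim
  # named numeric vectors round-trip as lists; restore them
  for (nm in c("sas_missing_fraction", "sex_female_fraction"))
    sim_args[[nm]] <- unlist(sim_args[[nm]])
  for (nm in c("gm_volume_means_sds", "age_params", "education_params",
               "pas_params", "sas_params"))
    sim_args[[nm]] <- lapply(sim_args[[nm]], unlist)
  for (nm in c("duration_params", "cpz_params", "volume_shape"))
    sim_args[[nm]] <- unlist(sim_args[[nm]])
  sim <- do.call(simulation_config, sim_args)
  do.call(run_config, c(list(sim = sim),
                        x[setdiff(names(x), "sim")]))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, constructs every subject's global network and
#' small-worldness, optionally the local-scale (ICN and regional) metrics,
#' runs the statistical layer, and writes all artifacts to `out_dir`:
#' `atlas.nii.gz` + `atlas_regions.csv`, per-subject `nodes/*.csv` and
#' `edges/*.tsv`, `metrics_global.csv`, `metrics_local.csv`, `cohort.csv`,
#' `stats_*.csv` and `manifest.json` (configuration echo, package version
#' and md5 checksums of every output). Per-subject failures are quarantined
#' with a diagnostic and the run continues; the run errors only if no
#' subject completes.
#'
#' @param rc a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param write_subject_files write per-subject node tables and edge lists
#'   (default TRUE).
#' @return invisibly, a list with `cohort` (covariates + sigma),
#'   `metrics_local`, `stats`, `failures`, `manifest_path`.
#' @export
run_pipeline <- function(rc, out_dir, write_subject_files = TRUE) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                                sprintf(...), "\n", file = log_path,
                                append = TRUE)
  cat(NULL, file = log_path)      # truncate
  log_line("run started (master seed %d)", rc$master_seed)
  if (write_subject_files) {
    dir.create(file.path(out_dir, "nodes"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "edges"), showWarnings = FALSE)
  }
  cfg <- rc$sim
  cohort <- generate_cohort(cfg)
  cov <- cohort$covariates
  n <- nrow(cov)
  gl_rows <- vector("list", n)
  loc_rows <- vector("list", n)
  failures <- list()
  for (i in seq_len(n)) {
    sid <- cov$subject_id[i]
    res <- tryCatch({
      sres <- construct_gm_network(
        cohort$volumes[[sid]], rc$gm_voxel_threshold,
        rc$min_gm_voxels_per_cube, n_perm = rc$n_perm, q = rc$q,
        n_random = rc$n_random,
        swap_attempts_factor = rc$swap_attempts_factor,
        seed = derive_seed(rc$master_seed, "net", sid))
      if (write_subject_files) {
        nod <- data.frame(node_index = seq_len(sres$nodes$n_nodes) - 1L,
                          x = sres$nodes$origins[, 1],
                          y = sres$nodes$origins[, 2],
                          z = sres$nodes$origins[, 3])
        utils::write.csv(nod, file.path(out_dir, "nodes",
                                        paste0(sid, ".csv")),
                         row.names = FALSE)
        write_edge_list(sres$network,
                        file.path(out_dir, "edges", paste0(sid, ".tsv")))
      }
      loc <- NULL
      for (lev in rc$levels) {
        lr <- regional_small_worldness(
          cohort$volumes[[sid]], cohort$atlas, level = lev,
          gm_voxel_threshold = rc$gm_voxel_threshold,
          min_gm_voxels_per_cube = rc$min_gm_voxels_per_cube,
          n_perm = rc$n_perm, q = rc$q, n_random = rc$n_random,
          swap_attempts_factor = rc$swap_attempts_factor,
          seed = derive_seed(rc$master_seed, "local", lev, sid))
        loc <- rbind(loc, lr)
      }
      list(metrics = sres$metrics, local = loc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      log_line("subject %s FAILED: %s", sid, conditionMessage(res))
      next
    }
    log_line("subject %s done (sigma %.4f)", sid, res$metrics$sigma)
    gl <- as.data.frame(res$metrics)
    gl$subject_id <- sid
    gl_rows[[i]] <- gl
    loc_rows[[i]] <- res$local
  }
  gl_df <- do.call(rbind, gl_rows)
  if (is.null(gl_df) || nrow(gl_df) == 0L)
    stop("pipeline failed for every subject", call. = FALSE)
  loc_df <- do.call(rbind, loc_rows)
  cov <- merge(cov, gl_df[, c("subject_id", "sigma")], by = "subject_id",
               all.x = TRUE, sort = FALSE)
  stats <- run_full_statistics(cov[!is.na(cov$sigma), ], regional = loc_df,
                               q = rc$fdr_q, min_avg_nodes = rc$min_avg_nodes)
  # artifacts
  write_atlas(cohort$atlas, file.path(out_dir, "atlas.nii.gz"),
              file.path(out_dir, "atlas_regions.csv"))
  write_cohort_csv(cov, file.path(out_dir, "cohort.csv"))
  utils::write.csv(gl_df, file.path(out_dir, "metrics_global.csv"),
                   row.names = FALSE)
  if (!is.null(loc_df))
    utils::write.csv(loc_df, file.path(out_dir, "metrics_local.csv"),
                     row.names = FALSE)
  for (nm in c("demographics", "ancova", "correlations", "posthoc")) {
    if (!is.null(stats[[nm]]))
      utils::write.csv(stats[[nm]], file.path(out_dir,
                                              paste0("stats_", nm, ".csv")),
                       row.names = FALSE)
  }
  log_line("statistics complete: %d ANCOVA rows, %d correlation rows",
           nrow(stats$ancova),
           if (is.null(stats$correlations)) 0L else nrow(stats$correlations))
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json", "run.log"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gmnet")),
    master_seed = rc$master_seed,
    config = unclass(rc$sim),
    network_params = rc[c("gm_voxel_threshold", "min_gm_voxels_per_cube",
                          "n_perm", "q", "n_random", "swap_attempts_factor",
                          "levels", "min_avg_nodes", "fdr_q")],
    n_failures = length(failures), failures = failures,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cov, metrics_local = loc_df, stats = stats,
                 failures = failures, manifest_path = manifest_path))
}
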