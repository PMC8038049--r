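## Atlas-masked local-scale analysis.
##
## Per-region node subsets are formed by majority vote of each cube's 27
## voxel labels (background excluded, ties to the smallest region id), at two
## levels: the 7 intrinsic connectivity networks (unions of member regions)
## and individual atlas regions. Each region's network is constructed with
## the identical procedure used at the global scale, including a region-local
## permutation null; regions whose cohort-average node count falls below 30
## are omitted from statistics.

#' Assign cube nodes to atlas regions
#'
#' Each cube node is assigned to the region holding the majority of its 27
#' voxels' labels; background (0) is excluded from the vote and ties go to
#' the smallest region id. Nodes whose 27 voxels are all background stay
#' unassigned (NA).
#'
#' @param nodes a `gm_nodeset`.
#' @param atlas a `gm_atlas` on the same voxel grid.
#' @return integer vector of length `nodes$n_nodes` with region ids (NA =
#'   unassigned).
#' @export
assign_nodes_to_regions <- function(nodes, atlas) {
  stopifnot(inherits(nodes, "gm_nodeset"), inherits(atlas, "gm_atlas"))
  d <- dim(atlas$labels)
  if (nodes$n_nodes > 0 && any(nodes$origins + 3L > matrix(d, nodes$n_nodes, 3,
                                                           byrow = TRUE)))
    stop("atlas grid does not cover the node grid (shape mismatch)",
         call. = FALSE)
  if (nodes$n_nodes == 0L) return(integer(0))
  if (nrow(atlas$region_table) == 0L)
    return(rep(NA_integer_, nodes$n_nodes))
  L <- vapply(1:27, function(k) {
    dd <- arrayInd(k, c(3L, 3L, 3L)) - 1L
    atlas$labels[cbind(nodes$origins[, 1] + dd[1] + 1L,
                       nodes$origins[, 2] + dd[2] + 1L,
                       nodes$origins[, 3] + dd[3] + 1L)]
  }, integer(nodes$n_nodes))
  L <- matrix(L, nrow = nodes$n_nodes)
  majority_region(L, max(atlas$region_table$region_id))
}

# row-wise majority label of an n x 27 label matrix, background (0) excluded,
# ties to the smallest region id; all-background rows give NA
majority_region <- function(L, n_regions) {
  counts <- vapply(seq_len(n_regions), function(r) rowSums(L == r),
                   numeric(nrow(L)))
  counts <- matrix(counts, nrow = nrow(L))
  out <- max.col(counts, ties.method = "first")
  out[rowSums(counts) == 0] <- NA_integer_
  as.integer(out)
}

#' Subset a node set
#'
#' @param nodes a `gm_nodeset`.
#' @param idx node indices to keep.
#' @return a `gm_nodeset` restricted to `idx` (order preserved).
#' @export
subset_nodes <- function(nodes, idx) {
  stopifnot(inherits(nodes, "gm_nodeset"))
  structure(list(subject_id = nodes$subject_id,
                 origins = nodes$origins[idx, , drop = FALSE],
                 intensities = nodes$intensities[idx, , drop = FALSE],
                 n_nodes = length(idx)),
            class = "gm_nodeset")
}

#' Cohort-level region filter on average node count
#'
#' A region is retained iff its mean node count across all subjects (both
#' groups pooled) is at least `min_avg`; regions with an average below the
#' threshold are omitted from statistics. The retained set is by construction
#' identical for both groups.
#'
#' @param counts numeric matrix, subjects x regions (dimnames give region
#'   ids/names), or a data frame coercible to one.
#' @param min_avg minimum average node count (default 30; a region at exactly
#'   30 is retained).
#' @return character vector of retained region column names.
#' @export
filter_regions_min_nodes <- function(counts, min_avg = 30) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("empty cohort: no subject rows", call. = FALSE)
  stop_if_not_scalar(min_avg, "min_avg", 0)
  keep <- colMeans(counts) >= min_avg
  colnames(counts)[keep]
}

#' Per-region small-worldness for one subject
#'
#' Runs the identical network construction used at the global scale
#' (similarity matrix, region-local permutation null, FDR binarization,
#' degree-matched reference ensemble) on each region's node subset, at the
#' chosen level: `"icn7"` groups regions into their 7 intrinsic connectivity
#' networks; `"regional"` treats every atlas region separately. Regions
#' failing the preconditions (fewer than `min_nodes` nodes, edgeless
#' networks) yield rows of missing values with an explicit status, never
#' silent zeros.
#'
#' @param volume a [gm_volume()] (2 mm isotropic).
#' @param atlas a `gm_atlas` on the same grid.
#' @param level `"icn7"` or `"regional"`.
#' @param gm_voxel_threshold,min_gm_voxels_per_cube node extraction
#'   parameters, as in [extract_cube_nodes()].
#' @param n_perm permutation-null size per region (>= 1000).
#' @param q FDR level for binarization.
#' @param n_random,swap_attempts_factor reference-ensemble parameters, as in
#'   [small_worldness()].
#' @param min_nodes minimum node count to attempt construction (default 2).
#' @param seed integer seed; per-region streams are derived from it.
#' @return data frame with one row per region/ICN: `subject_id`, `scope`,
#'   `region_id`, `n_nodes`, `n_edges`, `sigma`, `gamma`, `lam`,
#'   `component_fraction`, `status`.
#' @export
regional_small_worldness <- function(volume, atlas,
                                     level = c("icn7", "regional"),
                                     gm_voxel_threshold = 0.1,
                                     min_gm_voxels_per_cube = 1L,
                                     n_perm = 1e5, q = 0.05,
                                     n_random = 20L, swap_attempts_factor = 10L,
                                     min_nodes = 2L, seed = 1L) {
  level <- match.arg(level)
  stopifnot(inherits(volume, "gm_volume"), inherits(atlas, "gm_atlas"))
  nodes <- extract_cube_nodes(volume, gm_voxel_threshold, min_gm_voxels_per_cube)
  region_of <- assign_nodes_to_regions(nodes, atlas)
  tab <- atlas$region_table
  if (level == "icn7") {
    groupings <- unique(tab$grouping[!is.na(tab$grouping) & tab$grouping != "none"])
    scopes <- lapply(groupings, function(g)
      which(region_of %in% tab$region_id[!is.na(tab$grouping) & tab$grouping == g]))
    scope_ids <- groupings
  } else {
    scopes <- lapply(tab$region_id, function(r) which(region_of %in% r))
    scope_ids <- as.character(tab$region_id)
  }
  rows <- lapply(seq_along(scopes), function(k) {
    idx <- scopes[[k]]
    base <- data.frame(subject_id = volume$subject_id,
                       scope = paste0(if (level == "icn7") "icn:" else "region:",
                                      scope_ids[k]),
                       region_id = scope_ids[k], n_nodes = length(idx),
                       n_edges = NA_integer_, sigma = NA_real_,
                       gamma = NA_real_, lam = NA_real_,
                       component_fraction = NA_real_,
                       status = "too_few_nodes", stringsAsFactors = FALSE)
    if (length(idx) < max(2L, min_nodes)) return(base)
    sub <- subset_nodes(nodes, idx)
    sim <- build_similarity_matrix(sub)
    nul <- estimate_null(sub, n_perm = n_perm,
                         seed = derive_seed(seed, "null", scope_ids[k]))
    net <- binarize_fdr(sim, nul, q = q)
    base$n_edges <- igraph::ecount(net)
    if (igraph::ecount(net) < 1L || igraph::vcount(net) < 3L) {
      base$status <- "degenerate_network"
      return(base)
    }
    met <- small_worldness(net, n_random = n_random,
                           swap_attempts_factor = swap_attempts_factor,
                           seed = derive_seed(seed, "sw", scope_ids[k]))
    base$sigma <- met$sigma; base$gamma <- met$gamma; base$lam <- met$lam
    base$component_fraction <- met$component_fraction
    base$status <- met$status
    base
  })
  do.call(rbind, rows)
}
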