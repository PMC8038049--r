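## Single-subject grey matter similarity network construction.
##
## A segmented grey-matter (GM) partial-volume map is tiled into non-
## overlapping 3x3x3-voxel cubes; each cube with enough GM becomes a graph
## node carrying its 27 raw intensities. Edge weights are the maximum, over
## the orthogonal rotations of the cube, of the Pearson correlation between
## the two intensity vectors; the similarity matrix is binarized at a
## permutation-null threshold controlled at FDR 5% per subject.

# volumes ---------------------------------------------------------------

#' Grey matter partial-volume map
#'
#' Lightweight container for one subject's segmented GM map: a 3D array of
#' partial-volume estimates in \[0, 1\] plus the voxel size in mm.
#'
#' @param data 3D numeric array with values in \[0, 1\].
#' @param voxel_size numeric length-3, mm per axis (default isotropic 2 mm).
#' @param subject_id identifier.
#' @return An object of class `gm_volume`.
#' @export
gm_volume <- function(data, voxel_size = c(2, 2, 2), subject_id = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (anyNA(data) || min(data) < 0 || max(data) > 1)
    stop("GM partial-volume values must lie in [0, 1]", call. = FALSE)
  voxel_size <- rep_len(as.double(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel sizes must be positive", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size,
                 subject_id = as.character(subject_id)),
            class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume> subject %s: %s voxels @ %s mm, GM volume %.1f cm^3\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              total_gm_volume(x)))
  invisible(x)
}

#' Total grey matter volume of a map, in cm^3
#'
#' Sum of partial-volume estimates times the voxel volume (the `fslstats`
#' convention for segmented tissue volume).
#'
#' @param volume a [gm_volume()].
#' @return scalar, cm^3.
#' @export
total_gm_volume <- function(volume) {
  stopifnot(inherits(volume, "gm_volume"))
  sum(volume$data) * prod(volume$voxel_size) / 1000
}

#' Reslice a GM map to isotropic 2 mm voxels
#'
#' Trilinear interpolation onto a 2 mm isotropic grid covering the same
#' physical extent (voxel-center convention); values are re-clamped to
#' \[0, 1\]. A volume that is already 2 mm isotropic is passed through
#' unchanged.
#'
#' @param volume a [gm_volume()].
#' @return a [gm_volume()] on a 2 mm isotropic grid.
#' @export
reslice_to_2mm <- function(volume) {
  stopifnot(inherits(volume, "gm_volume"))
  vs <- volume$voxel_size
  if (all(abs(vs - 2) < 1e-9)) return(volume)
  d_in <- dim(volume$data)
  d_out <- pmax(1L, as.integer(round(d_in * vs / 2)))
  # fractional 0-based input index of each output voxel center, per axis
  ax <- lapply(1:3, function(k) {
    xi <- (seq_len(d_out[k]) - 1) * 2 / vs[k]
    pmin(pmax(xi, 0), d_in[k] - 1)
  })
  i0 <- lapply(1:3, function(k) pmin(floor(ax[[k]]), max(d_in[k] - 2, 0)))
  w  <- lapply(1:3, function(k) ax[[k]] - i0[[k]])
  # expand to the full output grid (x fastest, matching R array order)
  gx <- rep(seq_len(d_out[1]), times = d_out[2] * d_out[3])
  gy <- rep(rep(seq_len(d_out[2]), each = d_out[1]), times = d_out[3])
  gz <- rep(seq_len(d_out[3]), each = d_out[1] * d_out[2])
  x0 <- i0[[1]][gx]; y0 <- i0[[2]][gy]; z0 <- i0[[3]][gz]
  wx <- w[[1]][gx];  wy <- w[[2]][gy];  wz <- w[[3]][gz]
  at <- function(dx, dy, dz) {
    volume$data[cbind(pmin(x0 + dx, d_in[1] - 1) + 1,
                      pmin(y0 + dy, d_in[2] - 1) + 1,
                      pmin(z0 + dz, d_in[3] - 1) + 1)]
  }
  out <- at(0, 0, 0) * (1 - wx) * (1 - wy) * (1 - wz) +
         at(1, 0, 0) * wx       * (1 - wy) * (1 - wz) +
         at(0, 1, 0) * (1 - wx) * wy       * (1 - wz) +
         at(1, 1, 0) * wx       * wy       * (1 - wz) +
         at(0, 0, 1) * (1 - wx) * (1 - wy) * wz +
         at(1, 0, 1) * wx       * (1 - wy) * wz +
         at(0, 1, 1) * (1 - wx) * wy       * wz +
         at(1, 1, 1) * wx       * wy       * wz
  out <- pmin(pmax(out, 0), 1)
  gm_volume(array(out, d_out), voxel_size = c(2, 2, 2),
            subject_id = volume$subject_id)
}

# cube nodes ------------------------------------------------------------

#' Extract 3x3x3-voxel cube nodes from a GM map
#'
#' The volume is tiled by non-overlapping 3x3x3 cubes anchored at the array
#' origin (incomplete trailing cubes are dropped). A cube becomes a node iff
#' at least `min_gm_voxels_per_cube` of its 27 voxels exceed
#' `gm_voxel_threshold`. Each node stores its raw 27 intensities in canonical
#' x-fastest order, and its 0-based origin (lowest-index corner, a multiple
#' of 3 on every axis).
#'
#' @param volume a [gm_volume()] (2 mm isotropic).
#' @param gm_voxel_threshold GM partial-volume value a voxel must exceed to
#'   count as grey matter (default 0.1).
#' @param min_gm_voxels_per_cube minimum number of supra-threshold voxels for
#'   a cube to become a node (default 1; permissive, preserves node count).
#' @return An object of class `gm_nodeset`: `subject_id`, `origins`
#'   (n x 3 integer, 0-based), `intensities` (n x 27), `n_nodes`.
#' @export
extract_cube_nodes <- function(volume, gm_voxel_threshold = 0.1,
                               min_gm_voxels_per_cube = 1L) {
  stopifnot(inherits(volume, "gm_volume"))
  stop_if_not_scalar(gm_voxel_threshold, "gm_voxel_threshold", 0, 1 - 1e-12)
  min_gm_voxels_per_cube <- stop_if_not_count(min_gm_voxels_per_cube,
                                              "min_gm_voxels_per_cube")
  if (min_gm_voxels_per_cube > 27L)
    stop("`min_gm_voxels_per_cube` must be <= 27", call. = FALSE)
  d <- dim(volume$data)
  nb <- d %/% 3L
  if (any(nb < 1L)) {
    return(structure(list(subject_id = volume$subject_id,
                          origins = matrix(integer(), 0, 3),
                          intensities = matrix(numeric(), 0, 27),
                          n_nodes = 0L),
                     class = "gm_nodeset"))
  }
  a <- volume$data[seq_len(3L * nb[1]), seq_len(3L * nb[2]), seq_len(3L * nb[3]),
                   drop = FALSE]
  dim(a) <- c(3L, nb[1], 3L, nb[2], 3L, nb[3])
  a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))      # (dx,dy,dz, cx,cy,cz)
  dim(a) <- c(27L, prod(nb))
  intens <- t(a)                                 # cubes x 27, x-fastest
  ncube <- prod(nb)
  ori <- cbind(rep(seq_len(nb[1]) - 1L, times = nb[2] * nb[3]),
               rep(rep(seq_len(nb[2]) - 1L, each = nb[1]), times = nb[3]),
               rep(seq_len(nb[3]) - 1L, each = nb[1] * nb[2])) * 3L
  keep <- rowSums(intens > gm_voxel_threshold) >= min_gm_voxels_per_cube
  structure(list(subject_id = volume$subject_id,
                 origins = ori[keep, , drop = FALSE],
                 intensities = intens[keep, , drop = FALSE],
                 n_nodes = sum(keep)),
            class = "gm_nodeset")
}

#' Construct a node set directly from intensity vectors
#'
#' Mainly useful for simulation studies and tests that need cube nodes with a
#' prescribed intensity structure, bypassing volume tiling.
#'
#' @param intensities n x 27 numeric matrix, one row per node (canonical
#'   x-fastest voxel order).
#' @param origins optional n x 3 integer matrix of 0-based origins (multiples
#'   of 3); defaults to a line of cubes along x.
#' @param subject_id identifier.
#' @return a `gm_nodeset`.
#' @export
node_set <- function(intensities, origins = NULL, subject_id = "nodes") {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != 27L)
    stop("`intensities` must have 27 columns", call. = FALSE)
  n <- nrow(intensities)
  if (is.null(origins))
    origins <- cbind((seq_len(n) - 1L) * 3L, 0L, 0L)
  origins <- matrix(as.integer(origins), n, 3)
  if (any(origins %% 3L != 0L) || any(origins < 0L))
    stop("origins must be non-negative multiples of 3", call. = FALSE)
  if (anyDuplicated(split(origins, seq_len(n))))
    stop("duplicate node origins", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), origins = origins,
                 intensities = intensities, n_nodes = n),
            class = "gm_nodeset")
}

#' @export
print.gm_nodeset <- function(x, ...) {
  cat(sprintf("<gm_nodeset> subject %s: %d cube nodes\n", x$subject_id, x$n_nodes))
  invisible(x)
}

# rotations -------------------------------------------------------------

#' Orthogonal symmetries of the 3x3x3 cube as index permutations
#'
#' The 24 proper rotations of the cube (optionally extended to all 48
#' orthogonal symmetries including reflections) act exactly on a 3x3x3 voxel
#' grid. Each symmetry is returned as a permutation of the canonical
#' x-fastest flattening order: applying column `r` to an intensity vector
#' `b` as `b[rotations[, r]]` yields the rotated cube.
#'
#' @param include_reflections extend the set from the 24 proper rotations to
#'   all 48 orthogonal symmetries.
#' @return 27 x n_rot integer matrix of permutation indices; the first column
#'   is the identity.
#' @export
cube_rotations <- function(include_reflections = FALSE) {
  coords <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  idx_of <- function(m) (m[, 1] + 1) + 3 * (m[, 2] + 1) + 9 * (m[, 3] + 1) + 1
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms3) for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    M <- matrix(0, 3, 3)
    M[cbind(1:3, p)] <- c(s1, s2, s3)
    if (!include_reflections && round(det(M)) != 1) next
    out[[length(out) + 1L]] <- idx_of(coords %*% M)
  }
  perm <- do.call(cbind, out)
  # put the identity first (cosmetic but convenient in tests)
  id <- which(colSums(perm == 1:27) == 27L)
  perm <- perm[, c(id, setdiff(seq_len(ncol(perm)), id)), drop = FALSE]
  storage.mode(perm) <- "integer"
  perm
}

# row-standardize to unit-norm centered vectors; constant rows become zero,
# which encodes the zero-variance convention (correlation defined as 0)
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm < 1e-12] <- Inf
  x / nrm
}

#' Rotation-maximized similarity of two cube intensity vectors
#'
#' The maximum, over all cube symmetries in `rotations`, of the Pearson
#' correlation between `a` and the rotated `b`. If either vector has zero
#' variance every candidate correlation is defined as 0.
#'
#' @param a,b numeric length-27 intensity vectors in canonical order.
#' @param rotations permutation matrix from [cube_rotations()].
#' @return scalar in \[-1, 1\].
#' @export
cube_similarity <- function(a, b, rotations = cube_rotations()) {
  if (length(a) != 27L || length(b) != 27L)
    stop("cube intensity vectors must have exactly 27 entries", call. = FALSE)
  za <- standardize_rows(matrix(a, 1))[1, ]
  zb <- standardize_rows(matrix(b, 1))[1, ]
  max(vapply(seq_len(ncol(rotations)),
             function(r) sum(za * zb[rotations[, r]]), numeric(1)))
}

#' Build the full rotation-maximized similarity matrix of a node set
#'
#' Evaluates [cube_similarity()] for every unordered node pair. The
#' diagonal is set to 1 by convention and excluded from all downstream
#' analysis (only the off-diagonal entries are ever thresholded).
#'
#' @param nodes a `gm_nodeset` with at least 2 nodes.
#' @param rotations permutation matrix from [cube_rotations()].
#' @return symmetric n x n numeric matrix with entries in \[-1, 1\].
#' @export
build_similarity_matrix <- function(nodes, rotations = cube_rotations()) {
  stopifnot(inherits(nodes, "gm_nodeset"))
  n <- nodes$n_nodes
  if (n < 2L) stop("need at least 2 nodes to build a similarity matrix",
                   call. = FALSE)
  Z <- standardize_rows(nodes$intensities)
  S <- matrix(-Inf, n, n)
  for (r in seq_len(ncol(rotations)))
    S <- pmax(S, tcrossprod(Z, Z[, rotations[, r], drop = FALSE]))
  S <- pmax(S, t(S))              # exact symmetry (group is inverse-closed)
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  S
}

# permutation null ------------------------------------------------------

# permute the 27 entries of every row of `x` independently (vectorized)
permute_rows27 <- function(x) {
  n <- nrow(x)
  o <- order(rep(seq_len(n), times = 27L), stats::runif(n * 27L))
  col_of <- ((o - 1L) %/% n) + 1L            # for each row, a random column order
  cols <- as.vector(t(matrix(col_of, nrow = 27L)))   # row-major: row1's 27 cols, ...
  matrix(x[cbind(rep(seq_len(n), each = 27L), cols)], nrow = n, byrow = TRUE)
}

#' Permutation null distribution of the rotation-maximized similarity
#'
#' Draws `n_perm` random node pairs with replacement, independently permutes
#' the 27 intensities of each member, and records the rotation-maximized
#' similarity of the permuted pair. This is the reference distribution used
#' to convert observed similarities into one-sided empirical p-values.
#'
#' @param nodes a `gm_nodeset` with at least 2 nodes.
#' @param n_perm number of permuted pairs (>= 1000; default 1e5).
#' @param seed integer seed.
#' @param rotations permutation matrix from [cube_rotations()].
#' @return object of class `gm_null`: `samples` (sorted ascending), `n_perm`,
#'   `seed`.
#' @export
estimate_null <- function(nodes, n_perm = 1e5, seed = 1L,
                          rotations = cube_rotations()) {
  stopifnot(inherits(nodes, "gm_nodeset"))
  if (nodes$n_nodes < 2L) stop("need at least 2 nodes", call. = FALSE)
  n_perm <- stop_if_not_count(n_perm, "n_perm", lo = 1000L)
  samples <- with_seed(seed, {
    i <- sample.int(nodes$n_nodes, n_perm, replace = TRUE)
    j <- sample.int(nodes$n_nodes, n_perm, replace = TRUE)
    A <- permute_rows27(nodes$intensities[i, , drop = FALSE])
    B <- permute_rows27(nodes$intensities[j, , drop = FALSE])
    ZA <- standardize_rows(A)
    ZB <- standardize_rows(B)
    s <- rep(-Inf, n_perm)
    for (r in seq_len(ncol(rotations)))
      s <- pmax(s, rowSums(ZA * ZB[, rotations[, r], drop = FALSE]))
    pmin(pmax(s, -1), 1)
  })
  structure(list(samples = sort(samples), n_perm = n_perm, seed = as.integer(seed)),
            class = "gm_null")
}

#' @export
print.gm_null <- function(x, ...) {
  cat(sprintf("<gm_null> %d permuted pairs, mean %.3f, q99 %.3f\n",
              x$n_perm, mean(x$samples),
              stats::quantile(x$samples, 0.99, names = FALSE)))
  invisible(x)
}

#' Binarize a similarity matrix at an FDR-controlled permutation threshold
#'
#' Each upper-triangle similarity gets a one-sided empirical p-value
#' `P(null >= value)` with add-one smoothing, `p = (1 + #\{null >= v\}) /
#' (n_perm + 1)`; Benjamini-Hochberg is applied at level `q` over the
#' subject's full edge family, and surviving entries become edges of an
#' undirected simple graph.
#'
#' @param sim symmetric similarity matrix from [build_similarity_matrix()].
#' @param null a `gm_null` from [estimate_null()].
#' @param q FDR level (default 0.05).
#' @return an undirected [igraph::graph] on `nrow(sim)` vertices.
#' @export
binarize_fdr <- function(sim, null, q = 0.05) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop("`sim` must be a square matrix", call. = FALSE)
  if (!inherits(null, "gm_null") || length(null$samples) == 0L)
    stop("`null` must be a non-empty gm_null", call. = FALSE)
  stop_if_not_scalar(q, "q", 1e-12, 1 - 1e-12)
  n <- nrow(sim)
  ut <- which(upper.tri(sim))
  v <- sim[ut]
  n_ge <- null$n_perm - findInterval(v, null$samples, left.open = TRUE)
  p <- (1 + n_ge) / (null$n_perm + 1)
  p_adj <- stats::p.adjust(p, method = "BH")
  sel <- ut[p_adj <= q]
  ij <- arrayInd(sel, dim(sim))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ij)) g <- igraph::add_edges(g, as.vector(t(ij)))
  g
}
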