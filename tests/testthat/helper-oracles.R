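# Independent brute-force oracles and small fixtures used across the suite.

# --- independent enumeration of the 24 cube orientations -------------------
# Generates the proper rotation group of the cube by composing quarter turns
# about the x and z axes implemented with explicit index arithmetic (no shared
# code with cube_rotations()). Returns a 27 x 24 matrix of permutations of
# the canonical x-fastest flattening.
bf_cube_orientations <- function() {
  rot_x <- function(a) {           # quarter turn about x: (y,z) -> (z, 4-y)
    b <- array(0, c(3, 3, 3))
    for (x in 1:3) for (y in 1:3) for (z in 1:3) b[x, y, z] <- a[x, z, 4 - y]
    b
  }
  rot_z <- function(a) {           # quarter turn about z: (x,y) -> (y, 4-x)
    b <- array(0, c(3, 3, 3))
    for (x in 1:3) for (y in 1:3) for (z in 1:3) b[x, y, z] <- a[y, 4 - x, z]
    b
  }
  base <- array(1:27, c(3, 3, 3))
  seen <- list(as.vector(base))
  frontier <- list(base)
  while (length(frontier)) {
    nxt <- list()
    for (a in frontier) for (f in list(rot_x, rot_z)) {
      b <- f(a)
      key <- paste(as.vector(b), collapse = ",")
      if (!key %in% vapply(seen, paste, "", collapse = ",")) {
        seen[[length(seen) + 1L]] <- as.vector(b)
        nxt[[length(nxt) + 1L]] <- b
      }
    }
    frontier <- nxt
  }
  do.call(cbind, seen)
}

# --- brute-force rotation-maximized similarity -----------------------------
bf_cube_similarity <- function(a, b, perms) {
  vals <- apply(perms, 2, function(p) {
    bb <- b[p]
    if (stats::sd(a) == 0 || stats::sd(bb) == 0) 0 else stats::cor(a, bb)
  })
  max(vals)
}

# --- brute-force local clustering via adjacency powers ---------------------
bf_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(d < 2, 0, tri / (d * (d - 1) / 2))
  mean(cc)
}

# --- brute-force characteristic path length (Floyd-Warshall) ---------------
bf_path_length <- function(g) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  A <- as.matrix(igraph::as_adjacency_matrix(igraph::induced_subgraph(g, keep)))
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in 1:n) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  mean(D[upper.tri(D)])
}

# --- partial correlation via the inverse correlation matrix ----------------
bf_partial_cor <- function(x, y, covs) {
  R <- stats::cor(cbind(x, y, covs))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# --- Benjamini-Hochberg step-up rejection set by definition ----------------
bf_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rej <- logical(m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

# --- Yates chi-square by definition ----------------------------------------
bf_yates_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(pmax(0, abs(tab - E) - 0.5)^2 / E)
}

# --- fixtures ---------------------------------------------------------------
noise_nodes <- function(n, seed) {
  set.seed(seed)
  node_set(matrix(stats::runif(n * 27L), n, 27L))
}

# small simulation config on a 24^3 grid (desk-scale test conditions)
cfg24 <- function(n_patients = 4L, n_controls = 4L, ...) {
  simulation_config(n_patients = n_patients, n_controls = n_controls,
                    volume_shape = c(24L, 24L, 24L), ...)
}

# full single-subject chain: volume -> nodes -> similarity -> null -> FDR ->
# small-worldness; returns the metrics object
sigma_chain <- function(volume, n_perm = 1500, seed = 1L) {
  construct_gm_network(volume, n_perm = n_perm, seed = seed)$metrics
}

# global sigma for every subject of a cohort at reduced problem size: 1200
# permuted pairs per null, the full 20-reference ensemble with a 5x|E| swap
# budget (~3-4 successful swaps per edge; identical for every subject, so
# group comparisons are unaffected); rare per-subject failures (empty
# post-threshold network) are quarantined as NA, as in the pipeline
cohort_sigmas <- function(ch, master = 1L, n_perm = 1200) {
  vapply(seq_len(nrow(ch$covariates)), function(i)
    tryCatch(construct_gm_network(ch$volumes[[i]], n_perm = n_perm,
                                  swap_attempts_factor = 5L,
                                  seed = derive_seed(master, "subj", i))$metrics$sigma,
             error = function(e) NA_real_),
    numeric(1))
}
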