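# Network construction: cube tiling, rotation set, similarity, permutation
# null, FDR binarization.

test_that("cube rotation set is the proper rotation group of the cube", {
  R24 <- cube_rotations()
  expect_equal(ncol(R24), 24L)
  expect_equal(R24[, 1], 1:27)                       # identity first
  expect_equal(anyDuplicated(t(R24)), 0L)
  # closed under inverses
  keys <- apply(R24, 2, paste, collapse = ",")
  for (r in seq_len(24)) {
    inv <- order(R24[, r])
    expect_true(paste(inv, collapse = ",") %in% keys)
  }
  # matches an independent enumeration by composed quarter turns
  oracle <- bf_cube_orientations()
  expect_setequal(apply(R24, 2, paste, collapse = ","),
                  apply(oracle, 2, paste, collapse = ","))
  R48 <- cube_rotations(include_reflections = TRUE)
  expect_equal(ncol(R48), 48L)
  expect_equal(anyDuplicated(t(R48)), 0L)
  expect_true(all(keys %in% apply(R48, 2, paste, collapse = ",")))
})

test_that("cube similarity: identity, rotation invariance, brute-force oracle", {
  R <- cube_rotations()
  set.seed(42)
  a <- runif(27)
  expect_equal(cube_similarity(a, a), 1)
  # a rotated copy of a is a perfect match under the 24-rotation set
  for (r in c(2, 9, 24)) expect_equal(cube_similarity(a, a[R[, r]]), 1)
  # brute-force maximum over explicitly enumerated rotations
  for (i in 1:10) {
    b <- runif(27)
    expect_equal(cube_similarity(a, b), bf_cube_similarity(a, b, R),
                 tolerance = 1e-12)
    a <- b
  }
  expect_error(cube_similarity(runif(26), runif(27)), "27")
})

test_that("cube similarity is symmetric and handles zero variance", {
  set.seed(7)
  for (i in 1:5) {
    a <- runif(27); b <- runif(27)
    expect_equal(cube_similarity(a, b), cube_similarity(b, a),
                 tolerance = 1e-12)
  }
  expect_identical(cube_similarity(rep(0.5, 27), runif(27)), 0)
  expect_identical(cube_similarity(runif(27), rep(1, 27)), 0)
})

test_that("cube node extraction tiles the volume as specified", {
  v <- gm_volume(array(0.9, c(6, 6, 6)))
  nd <- extract_cube_nodes(v, gm_voxel_threshold = 0.1,
                           min_gm_voxels_per_cube = 1)
  expect_equal(nd$n_nodes, 8L)
  expect_true(all(nd$origins %% 3 == 0))
  expect_equal(anyDuplicated(nd$origins), 0L)

  expect_equal(extract_cube_nodes(gm_volume(array(1, c(5, 5, 5))))$n_nodes, 1L)
  expect_equal(extract_cube_nodes(gm_volume(array(0, c(9, 9, 9))))$n_nodes, 0L)

  # intensities are the raw voxel values in x-fastest order
  arr <- array(seq(0, 1, length.out = 216), c(6, 6, 6))
  nd <- extract_cube_nodes(gm_volume(arr), gm_voxel_threshold = 0,
                           min_gm_voxels_per_cube = 1)
  first <- nd$intensities[which(rowSums(nd$origins) == 0), ]
  expect_equal(first, as.vector(arr[1:3, 1:3, 1:3]))
  # node-count threshold honours min_gm_voxels_per_cube
  arr2 <- array(0, c(6, 6, 6)); arr2[1, 1, 1] <- 0.9
  expect_equal(extract_cube_nodes(gm_volume(arr2),
                                  min_gm_voxels_per_cube = 2)$n_nodes, 0L)
  expect_equal(extract_cube_nodes(gm_volume(arr2),
                                  min_gm_voxels_per_cube = 1)$n_nodes, 1L)
})

test_that("reslicing to 2 mm: identity, constants, volume preservation", {
  v2 <- gm_volume(array(runif(12^3), c(12, 12, 12)), voxel_size = c(2, 2, 2))
  expect_identical(reslice_to_2mm(v2), v2)

  vc <- gm_volume(array(0.4, c(10, 10, 10)), voxel_size = c(1, 1, 1))
  out <- reslice_to_2mm(vc)
  expect_equal(out$voxel_size, c(2, 2, 2))
  expect_true(all(abs(out$data - 0.4) < 1e-12))

  # 1 mm ball of radius 10 mm: foreground volume preserved within 10%
  n <- 24L
  co <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array(as.numeric((co$x - 12.5)^2 + (co$y - 12.5)^2 +
                             (co$z - 12.5)^2 <= 100), c(n, n, n))
  v1 <- gm_volume(ball, voxel_size = c(1, 1, 1))
  r <- reslice_to_2mm(v1)
  vol_in <- sum(ball) * 1                       # mm^3
  vol_out <- sum(r$data > 0.5) * 8
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.1)

  # anisotropic input comes out isotropic 2 mm
  va <- gm_volume(array(runif(8 * 8 * 16), c(8, 8, 16)),
                  voxel_size = c(2, 2, 1))
  ra <- reslice_to_2mm(va)
  expect_equal(ra$voxel_size, c(2, 2, 2))
  expect_equal(dim(ra$data), c(8L, 8L, 8L))
})

test_that("similarity matrix matches a per-pair brute-force recomputation", {
  nd <- noise_nodes(10, seed = 3)
  S <- build_similarity_matrix(nd)
  expect_equal(S, t(S))
  R <- cube_rotations()
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(S[i, j],
                 bf_cube_similarity(nd$intensities[i, ], nd$intensities[j, ], R),
                 tolerance = 1e-12)
  # identical non-constant nodes are perfectly similar
  one <- matrix(rep(runif(27), 3), 3, byrow = TRUE)
  S1 <- build_similarity_matrix(node_set(one))
  expect_equal(S1[upper.tri(S1)], rep(1, 3))
  expect_error(build_similarity_matrix(node_set(one[1, , drop = FALSE])),
               "at least 2")
})

test_that("permutation null is deterministic and distribution-consistent", {
  nd <- noise_nodes(40, seed = 5)
  n1 <- estimate_null(nd, n_perm = 2000, seed = 11)
  n2 <- estimate_null(nd, n_perm = 2000, seed = 11)
  expect_identical(n1$samples, n2$samples)
  n3 <- estimate_null(nd, n_perm = 2000, seed = 12)
  expect_false(identical(n1$samples, n3$samples))
  expect_true(all(n1$samples >= -1 & n1$samples <= 1))
  expect_false(is.unsorted(n1$samples))

  # for i.i.d. noise nodes permutation preserves the similarity distribution
  S <- build_similarity_matrix(nd)
  expect_lt(abs(mean(n1$samples) - mean(S[upper.tri(S)])), 0.05)

  # constant nodes: zero-variance convention makes every null sample 0
  cn <- node_set(matrix(0.7, 5, 27))
  expect_true(all(estimate_null(cn, n_perm = 1000, seed = 1)$samples == 0))
  expect_error(estimate_null(nd, n_perm = 500, seed = 1), ">= 1000")
})

test_that("FDR binarization matches a brute-force empirical-p + step-up oracle", {
  nd <- noise_nodes(12, seed = 9)
  S <- build_similarity_matrix(nd)
  null <- estimate_null(nd, n_perm = 1000, seed = 2)
  q <- 0.3                                 # permissive so some edges survive
  g <- binarize_fdr(S, null, q = q)
  # oracle: raw counts and step-up definition
  ut <- which(upper.tri(S))
  p <- vapply(S[ut], function(v)
    (1 + sum(null$samples >= v)) / (null$n_perm + 1), numeric(1))
  rej <- bf_bh_reject(p, q)
  want <- sort(ut[rej])
  got <- sort(which(upper.tri(S) &
                      as.matrix(igraph::as_adjacency_matrix(g)) > 0))
  expect_identical(got, want)
  expect_equal(igraph::vcount(g), 12L)
})

test_that("FDR binarization: impossible q empties the graph, lowering q never adds edges", {
  nd <- noise_nodes(15, seed = 13)
  S <- build_similarity_matrix(nd)
  null <- estimate_null(nd, n_perm = 1000, seed = 3)
  # smallest attainable adjusted p is >= 1/(n_perm+1); q below it kills all
  g0 <- binarize_fdr(S, null, q = 1e-6)
  expect_equal(igraph::ecount(g0), 0L)
  qs <- c(0.5, 0.2, 0.1, 0.05, 0.01)
  prev <- NULL
  for (q in qs) {
    e <- igraph::as_edgelist(binarize_fdr(S, null, q = q))
    key <- paste(e[, 1], e[, 2])
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("edge set is equivariant under node relabeling", {
  nd <- noise_nodes(12, seed = 21)
  S <- build_similarity_matrix(nd)
  null <- estimate_null(nd, n_perm = 1000, seed = 4)
  g <- binarize_fdr(S, null, q = 0.3)
  set.seed(1)
  perm <- sample(12)
  nd2 <- subset_nodes(nd, perm)           # relabeled node order
  S2 <- build_similarity_matrix(nd2)
  expect_equal(S2, S[perm, perm], tolerance = 1e-12)
  g2 <- binarize_fdr(S2, null, q = 0.3)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2))
  expect_equal(A2, A[perm, perm], ignore_attr = TRUE)
})

test_that("planted block structure is recovered at FDR 5%", {
  set.seed(77)
  base1 <- runif(27); base2 <- runif(27)
  blk <- function(base, k) t(replicate(k, pmin(pmax(base +
    rnorm(27, 0, 0.03), 0), 1)))
  nd <- node_set(rbind(blk(base1, 6), blk(base2, 6),
                       matrix(runif(8 * 27), 8, 27)))
  S <- build_similarity_matrix(nd)
  null <- estimate_null(nd, n_perm = 2000, seed = 5)
  g <- binarize_fdr(S, null, q = 0.05)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  within1 <- A[1:6, 1:6][upper.tri(diag(6))]
  within2 <- A[7:12, 7:12][upper.tri(diag(6))]
  expect_gte(mean(c(within1, within2)), 0.95)
  cross <- A[1:12, 13:20]
  expect_lt(mean(cross), 0.05 + 0.05)
})
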