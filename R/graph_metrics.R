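## Small-world graph metrics for binary undirected networks.
##
## sigma = gamma / lambda, where gamma = CC / <CC_rand> and
## lambda = L / <L_rand> are the clustering coefficient and characteristic
## path length normalized by their means over an ensemble of degree-matched
## random reference networks (Maslov-Sneppen double-edge swaps).

#' Mean Watts-Strogatz clustering coefficient
#'
#' Per-vertex local clustering (closed triangles over possible neighbor
#' pairs), with vertices of degree < 2 contributing 0; returns the mean over
#' all vertices.
#'
#' @param net an undirected [igraph::graph].
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) return(NaN)
  igraph::transitivity(net, type = "localaverage", isolates = "zero")
}

#' Characteristic path length
#'
#' Mean breadth-first shortest-path distance over all unordered vertex pairs
#' within the largest connected component; any disconnected remainder is
#' excluded. Standard convention for FDR-thresholded graphs, which need not
#' be connected.
#'
#' @param net an undirected [igraph::graph] with at least one edge.
#' @return scalar >= 1.
#' @export
characteristic_path_length <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0L)
    stop("characteristic path length is undefined for an edgeless graph",
         call. = FALSE)
  comp <- igraph::components(net)
  if (comp$no == 1L)
    return(igraph::mean_distance(net, directed = FALSE, unconnected = FALSE))
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  igraph::mean_distance(sub, directed = FALSE, unconnected = FALSE)
}

#' Degree-preserving randomization (Maslov-Sneppen rewiring)
#'
#' Repeated double-edge swaps that reject self-loops and duplicate edges,
#' yielding a random simple graph with exactly the source's degree sequence.
#' Graphs admitting no valid swap (e.g. a triangle) come back unchanged.
#'
#' @param net an undirected simple [igraph::graph] with >= 2 edges.
#' @param swap_attempts number of attempted swaps.
#' @param seed integer seed (deterministic output for fixed inputs).
#' @return an undirected [igraph::graph] with the same degree sequence.
#' @export
randomize_degree_preserving <- function(net, swap_attempts, seed = 1L) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) < 2L) return(net)
  swap_attempts <- stop_if_not_count(swap_attempts, "swap_attempts")
  with_seed(seed,
    igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                               niter = swap_attempts)))
}

#' Small-worldness of a binary network
#'
#' Builds `n_random` degree-preserving random references (seeds derived
#' deterministically from `seed`), computes ensemble means of the clustering
#' coefficient and characteristic path length (both under the same
#' largest-component convention as the target), and returns
#' `gamma = CC / <CC_rand>`, `lambda = L / <L_rand>`, `sigma = gamma /
#' lambda`. If an ensemble mean is 0 the normalized metrics are undefined
#' and `status` is set accordingly (no silent division).
#'
#' @param net an undirected [igraph::graph] with >= 3 vertices and >= 1 edge.
#' @param n_random reference ensemble size (default 20).
#' @param swap_attempts_factor attempted swaps per reference, as a multiple
#'   of the edge count (default 10).
#' @param seed integer seed.
#' @return object of class `network_metrics`: a list with `n_nodes`,
#'   `n_edges`, `cc_raw`, `L_raw`, `cc_rand_mean`, `L_rand_mean`, `gamma`,
#'   `lam`, `sigma`, `n_random`, `component_fraction`, `status`
#'   ("ok" or "undefined_sigma").
#' @export
small_worldness <- function(net, n_random = 20L, swap_attempts_factor = 10L,
                            seed = 1L) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) < 3L || igraph::ecount(net) < 1L)
    stop("small-worldness needs >= 3 vertices and >= 1 edge", call. = FALSE)
  n_random <- stop_if_not_count(n_random, "n_random")
  swap_attempts_factor <- stop_if_not_count(swap_attempts_factor,
                                            "swap_attempts_factor")
  cc <- clustering_coefficient(net)
  L <- characteristic_path_length(net)
  swaps <- swap_attempts_factor * igraph::ecount(net)
  cc_r <- numeric(n_random)
  L_r <- numeric(n_random)
  for (k in seq_len(n_random)) {
    ref <- randomize_degree_preserving(net, swaps,
                                       seed = derive_seed(seed, "ref", k))
    cc_r[k] <- clustering_coefficient(ref)
    L_r[k] <- characteristic_path_length(ref)
  }
  comp <- igraph::components(net)
  out <- list(n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
              cc_raw = cc, L_raw = L,
              cc_rand_mean = mean(cc_r), L_rand_mean = mean(L_r),
              gamma = NA_real_, lam = NA_real_, sigma = NA_real_,
              n_random = n_random,
              component_fraction = max(comp$csize) / igraph::vcount(net),
              status = "ok")
  if (out$cc_rand_mean <= 0 || out$L_rand_mean <= 0) {
    out$status <- "undefined_sigma"
  } else {
    out$gamma <- cc / out$cc_rand_mean
    out$lam <- L / out$L_rand_mean
    out$sigma <- out$gamma / out$lam
  }
  structure(out, class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> n=%d, |E|=%d, CC=%.3f, L=%.3f, gamma=%.3f, lambda=%.3f, sigma=%.3f (%s)\n",
    x$n_nodes, x$n_edges, x$cc_raw, x$L_raw, x$gamma, x$lam, x$sigma, x$status))
  invisible(x)
}

#' Flatten network metrics to a one-row data frame
#'
#' @param x a `network_metrics` object.
#' @param row.names,optional,... passed through (unused).
#' @return one-row data frame with the metric fields.
#' @export
as.data.frame.network_metrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(n_nodes = x$n_nodes, n_edges = x$n_edges, cc_raw = x$cc_raw,
             L_raw = x$L_raw, cc_rand_mean = x$cc_rand_mean,
             L_rand_mean = x$L_rand_mean, gamma = x$gamma, lam = x$lam,
             sigma = x$sigma, component_fraction = x$component_fraction,
             status = x$status, stringsAsFactors = FALSE)
}
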