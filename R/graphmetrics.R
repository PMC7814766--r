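#' Watts-Strogatz local clustering coefficient
#'
#' Per node: the number of edges among the node's neighbors divided by all
#' possible edges among them. Nodes with degree < 2 get 0 (the Brain
#' Connectivity Toolbox convention). Computed from the adjacency matrix as
#' diag(A^3) / (k (k - 1)), which keeps the permutation engine fast.
#'
#' @param graph A `binary_graph` (0/1 symmetric adjacency, zero diagonal).
#' @return List with `per_node` values and their unweighted `mean`.
#' @export
clustering_coefficient <- function(graph) {
  A <- unclass(graph)
  k <- rowSums(A)
  A2 <- A %*% A
  triangles <- rowSums(A2 * A)        # = diag(A %*% A %*% A)
  denom <- k * (k - 1)
  cc <- ifelse(denom > 0, triangles / denom, 0)
  names(cc) <- rownames(A)
  list(per_node = cc, mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all reachable ordered node pairs. If the
#' graph is disconnected, unreachable pairs are dropped and `disconnected` is
#' set; the analysis grid is normally chosen so that networks are fully
#' connected and the flag stays FALSE.
#'
#' @param graph A `binary_graph` with at least 2 nodes.
#' @return List with `L`, `disconnected`, and `n_pairs_used`.
#' @export
characteristic_path_length <- function(graph) {
  A <- unclass(graph)
  if (nrow(A) < 2L) stop("graph must have at least 2 nodes")
  if (sum(A) == 0) stop("graph has no edges")
  D <- igraph::distances(as_igraph(graph))
  d <- D[upper.tri(D)]
  reachable <- is.finite(d)
  list(L = mean(d[reachable]),
       disconnected = !all(reachable),
       n_pairs_used = sum(reachable))
}

#' Global efficiency
#'
#' The default follows the literal definition E = 1/L (inverse characteristic
#' path length). `variant = "mean_inverse_distance"` computes the
#' Latora-Marchiori efficiency, the mean of inverse pairwise distances
#' (unreachable pairs contribute 0); the two definitions differ on any graph
#' whose distances are not all equal.
#'
#' @param graph A `binary_graph`.
#' @param variant `"inverse_L"` (default) or `"mean_inverse_distance"`.
#' @return Efficiency value (scalar).
#' @export
global_efficiency <- function(graph,
                              variant = c("inverse_L", "mean_inverse_distance")) {
  variant <- match.arg(variant)
  if (variant == "inverse_L") {
    return(1 / characteristic_path_length(graph)$L)
  }
  D <- igraph::distances(as_igraph(graph))
  d <- D[upper.tri(D)]
  mean(1 / d)                         # Inf distances -> 0 contribution
}

#' Degree-preserving random reference graph
#'
#' Maslov-Sneppen double-edge swaps (10 x |E| attempted swaps) on a copy of
#' the graph, preserving the degree sequence exactly. Used as the null model
#' for small-worldness normalization.
#'
#' @param graph A `binary_graph` with at least 2 edges.
#' @param seed RNG seed.
#' @return A rewired `binary_graph` with the same degree sequence.
#' @export
random_reference <- function(graph, seed = 1L) {
  A <- unclass(graph)
  n_edges <- sum(A) / 2
  if (n_edges < 2) stop("graph must have at least 2 edges")
  g <- as_igraph(graph)
  rg <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = 10 * n_edges)))
  B <- as.matrix(igraph::as_adjacency_matrix(rg))
  storage.mode(B) <- "integer"
  dimnames(B) <- dimnames(A)
  if (all(B == A)) {
    warning("rewiring left the graph unchanged (no swappable edge pairs?)")
  }
  structure(B, class = class(graph), density = attr(graph, "density"),
            achieved_density = attr(graph, "achieved_density"),
            group = attr(graph, "group"))
}

#' Small-worldness
#'
#' Humphries-Gurney sigma = (C / C_rand) / (L / L_rand), where C and L are the
#' graph's mean clustering coefficient and characteristic path length, and
#' C_rand, L_rand are means over `n_rand` degree-preserving random references.
#' sigma > 1 indicates small-world organization (high clustering at near-random
#' path length).
#'
#' @param graph A `binary_graph`.
#' @param n_rand Number of random references (default 100).
#' @param seed RNG seed (reference seeds are derived from it).
#' @return List with `sigma`, `C`, `L`, `C_rand`, `L_rand`, `sigma_sd` (the
#'   Monte-Carlo SD of per-reference sigmas) and `disconnected`.
#' @export
small_worldness <- function(graph, n_rand = 100L, seed = 1L) {
  C <- clustering_coefficient(graph)$mean
  pl <- characteristic_path_length(graph)
  seeds <- derive_seeds(seed, paste0("ref", seq_len(n_rand)))
  Cr <- numeric(n_rand)
  Lr <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    ref <- random_reference(graph, seed = seeds[i])
    Cr[i] <- clustering_coefficient(ref)$mean
    Lr[i] <- characteristic_path_length(ref)$L
  }
  if (mean(Cr) == 0) stop("reference clustering is zero; cannot normalize")
  sigma_i <- (C / Cr) / (pl$L / Lr)
  list(sigma = (C / mean(Cr)) / (pl$L / mean(Lr)),
       C = C, L = pl$L, C_rand = mean(Cr), L_rand = mean(Lr),
       sigma_sd = stats::sd(sigma_i), disconnected = pl$disconnected)
}

#' Eigenvector centrality
#'
#' Entries of the principal eigenvector of the adjacency matrix, fixed to the
#' nonnegative (Perron) sign convention and unit Euclidean norm. On a
#' disconnected graph the vector is supported on the component with the
#' largest leading eigenvalue; `component_restricted` flags that case.
#'
#' @param graph A non-empty `binary_graph`.
#' @return List with `centrality` (named vector) and `component_restricted`.
#' @export
eigenvector_centrality <- function(graph) {
  A <- unclass(graph)
  if (nrow(A) < 1L || sum(A) == 0) stop("graph has no edges")
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8) {
    stop("leading eigenvector is not sign-consistent (degenerate spectrum)")
  }
  v[v < 0] <- 0
  v <- v / sqrt(sum(v^2))
  names(v) <- rownames(A)
  g <- as_igraph(graph)
  list(centrality = v,
       component_restricted = igraph::components(g)$no > 1L)
}

#' Density-averaged hub profile
#'
#' Averages each region's eigenvector centrality over a coarse density grid
#' (default: strongest 5-35% of links in 5% increments), z-scores the averages
#' across regions, and flags hubs where z > `z_threshold` (default 1.5).
#'
#' @param matrix A `cov_matrix`.
#' @param grid Densities to average over.
#' @param z_threshold Hub cutoff on the z-scored average centrality.
#' @return A `hub_profile` data frame: region, mean_centrality, z, hub.
#' @export
hub_profile <- function(matrix, grid = seq(0.05, 0.35, by = 0.05),
                        z_threshold = 1.5) {
  cents <- vapply(grid, function(d) {
    eigenvector_centrality(threshold_density(matrix, d))$centrality
  }, numeric(nrow(matrix)))
  m <- rowMeans(cents)
  s <- stats::sd(m)
  if (s <= 1e-12 * max(abs(m), 1)) {
    stop("centrality is constant across regions; z-score undefined")
  }
  z <- (m - mean(m)) / s
  regions <- rownames(matrix)
  if (is.null(regions)) regions <- region_names(nrow(matrix))
  out <- data.frame(region = regions, mean_centrality = m, z = z,
                    hub = z > z_threshold, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("hub_profile", "data.frame")
  out
}

#' Strength assortativity of a network
#'
#' Assortative-mixing coefficient over edges, with a supplied per-node
#' strength (here: the density-averaged eigenvector centrality). For edge i
#' with endpoint strengths j_i and k_i, and M edges,
#' \deqn{r = \frac{M^{-1}\sum_i j_i k_i - \left[M^{-1}\sum_i \tfrac12 (j_i + k_i)\right]^2}
#'            {M^{-1}\sum_i \tfrac12 (j_i^2 + k_i^2) - \left[M^{-1}\sum_i \tfrac12 (j_i + k_i)\right]^2}}
#' Positive r: nodes connect to nodes of similar strength (hubs with hubs).
#'
#' @param graph A `binary_graph` with at least 2 edges.
#' @param strength Numeric per-node strength values, in node order.
#' @return Assortativity coefficient in [-1, 1].
#' @export
assortativity_strength <- function(graph, strength) {
  A <- unclass(graph)
  if (length(strength) != nrow(A)) {
    stop("strength must have one value per node")
  }
  ep <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  M <- nrow(ep)
  if (M < 2L) stop("graph must have at least 2 edges")
  j <- strength[ep[, 1L]]
  k <- strength[ep[, 2L]]
  mu <- mean((j + k) / 2)
  num <- mean(j * k) - mu^2
  den <- mean((j^2 + k^2) / 2) - mu^2
  if (abs(den) < 1e-15) {
    stop("assortativity undefined: all endpoint strengths are equal")
  }
  num / den
}
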