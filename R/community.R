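# weights input: cov_matrix or plain symmetric matrix; negatives and the
# diagonal are removed before community detection (positive weighted network).
positive_weights <- function(weights) {
  W <- unclass(as.matrix(weights))
  W[W < 0] <- 0
  diag(W) <- 0
  if (sum(W) == 0) stop("no positive weights left in the network")
  W
}

# canonical labeling: modules renumbered 1..K in order of first appearance
canonical_partition <- function(labels, regions = NULL) {
  lab <- match(labels, unique(labels))
  names(lab) <- if (!is.null(regions)) regions else names(labels)
  lab
}

new_partition <- function(labels, group = NA_character_, stage = "single-run") {
  structure(as.integer(labels), names = names(labels),
            class = "partition",
            n_modules = length(unique(labels)),
            group = group, stage = stage)
}

#' Single Louvain run on the positive weighted network
#'
#' Standard Louvain modularity maximization (resolution 1.0) on the weighted
#' graph of positive connections. The node visit order is randomized by the
#' seed, so different seeds can return different local optima — the reason the
#' consensus procedure exists.
#'
#' @param weights A `cov_matrix` or symmetric weight matrix; negative entries
#'   are removed.
#' @param seed RNG seed controlling the randomized node order.
#' @return A `partition`: integer module label per region, labels contiguous
#'   from 1.
#' @export
louvain_once <- function(weights, seed = 1L) {
  W <- positive_weights(weights)
  R <- nrow(W)
  with_seed(seed, {
    perm <- sample.int(R)                       # randomize node visit order
    Wp <- W[perm, perm]
    g <- igraph::graph_from_adjacency_matrix(Wp, mode = "undirected",
                                             weighted = TRUE)
    cl <- igraph::cluster_louvain(g)
    memb <- integer(R)
    memb[perm] <- igraph::membership(cl)
  })
  lab <- canonical_partition(memb, rownames(W))
  new_partition(lab, group = attr(weights, "group"), stage = "single-run")
}

# co-assignment indicator average over a list of partitions
agreement_matrix <- function(partitions) {
  R <- length(partitions[[1L]])
  D <- matrix(0, R, R)
  for (p in partitions) {
    D <- D + outer(p, p, "==")
  }
  D <- D / length(partitions)
  diag(D) <- 1
  D
}

#' Consensus Louvain partition
#'
#' Stabilizes Louvain's run-to-run variability: (1) run Louvain `n_runs` times
#' on the positive weighted network and form the consensus (agreement) matrix
#' D, where D_ij is the fraction of runs assigning regions i and j to the same
#' module; (2) zero entries below `tau`; (3) run Louvain `n_consensus_runs`
#' times on the pruned consensus matrix. If all runs agree, that partition is
#' the consensus; otherwise the agreement matrix of those runs is pruned and
#' re-clustered, up to `max_iter` iterations.
#'
#' @param weights A `cov_matrix` or symmetric weight matrix.
#' @param n_runs Initial Louvain repetitions (default 150).
#' @param tau Agreement threshold below which entries are zeroed (default 0.5).
#' @param n_consensus_runs Louvain repetitions on the consensus matrix
#'   (default 100).
#' @param seed RNG seed; all run seeds are derived from it.
#' @param max_iter Iteration cap for the consensus loop (default 20).
#' @return A `partition` with stage "consensus"; attribute `n_iterations`
#'   records how many consensus rounds were needed.
#' @export
consensus_partition <- function(weights, n_runs = 150L, tau = 0.5,
                                n_consensus_runs = 100L, seed = 1L,
                                max_iter = 20L) {
  W <- positive_weights(weights)
  seeds <- derive_seeds(seed, paste0("run", seq_len(n_runs + max_iter * n_consensus_runs)))
  runs <- lapply(seq_len(n_runs), function(i) louvain_once(W, seed = seeds[i]))
  next_seed <- n_runs
  for (iter in seq_len(max_iter)) {
    D <- agreement_matrix(runs)
    D[D < tau] <- 0
    off <- D
    diag(off) <- 0
    if (sum(off) == 0) stop("consensus matrix is fully zeroed; lower tau")
    dimnames(D) <- dimnames(W)
    runs <- lapply(seq_len(n_consensus_runs), function(i) {
      louvain_once(D, seed = seeds[next_seed + i])
    })
    next_seed <- next_seed + n_consensus_runs
    first <- unclass(runs[[1L]])
    if (all(vapply(runs, function(p) identical(unclass(p), first), logical(1)))) {
      out <- new_partition(first, group = attr(weights, "group"),
                           stage = "consensus")
      attr(out, "n_iterations") <- iter
      return(out)
    }
  }
  stop(sprintf("consensus did not converge within %d iterations", max_iter))
}

#' Newman modularity Q of a partition
#'
#' Q = sum over modules of (e_mm - a_m^2): the fraction of edge weight inside
#' each module minus the expectation under the configuration model. Works on
#' binary graphs (for the density-grid curves) and on weight matrices (for
#' diagnostics on the weighted network).
#'
#' @param x A `binary_graph` or nonnegative symmetric weight matrix.
#' @param partition A `partition` (or integer vector) covering all nodes.
#' @return Modularity Q (always in [-0.5, 1]).
#' @export
modularity_q <- function(x, partition) {
  W <- unclass(as.matrix(x))
  diag(W) <- 0
  if (any(W < 0)) stop("modularity_q expects nonnegative weights")
  lab <- as.integer(partition)
  if (length(lab) != nrow(W)) stop("partition does not cover all nodes")
  two_m <- sum(W)
  if (two_m == 0) stop("graph has no edges")
  k <- rowSums(W)
  same <- outer(lab, lab, "==")
  sum((W - outer(k, k) / two_m) * same) / two_m
}

# mean Fisher z over a set of correlations, with clipping at |r| = 1 - 1e-7
# so degenerate (perfectly correlated) synthetic inputs stay finite
mean_fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  mean(atanh(r))
}

#' Segregation index of a module
#'
#' SI = (Zw - Zb) / Zw, where Zw is the mean Fisher-z-transformed correlation
#' over region pairs inside the module and Zb the mean over pairs joining the
#' module to all other regions (all module x non-module pairs, unweighted).
#' SI near 1: the module is strongly set apart from the rest of the network;
#' SI = 0: no segregation.
#'
#' @param weights A `cov_matrix` (correlations; not thresholded).
#' @param partition A `partition` over the matrix's regions.
#' @param module Module label whose segregation is measured.
#' @return List with `si`, `z_within`, `z_between`, and pair counts.
#' @export
segregation_index <- function(weights, partition, module) {
  W <- unclass(as.matrix(weights))
  lab <- as.integer(partition)
  if (length(lab) != nrow(W)) stop("partition does not cover all regions")
  inside <- which(lab == module)
  outside <- which(lab != module)
  if (length(inside) < 2L) stop("module must contain at least 2 regions")
  if (length(outside) == 0L) {
    stop("module spans all regions; no between-module pairs exist")
  }
  win <- W[inside, inside][upper.tri(diag(length(inside)))]
  btw <- as.vector(W[inside, outside])
  zw <- mean_fisher_z(win)
  zb <- mean_fisher_z(btw)
  if (zw == 0) stop("mean within-module Fisher z is zero; SI undefined")
  list(si = (zw - zb) / zw, z_within = zw, z_between = zb,
       n_within_pairs = length(win), n_between_pairs = length(btw))
}

#' Cross-group segregation contrast with partition transfer
#'
#' Computes the segregation index of `module` in both groups using group A's
#' partition for both (the partition-transfer design: the case group's
#' modular structure is imposed on the comparison group, under the null that
#' the module is equally segregated in both). The difference SI_A - SI_B is
#' the statistic handed to the permutation engine.
#'
#' @param weights_a,weights_b `cov_matrix` objects for the two groups over
#'   the same regions.
#' @param partition_from_a The partition derived from group A.
#' @param module Module label (in group A's partition).
#' @return List with `si_a`, `si_b` and `difference` (= si_a - si_b).
#' @export
transfer_si_contrast <- function(weights_a, weights_b, partition_from_a,
                                 module) {
  if (!identical(dim(weights_a), dim(weights_b))) {
    stop("the two groups must cover the same region set")
  }
  si_a <- segregation_index(weights_a, partition_from_a, module)
  si_b <- segregation_index(weights_b, partition_from_a, module)
  list(si_a = si_a$si, si_b = si_b$si, difference = si_a$si - si_b$si)
}
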