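# Brute-force reference implementations and small fixtures used across tests.
# Each oracle is deliberately naive (loops / enumeration / power iteration) and
# independent of the package's matrix-algebra code paths.

bg <- function(A) {
  dimnames(A) <- list(sprintf("region_%03d", seq_len(nrow(A))),
                      sprintf("region_%03d", seq_len(nrow(A))))
  as_binary_graph(A)
}

# canonical toy graphs
graph_k4 <- function() bg(matrix(1, 4, 4) - diag(4))
graph_star <- function(n_leaves = 3) {
  A <- matrix(0, n_leaves + 1, n_leaves + 1)
  A[1, -1] <- 1; A[-1, 1] <- 1
  bg(A)
}
graph_path <- function(n = 3) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  bg(A)
}
graph_two_cliques <- function(k = 4) {
  A <- matrix(0, 2 * k, 2 * k)
  A[1:k, 1:k] <- 1; A[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(A) <- 0
  bg(A)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  bg(A + t(A))
}

connected_random_graph <- function(n, p, seed) {
  for (k in 0:200) {
    g <- random_graph(n, p, seed + 7919 * k)
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(unclass(g), mode = "undirected"))
    if (comp$no == 1L && sum(g) / 2 >= 2) return(g)
  }
  stop("could not draw a connected graph")
}

# triangle enumeration clustering
bf_clustering <- function(graph) {
  A <- unclass(graph)
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) next
    links <- 0
    for (i in seq_along(nb)) {
      for (j in seq_along(nb)) {
        if (i < j && A[nb[i], nb[j]] == 1) links <- links + 1
      }
    }
    cc[v] <- 2 * links / (length(nb) * (length(nb) - 1))
  }
  cc
}

# Floyd-Warshall characteristic path length over reachable pairs
bf_path_length <- function(graph) {
  A <- unclass(graph)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

# power iteration on A + I (strictly dominant eigenvalue for any symmetric
# 0/1 adjacency), Perron-normalized
bf_eigencentrality <- function(graph, iters = 50000, tol = 1e-14) {
  A <- unclass(graph) + diag(nrow(graph))
  v <- rep(1 / sqrt(nrow(A)), nrow(A))
  for (i in seq_len(iters)) {
    w <- as.vector(A %*% v)
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  v / sqrt(sum(v^2))
}

# Newman Q by explicit edge-fraction bookkeeping
bf_modularity <- function(graph, labels) {
  A <- unclass(graph)
  m2 <- sum(A)                       # 2m
  mods <- unique(labels)
  q <- 0
  for (mm in mods) {
    idx <- which(labels == mm)
    e_mm <- sum(A[idx, idx]) / m2
    a_m <- sum(A[idx, ]) / m2
    q <- q + e_mm - a_m^2
  }
  q
}

# the strength-assortativity formula evaluated edge by edge
bf_assortativity <- function(graph, strength) {
  A <- unclass(graph)
  s_jk <- s_half <- s_sq <- 0
  M <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && A[i, j] == 1) {
        M <- M + 1
        s_jk <- s_jk + strength[i] * strength[j]
        s_half <- s_half + (strength[i] + strength[j]) / 2
        s_sq <- s_sq + (strength[i]^2 + strength[j]^2) / 2
      }
    }
  }
  ((s_jk / M) - (s_half / M)^2) / ((s_sq / M) - (s_half / M)^2)
}

# small multi-site null cohort used by several inference tests
quick_cohort <- function(seed, n_regions = 20, per_site = c(10, 10),
                         scales = NULL, ...) {
  generate_cohort(synthetic_config(
    n_regions = n_regions, n_modules = 2, n_sites = length(per_site),
    per_site_counts = per_site, site_scales = scales,
    rho_within = 0.4, rho_between = 0.1, seed = seed, ...))
}

# subsample a matched cohort into unbalanced site x group composition
unbalance_cohort <- function(tab, keep_a, keep_b) {
  sites <- sort(unique(tab$site))
  keep <- unlist(lapply(seq_along(sites), function(i) {
    c(which(tab$site == sites[i] & tab$group == "A")[seq_len(keep_a[i])],
      which(tab$site == sites[i] & tab$group == "B")[seq_len(keep_b[i])])
  }))
  tab[keep, , drop = FALSE]
}

# seed-scoped evaluation for tests, restoring the caller's RNG state
with_seed_for_test <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
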