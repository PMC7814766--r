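test_that("clustering coefficient matches closed forms", {
  expect_equal(clustering_coefficient(graph_k4())$per_node,
               rep(1, 4), ignore_attr = TRUE)
  expect_equal(clustering_coefficient(graph_k4())$mean, 1)
  expect_equal(clustering_coefficient(graph_star())$mean, 0)
  k4m <- unclass(graph_k4()); k4m[1, 2] <- k4m[2, 1] <- 0L
  cc <- clustering_coefficient(as_binary_graph(k4m))
  expect_equal(sort(unname(cc$per_node)), c(2/3, 2/3, 1, 1))
  expect_equal(cc$mean, 5/6)
})

test_that("path length and efficiency match closed forms", {
  expect_equal(characteristic_path_length(graph_k4())$L, 1)
  p3 <- graph_path(3)
  expect_equal(characteristic_path_length(p3)$L, 4/3)
  expect_equal(global_efficiency(graph_k4()), 1)
  expect_equal(global_efficiency(p3), 0.75)
  # the two efficiency definitions differ on P3
  expect_equal(global_efficiency(p3, "mean_inverse_distance"), 5/6)
})

test_that("disconnected graphs restrict to reachable pairs with a flag", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  pl <- characteristic_path_length(as_binary_graph(A))
  expect_equal(pl$L, 1)
  expect_true(pl$disconnected)
  expect_equal(pl$n_pairs_used, 2)
  expect_error(characteristic_path_length(as_binary_graph(matrix(0, 3, 3))),
               "no edges")
})

test_that("eigenvector centrality matches analytic eigenvectors", {
  ec <- eigenvector_centrality(graph_k4())$centrality
  expect_equal(unname(ec), rep(0.5, 4))
  star <- eigenvector_centrality(graph_star(3))$centrality
  expect_equal(unname(star[1] / star[2]), sqrt(3), tolerance = 1e-10)
  expect_equal(unname(star), c(sqrt(3), 1, 1, 1) / sqrt(6), tolerance = 1e-10)
  p3 <- eigenvector_centrality(graph_path(3))$centrality
  expect_equal(unname(p3), c(0.5, sqrt(2)/2, 0.5), tolerance = 1e-10)
  expect_equal(sum(p3^2), 1)
})

test_that("assortativity formula matches closed-form cases", {
  # two disjoint edges, like-with-like strengths: perfect assortative mixing
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_equal(assortativity_strength(as_binary_graph(A), c(1, 1, 4, 4)), 1)
  # P3 with the eigenvector strengths: every edge joins unlike strengths
  expect_equal(
    assortativity_strength(graph_path(3), c(0.5, sqrt(2)/2, 0.5)), -1)
  # equal strengths everywhere: undefined
  expect_error(assortativity_strength(graph_k4(), rep(0.5, 4)), "undefined")
})

test_that("metric implementations agree with brute-force oracles", {
  for (s in 1:30) {
    g <- random_graph(sample(6:12, 1), runif(1, 0.3, 0.7), seed = 1000 + s)
    if (sum(g) / 2 < 2) next
    expect_equal(unname(clustering_coefficient(g)$per_node), bf_clustering(g),
                 tolerance = 1e-9)
    expect_equal(characteristic_path_length(g)$L, bf_path_length(g),
                 tolerance = 1e-9)
    labs <- sample(1:3, nrow(g), replace = TRUE)
    expect_equal(modularity_q(g, labs), bf_modularity(g, labs),
                 tolerance = 1e-12)
    gi <- igraph::graph_from_adjacency_matrix(unclass(g), mode = "undirected")
    expect_equal(modularity_q(g, labs), igraph::modularity(gi, labs),
                 tolerance = 1e-12)
    strength <- runif(nrow(g))
    if (stats::sd(strength) > 0) {
      expect_equal(assortativity_strength(g, strength),
                   bf_assortativity(g, strength), tolerance = 1e-12)
    }
  }
  for (s in 1:10) {
    g <- connected_random_graph(sample(6:12, 1), 0.5, seed = 2000 + s)
    expect_equal(unname(eigenvector_centrality(g)$centrality),
                 bf_eigencentrality(g), tolerance = 1e-9)
  }
})

test_that("per-node metrics are equivariant under node relabeling", {
  g <- connected_random_graph(10, 0.4, seed = 77)
  set.seed(7)
  perm <- sample(10)
  gp <- as_binary_graph(unclass(g)[perm, perm])
  expect_equal(unname(clustering_coefficient(gp)$per_node),
               unname(clustering_coefficient(g)$per_node[perm]))
  expect_equal(unname(eigenvector_centrality(gp)$centrality),
               unname(eigenvector_centrality(g)$centrality[perm]),
               tolerance = 1e-9)
  expect_equal(characteristic_path_length(gp)$L,
               characteristic_path_length(g)$L)
})

test_that("rewiring preserves the degree sequence and erodes lattice order", {
  set.seed(5)
  ring <- igraph::sample_smallworld(1, 40, 3, 0)   # pure ring lattice
  g <- as_binary_graph(as.matrix(igraph::as_adjacency_matrix(ring)))
  expect_warning(refs <- lapply(1:20, function(i)
    random_reference(g, seed = i)), NA)
  for (r in refs[1:3]) {
    expect_equal(rowSums(unclass(r)), rowSums(unclass(g)))
  }
  ref_cc <- vapply(refs, function(r) clustering_coefficient(r)$mean,
                   numeric(1))
  expect_lt(mean(ref_cc), clustering_coefficient(g)$mean)
  # complete graph: no legal swap exists, graph returned unchanged
  expect_warning(same <- random_reference(graph_k4(), seed = 1), "unchanged")
  expect_equal(unclass(same), unclass(graph_k4()))
})

test_that("sigma equals 1 when a graph is its own reference", {
  C <- 0.42; L <- 2.3
  expect_equal((C / C) / (L / L), 1)
  # and the reported sigma uses the component ratio form
  g <- connected_random_graph(20, 0.3, seed = 12)
  sw <- small_worldness(g, n_rand = 10, seed = 3)
  expect_equal(sw$sigma, (sw$C / sw$C_rand) / (sw$L / sw$L_rand))
  expect_false(sw$disconnected)
})

test_that("hub profile z-scores are standardized and respect the threshold", {
  tab <- generate_cohort(synthetic_config(
    n_regions = 24, n_modules = 3, n_sites = 1, per_site_counts = 60,
    seed = 21))
  C <- build_covariance(tab, "A")
  hp <- hub_profile(C)
  expect_equal(mean(hp$z), 0, tolerance = 1e-8)
  expect_equal(stats::sd(hp$z), 1, tolerance = 1e-8)
  expect_identical(hp$hub, hp$z > 1.5)
})

test_that("no hubs emerge in expectation under structural exchangeability", {
  hub_frac <- vapply(1:5, function(s) {
    tab <- generate_cohort(synthetic_config(
      n_regions = 30, n_modules = 1, n_sites = 1, per_site_counts = 150,
      rho_within = 0.3, rho_between = 0.3, seed = s))
    mean(hub_profile(build_covariance(tab, "A"))$hub)
  }, numeric(1))
  expect_lte(mean(hub_frac), 0.10)
})

test_that("constant centrality makes the hub z-score error out", {
  M <- matrix(1, 6, 6)   # complete graph at density 1: all centralities equal
  expect_error(hub_profile(M, grid = 1.0), "undefined|constant")
})
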