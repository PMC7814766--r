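two_clique_weights <- function(k = 5, w = 0.8) {
  W <- matrix(0, 2 * k, 2 * k)
  W[1:k, 1:k] <- w
  W[(k + 1):(2 * k), (k + 1):(2 * k)] <- w
  diag(W) <- 1
  dimnames(W) <- list(sprintf("region_%03d", 1:(2 * k)),
                      sprintf("region_%03d", 1:(2 * k)))
  W
}

test_that("louvain recovers trivially separable structure", {
  W <- two_clique_weights()
  p <- louvain_once(W, seed = 1)
  expect_equal(attr(p, "n_modules"), 2L)
  expect_equal(as.integer(p), rep(1:2, each = 5))
  W1 <- matrix(0.5, 6, 6); diag(W1) <- 1
  expect_equal(attr(louvain_once(W1, seed = 2), "n_modules"), 1L)
})

test_that("partition labels are contiguous from 1 and cover all regions", {
  tab <- generate_cohort(synthetic_config(
    n_regions = 30, n_modules = 3, n_sites = 1, per_site_counts = 80,
    seed = 14))
  p <- louvain_once(build_covariance(tab, "A"), seed = 5)
  expect_length(p, 30)
  expect_equal(sort(unique(as.integer(p))), seq_len(attr(p, "n_modules")))
})

test_that("agreement matrix of identical partitions is exactly 0/1", {
  parts <- replicate(5, c(1L, 1L, 2L, 2L, 3L), simplify = FALSE)
  D <- scnet:::agreement_matrix(parts)
  expect_true(all(D %in% c(0, 1)))
  expect_equal(diag(D), rep(1, 5))
  expect_equal(D, t(D))
})

test_that("consensus is a fixed point on stable graphs and reproducible", {
  W <- two_clique_weights()
  cp <- consensus_partition(W, n_runs = 20, n_consensus_runs = 10, seed = 3)
  expect_equal(attr(cp, "n_iterations"), 1L)
  expect_equal(as.integer(cp), rep(1:2, each = 5))
  cp2 <- consensus_partition(W, n_runs = 20, n_consensus_runs = 10, seed = 3)
  expect_identical(unclass(cp), unclass(cp2))
})

test_that("consensus recovers a planted 4-block covariance", {
  recovered <- vapply(1:5, function(s) {
    cfg <- synthetic_config(n_regions = 40, n_modules = 4, n_sites = 1,
                            per_site_counts = 150, rho_within = 0.6,
                            rho_between = 0.1, seed = s)
    tab <- generate_cohort(cfg)
    cp <- consensus_partition(build_covariance(tab, "A"),
                              n_runs = 50, n_consensus_runs = 30, seed = s)
    blocks <- split(seq_len(40), planted_truth(cfg)$partition_a)
    intact <- vapply(blocks, function(b)
      length(unique(unclass(cp)[b])) == 1L, logical(1))
    sum(intact)
  }, numeric(1))
  expect_true(mean(recovered >= 3) >= 0.9)
})

test_that("modularity Q matches analytic values", {
  g <- graph_two_cliques(4)
  expect_equal(modularity_q(g, rep(1, 8)), 0)
  expect_equal(modularity_q(g, rep(1:2, each = 4)), 0.5)
  # three equal cliques: Q = 1 - 1/3
  A <- matrix(0, 9, 9)
  for (b in 0:2) A[b * 3 + 1:3, b * 3 + 1:3] <- 1
  diag(A) <- 0
  expect_equal(modularity_q(as_binary_graph(A), rep(1:3, each = 3)), 2/3)
})

test_that("segregation index reproduces the worked example", {
  # module {1,2,3} with all within correlations 0.5; region 4 attached at 0.2
  W <- matrix(0.2, 4, 4)
  W[1:3, 1:3] <- 0.5
  diag(W) <- 1
  si <- segregation_index(W, c(1, 1, 1, 2), 1)
  expect_equal(si$z_within, atanh(0.5))
  expect_equal(si$z_between, atanh(0.2))
  expect_equal(si$si, (atanh(0.5) - atanh(0.2)) / atanh(0.5))
  expect_equal(si$si, 0.6310, tolerance = 1e-3)
})

test_that("segregation index limits behave", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 0.5
  diag(W) <- 1
  # orthogonal module: z_between = 0 so SI = 1
  expect_equal(segregation_index(W, c(1, 1, 1, 2, 2, 2), 1)$si, 1)
  # z_within = z_between: SI = 0
  W2 <- matrix(0.4, 6, 6); diag(W2) <- 1
  expect_equal(segregation_index(W2, c(1, 1, 1, 2, 2, 2), 1)$si, 0)
  # degenerate partitions
  expect_error(segregation_index(W, c(1, 2, 2, 2, 2, 2), 1), "at least 2")
  expect_error(segregation_index(W, rep(1, 6), 1), "spans all")
  # correlations at 1 are clipped, not infinite
  W3 <- matrix(1, 4, 4)
  si3 <- segregation_index(W3, c(1, 1, 2, 2), 1)
  expect_true(is.finite(si3$si))
})

test_that("SI is at most 1 for positive within and nonnegative between", {
  set.seed(9)
  for (i in 1:20) {
    W <- stats::cor(matrix(rnorm(40 * 8), 40, 8) +
                      rnorm(40))        # shared noise: positive-ish correlations
    lab <- sample(1:2, 8, replace = TRUE)
    if (min(table(factor(lab, 1:2))) < 2) next
    si <- segregation_index(W, lab, 1)
    if (si$z_within > 0 && si$z_between >= 0) expect_lte(si$si, 1)
  }
})

test_that("transfer contrast is zero for identical groups, positive for split", {
  W <- two_clique_weights()
  ct <- transfer_si_contrast(W, W, c(rep(1, 5), rep(2, 5)), 1)
  expect_equal(ct$difference, 0)
  cfg <- synthetic_config(n_regions = 24,
                          module_labels = rep(1:2, times = c(16, 8)),
                          n_sites = 1, per_site_counts = 150,
                          rho_within = 0.6, rho_between = 0.1,
                          split_module = 1, split_strength = 0.5, seed = 2)
  tab <- generate_cohort(cfg)
  ca <- build_covariance(tab, "A")
  cb <- build_covariance(tab, "B")
  truth <- planted_truth(cfg)
  sub_label <- truth$partition_b[[9]]   # second sub-block of the split module
  # partition from the case group (B); SI higher in B where the split exists
  d <- transfer_si_contrast(cb, ca, truth$partition_b, sub_label)
  expect_gt(d$difference, 0)
})

test_that("Q stays in [-0.5, 1] on random weighted graphs", {
  set.seed(10)
  for (i in 1:20) {
    W <- abs(stats::cor(matrix(rnorm(30 * 10), 30, 10)))
    lab <- sample(1:3, 10, replace = TRUE)
    q <- modularity_q(W, lab)
    expect_gte(q, -0.5)
    expect_lte(q, 1)
  }
})
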