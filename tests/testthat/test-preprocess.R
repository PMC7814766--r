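make_table <- function(values, site = rep("s1", nrow(values)),
                       group = rep(c("A", "B"), length.out = nrow(values)),
                       age = seq(10, 20, length.out = nrow(values)),
                       sex = rep(c("male", "female"),
                                 length.out = nrow(values))) {
  colnames(values) <- sprintf("region_%03d", seq_len(ncol(values)))
  tab <- data.frame(subject_id = sprintf("S%02d", seq_len(nrow(values))),
                    site = site, group = group, age = age, sex = sex,
                    fiq = 100, stringsAsFactors = FALSE)
  cbind(tab, as.data.frame(values))
}

test_that("mad_rescale divides by the hand-computed raw MAD", {
  tab <- make_table(cbind(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 100)))
  out <- mad_rescale(tab)
  # median 6, |x-6| = 4,2,0,2,4, MAD = 2
  expect_equal(out$region_001, c(1, 2, 3, 4, 5))
  # median 3, deviations 2,1,0,1,97, MAD = 1: robust to the outlier
  expect_equal(out$region_002, c(1, 2, 3, 4, 100))
})

test_that("mad_rescale errors on constant data, naming site and region", {
  tab <- make_table(cbind(c(5, 5, 5, 5), c(1, 2, 3, 4)))
  expect_error(mad_rescale(tab), "s1.*region_001")
})

test_that("after rescaling, every (site, region) MAD is exactly 1", {
  tab <- generate_cohort(synthetic_config(
    n_regions = 8, n_modules = 2, n_sites = 3, per_site_counts = c(7, 9, 8),
    site_scales = c(0.5, 1, 4), seed = 2))
  out <- mad_rescale(tab)
  for (s in unique(out$site)) {
    mads <- apply(region_matrix(out[out$site == s, ]), 2,
                  stats::mad, constant = 1)
    expect_equal(unname(mads), rep(1, 8))
  }
})

test_that("regression removes an exact covariate signal", {
  age <- seq(8, 28, length.out = 12)
  vals <- cbind(2 * age + 5, -1 * age + 3)
  tab <- make_table(vals, age = age)
  # the global mean is itself a linear function of age here, so the design is
  # rank-deficient and the regression warns while dropping the extra column
  expect_warning(res <- regress_covariates(tab), "rank-deficient")
  expect_lt(max(abs(region_matrix(res))), 1e-8)
})

test_that("residuals are orthogonal to every regressor and centered", {
  tab <- generate_cohort(synthetic_config(
    n_regions = 6, n_modules = 2, n_sites = 1, per_site_counts = 40,
    beta_age = 0.3, beta_sex = 1.2, seed = 9))
  res <- regress_covariates(tab)
  R <- region_matrix(res)
  expect_lt(max(abs(colMeans(R))), 1e-10)
  sexn <- as.numeric(res$sex == "male")
  global <- rowMeans(region_matrix(tab))
  for (v in list(res$age, sexn, global)) {
    ip <- abs(crossprod(R, v - mean(v)))
    expect_lt(max(ip / (sqrt(colSums(R^2)) * sqrt(sum((v - mean(v))^2)))),
              1e-8)
  }
})

test_that("regression is idempotent and preserves noise variance", {
  set.seed(31)
  n <- 500
  age <- runif(n, 8, 28)
  vals <- matrix(rnorm(n * 20), n, 20) + 0.5 * age
  tab <- make_table(vals, age = age,
                    sex = sample(c("male", "female"), n, replace = TRUE))
  res <- regress_covariates(tab)
  v <- apply(region_matrix(res), 2, stats::var)
  expect_gt(mean(v), 0.85)
  expect_lt(mean(v), 1.15)
  # regressing the residuals on the same covariates leaves them unchanged
  res2 <- regress_covariates(res, global = rowMeans(region_matrix(tab)))
  expect_equal(region_matrix(res2), region_matrix(res), tolerance = 1e-10)
})

test_that("a single-sex stratum drops the sex regressor with a warning", {
  set.seed(4)
  tab <- make_table(matrix(rnorm(40), 10, 4), sex = rep("male", 10))
  expect_warning(res <- regress_covariates(tab), "sex")
  expect_lt(max(abs(colMeans(region_matrix(res)))), 1e-10)
})

test_that("site_bias_check flags a scale-confounded site, correction clears it", {
  flag_counts <- vapply(1:10, function(s) {
    tab <- generate_cohort(synthetic_config(
      n_regions = 60, n_modules = 2, n_sites = 3,
      per_site_counts = c(30, 30, 30), site_scales = c(1, 1, 2), seed = s))
    raw <- site_bias_check(tab)
    cooked <- site_bias_check(regress_covariates(mad_rescale(tab)))
    c(raw = sum(raw$flagged & raw$site == "site03"),
      cooked_site3 = sum(cooked$flagged & cooked$site == "site03"),
      cooked_all = sum(cooked$flagged, na.rm = TRUE))
  }, numeric(3))
  # the doubled-scale site is flagged in both groups in every raw cohort
  expect_true(all(flag_counts["raw", ] == 2))
  # after MAD rescaling + covariate regression the flags return to near-null
  expect_lte(mean(flag_counts["cooked_site3", ]) / 2, 0.3)
  expect_lte(mean(flag_counts["cooked_all", ]) / 6, 0.2)
})

test_that("site_bias_check stays near the nominal level under the null", {
  frac <- vapply(1:100, function(s) {
    tab <- generate_cohort(synthetic_config(
      n_regions = 8, n_modules = 2, n_sites = 3,
      per_site_counts = c(10, 10, 10), site_scales = c(1, 1, 1), seed = s))
    out <- site_bias_check(tab)
    mean(out$flagged, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("sites with fewer than 3 subjects per group are skipped", {
  tab <- generate_cohort(synthetic_config(
    n_regions = 5, n_modules = 1, n_sites = 2, per_site_counts = c(10, 2),
    seed = 1))
  out <- site_bias_check(tab)
  expect_true(all(is.na(out$t[out$site == "site02"])))
  expect_true(all(!is.na(out$t[out$site == "site01"])))
})
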