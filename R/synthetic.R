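#' Configuration for a synthetic multi-site morphometry cohort
#'
#' Describes a two-group (A = control-like, B = case-like), multi-site cohort
#' with planted block covariance structure. Regions are partitioned into
#' modules; region values for a subject are driven by a shared latent factor
#' (giving the between-module correlation), one latent factor per module
#' (raising within-module correlation), optional sub-block factors that split
#' one module in group B only, plus covariate effects and Gaussian noise, all
#' multiplied by a per-site measurement scale.
#'
#' With total latent-plus-noise variance \eqn{T = \sigma^2/(1-\rho_w)}, the
#' loadings are \eqn{a = \sqrt{\rho_b T}} on the shared factor and
#' \eqn{b = \sqrt{(\rho_w-\rho_b) T}} on the module factor, so that the
#' expected correlation is \eqn{\rho_w} within a module and \eqn{\rho_b}
#' between modules. When a module is split (group B only), its regions load
#' \eqn{b' = \sqrt{(\rho_w - s - \rho_b) T}} on the module factor and
#' \eqn{c = \sqrt{s T}} on their sub-block factor, with \eqn{s} =
#' `split_strength`, so the correlation across the sub-block boundary drops to
#' \eqn{\rho_w - s} while within-sub-block correlation stays at \eqn{\rho_w}.
#' The construction is a nonnegative factor model, hence the implied
#' correlation matrices are positive semidefinite by construction.
#'
#' @param n_regions Number of cortical regions (default 148, the Destrieux
#'   parcellation size).
#' @param module_labels Integer module id per region; default splits regions
#'   into `n_modules` contiguous, near-equal blocks.
#' @param n_modules Number of modules used when `module_labels` is NULL.
#' @param n_sites Number of acquisition sites.
#' @param per_site_counts Subjects per group at each site (the two groups get
#'   identical counts: a matched design).
#' @param rho_within,rho_between Target within/between-module correlations,
#'   both in [0, 1) with `rho_between <= rho_within`.
#' @param site_scales Positive measurement-scale multiplier per site; default
#'   spreads scales over 0.6-1.8 to emulate scanner/protocol differences.
#' @param beta_age,beta_sex Covariate effect sizes (measure units per year and
#'   per unit of the 0/1 male indicator).
#' @param noise_sd Residual standard deviation of each region value.
#' @param baseline Mean measure level before covariates and scaling.
#' @param age_range Ages are drawn uniformly within this band (years).
#' @param p_male Probability a subject is male.
#' @param split_module Optional module id split into two sub-blocks for group B
#'   only; NULL for no split.
#' @param split_strength Correlation drop across the sub-block boundary.
#' @param seed RNG seed; generation is bit-reproducible given the config.
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_cohort()], [planted_truth()]
#' @export
synthetic_config <- function(n_regions = 148L, module_labels = NULL,
                             n_modules = 4L, n_sites = 4L,
                             per_site_counts = rep(20L, n_sites),
                             rho_within = 0.6, rho_between = 0.1,
                             site_scales = NULL,
                             beta_age = 0, beta_sex = 0,
                             noise_sd = 1, baseline = 10,
                             age_range = c(8, 30), p_male = 0.8,
                             split_module = NULL, split_strength = 0.5,
                             seed = 1L) {
  stopifnot_scalar_count(n_regions, "n_regions")
  stopifnot_scalar_count(n_sites, "n_sites")
  if (is.null(module_labels)) {
    stopifnot_scalar_count(n_modules, "n_modules")
    module_labels <- sort(rep_len(seq_len(n_modules), n_regions))
  }
  module_labels <- as.integer(module_labels)
  if (length(module_labels) != n_regions) {
    stop("module_labels must have one entry per region")
  }
  if (length(per_site_counts) != n_sites) {
    stop("per_site_counts must have one entry per site")
  }
  per_site_counts <- as.integer(per_site_counts)
  if (any(per_site_counts < 1L)) stop("per-site subject counts must be positive")
  if (is.null(site_scales)) {
    site_scales <- if (n_sites == 1L) 1 else seq(0.6, 1.8, length.out = n_sites)
  }
  if (length(site_scales) != n_sites || any(site_scales <= 0)) {
    stop("site_scales must be one positive multiplier per site")
  }
  if (rho_within < 0 || rho_within >= 1 || rho_between < 0 || rho_between >= 1) {
    stop("rho_within and rho_between must lie in [0, 1)")
  }
  if (rho_between > rho_within) {
    stop("rho_between must not exceed rho_within")
  }
  if (!is.null(split_module)) {
    if (!split_module %in% module_labels) {
      stop("split_module is not a module label")
    }
    if (sum(module_labels == split_module) < 2L) {
      stop("split_module must contain at least 2 regions")
    }
    if (split_strength < 0 ||
        rho_within - split_strength < rho_between - 1e-12) {
      stop(paste0("split_strength must satisfy 0 <= split_strength <= ",
                  "rho_within - rho_between (nonnegative loadings)"))
    }
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("age_range must be an increasing (min, max) pair")
  }
  cfg <- list(
    n_regions = as.integer(n_regions), module_labels = module_labels,
    n_sites = as.integer(n_sites), per_site_counts = per_site_counts,
    rho_within = rho_within, rho_between = rho_between,
    site_scales = as.numeric(site_scales),
    beta_age = beta_age, beta_sex = beta_sex,
    noise_sd = noise_sd, baseline = baseline,
    age_range = as.numeric(age_range), p_male = p_male,
    split_module = split_module, split_strength = split_strength,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# factor loadings implied by the correlation targets (documented in
# ?synthetic_config); T is the total variance of a region value before site
# scaling and covariate effects.
config_loadings <- function(config) {
  tv <- config$noise_sd^2 / (1 - config$rho_within)
  l <- list(
    total_var = tv,
    shared = sqrt(config$rho_between * tv),
    module = sqrt((config$rho_within - config$rho_between) * tv)
  )
  if (!is.null(config$split_module)) {
    l$module_split <- sqrt(max(
      (config$rho_within - config$split_strength - config$rho_between) * tv, 0))
    l$sub_block <- sqrt(config$split_strength * tv)
  }
  l
}

# region indices of the two sub-blocks of the split module (first half / rest)
split_blocks <- function(config) {
  idx <- which(config$module_labels == config$split_module)
  half <- ceiling(length(idx) / 2)
  list(first = idx[seq_len(half)], second = idx[-seq_len(half)])
}

#' Generate a synthetic multi-site two-group cohort
#'
#' Draws a cohort table under the latent-factor model described in
#' [synthetic_config()]. Age, sex and FIQ draws are cloned across the two
#' groups within each site, so the groups are exactly covariate-matched, as in
#' a matched case-control design. Latent factors and noise are independent per
#' subject. Every subject's region values (including noise) are multiplied by
#' the subject's site scale, so site differences are pure scale effects that
#' MAD rescaling can remove.
#'
#' @param config A [synthetic_config()] object.
#' @return A `cohort_table` data frame: `subject_id`, `site`, `group` (A/B),
#'   `age`, `sex`, `fiq`, then one `region_*` column per region.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  R <- config$n_regions
  mod <- config$module_labels
  n_mod <- max(mod)
  ld <- config_loadings(config)
  per_group <- sum(config$per_site_counts)
  n_tot <- 2L * per_group

  with_seed(config$seed, {
    # covariates: one draw per matched pair, cloned across groups
    age1 <- stats::runif(per_group, config$age_range[1], config$age_range[2])
    sex1 <- stats::rbinom(per_group, 1L, config$p_male)
    fiq1 <- stats::rnorm(per_group, 105, 15)
    site1 <- rep(seq_len(config$n_sites), config$per_site_counts)

    age <- c(age1, age1)
    sexn <- c(sex1, sex1)
    fiq <- c(fiq1, fiq1)
    site <- c(site1, site1)
    group <- rep(c("A", "B"), each = per_group)

    # latent factors and noise, independent per subject
    h <- stats::rnorm(n_tot)
    f <- matrix(stats::rnorm(n_tot * n_mod), n_tot, n_mod)
    g <- matrix(stats::rnorm(n_tot * 2L), n_tot, 2L)
    eps <- matrix(stats::rnorm(n_tot * R, sd = config$noise_sd), n_tot, R)

    latent <- ld$shared * h + ld$module * f[, mod, drop = FALSE]
    if (!is.null(config$split_module)) {
      blocks <- split_blocks(config)
      b_rows <- which(group == "B")
      m <- config$split_module
      for (k in 1:2) {
        cols <- blocks[[k]]
        latent[b_rows, cols] <-
          ld$shared * h[b_rows] + ld$module_split * f[b_rows, m] +
          ld$sub_block * g[b_rows, k]
      }
    }

    values <- config$baseline + config$beta_age * age +
      config$beta_sex * sexn + latent + eps
    values <- values * config$site_scales[site]

    tab <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n_tot)),
      site = sprintf("site%02d", site),
      group = group,
      age = age,
      sex = ifelse(sexn == 1L, "male", "female"),
      fiq = fiq,
      stringsAsFactors = FALSE
    )
    colnames(values) <- region_names(R)
    tab <- cbind(tab, as.data.frame(values))
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Ground truth of a synthetic configuration
#'
#' Returns the planted module partition of each group and the analytic
#' expected correlation matrix implied by the factor loadings. The expected
#' matrix describes the correlation structure of the measure net of covariate
#' effects (covariates add common variance shared by all regions); with
#' `beta_age = beta_sex = 0` it is the expected raw correlation matrix. In
#' group B with a split module, the two sub-blocks appear as separate modules
#' and the correlation across the sub-block boundary is
#' `rho_within - split_strength`.
#'
#' @param config A [synthetic_config()] object.
#' @return List with `partition_a`, `partition_b` (integer module per region),
#'   `expected_a`, `expected_b` (region x region correlation matrices) and
#'   `loadings` (the factor loading values).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  R <- config$n_regions
  mod <- config$module_labels
  same_mod <- outer(mod, mod, "==")
  expected <- matrix(config$rho_between, R, R)
  expected[same_mod] <- config$rho_within
  diag(expected) <- 1
  rn <- region_names(R)
  dimnames(expected) <- list(rn, rn)

  part_a <- mod
  names(part_a) <- rn
  part_b <- part_a
  expected_b <- expected

  if (!is.null(config$split_module)) {
    blocks <- split_blocks(config)
    part_b[blocks$second] <- max(mod) + 1L
    part_b <- match(part_b, unique(part_b))  # contiguous labels from 1
    names(part_b) <- rn
    expected_b[blocks$first, blocks$second] <-
      config$rho_within - config$split_strength
    expected_b[blocks$second, blocks$first] <-
      config$rho_within - config$split_strength
  }

  list(partition_a = part_a, partition_b = part_b,
       expected_a = expected, expected_b = expected_b,
       loadings = config_loadings(config))
}
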