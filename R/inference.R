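#' Center-paired (site-stratified) group-label shuffle
#'
#' Permutes group labels independently within each acquisition site,
#' preserving every site's per-group counts, and concatenates the sites'
#' outcomes into one randomized labeling. This prevents the failure mode of
#' unrestricted shuffling in multi-site data, where all of one site's subjects
#' can land in one pseudo-group and site effects masquerade as group effects.
#'
#' @param group_labels Vector of group labels (two groups).
#' @param site_labels Vector of site labels, same length.
#' @param seed Optional RNG seed; NULL uses the current RNG stream (the
#'   permutation engine calls this in a seeded loop).
#' @return Permuted group-label vector in the original subject order.
#' @export
center_paired_shuffle <- function(group_labels, site_labels, seed = NULL) {
  if (length(group_labels) != length(site_labels)) {
    stop("group and site label vectors must have the same length")
  }
  shuffle <- function() {
    out <- group_labels
    for (s in unique(site_labels)) {
      idx <- which(site_labels == s)
      if (length(unique(group_labels[idx])) < 2L) {
        stop(sprintf("site '%s' has all subjects in one group; cannot pair", s))
      }
      out[idx] <- group_labels[idx][sample.int(length(idx))]
    }
    out
  }
  if (is.null(seed)) shuffle() else with_seed(seed, shuffle())
}

#' Permutation test of a group-difference statistic
#'
#' Evaluates `statistic(X_a, X_b)` — a deterministic map from two
#' subjects-x-regions residual matrices to a scalar or vector (e.g. a metric
#' over the density grid) — on the observed grouping, then on `n_perm`
#' center-paired permutations of the group labels. Both pseudo-group networks
#' are rebuilt inside the statistic on every draw. Per element, the two-tailed
#' p-value is the add-one-corrected tail probability
#' p = (1 + #\{|d_null| >= |d_obs|\}) / (n_valid + 1), and the 95% null
#' confidence band is reported for plotting.
#'
#' Permutations operate on residuals (the covariate regression is fitted once,
#' pooled across groups, so residuals are exchangeable under the null); a
#' statistic that fails on a permuted split is recorded as a failed draw, and
#' more than 1% failures aborts.
#'
#' @param residuals A `residual_table`, or a subjects x regions matrix.
#' @param sites Site label per subject (taken from the table if NULL).
#' @param labels Group label per subject (taken from the table if NULL).
#' @param statistic Function of two matrices returning a numeric vector; may
#'   carry a `names` attribute on its result.
#' @param n_perm Number of permutations (default 5000).
#' @param seed RNG seed.
#' @param stratified If FALSE, uses an unrestricted shuffle instead of the
#'   center-paired one (comparison harness only).
#' @param name Statistic name stored in the result.
#' @return A `perm_test` object: observed values, null matrix
#'   (n_perm x length), 95% CI of the null, p-values, failure count.
#' @export
permutation_test <- function(residuals, sites = NULL, labels = NULL,
                             statistic, n_perm = 5000L, seed = 1L,
                             stratified = TRUE, name = "statistic") {
  if (is.data.frame(residuals)) {
    if (is.null(sites)) sites <- residuals$site
    if (is.null(labels)) labels <- residuals$group
    X <- region_matrix(residuals)
  } else {
    X <- as.matrix(residuals)
  }
  if (is.null(labels)) stop("group labels are required")
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("exactly two groups are required")
  split_eval <- function(lab) {
    statistic(X[lab == groups[1L], , drop = FALSE],
              X[lab == groups[2L], , drop = FALSE])
  }
  observed <- split_eval(labels)
  null_mat <- matrix(NA_real_, n_perm, length(observed))
  n_failed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- if (stratified) {
        center_paired_shuffle(labels, sites)
      } else {
        labels[sample.int(length(labels))]
      }
      val <- tryCatch(split_eval(perm), error = function(e) NULL)
      if (is.null(val)) {
        n_failed <- n_failed + 1L
      } else {
        null_mat[b, ] <- val
      }
    }
  })
  if (n_failed > 0.01 * n_perm) {
    stop(sprintf("statistic failed on %d of %d permutations", n_failed, n_perm))
  }
  n_valid <- n_perm - n_failed
  p <- vapply(seq_along(observed), function(j) {
    (1 + sum(abs(null_mat[, j]) >= abs(observed[j]), na.rm = TRUE)) /
      (n_valid + 1)
  }, numeric(1))
  ci <- apply(null_mat, 2L, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  structure(list(name = name, observed = observed, null = null_mat,
                 ci_lower = ci[1L, ], ci_upper = ci[2L, ], p = p,
                 n_perm = n_perm, n_failed = n_failed,
                 stratified = stratified),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s (%d permutations%s, %d failed)\n",
              x$name, x$n_perm,
              if (x$stratified) ", center-paired" else ", unstratified",
              x$n_failed))
  print(data.frame(observed = x$observed, ci_lower = x$ci_lower,
                   ci_upper = x$ci_upper, p = x$p))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction within a family
#'
#' @param p Vector of p-values in (0, 1].
#' @param q_level FDR level for the rejection flags (default 0.05).
#' @return List with `q` (BH-adjusted values) and `reject` flags.
#' @export
fdr_correct <- function(p, q_level = 0.05) {
  if (length(p) == 0L) stop("empty p-value family")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= q_level)
}

#' Regionwise group comparison under the center-paired null
#'
#' Per region, tests the between-group difference of mean measure values with
#' the center-paired permutation of the mean difference (the same null as the
#' network comparisons), and applies BH-FDR across regions.
#'
#' @param table A cohort-like data frame with `group`, `site` and region
#'   columns.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param q_level FDR level.
#' @return Data frame: region, mean_diff (group1 - group2 in sorted label
#'   order), p, q, reject.
#' @export
regionwise_group_test <- function(table, n_perm = 1000L, seed = 1L,
                                  q_level = 0.05) {
  groups <- sort(unique(table$group))
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (min(table(table$group)) < 3L) stop("both groups need at least 3 subjects")
  stat <- function(xa, xb) colMeans(xa) - colMeans(xb)
  pt <- permutation_test(table, statistic = stat, n_perm = n_perm,
                         seed = seed, name = "regionwise mean difference")
  fq <- fdr_correct(pt$p, q_level)
  data.frame(region = region_columns(table), mean_diff = unname(pt$observed),
             p = pt$p, q = fq$q, reject = fq$reject,
             stringsAsFactors = FALSE)
}

#' Correlation between regional structure and hub centrality
#'
#' Pearson correlation, across regions, between the group-mean residual
#' measure and the z-scored density-averaged eigenvector centrality, with the
#' p-value from the standard correlation t test. Used to ask whether
#' structurally larger/thicker regions occupy more central network positions.
#'
#' @param residuals A `residual_table` (one group's rows) or subjects x
#'   regions matrix.
#' @param profile A `hub_profile` for the same regions.
#' @return List with `r`, `p` and `n_regions`.
#' @export
correlate_structure_centrality <- function(residuals, profile) {
  X <- if (is.data.frame(residuals) && !is.null(residuals$group)) {
    region_matrix(residuals)
  } else {
    as.matrix(residuals)
  }
  if (ncol(X) != nrow(profile)) stop("region counts do not match")
  mean_res <- colMeans(X)
  if (stats::sd(mean_res) == 0 || stats::sd(profile$z) == 0) {
    stop("zero-variance vector; correlation undefined")
  }
  ct <- stats::cor.test(mean_res, profile$z)
  list(r = unname(ct$estimate), p = ct$p.value, n_regions = ncol(X))
}
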