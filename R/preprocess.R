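#' Harmonize site scale by median-absolute-deviation rescaling
#'
#' For every acquisition site and every region, the raw MAD
#' \eqn{\mathrm{median}(|x - \mathrm{median}(x)|)} of that region's values
#' across the site's subjects (both diagnostic groups jointly) is computed and
#' each subject's value is divided by it, yielding a dimensionless
#' "ratio of MAD". The raw MAD is used, without the 1.4826 Gaussian
#' consistency factor: the constant is site-wide per region and would cancel
#' in the Pearson correlations downstream anyway.
#'
#' @param table A `cohort_table`-like data frame with `site` and `region_*`
#'   columns.
#' @param reference Optional larger table (e.g. all subjects of a site before
#'   matched selection) from which the per-site MADs are computed instead;
#'   must contain the same sites and region columns.
#' @return The table with region values divided by their (site, region) MAD.
#' @export
mad_rescale <- function(table, reference = NULL) {
  rc <- region_columns(table)
  if (length(rc) == 0L) stop("table has no region columns")
  ref <- if (is.null(reference)) table else reference
  if (!all(unique(table$site) %in% unique(ref$site))) {
    stop("reference table does not cover all sites")
  }
  for (s in unique(table$site)) {
    n_ref <- sum(ref$site == s)
    if (n_ref < 2L) stop(sprintf("site '%s' has fewer than 2 subjects", s))
    refm <- as.matrix(ref[ref$site == s, rc, drop = FALSE])
    mads <- apply(refm, 2L, stats::mad, constant = 1)
    if (any(mads == 0)) {
      bad <- rc[which(mads == 0)[1]]
      stop(sprintf("MAD is zero for site '%s', region '%s' (constant data)",
                   s, bad))
    }
    rows <- table$site == s
    table[rows, rc] <- sweep(as.matrix(table[rows, rc, drop = FALSE]),
                             2L, mads, "/")
  }
  table
}

#' Regress covariates out of regional measures
#'
#' Fits, per region, an ordinary least squares model of the (rescaled) measure
#' on intercept + age + sex + the subject-level global mean of the same
#' measure, and returns the residuals. The table passed in is treated as one
#' regression stratum (callers split by age band beforehand); by default the
#' fit pools both diagnostic groups so that residuals are exchangeable under a
#' group-label permutation null.
#'
#' Sex is coded male = 1, female = 0. A rank-deficient design (e.g. a
#' single-sex stratum) drops the offending regressor with a warning.
#'
#' @param table A cohort-like data frame (one age stratum).
#' @param by_group If TRUE, fit the regression separately within each
#'   diagnostic group instead of pooling.
#' @param global Optional per-subject global covariate; defaults to the row
#'   mean of the table's region columns. Supplying the original global means
#'   makes the operation idempotent on its own residuals.
#' @return A `residual_table`: same metadata, region columns replaced by
#'   residuals.
#' @export
regress_covariates <- function(table, by_group = FALSE, global = NULL) {
  rc <- region_columns(table)
  if (length(rc) == 0L) stop("table has no region columns")
  if (by_group) {
    parts <- lapply(split(seq_len(nrow(table)), table$group), function(i) {
      regress_covariates(table[i, , drop = FALSE], by_group = FALSE,
                         global = global[i])
    })
    out <- do.call(rbind, parts)
    out <- out[order(match(out$subject_id, table$subject_id)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("residual_table", "data.frame")
    return(out)
  }
  Y <- region_matrix(table)
  sexn <- as.numeric(table$sex %in% c("male", "M", "1", 1))
  if (is.null(global)) global <- rowMeans(Y)
  X <- cbind(intercept = 1, age = as.numeric(table$age), sex = sexn,
             global_mean = global)
  if (nrow(X) < ncol(X) + 2L) {
    stop("stratum too small for the covariate regression")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warning(sprintf("rank-deficient design; dropping regressor(s): %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, Y)
  table[, rc] <- res
  class(table) <- c("residual_table", "data.frame")
  table
}

#' Per-site bias check after harmonization
#'
#' For each diagnostic group, computes every subject's whole-cortex mean
#' (mean over region columns), then tests each site's subject means against
#' the grand mean over all the group's subjects with a one-sample t test, and
#' applies Benjamini-Hochberg FDR across the sites of the group. Sites with
#' fewer than 3 subjects in a group are flagged and skipped.
#'
#' @param table A cohort-like data frame (typically corrected data: rescaled
#'   and/or residualized).
#' @param q_level FDR level used for the `flagged` column.
#' @return Data frame with one row per (group, site): n, mean, t, p, q and a
#'   `flagged` logical (NA when skipped).
#' @export
site_bias_check <- function(table, q_level = 0.05) {
  if (length(unique(table$site)) < 2L) stop("need at least 2 sites")
  subj_mean <- rowMeans(region_matrix(table))
  out <- do.call(rbind, lapply(unique(table$group), function(g) {
    in_g <- table$group == g
    grand <- mean(subj_mean[in_g])
    rows <- lapply(sort(unique(table$site[in_g])), function(s) {
      x <- subj_mean[in_g & table$site == s]
      if (length(x) < 3L) {
        return(data.frame(group = g, site = s, n = length(x),
                          mean = mean(x), t = NA_real_, p = NA_real_))
      }
      tt <- stats::t.test(x, mu = grand)
      data.frame(group = g, site = s, n = length(x), mean = mean(x),
                 t = unname(tt$statistic), p = tt$p.value)
    })
    fam <- do.call(rbind, rows)
    fam$q <- NA_real_
    ok <- !is.na(fam$p)
    fam$q[ok] <- stats::p.adjust(fam$p[ok], method = "BH")
    fam
  }))
  out$flagged <- out$q < q_level
  rownames(out) <- NULL
  out
}
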