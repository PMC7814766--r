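#' Group-level structural covariance matrix
#'
#' Pearson-correlates every pair of regions across the subjects of one group,
#' yielding the symmetric region x region association matrix whose
#' upper-triangular entries are the network's candidate connections (for R
#' regions, R(R-1)/2 unique connections; 10,878 at R = 148).
#'
#' @param residuals A `residual_table` (or any cohort-like table).
#' @param group Group label to select, matched against the `group` column;
#'   NULL uses all rows.
#' @return A `cov_matrix`: correlation matrix with attributes `group`,
#'   `n_subjects` and region dimnames.
#' @export
build_covariance <- function(residuals, group = NULL) {
  tab <- if (is.null(group)) residuals else
    residuals[residuals$group == group, , drop = FALSE]
  X <- region_matrix(tab)
  if (nrow(X) < 3L) stop("need at least 3 subjects in the group")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("region '%s' is constant within the group",
                 colnames(X)[which(sds == 0)[1]]))
  }
  C <- stats::cor(X)
  new_cov_matrix(C, group = if (is.null(group)) "all" else group,
                 n_subjects = nrow(X))
}

new_cov_matrix <- function(values, group = NA_character_, n_subjects = NA_integer_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-12) stop("matrix is not symmetric")
  if (is.null(rownames(values))) {
    dimnames(values) <- list(region_names(nrow(values)),
                             region_names(nrow(values)))
  }
  structure(values, class = c("cov_matrix", "matrix", "array"),
            group = group, n_subjects = n_subjects)
}

# upper-triangle index pairs, ordered lexicographically by (i, j)
upper_pairs <- function(R) {
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
}

#' Binarize a covariance matrix at a target link density
#'
#' Removes self-connections and all non-positive correlations, ranks the
#' remaining edges by correlation (descending), and keeps the strongest
#' k = round(density x R(R-1)/2). The denominator counts all region pairs,
#' not only positive ones, so "density" is a fraction of possible
#' connections. Ties at the cutoff are broken deterministically by the sorted
#' (i, j) region-index pair. If fewer than k positive correlations exist, all
#' are kept and the achieved density is recorded with a warning.
#'
#' @param matrix A `cov_matrix` (or plain symmetric matrix).
#' @param density Target edge density in (0, 1].
#' @return A `binary_graph`: 0/1 adjacency with zero diagonal and attributes
#'   `density` (requested), `achieved_density`, `group`.
#' @export
threshold_density <- function(matrix, density) {
  if (length(density) != 1L || density <= 0 || density > 1) {
    stop("density must lie in (0, 1]")
  }
  R <- nrow(matrix)
  pairs <- upper_pairs(R)
  vals <- matrix[pairs]
  n_pairs <- nrow(pairs)
  k <- round(density * n_pairs)
  pos <- which(vals > 0)
  ord <- pos[order(-vals[pos], pairs[pos, 1L], pairs[pos, 2L])]
  if (length(ord) < k) {
    warning(sprintf(
      "only %d positive connections available; achieved density %.4f < %.4f",
      length(ord), length(ord) / n_pairs, density))
    keep <- ord
  } else {
    keep <- ord[seq_len(k)]
  }
  A <- matrix(0L, R, R, dimnames = dimnames(matrix))
  A[pairs[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(A, class = c("binary_graph", "matrix", "array"),
            density = density,
            achieved_density = length(keep) / n_pairs,
            group = attr(matrix, "group"))
}

#' Threshold a covariance matrix over a density grid
#'
#' One binary graph per density. Because the edge ranking does not depend on
#' the density, the graphs are nested: the edge set at a lower density is a
#' subset of the edge set at any higher density.
#'
#' @param matrix A `cov_matrix`.
#' @param d_min,d_max,step Density grid bounds and increment; the default
#'   8-35% in 1% steps is the standard analysis grid, chosen so that group
#'   networks are typically fully connected at the lower end.
#' @return Named list of `binary_graph`s (names are the densities).
#' @export
density_grid <- function(matrix, d_min = 0.08, d_max = 0.35, step = 0.01) {
  if (d_min > d_max || step <= 0) stop("invalid density grid")
  densities <- seq(d_min, d_max, by = step)
  out <- lapply(densities, function(d) threshold_density(matrix, d))
  names(out) <- formatC(densities, format = "g")
  out
}

# igraph view of a binary graph (undirected, simple)
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(unclass(graph), mode = "undirected")
}

#' Wrap a 0/1 adjacency matrix as a binary graph
#'
#' Lets externally constructed graphs (e.g. canonical random-graph models)
#' flow into the metric functions.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param density Optional density annotation.
#' @param group Optional group annotation.
#' @return A `binary_graph`.
#' @export
as_binary_graph <- function(adjacency, density = NA_real_,
                            group = NA_character_) {
  A <- as.matrix(adjacency)
  if (!all(A %in% c(0, 1))) stop("adjacency must be 0/1")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  storage.mode(A) <- "integer"
  if (is.null(rownames(A))) {
    dimnames(A) <- list(region_names(nrow(A)), region_names(nrow(A)))
  }
  achieved <- sum(A) / (nrow(A) * (nrow(A) - 1))
  structure(A, class = c("binary_graph", "matrix", "array"),
            density = if (is.na(density)) achieved else density,
            achieved_density = achieved, group = group)
}
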