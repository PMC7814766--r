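# Plain-text readers/writers for every artifact the pipeline produces.
# All tabular formats are CSV with headers; structured results are JSON.

#' Write / read a cohort or residual table as CSV
#'
#' Metadata columns first, then `region_*` columns, one row per subject.
#'
#' @param table A `cohort_table` or `residual_table`.
#' @param path Output CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   table with its class restored.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param residual If TRUE, the table read back is classed `residual_table`.
#' @export
read_cohort <- function(path, residual = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (length(region_columns(tab)) == 0L) {
    stop("file has no 'region_*' columns; not a cohort table")
  }
  class(tab) <- c(if (residual) "residual_table" else "cohort_table",
                  "data.frame")
  tab
}

#' Write / read a covariance matrix as square CSV
#'
#' Region labels form the header and first column; group and subject count
#' travel in a JSON sidecar `<path>.json`.
#'
#' @param matrix A `cov_matrix`.
#' @param path Output CSV path.
#' @export
write_covariance <- function(matrix, path) {
  df <- data.frame(region = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(group = attr(matrix, "group"),
         n_subjects = attr(matrix, "n_subjects")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_covariance
#' @export
read_covariance <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$region
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(group = NA_character_, n_subjects = NA_integer_)
  }
  m <- (m + t(m)) / 2      # remove asymmetry from decimal round-trip
  new_cov_matrix(m, group = meta$group, n_subjects = meta$n_subjects)
}

#' Write / read a binary graph as an edge list CSV with a JSON sidecar
#'
#' The CSV holds one row per edge (region_i, region_j, weight = 1); density,
#' achieved density, group and the full region set go in `<path>.json` so the
#' adjacency can be reconstructed exactly (including isolated nodes).
#'
#' @param graph A `binary_graph`.
#' @param path Output CSV path.
#' @export
write_bingraph <- function(graph, path) {
  A <- unclass(graph)
  ep <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  el <- data.frame(region_i = rownames(A)[ep[, 1L]],
                   region_j = colnames(A)[ep[, 2L]], weight = 1L)
  el <- el[order(el$region_i, el$region_j), , drop = FALSE]
  utils::write.csv(el, path, row.names = FALSE)
  jsonlite::write_json(
    list(density = attr(graph, "density"),
         achieved_density = attr(graph, "achieved_density"),
         group = attr(graph, "group"),
         regions = rownames(A)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bingraph
#' @export
read_bingraph <- function(path) {
  el <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  R <- length(meta$regions)
  A <- matrix(0L, R, R, dimnames = list(meta$regions, meta$regions))
  if (nrow(el) > 0L) {
    i <- match(el$region_i, meta$regions)
    j <- match(el$region_j, meta$regions)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  structure(A, class = c("binary_graph", "matrix", "array"),
            density = meta$density, achieved_density = meta$achieved_density,
            group = meta$group)
}

#' Write / read a module partition
#'
#' Two-column CSV (region, module); group and stage go in `<path>.json`.
#'
#' @param partition A `partition`.
#' @param path Output CSV path.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(
    data.frame(region = names(partition), module = as.integer(partition)),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(group = attr(partition, "group"), stage = attr(partition, "stage"),
         n_modules = attr(partition, "n_modules")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab <- df$module
  names(lab) <- df$region
  new_partition(lab, group = meta$group, stage = meta$stage)
}

#' Write / read a permutation test result as JSON
#'
#' The null sample is stored alongside as `<path>.null.csv` when
#' `with_null = TRUE`.
#'
#' @param result A `perm_test`.
#' @param path Output JSON path.
#' @param with_null Also write the permutation null sample as CSV.
#' @export
write_test_result <- function(result, path, with_null = FALSE) {
  jsonlite::write_json(
    list(name = result$name,
         observed = result$observed,
         element = names(result$observed),
         ci_lower = result$ci_lower, ci_upper = result$ci_upper,
         p = result$p, n_perm = result$n_perm, n_failed = result$n_failed,
         stratified = result$stratified),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (with_null) {
    utils::write.csv(as.data.frame(result$null),
                     paste0(path, ".null.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_test_result
#' @export
read_test_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  obs <- x$observed
  if (!is.null(x$element) && !all(is.na(x$element))) names(obs) <- x$element
  null_path <- paste0(path, ".null.csv")
  null_mat <- if (file.exists(null_path)) {
    as.matrix(utils::read.csv(null_path))
  } else {
    NULL
  }
  structure(list(name = x$name, observed = obs, null = null_mat,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper, p = x$p,
                 n_perm = x$n_perm, n_failed = x$n_failed,
                 stratified = x$stratified),
            class = "perm_test")
}
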