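# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never clobber user RNG flow.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# One top-level seed -> a named vector of independent stage seeds (all < 2^31).
# Drawing them from a seeded stream keeps the derivation documented and stable.
derive_seeds <- function(seed, stages) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(stages))
    names(s) <- stages
    s
  })
}

#' Names of the region-measure columns of a cohort-like table
#'
#' Region columns are all columns matching `^region_`; every other column is
#' treated as subject metadata.
#'
#' @param table A data frame with `region_*` measure columns.
#' @return Character vector of region column names, in table order.
#' @export
region_columns <- function(table) {
  grep("^region_", names(table), value = TRUE)
}

# Extract the subjects x regions measure matrix from a cohort-like table.
region_matrix <- function(table) {
  rc <- region_columns(table)
  if (length(rc) == 0L) stop("table has no 'region_*' columns")
  m <- as.matrix(table[, rc, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$subject_id
  m
}

# zero-padded region label maker, shared by generator and readers
region_names <- function(n) sprintf("region_%03d", seq_len(n))

stopifnot_scalar_count <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("'%s' must be a single positive integer", what))
  }
}
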