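#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic fan-out of a global seed into per-stage seeds (< 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(phantom = 11L, spots = 23L, preprocess = 37L, cluster = 53L,
            embed = 67L, enrich = 83L, quantify = 101L, biomarker = 127L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offs[[stage]]) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and reference labels;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expectation under independent random labelings.
#'
#' @param a,b Vectors of equal length (any label type).
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Strict numeric CSV cell check used by readers.
assert_numeric_cells <- function(df, path, skip_cols = character()) {
  for (cn in setdiff(colnames(df), skip_cols)) {
    v <- df[[cn]]
    if (is.character(v) || anyNA(suppressWarnings(as.numeric(v)))) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop(sprintf("%s: non-numeric or missing value at row %d, column '%s'",
                   path, bad, cn))
    }
  }
  invisible(df)
}
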