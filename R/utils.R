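# Internal helpers shared across modules.

#' Derive per-replicate RNG seeds from a master seed
#'
#' Replicate seeds are pre-drawn as a block from the master seed, so replicate
#' `i` depends only on `(master_seed, i)` and not on how many replicates were
#' consumed before it. Seeds are kept below 2^31 (R integer range).
#'
#' @param master_seed Integer master seed.
#' @param n Number of replicate seeds to derive.
#' @return Integer vector of length `n`.
#' @keywords internal
replicate_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed %% 2147483647))
  sample.int(2147483646L, n, replace = TRUE)
}

# set.seed() only when a seed was supplied
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  invisible(NULL)
}

# upper-triangle (incl. diagonal) pair index in a fixed column-major order;
# every per-pair vector in the package follows this order
pair_index <- function(factors) {
  n <- length(factors)
  idx <- which(upper.tri(matrix(0L, n, n), diag = TRUE), arr.ind = TRUE)
  data.frame(
    i = idx[, "row"], j = idx[, "col"],
    factor_i = factors[idx[, "row"]], factor_j = factors[idx[, "col"]],
    stringsAsFactors = FALSE
  )
}

# extract per-pair vector from a symmetric factors x factors matrix
pair_vector <- function(m) m[upper.tri(m, diag = TRUE)]

`%||%` <- function(a, b) if (is.null(a)) b else a
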