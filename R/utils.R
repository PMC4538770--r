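# Internal helpers: seed management and input checks.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# state.  All exported functions that consume randomness route through this,
# so a single user-supplied seed makes whole pipelines reproducible.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage sub-seed from the master seed.  Kept strictly below
# .Machine$integer.max so set.seed() always receives a valid 32-bit integer.
subseed <- function(seed, k) {
  s <- (as.double(seed) + as.double(k) * 7919) %% 2147483646
  as.integer(s) + 1L
}

# Validate a genes x samples expression matrix: numeric, finite, >= 3 samples,
# unique identifiers.  Adds default dimnames when absent.
check_matrix <- function(x, min_samples = 3L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (nrow(x) < 1L)
    stop("expression matrix must contain at least one gene (row)")
  if (ncol(x) < min_samples)
    stop("expression matrix must contain at least ", min_samples,
         " samples (columns), got ", ncol(x))
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("g%d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("s%d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers in expression matrix")
  x
}

#' Standardize gene rows
#'
#' Centers and scales every row of an expression matrix to mean 0 and
#' standard deviation 1, which puts DCOL magnitudes and Euclidean sample
#' distances on a common footing across genes.  Rows with zero variance
#' (flat probes) are centered only, so they become all-zero rather than
#' NaN; downstream they can never reach significance.
#'
#' @param x numeric genes x samples matrix.
#' @return matrix of the same shape with standardized rows.
#' @export
standardize_rows <- function(x) {
  x <- check_matrix(x)
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  s[s == 0] <- 1
  xc / s
}

check_order <- function(order, n) {
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("order must be a permutation of 1..", n,
         " (length ", length(order), " given)")
  as.integer(order)
}
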