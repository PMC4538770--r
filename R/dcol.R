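#' Distance based on Conditional Ordered List (DCOL)
#'
#' DCOL measures how much a variable `y` varies between consecutive samples
#' once the samples are arranged by a conditioning order.  For an ordering
#' \eqn{o} of the \eqn{n} samples,
#' \deqn{d_{col}(y \mid o) = \frac{1}{n-1} \sum_{i=2}^{n}
#'   \lvert y_{o(i)} - y_{o(i-1)} \rvert.}
#' Small values indicate that `y` changes smoothly along the order, i.e.
#' that `y` depends (possibly nonlinearly) on whatever the order encodes.
#' The statistic is invariant to reversing the order.
#'
#' @param y numeric vector of length n (one gene across samples).
#' @param order integer permutation of `1:n`; typically a cluster profile
#'   from [hamiltonian_order()], or `order(x)` to condition on a single
#'   covariate.
#' @return a single nonnegative number.
#' @seealso [dcol_null_params()], [dcol_pvalue()]
#' @examples
#' dcol(c(1, 3, 2), 1:3)          # (|3-1| + |2-3|)/2 = 1.5
#' dcol(c(1, 3, 2), order(c(1, 3, 2)))  # minimal over all orders
#' @export
dcol <- function(y, order) {
  if (!is.numeric(y) || length(y) < 2L)
    stop("y must be a numeric vector of length >= 2")
  order <- check_order(order, length(y))
  v <- y[order]
  sum(abs(diff(v))) / (length(y) - 1L)
}

# Vectorized DCOL of every row of x against one sample order.
dcol_rows <- function(x, order) {
  order <- check_order(order, ncol(x))
  cpp_dcol_rows(x, order)
}

#' Per-gene null distribution of DCOL by column permutation
#'
#' Under the null hypothesis that a gene is independent of a conditioning
#' order, that order is just a random rearrangement of the gene's values.
#' The null distribution of DCOL is therefore estimated by permuting the
#' columns of the matrix `B` times (one shared permutation stream applied
#' to all genes jointly) and recording, for each gene, the mean `mu` and
#' standard deviation `sigma` of the resulting DCOL values.  Because the
#' null does not involve the conditioning order at all, one set of
#' parameters per gene serves for testing against any number of cluster
#' profiles.
#'
#' @param x numeric genes x samples matrix.
#' @param B number of column permutations (default 500).
#' @param seed integer seed; results are reproducible given the seed.
#' @return an object of class `"dcol_null"`: a list with numeric vectors
#'   `mu` and `sigma` (named by gene) and the count `n_permutations`.
#' @export
dcol_null_params <- function(x, B = 500L, seed = 1L) {
  x <- check_matrix(x, min_samples = 2L)
  B <- as.integer(B)
  if (is.na(B) || B < 2L)
    stop("B must be at least 2 (standard deviation is undefined otherwise)")
  n <- ncol(x)
  p <- nrow(x)
  s1 <- numeric(p)
  s2 <- numeric(p)
  with_seed(seed, {
    for (b in seq_len(B)) {
      d <- dcol_rows(x, sample.int(n))
      s1 <- s1 + d
      s2 <- s2 + d * d
    }
  })
  mu <- s1 / B
  sigma <- sqrt(pmax(0, (s2 - B * mu^2) / (B - 1)))
  structure(
    list(mu = stats::setNames(mu, rownames(x)),
         sigma = stats::setNames(sigma, rownames(x)),
         n_permutations = B),
    class = "dcol_null")
}

#' p-value of an observed DCOL under the permutation null
#'
#' Left-tail probability of the observed DCOL under a normal approximation
#' `N(mu, sigma^2)` to the permutation null: small DCOL values are evidence
#' of dependence.  Genes whose null standard deviation is zero (constant
#' rows) receive p = 1, so flat probes can never be pulled into a cluster.
#'
#' @param d observed DCOL value(s).
#' @param mu,sigma per-gene null mean and standard deviation, e.g. from
#'   [dcol_null_params()]; recycled against `d`.
#' @return p-value(s) in \[0, 1\].
#' @export
dcol_pvalue <- function(d, mu, sigma) {
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  p <- rep(1, length(d))
  ok <- sigma > 0
  if (any(ok))
    p[ok] <- stats::pnorm(d[ok], mean = if (length(mu) > 1) mu[ok] else mu,
                          sd = if (length(sigma) > 1) sigma[ok] else sigma)
  p
}

#' @export
print.dcol_null <- function(x, ...) {
  cat("DCOL permutation null parameters\n")
  cat("  genes:        ", length(x$mu), "\n")
  cat("  permutations: ", x$n_permutations, "\n")
  cat("  mu  range:    ", format(range(x$mu), digits = 4), "\n")
  cat("  sigma range:  ", format(range(x$sigma), digits = 4), "\n")
  invisible(x)
}
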