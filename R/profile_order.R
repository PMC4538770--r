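#' Pairwise sample distances within a gene subspace
#'
#' Euclidean distance between every pair of sample columns, using only the
#' rows in `genes`.  This is the geometry in which a cluster's profile is
#' sought: samples are points in the member genes' subspace, and the
#' profile is a short open path through them.
#'
#' @param x numeric genes x samples matrix.
#' @param genes nonempty vector of row indices (or row names).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
sample_distances <- function(x, genes) {
  x <- check_matrix(x, min_samples = 2L)
  if (length(genes) == 0L)
    stop("gene subset must be nonempty")
  if (is.character(genes)) genes <- match(genes, rownames(x))
  if (anyNA(genes) || any(genes < 1L) || any(genes > nrow(x)))
    stop("gene subset contains invalid row indices")
  d <- cpp_sample_dist(x, as.integer(genes))
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

check_distmat <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8 * (1 + max(abs(d))))
    stop("distance matrix must be symmetric")
  unname(d)
}

#' Length of an open sample path
#'
#' Sum of distances between consecutive samples along `order`; the quantity
#' minimized by [hamiltonian_order()].  Invariant under reversal.
#'
#' @param d symmetric n x n distance matrix.
#' @param order integer permutation of `1:n`.
#' @return nonnegative path length.
#' @export
path_length <- function(d, order) {
  d <- check_distmat(d)
  n <- nrow(d)
  order <- check_order(order, n)
  if (n < 2L) return(0)
  sum(d[cbind(order[-n], order[-1L])])
}

# Greedy nearest-neighbor path from a given start; ties go to the lowest
# sample index.
nn_path <- function(d, start) {
  cpp_nn_path(d, as.integer(start))
}

# 2-opt descent for an open path; strict improvement threshold guards
# against floating-point cycling.
two_opt <- function(d, path) {
  cpp_two_opt(d, as.integer(path), 1e-10 * (1 + max(d)))
}

#' Short Hamiltonian path through the samples
#'
#' Heuristic solution of the open traveling-salesman problem that defines a
#' cluster profile: an ordering of samples minimizing the sum of distances
#' between consecutive samples.  In one dimension this reduces to plain
#' sorting; in the subspace of a gene cluster it generalizes sorting to the
#' cluster's shared (possibly nonlinear) trajectory.
#'
#' The heuristic builds nearest-neighbor paths from `min(n, 10)` seeded
#' start samples and polishes the three shortest with 2-opt segment
#' reversals until no improving reversal exists, keeping the best.  The
#' result never exceeds the worst nearest-neighbor construction and is
#' deterministic given the seed.
#'
#' @param d symmetric n x n sample distance matrix (n >= 2).
#' @param seed integer seed selecting the start samples.
#' @return integer permutation of `1:n`.
#' @seealso [sample_distances()], [path_length()]
#' @export
hamiltonian_order <- function(d, seed = 1L) {
  d <- check_distmat(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 samples to order")
  if (n == 2L) return(1:2)
  n_starts <- min(n, 10L)
  starts <- with_seed(seed, sample.int(n, n_starts))
  paths <- lapply(starts, function(s) nn_path(d, s))
  lens <- vapply(paths, function(p) path_length(d, p), numeric(1))
  # polish the few best constructions: 2-opt basins differ by start, and
  # the shortest greedy path is not always in the best basin
  polish <- order(lens)[seq_len(min(3L, length(paths)))]
  best <- NULL
  best_len <- Inf
  for (i in polish) {
    p <- two_opt(d, paths[[i]])
    len <- path_length(d, p)
    if (len < best_len) {
      best <- p
      best_len <- len
    }
  }
  best
}

#' Are two sample orders the same undirected path?
#'
#' Profiles are open paths without a preferred direction, so an order and
#' its reversal are equivalent.
#'
#' @param a,b integer permutations of equal length.
#' @return `TRUE` iff `a == b` or `a == rev(b)`.
#' @export
orders_equivalent <- function(a, b) {
  if (length(a) != length(b))
    stop("orders have different lengths")
  identical(as.integer(a), as.integer(b)) ||
    identical(as.integer(a), rev(as.integer(b)))
}
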