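#' Score curve over candidate cluster numbers
#'
#' Runs [kprofiles()] at each candidate K and records the
#' [cluster_score()] (sum of negative log p-values), the quantity whose
#' elbow indicates the number of clusters.
#'
#' @param x numeric genes x samples matrix.
#' @param ks increasing vector of candidate K values (all >= 1).
#' @param seed integer seed; each K gets its own derived sub-seed.
#' @param ... further arguments passed to [kprofiles()] (e.g. `B`,
#'   `max_iter`).
#' @return data frame with columns `k` and `score`.
#' @export
score_curve <- function(x, ks, seed = 1L, ...) {
  ks <- as.integer(ks)
  if (length(ks) == 0L || anyNA(ks) || any(ks < 1L))
    stop("ks must be a nonempty vector of positive integers")
  scores <- vapply(seq_along(ks), function(i) {
    kprofiles(x, K = ks[i], seed = subseed(seed, ks[i]), ...)$score
  }, numeric(1))
  data.frame(k = ks, score = scores)
}

#' Elbow of a score curve
#'
#' Deterministic stand-in for eyeballing the score-vs-K plot: returns the
#' interior K whose curve point lies farthest from the chord joining the
#' first and last points.  Because the perpendicular distance to the chord
#' is proportional to the vertical deviation from it, the choice is
#' invariant to affine rescaling of the score axis.  Ties break toward the
#' smaller K.
#'
#' @param curve data frame with columns `k` and `score` (>= 3 rows),
#'   `k` strictly increasing.
#' @return the chosen K.
#' @export
choose_k_elbow <- function(curve) {
  if (!is.data.frame(curve) || !all(c("k", "score") %in% names(curve)))
    stop("curve must be a data frame with columns 'k' and 'score'")
  m <- nrow(curve)
  if (m < 3L) stop("need at least 3 curve points to locate an elbow")
  k <- curve$k
  s <- curve$score
  if (any(diff(k) <= 0)) stop("k values must be strictly increasing")
  chord <- s[1L] + (k - k[1L]) * (s[m] - s[1L]) / (k[m] - k[1L])
  dev <- abs(s - chord)
  interior <- 2L:(m - 1L)
  k[interior][which.max(dev[interior])]
}

#' Gap-style score for a given K
#'
#' Compares the observed [cluster_score()] at K with its expectation under
#' a structureless reference: `n_ref` matrices obtained by independently
#' permuting the entries within every gene row, which preserves each
#' gene's marginal distribution while destroying all inter-gene
#' dependency.  A clearly positive gap means the fitted structure exceeds
#' what identical marginals produce by chance.
#'
#' @param x numeric genes x samples matrix.
#' @param K number of clusters.
#' @param n_ref number of reference matrices (default 5).
#' @param seed integer seed.
#' @param ... further arguments passed to [kprofiles()].
#' @return observed score minus mean reference score.
#' @export
gap_score <- function(x, K, n_ref = 5L, seed = 1L, ...) {
  x <- check_matrix(x)
  n_ref <- as.integer(n_ref)
  if (is.na(n_ref) || n_ref < 1L) stop("n_ref must be at least 1")
  obs <- kprofiles(x, K = K, seed = subseed(seed, 0L), ...)$score
  ref <- vapply(seq_len(n_ref), function(r) {
    xr <- with_seed(subseed(seed, 1000L + r),
                    t(apply(x, 1L, sample)))
    dimnames(xr) <- dimnames(x)
    kprofiles(xr, K = K, seed = subseed(seed, 2000L + r), ...)$score
  }, numeric(1))
  obs - mean(ref)
}
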