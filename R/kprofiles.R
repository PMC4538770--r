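#' Multiple-testing transform of the p-value cutoff
#'
#' Each gene is implicitly tested against all K cluster profiles and the
#' minimum of the K p-values is taken.  Treating the K p-values as
#' independent uniforms under the null, the per-comparison cutoff that
#' keeps the family-wise rate at the nominal `pi` is
#' \deqn{\pi' = 1 - (1 - \pi)^{1/K}.}
#'
#' @param pi nominal cutoff in (0, 1).
#' @param K number of clusters (>= 1); `K = 1` leaves `pi` unchanged.
#' @return transformed cutoff, strictly decreasing in K.
#' @export
adjust_cutoff <- function(pi, K) {
  if (!is.numeric(pi) || pi <= 0 || pi >= 1)
    stop("pi must lie strictly between 0 and 1")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  1 - (1 - pi)^(1 / K)
}

#' Random initial cluster profiles
#'
#' K profiles with empty member sets and independent uniformly random
#' sample orders — the starting point of the clustering iteration.
#'
#' @param K number of clusters (>= 1).
#' @param n_samples number of samples (>= 2).
#' @param seed integer seed.
#' @return list of K profiles, each `list(members = integer(0), order = <permutation>)`.
#' @export
init_profiles <- function(K, n_samples, seed = 1L) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  if (n_samples < 2L) stop("need at least 2 samples")
  with_seed(seed, lapply(seq_len(K), function(k)
    list(members = integer(0), order = sample.int(n_samples))))
}

#' Significance-gated assignment of genes to profiles
#'
#' Computes each gene's DCOL against every profile's order, picks the
#' profile with the minimum DCOL (ties to the lowest cluster index), and
#' converts that minimum to a p-value using the gene's permutation-null
#' parameters.  A gene is assigned only if its p-value passes the
#' K-adjusted cutoff; otherwise it is left unassigned (label 0), so noise
#' genes do not contaminate profile estimates.
#'
#' @param x numeric genes x samples matrix.
#' @param profiles list of profiles as produced by [init_profiles()] or
#'   [update_profiles()].
#' @param null_params `"dcol_null"` object estimated on `x`.
#' @param cutoff nominal p-value cutoff in (0, 1) before the K adjustment.
#' @return list with integer `assignment` (0 = unassigned) and numeric
#'   `p_values` (the per-gene minimum p-value), both named by gene.
#' @export
assign_genes <- function(x, profiles, null_params, cutoff) {
  x <- check_matrix(x)
  K <- length(profiles)
  if (K < 1L) stop("profiles must be a nonempty list")
  if (length(null_params$mu) != nrow(x))
    stop("null parameters were estimated on a different number of genes")
  D <- vapply(profiles, function(pr) dcol_rows(x, pr$order), numeric(nrow(x)))
  D <- matrix(D, nrow = nrow(x))
  best <- max.col(-D, ties.method = "first")
  d_best <- D[cbind(seq_len(nrow(x)), best)]
  p <- dcol_pvalue(d_best, null_params$mu, null_params$sigma)
  thr <- adjust_cutoff(cutoff, K)
  assignment <- ifelse(p <= thr, best, 0L)
  list(assignment = stats::setNames(as.integer(assignment), rownames(x)),
       p_values = stats::setNames(p, rownames(x)))
}

#' Recompute cluster profiles from the current assignment
#'
#' For each nonempty cluster, the profile is the short Hamiltonian path
#' through the samples in the member genes' subspace.  Unassigned genes
#' (label 0) contribute to no profile.
#'
#' Empty clusters receive a fresh seeded random order, which keeps K
#' fixed; the main [kprofiles()] loop additionally re-nucleates dead and
#' duplicated profiles at informative sample orders (see the package
#' vignette), since a purely random order attracts no genes through the
#' significance gate.
#'
#' @param x numeric genes x samples matrix.
#' @param assignment integer vector with values in `0:K`.
#' @param K number of clusters.
#' @param seed integer seed (used for empty-cluster re-initialization and
#'   TSP start selection).
#' @return list of K profiles (`members`, `order`).
#' @export
update_profiles <- function(x, assignment, K, seed = 1L) {
  x <- check_matrix(x)
  K <- as.integer(K)
  if (any(assignment < 0L | assignment > K))
    stop("assignment values must lie in 0..K")
  lapply(seq_len(K), function(k) {
    members <- which(assignment == k)
    if (length(members) == 0L) {
      list(members = members,
           order = with_seed(subseed(seed, k), sample.int(ncol(x))))
    } else {
      dm <- sample_distances(x, members)
      list(members = members,
           order = hamiltonian_order(dm, seed = subseed(seed, k)))
    }
  })
}

neglog <- function(p) -log(pmax(p, 1e-300))

# Per-gene p-value of every profile: genes x K matrix.
profile_pvalues <- function(x, profiles, null_params) {
  P <- vapply(profiles, function(pr)
    dcol_pvalue(dcol_rows(x, pr$order), null_params$mu, null_params$sigma),
    numeric(nrow(x)))
  matrix(P, nrow = nrow(x))
}

# Row-wise smallest and second-smallest values with the argmin, so the
# minimum excluding any one column is available in O(1).
row_two_mins <- function(P) {
  arg1 <- max.col(-P, ties.method = "first")
  idx <- cbind(seq_len(nrow(P)), arg1)
  min1 <- P[idx]
  P2 <- P
  P2[idx] <- Inf
  min2 <- P2[cbind(seq_len(nrow(P)), max.col(-P2, ties.method = "first"))]
  list(min1 = min1, min2 = min2, arg1 = arg1)
}

# Build a trial profile order seeded at gene g: start from g's own sorted
# order (its DCOL minimizer), recruit every gene significant against it,
# and, if any were recruited, denoise by refitting the Hamiltonian path
# on the recruit set.  With noisy data the single-gene sort is a blurred
# view of the cluster trajectory; the TSP refit on the recruits averages
# the noise out.
nucleus_order <- function(x, g, null_params, thr, seed) {
  o <- order(x[g, ])
  p <- dcol_pvalue(dcol_rows(x, o), null_params$mu, null_params$sigma)
  recruits <- which(p <= thr)
  if (length(recruits) >= 2L)
    o <- hamiltonian_order(sample_distances(x, recruits), seed = seed)
  o
}

# Profile swap moves (the PAM analogue for profiles): propose replacing
# one profile's order by a nucleus order grown from a gene the current
# profiles explain poorly, and accept the replacement only if the total
# score sum(-log p) improves by a clear margin.  A nucleus grown from an
# unmodeled cluster pulls the whole cluster through the significance gate
# on the next pass, while one grown from an isolated noise gene adds
# almost nothing and its swap is rejected.  This is what lets the
# iteration escape the classic fixed points of Lloyd-style alternation —
# two profiles splitting one cluster, or one profile absorbing two —
# which the significance gate would otherwise freeze in place: a random
# re-seed can never recruit genes, but a nucleus order can.
# Deterministic given the seed; candidates are a rank-stratified slice of
# the genes ordered by how poorly the current profiles explain them.
# Returns the (possibly) modified profiles, the number of accepted swaps,
# and the overall best move of the first sweep regardless of sign — the
# "kick" the refinement phase uses to escape score valleys that no
# single uphill swap can cross.
swap_profiles <- function(x, profiles, null_params, cutoff, seed,
                          n_candidates = 15L, margin = 1e-3,
                          exclude = integer(0)) {
  K <- length(profiles)
  if (K < 2L)
    return(list(profiles = profiles, n_accepted = 0L, kick = NULL))
  thr <- adjust_cutoff(cutoff, K)
  P <- profile_pvalues(x, profiles, null_params)
  n_accepted <- 0L
  kick <- NULL
  for (sweep in seq_len(K)) {
    mm <- row_two_mins(P)
    S0 <- sum(neglog(mm$min1))
    pool <- setdiff(which(null_params$sigma > 0), exclude)
    if (length(pool) < 2L) break
    ranks <- order(mm$min1[pool], decreasing = TRUE)
    take <- unique(round(seq(1L, length(pool),
                             length.out = min(n_candidates, length(pool)))))
    cand <- pool[ranks[take]]
    best_gain <- 0
    best_move <- NULL
    for (i in seq_along(cand)) {
      o <- nucleus_order(x, cand[i], null_params, thr,
                         seed = subseed(seed, 10L * sweep + i))
      colP <- dcol_pvalue(dcol_rows(x, o), null_params$mu, null_params$sigma)
      for (k in seq_len(K)) {
        excl <- ifelse(mm$arg1 == k, mm$min2, mm$min1)
        Snew <- sum(neglog(pmin(excl, colP)))
        if (sweep == 1L &&
            (is.null(kick) || Snew - S0 > kick$gain))
          kick <- list(k = k, order = o, gene = cand[i], gain = Snew - S0)
        if (Snew > S0 * (1 + margin) && Snew - S0 > best_gain) {
          best_gain <- Snew - S0
          best_move <- list(k = k, order = o, colP = colP)
        }
      }
    }
    if (is.null(best_move)) break
    n_accepted <- n_accepted + 1L
    profiles[[best_move$k]] <- list(members = integer(0),
                                    order = best_move$order)
    P[, best_move$k] <- best_move$colP
  }
  list(profiles = profiles, n_accepted = n_accepted, kick = kick)
}

#' K-profiles nonlinear clustering
#'
#' Nonlinear counterpart of K-means for genes x samples expression data.
#' Instead of a mean vector, each cluster is summarized by a profile — an
#' ordering of the samples (short Hamiltonian path in the cluster's gene
#' subspace) — and a gene's closeness to a cluster is its DCOL along the
#' profile, judged for significance against the gene's own permutation
#' null.  The iteration alternates significance-gated assignment with TSP
#' profile updates while the nominal p-value cutoff decays linearly from
#' `p_start` to `p_end`, so early arbitrary profiles recruit loosely and
#' mature profiles retain only genuinely associated genes.  Genes never
#' reaching significance end unassigned (cluster 0).
#'
#' @param x numeric genes x samples matrix (at least 3 samples).
#' @param K number of clusters.
#' @param p_start,p_end initial and final nominal p-value cutoffs
#'   (defaults 0.2 and 0.05); `p_end <= p_start`.
#' @param max_iter number of iterations over which the cutoff ramps down
#'   to `p_end` (default 20).
#' @param refine_iter additional refinement budget after the ramp
#'   (default `max_iter`): iterations at `p_end` during which the search
#'   may keep improving the score by profile swap moves and score-guided
#'   kicks (see Details) before settling; the best-scoring state visited
#'   at the final cutoff is returned.  Set to 0 to stop at the end of the
#'   ramp.
#' @param nstart number of random initializations (default 2, as with
#'   [stats::kmeans()] restarts); the fit with the best score is
#'   returned.  The permutation null is estimated once and shared.
#' @param B number of column permutations for the DCOL null (default 500).
#' @param seed integer seed governing every random choice (null
#'   permutations, initial profiles, empty-cluster restarts, TSP starts).
#' @param standardize standardize gene rows first (default `TRUE`).
#'
#' @details Lloyd-style alternation alone is easily trapped: two profiles
#' can stably split one cluster, or one profile absorb two, and the
#' significance gate prevents a randomly re-seeded profile from ever
#' recruiting genes.  The iteration therefore also proposes *swap moves*
#' — replacing a profile with a nucleus order grown from a poorly
#' explained gene — accepting them only when the model-fit score
#' [cluster_score()] improves, and, once assignments are stable at the
#' final cutoff, a few score-guided kicks (best swap even if locally
#' downhill) with the best-scoring state retained.
#' @return object of class `"kprofiles"`: list with `assignment` (named
#'   integer vector, 0 = unassigned), `p_values` (named per-gene minimum
#'   p-value), `profiles` (list of K `members`/`order` pairs), `K`,
#'   `n_iterations`, `converged`, and `score` (sum of -log p).
#' @examples
#' sim <- simulate_expression(m_clusters = 2, genes_per_cluster = 15,
#'                            n_samples = 30, n_noise_genes = 5,
#'                            noise_sd = 0.2, seed = 1)
#' fit <- kprofiles(sim$matrix, K = 2, B = 100, seed = 1)
#' table(fit$assignment, sim$labels)
#' @export
kprofiles <- function(x, K, p_start = 0.2, p_end = 0.05, max_iter = 20L,
                      refine_iter = 2L * max_iter, nstart = 2L, B = 500L,
                      seed = 1L, standardize = TRUE) {
  x <- check_matrix(x)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  if (p_start <= 0 || p_start >= 1 || p_end <= 0 || p_end >= 1)
    stop("p_start and p_end must lie strictly between 0 and 1")
  if (p_end > p_start) stop("p_end must not exceed p_start")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("max_iter must be positive")
  if (standardize) x <- standardize_rows(x)
  refine_iter <- as.integer(refine_iter)
  if (is.na(refine_iter) || refine_iter < 0L)
    stop("refine_iter must be nonnegative")
  nstart <- as.integer(nstart)
  if (is.na(nstart) || nstart < 1L) stop("nstart must be positive")

  # the permutation null does not depend on the initialization, so it is
  # estimated once and shared across restarts
  null_params <- dcol_null_params(x, B = B, seed = subseed(seed, 0L))
  best_fit <- NULL
  for (r in seq_len(nstart)) {
    fit <- kprofiles_once(x, K, p_start, p_end, max_iter, refine_iter,
                          null_params,
                          seed = if (r == 1L) seed else subseed(seed, 900000L + r))
    if (is.null(best_fit) || fit$score > best_fit$score) best_fit <- fit
  }
  best_fit$nstart <- nstart
  best_fit
}

kprofiles_once <- function(x, K, p_start, p_end, max_iter, refine_iter,
                           null_params, seed) {
  profiles <- init_profiles(K, ncol(x), seed = subseed(seed, 1L))
  cutoffs <- if (max_iter == 1L) p_end else
    seq(p_start, p_end, length.out = max_iter)

  total_iter <- max_iter + refine_iter
  # more clusters means more distinct trapped configurations worth probing
  kick_patience <- max(3L, K %/% 2L)
  prev <- NULL
  best <- NULL
  kicks_since_best <- 0L
  kicked <- integer(0)
  converged <- FALSE
  t_done <- 0L
  for (t in seq_len(total_iter)) {
    cutoff_t <- if (t >= max_iter) p_end else cutoffs[t]
    asg <- assign_genes(x, profiles, null_params, cutoff_t)
    t_done <- t
    at_end <- cutoff_t <= p_end
    if (at_end) {
      S <- cluster_score(asg$p_values)
      if (is.null(best) || S > best$score) {
        best <- list(profiles = profiles, assignment = asg$assignment,
                     p_values = asg$p_values, score = S)
        kicks_since_best <- 0L
        kicked <- integer(0)
      }
    }
    stable <- identical(asg$assignment, prev)
    prev <- asg$assignment
    profiles <- update_profiles(x, asg$assignment, K,
                                seed = subseed(seed, 100L + t))
    sw <- swap_profiles(x, profiles, null_params, cutoff_t,
                        seed = subseed(seed, 500L + t), exclude = kicked)
    profiles <- sw$profiles
    if (at_end && stable && sw$n_accepted == 0L) {
      # local optimum at the final cutoff: either accept it, or kick a
      # profile to look for a better one while keeping the best state
      if (is.null(sw$kick) || kicks_since_best >= kick_patience || t >= total_iter) {
        converged <- TRUE
        break
      }
      profiles[[sw$kick$k]] <- list(members = integer(0),
                                    order = sw$kick$order)
      kicked <- c(kicked, sw$kick$gene)
      kicks_since_best <- kicks_since_best + 1L
    }
  }
  if (is.null(best))  # budget ended before the cutoff reached p_end
    best <- list(profiles = profiles, assignment = asg$assignment,
                 p_values = asg$p_values, score = cluster_score(asg$p_values))
  profiles <- best$profiles
  for (k in seq_len(K))
    profiles[[k]]$members <- which(best$assignment == k)

  structure(
    list(assignment = best$assignment,
         p_values = best$p_values,
         profiles = profiles,
         K = K,
         n_iterations = t_done,
         converged = converged,
         score = best$score,
         null_params = null_params),
    class = "kprofiles")
}

#' Model-fit score: sum of negative log p-values
#'
#' The K-profiles analogue of the within-cluster sum of squares used for
#' choosing K in K-means: \eqn{\sum_i -\log p_i} over all genes (assigned
#' and unassigned), where \eqn{p_i} is gene i's final minimum DCOL
#' p-value.  Larger scores mean more dependency structure captured.
#' p-values are floored at 1e-300 before the log so perfect fits do not
#' produce infinities.
#'
#' @param fit a `"kprofiles"` object, or directly a numeric vector of
#'   per-gene p-values.
#' @return nonnegative score.
#' @export
cluster_score <- function(fit) {
  p <- if (inherits(fit, "kprofiles")) fit$p_values else fit
  if (!is.numeric(p) || length(p) == 0L)
    stop("need a kprofiles fit or a numeric vector of p-values")
  sum(-log(pmax(p, 1e-300)))
}

#' @export
print.kprofiles <- function(x, ...) {
  sizes <- vapply(x$profiles, function(p) length(p$members), integer(1))
  cat("K-profiles clustering\n")
  cat("  genes:       ", length(x$assignment),
      " (", sum(x$assignment == 0L), " unassigned)\n", sep = "")
  cat("  K:           ", x$K, "  cluster sizes: ",
      paste(sizes, collapse = ", "), "\n", sep = "")
  cat("  iterations:  ", x$n_iterations,
      if (x$converged) " (converged)" else " (max reached)", "\n", sep = "")
  cat("  score:       ", format(x$score, digits = 6), "\n", sep = "")
  invisible(x)
}
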