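#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions of the same items
#' (Hubert-Arabie form), computed from the pair-count contingency table:
#' 1 for identical partitions up to relabeling, about 0 for independent
#' ones, and possibly negative for partitions that agree less than chance.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors have different lengths")
  if (length(a) < 2L)
    stop("need at least 2 items")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  S <- sum(ch2(tab))
  A <- sum(ch2(rowSums(tab)))
  B <- sum(ch2(colSums(tab)))
  Tn <- ch2(length(a))
  E <- A * B / Tn
  denom <- (A + B) / 2 - E
  if (denom == 0) return(if (S == E) 1 else 0)
  (S - E) / denom
}

#' Confusion matrix between reported and true clusters
#'
#' Cross-tabulates a clustering result against truth.  Rows are the
#' reported clusters with an "unassigned" row first (reported label 0);
#' columns are the true clusters with the pure-noise group (true label 0)
#' first.  A good result concentrates counts on a diagonal-like pattern
#' with the noise column absorbed by the unassigned row.
#'
#' @param reported integer labels, 0 = unassigned.
#' @param truth integer labels, 0 = noise gene.
#' @return integer matrix with descriptive dimnames.
#' @export
cluster_confusion <- function(reported, truth) {
  if (length(reported) != length(truth))
    stop("label vectors have different lengths")
  rlev <- sort(unique(c(0L, as.integer(reported))))
  tlev <- sort(unique(c(0L, as.integer(truth))))
  tab <- table(factor(reported, levels = rlev),
               factor(truth, levels = tlev))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab))
  rownames(m) <- ifelse(rlev == 0L, "unassigned", paste0("cluster", rlev))
  colnames(m) <- ifelse(tlev == 0L, "noise", paste0("true", tlev))
  m
}

# ARI restricted to genes that truly belong to a cluster; a signal gene
# the method left unassigned keeps label 0, i.e. forms its own "missed"
# group and is penalized.
benchmark_ari <- function(reported, truth) {
  keep <- truth != 0L
  adjusted_rand_index(reported[keep], truth[keep])
}

#' Benchmark K-profiles against a k-means baseline on simulated data
#'
#' For each simulation setting and replicate, generates a dataset with
#' [simulate_expression()], runs each method with K equal to the true
#' number of clusters, and scores the result by the Adjusted Rand Index
#' over the genes that truly belong to a cluster (an unassigned signal
#' gene counts against the method).  The k-means baseline is
#' [stats::kmeans()] on the standardized rows with 10 restarts — the
#' linear reference the nonlinear method is meant to beat when
#' dependencies are non-monotone.
#'
#' @param specs list of simulation settings; each element is a named list
#'   of arguments for [simulate_expression()] (everything except `seed`).
#' @param methods subset of `c("kprofiles", "kmeans")`.
#' @param reps replicates per setting (fresh data each time).
#' @param seed integer seed; every replicate and method gets a derived
#'   sub-seed, so the whole table is reproducible.
#' @param ... further arguments passed to [kprofiles()] (e.g. `B`).
#' @return data frame with columns `mechanism`, `m`, `noise_sd`,
#'   `method`, `rep`, `ari`.
#' @export
run_benchmark <- function(specs, methods = c("kprofiles", "kmeans"),
                          reps = 1L, seed = 1L, ...) {
  if (!is.list(specs) || length(specs) == 0L)
    stop("specs must be a nonempty list of simulation settings")
  if (!is.list(specs[[1L]])) specs <- list(specs)
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be at least 1")

  out <- list()
  row <- 0L
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    for (r in seq_len(reps)) {
      sim <- do.call(simulate_expression,
                     c(sp, list(seed = subseed(seed, i * 10000L + r))))
      M <- sim$spec$m_clusters
      xs <- standardize_rows(sim$matrix)
      for (method in methods) {
        reported <- if (method == "kprofiles") {
          fit <- kprofiles(xs, K = M, standardize = FALSE,
                           seed = subseed(seed, i * 10000L + 1000L + r), ...)
          fit$assignment
        } else {
          km <- with_seed(subseed(seed, i * 10000L + 2000L + r),
                          stats::kmeans(xs, centers = M, nstart = 10L))
          km$cluster
        }
        row <- row + 1L
        out[[row]] <- data.frame(
          mechanism = sim$spec$mechanism,
          m = M,
          noise_sd = sim$spec$noise_sd,
          method = method,
          rep = r,
          ari = benchmark_ari(as.integer(reported), sim$labels))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
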