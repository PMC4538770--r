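# Independent oracles used across the test files.  These deliberately use
# naive formulations (direct formula evaluation, exhaustive enumeration,
# brute-force pair counting) so they share no code with the package
# internals they check.

# Direct evaluation of the DCOL formula.
dcol_direct <- function(y, ord) {
  v <- y[ord]
  s <- 0
  for (i in 2:length(v)) s <- s + abs(v[i] - v[i - 1])
  s / (length(v) - 1)
}

# All permutations of 1:n as a matrix (n! rows), recursively.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[r, ]])
    }
  }
  out
}

# Brute-force shortest open path length through a distance matrix.
brute_shortest_path <- function(d) {
  perms <- all_perms(nrow(d))
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    len <- sum(d[cbind(p[-length(p)], p[-1])])
    if (len < best) best <- len
  }
  best
}

# Adjusted Rand Index by explicit pair counting over all item pairs.
ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  np <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / np
  maxind <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (maxind - expected)
}

# Small standardized matrix with planted structure for quick fits.
tiny_sim <- function(seed = 1, m = 2, gpc = 15, n = 30, noise = 5,
                     noise_sd = 0.2) {
  simulate_expression(m_clusters = m, genes_per_cluster = gpc,
                      n_samples = n, n_noise_genes = noise,
                      noise_sd = noise_sd, seed = seed)
}
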