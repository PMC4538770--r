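#' Link functions for simulated gene dependencies
#'
#' The four shapes used to couple a simulated gene to its driver: linear
#' (identity), sine `sin(pi * z)`, box wave `sign(sin(pi * z))`, and
#' absolute value.  With a standard-normal driver the sine and box waves
#' traverse about three half-cycles, giving strongly non-monotone
#' dependencies that defeat correlation-based clustering.  By default the
#' transformed vector is standardized to mean 0, sd 1 so that the additive
#' noise level is comparable across link functions.
#'
#' @param name one of `"linear"`, `"sine"`, `"box"`, `"abs"`.
#' @param x numeric driver vector.
#' @param standardize standardize the output (default `TRUE`).
#' @return numeric vector of the same length.
#' @export
apply_link <- function(name, x, standardize = TRUE) {
  v <- switch(name,
              linear = x,
              sine = sin(pi * x),
              box = ifelse(sin(pi * x) >= 0, 1, -1),
              abs = abs(x),
              stop("unknown link function: ", name))
  if (standardize) {
    v <- v - mean(v)
    s <- stats::sd(v)
    if (s > 0) v <- v / s
  }
  v
}

link_names <- c("linear", "sine", "box", "abs")

#' Simulate clustered expression data with nonlinear dependencies
#'
#' Generates a genes x samples matrix containing `m_clusters` clusters of
#' mutually dependent genes plus pure-noise genes, with known labels for
#' external evaluation (label 0 = noise gene).  Three generation
#' mechanisms are available:
#'
#' * `"hidden_factor"` — each cluster has one latent factor `z ~ N(0,1)`;
#'   every member gene is `f(z) + eps` with `f` drawn from `link_set`.
#' * `"dep1"` — genes are generated sequentially; each new gene is `f` of
#'   one uniformly chosen earlier gene in the cluster.
#' * `"dep2"` — each new gene is `b1*f(g1) + b2*g(g2)` for two chosen
#'   earlier genes, links `f`, `g`, and weights `b1, b2 ~ U(-1, 1)`.
#'
#' Every generated gene is standardized before noise, so `noise_sd` is the
#' noise standard deviation relative to unit signal.  For the sequential
#' mechanisms the noise is added after the whole cluster has been
#' generated, so downstream genes are functions of noise-free drivers.
#' Noise genes are i.i.d. standard normal.
#'
#' @param m_clusters number of true clusters M.
#' @param genes_per_cluster genes per cluster (default 100).
#' @param n_samples number of samples (default 100).
#' @param n_noise_genes pure-noise genes appended after the clusters
#'   (default 100).
#' @param mechanism `"hidden_factor"` (default), `"dep1"`, or `"dep2"`.
#' @param link_set subset of `c("linear", "sine", "box", "abs")`.
#' @param noise_sd standard deviation of the additive noise (default 0.5).
#' @param seed integer seed; the dataset is reproducible given the seed.
#' @return object of class `"sim_dataset"`: list with `matrix` (with gene
#'   and sample identifiers), integer `labels` (1..M, 0 for noise), and
#'   `spec` recording the arguments plus per-cluster generation details
#'   (chosen links, parent genes, weights).
#' @export
simulate_expression <- function(m_clusters, genes_per_cluster = 100L,
                                n_samples = 100L, n_noise_genes = 100L,
                                mechanism = c("hidden_factor", "dep1", "dep2"),
                                link_set = link_names, noise_sd = 0.5,
                                seed = 1L) {
  mechanism <- match.arg(mechanism)
  m_clusters <- as.integer(m_clusters)
  genes_per_cluster <- as.integer(genes_per_cluster)
  n_samples <- as.integer(n_samples)
  n_noise_genes <- as.integer(n_noise_genes)
  if (m_clusters < 1L) stop("m_clusters must be positive")
  if (genes_per_cluster < 1L) stop("genes_per_cluster must be positive")
  if (n_samples < 2L) stop("n_samples must be at least 2")
  if (n_noise_genes < 0L) stop("n_noise_genes must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(link_set) == 0L || !all(link_set %in% link_names))
    stop("link_set must be a nonempty subset of: ",
         paste(link_names, collapse = ", "))
  if (mechanism == "dep2" && genes_per_cluster < 2L)
    stop("dep2 needs at least 2 genes per cluster")

  p <- m_clusters * genes_per_cluster + n_noise_genes
  details <- vector("list", m_clusters)
  x <- with_seed(seed, {
    rows <- vector("list", m_clusters + 1L)
    for (m in seq_len(m_clusters)) {
      cl <- matrix(0, genes_per_cluster, n_samples)
      links <- character(genes_per_cluster)
      parents <- vector("list", genes_per_cluster)
      betas <- vector("list", genes_per_cluster)
      if (mechanism == "hidden_factor") {
        z <- stats::rnorm(n_samples)
        for (g in seq_len(genes_per_cluster)) {
          links[g] <- sample(link_set, 1L)
          cl[g, ] <- apply_link(links[g], z) +
            stats::rnorm(n_samples, sd = noise_sd)
        }
        details[[m]] <- list(z = z, links = links)
      } else {
        signal <- matrix(0, genes_per_cluster, n_samples)
        signal[1L, ] <- stats::rnorm(n_samples)
        sd1 <- stats::sd(signal[1L, ])
        if (sd1 > 0)
          signal[1L, ] <- (signal[1L, ] - mean(signal[1L, ])) / sd1
        for (g in seq_len(genes_per_cluster)[-1L]) {
          if (mechanism == "dep1") {
            par <- sample.int(g - 1L, 1L)
            links[g] <- sample(link_set, 1L)
            signal[g, ] <- apply_link(links[g], signal[par, ])
            parents[[g]] <- par
          } else {
            par <- if (g == 2L) c(1L, 1L) else sample.int(g - 1L, 2L)
            f <- sample(link_set, 1L)
            h <- sample(link_set, 1L)
            b <- stats::runif(2L, -1, 1)
            v <- b[1L] * apply_link(f, signal[par[1L], ]) +
              b[2L] * apply_link(h, signal[par[2L], ])
            v <- v - mean(v)
            sv <- stats::sd(v)
            if (sv > 0) v <- v / sv
            signal[g, ] <- v
            links[g] <- paste(f, h, sep = "+")
            parents[[g]] <- par
            betas[[g]] <- b
          }
        }
        cl <- signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                              nrow(signal), ncol(signal))
        details[[m]] <- list(links = links, parents = parents, betas = betas)
      }
      rows[[m]] <- cl
    }
    rows[[m_clusters + 1L]] <-
      if (n_noise_genes > 0L)
        matrix(stats::rnorm(n_noise_genes * n_samples),
               n_noise_genes, n_samples)
      else
        matrix(0, 0L, n_samples)
    do.call(rbind, rows)
  })

  rownames(x) <- sprintf("g%04d", seq_len(p))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  labels <- c(rep(seq_len(m_clusters), each = genes_per_cluster),
              rep(0L, n_noise_genes))
  structure(
    list(matrix = x,
         labels = stats::setNames(as.integer(labels), rownames(x)),
         spec = list(m_clusters = m_clusters,
                     genes_per_cluster = genes_per_cluster,
                     n_samples = n_samples,
                     n_noise_genes = n_noise_genes,
                     mechanism = mechanism,
                     link_set = link_set,
                     noise_sd = noise_sd,
                     seed = seed,
                     details = details)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  s <- x$spec
  cat("Simulated expression dataset (", s$mechanism, ")\n", sep = "")
  cat("  ", s$m_clusters, " clusters x ", s$genes_per_cluster,
      " genes + ", s$n_noise_genes, " noise genes, ",
      s$n_samples, " samples\n", sep = "")
  cat("  links: ", paste(s$link_set, collapse = ", "),
      "   noise sd: ", s$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix in the package's TSV dialect (see
#' [write_expression()]) and the true labels as a two-column TSV
#' (`gene_id`, `true_label`).
#'
#' @param sim a `"sim_dataset"` object.
#' @param matrix_path,labels_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_sim_dataset <- function(sim, matrix_path, labels_path) {
  if (!inherits(sim, "sim_dataset")) stop("sim must be a sim_dataset")
  write_expression(sim$matrix, matrix_path)
  df <- data.frame(gene_id = names(sim$labels), true_label = sim$labels)
  utils::write.table(df, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(c(matrix_path, labels_path))
}
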