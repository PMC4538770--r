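#' Read an expression matrix from TSV
#'
#' Expects the tab-separated dialect this package writes: a header row of
#' sample identifiers (first field names the gene-id column), one row per
#' gene with the gene identifier in the first column and numeric values in
#' the rest.  Missing or non-numeric cells, duplicate identifiers and
#' matrices with fewer than 3 samples are rejected with messages naming
#' the offending row and column.
#'
#' @param path file path.
#' @param standardize standardize gene rows on load (default `TRUE`),
#'   which makes DCOL magnitudes and sample distances comparable across
#'   genes.
#' @return numeric genes x samples matrix with gene/sample dimnames.
#' @export
read_expression <- function(path, standardize = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 4L)
    stop("matrix in ", path, " has fewer than 3 samples")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in ", path)
  x <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) | !nzchar(trimws(col)))
    if (length(bad) > 0L)
      stop("non-numeric or missing value at gene '", ids[bad[1L]],
           "', sample '", sample_ids[j], "' in ", path)
    x[, j] <- v
  }
  x <- check_matrix(x)
  if (standardize) standardize_rows(x) else x
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: UTF-8, tab-separated, `\n` line
#' endings, `.` decimal mark, header `gene_id` followed by the sample
#' identifiers.  Values are written with 15 significant digits so a
#' write/read round trip is lossless well past 1e-9.
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  x <- check_matrix(x, min_samples = 2L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con, sep = "\n")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], formatC(x[i, ], format = "g", digits = 15)),
          collapse = "\t"), character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Write clustering results to a directory
#'
#' Produces three plain-text files: `assignments.tsv` (gene_id, cluster —
#' 0 for unassigned — and the gene's final minimum DCOL p-value with 6
#' significant digits), `profiles.tsv` (one row per cluster listing the
#' sample identifiers in profile order), and `summary.txt` (K, iterations,
#' convergence, score).
#'
#' @param fit a `"kprofiles"` object.
#' @param sample_ids character vector of sample identifiers in matrix
#'   column order.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_result <- function(fit, sample_ids, dir) {
  if (!inherits(fit, "kprofiles")) stop("fit must be a kprofiles object")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(fit$profiles[[1L]]$order)
  if (length(sample_ids) != n)
    stop("sample_ids length does not match the fitted profiles")

  apath <- file.path(dir, "assignments.tsv")
  adf <- data.frame(gene_id = names(fit$assignment),
                    cluster = as.integer(fit$assignment),
                    p_value = formatC(fit$p_values, format = "g", digits = 6))
  utils::write.table(adf, apath, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  ppath <- file.path(dir, "profiles.tsv")
  plines <- vapply(seq_along(fit$profiles), function(k)
    paste(c(k, sample_ids[fit$profiles[[k]]$order]), collapse = "\t"),
    character(1))
  writeLines(c(paste(c("cluster", paste0("pos", seq_len(n))), collapse = "\t"),
               plines), ppath)

  spath <- file.path(dir, "summary.txt")
  writeLines(c(paste("K:", fit$K),
               paste("iterations:", fit$n_iterations),
               paste("converged:", fit$converged),
               paste("score:", formatC(fit$score, format = "g", digits = 10)),
               paste("unassigned:", sum(fit$assignment == 0L))),
             spath)
  invisible(c(apath, ppath, spath))
}
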