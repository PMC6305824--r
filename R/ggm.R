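# Shrinkage Gaussian graphical model inference for one condition.
#
# The estimator follows the analytic shrinkage scheme for correlation
# matrices with the identity target: the sample correlation matrix R is
# replaced by (1 - lambda*) R + lambda* I, where
#
#   lambda* = sum_{i<j} Var^(r_ij) / sum_{i<j} r_ij^2 , clipped to [0, 1],
#
# and Var^(r_ij) is the unbiased empirical variance of the per-sample
# cross-products of the standardized data. Partial correlations follow
# from the inverse of the shrunk correlation matrix via
# rho_ij = -omega_ij / sqrt(omega_ii * omega_jj).

#' Sample Pearson correlation of a gene-by-sample slice
#'
#' @param x genes-by-samples numeric matrix (one condition).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 3L) stop("need >= 3 samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0]
    stop("zero-variance gene(s): ", paste(bad, collapse = ", "))
  }
  stats::cor(t(x))
}

# center and scale rows (sd with n-1 denominator)
standardize_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  (x - m) / s
}

#' Analytic shrinkage intensity toward the identity target
#'
#' Computes `lambda* = sum Var^(r_ij) / sum r_ij^2` over the off-diagonal
#' pairs, clipped to \[0, 1\]. With standardized rows `z` and per-sample
#' cross-products `w_kij = z_ik z_jk`, the variance estimate is
#' `Var^(r_ij) = n / (n-1)^3 * sum_k (w_kij - mean_k w_kij)^2`. A zero
#' denominator (all sample correlations exactly zero) yields 1 by
#' convention.
#'
#' @param x genes-by-samples numeric matrix (one condition, >= 3 samples).
#' @return shrinkage intensity in \[0, 1\].
#' @export
shrinkage_lambda <- function(x) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  if (n < 3L) stop("need >= 3 samples to estimate Var(r)")
  z <- standardize_rows(x)
  zt <- t(z)                               # n x p
  sw <- crossprod(zt)                      # sum_k w_kij = (n-1) r_ij
  sw2 <- crossprod(zt^2)                   # sum_k w_kij^2
  vr <- n / (n - 1)^3 * (sw2 - sw^2 / n)
  r <- sw / (n - 1)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(vr[off]) / denom))
}

#' Partial correlations from a (shrunk) correlation matrix
#'
#' Inverts the matrix and applies
#' `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)`; the diagonal is set
#' to 1.
#'
#' @param shrunk_correlation symmetric positive-definite matrix.
#' @return partial-correlation matrix, unit diagonal.
#' @export
partial_correlations <- function(shrunk_correlation) {
  omega <- tryCatch(solve(shrunk_correlation),
                    error = function(e)
                      stop("correlation matrix is numerically singular"))
  pc <- precision_to_pcor(omega)
  dimnames(pc) <- dimnames(shrunk_correlation)
  pc
}

#' Rank all gene pairs by absolute partial correlation
#'
#' All i < j pairs sorted by `|pcor|` descending; ties are broken
#' lexicographically by `(gene_i, gene_j)` for cross-platform determinism.
#'
#' @param partial_correlation symmetric matrix.
#' @param gene_ids gene identifiers (defaults to the matrix rownames).
#' @return data.frame with columns `gene_i`, `gene_j`, `pcor`, `rank`.
#' @export
rank_edges <- function(partial_correlation, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(partial_correlation)
  p <- nrow(partial_correlation)
  stopifnot(length(gene_ids) == p)
  ut <- which(upper.tri(partial_correlation), arr.ind = TRUE)
  # within each upper-triangle pair the row index is the smaller one, and
  # gene_ids order defines the lexicographic convention used throughout
  gi <- gene_ids[ut[, 1]]
  gj <- gene_ids[ut[, 2]]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  pc <- partial_correlation[ut]
  o <- order(-abs(pc), gi, gj, method = "radix")
  data.frame(gene_i = gi[o], gene_j = gj[o], pcor = pc[o],
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Retain the top-k ranked edges
#'
#' @param edges ranked edge data.frame from [rank_edges()].
#' @param k number of edges to keep (default 1500).
#' @return the first `min(k, nrow(edges))` edges.
#' @export
top_k_edges <- function(edges, k = 1500L) {
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(edges))
    warning("k = ", k, " exceeds the ", nrow(edges),
            " candidate edges; returning all")
  utils::head(edges, k)
}

#' Fit a shrinkage partial-correlation model for one condition
#'
#' Genes are centered and scaled within the condition, the shrinkage
#' intensity is estimated analytically, and partial correlations are
#' computed from the inverted shrunk correlation matrix.
#'
#' @param x genes-by-samples matrix for one condition.
#' @param condition condition label.
#' @return a `PartialCorrelationModel`: list with `gene_ids`,
#'   `lambda_star`, `shrunk_correlation`, `partial_correlation`, `edges`
#'   (ranked), `n_samples`, `condition`.
#' @export
fit_ggm <- function(x, condition = "condition") {
  r <- sample_correlation(x)
  lambda <- shrinkage_lambda(x)
  p <- nrow(r)
  shrunk <- (1 - lambda) * r + lambda * diag(p)
  dimnames(shrunk) <- dimnames(r)
  pc <- partial_correlations(shrunk)
  structure(list(gene_ids = rownames(x), lambda_star = lambda,
                 shrunk_correlation = shrunk, partial_correlation = pc,
                 edges = rank_edges(pc), n_samples = ncol(x),
                 condition = condition),
            class = "PartialCorrelationModel")
}

#' @export
print.PartialCorrelationModel <- function(x, ...) {
  cat("PartialCorrelationModel (", x$condition, "): ",
      length(x$gene_ids), " genes, n = ", x$n_samples,
      ", lambda* = ", signif(x$lambda_star, 4), "\n", sep = "")
  invisible(x)
}
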