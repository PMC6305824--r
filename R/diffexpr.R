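# Per-dataset differential-expression calling and the multi-dataset
# intersection into mutual DEGs. The test is a per-gene two-sample Welch t
# (the interface also accepts externally computed p-values), adjustment is
# Benjamini-Hochberg, and calls use strict fold-change / adjusted-p
# thresholds (defaults fold-change > 2.0 or < 0.5, adjusted p < 0.01).

split_conditions <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  lv <- unique(study$condition)
  if (!all(c("normal", "cancer") %in% lv))
    stop("study must contain both 'normal' and 'cancer' samples")
  list(normal = study$values[, study$condition == "normal", drop = FALSE],
       cancer = study$values[, study$condition == "cancer", drop = FALSE])
}

#' Per-gene log2 fold-change (cancer minus normal)
#'
#' Difference of condition means on the log2 scale; the fold-change is
#' `2^log2fc`.
#'
#' @param study an `ExpressionStudy` containing both conditions.
#' @return named numeric vector of log2 fold-changes.
#' @export
log2_fold_change <- function(study) {
  sp <- split_conditions(study)
  if (ncol(sp$normal) == 0L || ncol(sp$cancer) == 0L)
    stop("a condition has zero samples")
  rowMeans(sp$cancer) - rowMeans(sp$normal)
}

#' Per-gene Welch two-sample t-test
#'
#' Two-sided p-value from the Welch statistic with Welch-Satterthwaite
#' degrees of freedom, computed independently per gene. Degenerate genes
#' with zero variance in both groups yield p = 1 when the group means are
#' equal and p = 0 otherwise.
#'
#' @param study an `ExpressionStudy` containing both conditions (>= 2
#'   samples per condition).
#' @return named numeric vector of raw p-values.
#' @export
gene_wise_test <- function(study) {
  sp <- split_conditions(study)
  n1 <- ncol(sp$normal); n2 <- ncol(sp$cancer)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per condition")
  m1 <- rowMeans(sp$normal); m2 <- rowMeans(sp$cancer)
  v1 <- apply(sp$normal, 1, stats::var)
  v2 <- apply(sp$cancer, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  stats::setNames(p, rownames(sp$normal))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  names(out) <- names(p_values)
  out
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its fold-change is strictly above `fc_hi` or
#' strictly below `fc_lo` AND its adjusted p-value is strictly below
#' `alpha`.
#'
#' @param log2fc named numeric vector of log2 fold-changes.
#' @param p_raw named numeric vector of raw p-values (same genes).
#' @param p_adj adjusted p-values; defaults to `bh_adjust(p_raw)`.
#' @param fc_hi upper fold-change threshold (default 2.0).
#' @param fc_lo lower fold-change threshold (default 0.5).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param dataset_id dataset label carried into the table.
#' @return a `DifferentialExpressionTable` data.frame with columns `gene`,
#'   `log2fc`, `fold_change`, `p_raw`, `p_adj`, `is_deg`.
#' @export
call_degs <- function(log2fc, p_raw, p_adj = bh_adjust(p_raw),
                      fc_hi = 2.0, fc_lo = 0.5, alpha = 0.01,
                      dataset_id = "dataset") {
  if (!(fc_lo > 0 && fc_lo < 1 && fc_hi > 1)) stop("need 0 < fc_lo < 1 < fc_hi")
  if (!(alpha > 0 && alpha < 1)) stop("need 0 < alpha < 1")
  stopifnot(length(log2fc) == length(p_raw), length(p_adj) == length(p_raw))
  fc <- 2^log2fc
  genes <- names(log2fc)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_along(log2fc))
  tab <- data.frame(gene = genes, log2fc = unname(log2fc),
                    fold_change = unname(fc), p_raw = unname(p_raw),
                    p_adj = unname(p_adj),
                    is_deg = unname((fc > fc_hi | fc < fc_lo) &
                                      p_adj < alpha),
                    stringsAsFactors = FALSE)
  attr(tab, "dataset_id") <- dataset_id
  class(tab) <- c("DifferentialExpressionTable", "data.frame")
  tab
}

#' Full differential-expression table for one study
#'
#' Convenience composition of [log2_fold_change()], [gene_wise_test()],
#' [bh_adjust()] and [call_degs()].
#'
#' @inheritParams call_degs
#' @param study an `ExpressionStudy`.
#' @return a `DifferentialExpressionTable`.
#' @export
deg_table <- function(study, fc_hi = 2.0, fc_lo = 0.5, alpha = 0.01) {
  lfc <- log2_fold_change(study)
  p <- gene_wise_test(study)
  call_degs(lfc, p[names(lfc)], fc_hi = fc_hi, fc_lo = fc_lo,
            alpha = alpha, dataset_id = study$dataset_id)
}

#' Intersect DEG calls across datasets into mutual DEGs
#'
#' @param tables list of `DifferentialExpressionTable` objects sharing a
#'   gene universe.
#' @return a `MutualDegSet`: list with `genes` (sorted character vector)
#'   and `per_dataset_counts` (named integer vector).
#' @export
mutual_degs <- function(tables) {
  if (!length(tables)) stop("empty table list")
  sets <- lapply(tables, function(t) t$gene[t$is_deg])
  ids <- vapply(seq_along(tables), function(i) {
    id <- attr(tables[[i]], "dataset_id")
    if (is.null(id)) sprintf("dataset%d", i) else id
  }, character(1))
  genes <- Reduce(intersect, sets)
  if (!length(genes))
    warning("mutual DEG intersection is empty")
  structure(list(genes = sort(genes),
                 per_dataset_counts = stats::setNames(
                   vapply(sets, length, integer(1)), ids)),
            class = "MutualDegSet")
}

#' @export
print.MutualDegSet <- function(x, ...) {
  cat("MutualDegSet:", length(x$genes), "mutual DEGs across",
      length(x$per_dataset_counts), "datasets (per-dataset:",
      paste(x$per_dataset_counts, collapse = ", "), ")\n")
  invisible(x)
}
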