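# Synthetic two-condition expression data with planted Gaussian graphical
# model structure. The generator draws from a multivariate normal whose
# precision matrix has a known sparse support (hub-spoke plus background
# edges), so network-recovery stages downstream have an exact ground truth.

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the package flows through a single user seed; each
#' stage draws from `seed * 100 + offset` (kept below 2^31) so stages are
#' independently reproducible.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (0-99 by convention).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.integer(seed)) %% 20000000L) * 100L + (offset %% 100L))
}

default_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# canonical unordered pair key for character ids
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Construct a planted precision model
#'
#' Builds a symmetric positive-definite precision matrix over `n_genes`
#' genes with unit diagonal, hub-spoke edges (each hub connected to
#' `hub_degree` distinct non-hub partners) and `background_edges` extra
#' random pairs. Off-diagonal entries are set so that the implied partial
#' correlations equal `partial_corr_magnitude` in absolute value (sign
#' random per edge). If the resulting matrix has minimum eigenvalue at or
#' below the floor 0.05, the diagonal is inflated once by a constant, which
#' preserves the support exactly and attenuates all planted partial
#' correlations by a common factor.
#'
#' @param n_genes number of genes.
#' @param n_hubs number of hub genes.
#' @param hub_degree spokes per hub.
#' @param background_edges number of additional random edges.
#' @param partial_corr_magnitude planted |partial correlation|, in (0, 0.5].
#' @param seed integer seed.
#' @param gene_ids optional character vector of gene identifiers.
#' @return an object of class `PrecisionModel`: list with `gene_ids`,
#'   `precision` (named matrix), `support` (data.frame `gene_i`, `gene_j`,
#'   `sign`, with `gene_i < gene_j`), `hub_genes`,
#'   `partial_corr_magnitude`.
#' @export
make_precision_model <- function(n_genes, n_hubs = 0L, hub_degree = 0L,
                                 background_edges = 0L,
                                 partial_corr_magnitude = 0.3,
                                 seed = 1L, gene_ids = NULL) {
  stopifnot(n_genes >= 1L, n_hubs >= 0L, hub_degree >= 0L,
            background_edges >= 0L)
  if (partial_corr_magnitude <= 0 || partial_corr_magnitude > 0.5)
    stop("partial_corr_magnitude must lie in (0, 0.5]")
  max_pairs <- n_genes * (n_genes - 1) / 2
  if (n_hubs * hub_degree + 2 * background_edges > max_pairs)
    stop("infeasible edge budget: n_hubs*hub_degree + 2*background_edges ",
         "exceeds ", max_pairs, " candidate pairs")
  if (n_hubs > 0L && hub_degree > n_genes - n_hubs)
    stop("hub_degree exceeds the number of available non-hub partners")
  if (is.null(gene_ids)) gene_ids <- default_gene_ids(n_genes)
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))

  set.seed(derive_seed(seed, 0L))
  hubs <- if (n_hubs > 0L) sort(sample.int(n_genes, n_hubs)) else integer(0)
  non_hubs <- setdiff(seq_len(n_genes), hubs)
  ei <- integer(0); ej <- integer(0)
  for (h in hubs) {
    spokes <- sample(non_hubs, hub_degree)
    ei <- c(ei, rep(h, hub_degree)); ej <- c(ej, spokes)
  }
  edges <- unique(data.frame(i = pmin(ei, ej), j = pmax(ei, ej)))
  if (background_edges > 0L) {
    taken <- paste(edges$i, edges$j)
    all_i <- rep(seq_len(n_genes - 1L), times = (n_genes - 1L):1L)
    all_j <- unlist(lapply(seq_len(n_genes - 1L),
                           function(i) (i + 1L):n_genes))
    free <- which(!(paste(all_i, all_j) %in% taken))
    if (length(free) < background_edges)
      stop("infeasible edge budget: not enough free pairs for background")
    pick <- sample(free, background_edges)
    edges <- rbind(edges, data.frame(i = all_i[pick], j = all_j[pick]))
  }
  signs <- if (nrow(edges)) sample(c(-1, 1), nrow(edges), replace = TRUE)
           else numeric(0)
  build_precision_from_edges(gene_ids, edges, signs,
                             partial_corr_magnitude,
                             hub_genes = gene_ids[hubs])
}

# Assemble a precision matrix from an explicit edge table (indices i<j) and
# per-edge signs. Shared between make_precision_model and the two-condition
# builder, which needs identical edges/signs across conditions.
build_precision_from_edges <- function(gene_ids, edges, signs, magnitude,
                                       hub_genes = character(0),
                                       eig_floor = 0.05) {
  p <- length(gene_ids)
  omega <- diag(p)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      # unit-diagonal precision: pcor_ij = -omega_ij, so plant -sign*rho
      omega[edges$i[k], edges$j[k]] <- -signs[k] * magnitude
      omega[edges$j[k], edges$i[k]] <- -signs[k] * magnitude
    }
  }
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= eig_floor) {
    omega <- omega + diag(eig_floor - ev_min + 1e-8, p)
    ev_min2 <- min(eigen(omega, symmetric = TRUE,
                         only.values = TRUE)$values)
    if (ev_min2 <= eig_floor - 1e-9)
      stop("internal error: precision not positive definite after inflation")
  }
  dimnames(omega) <- list(gene_ids, gene_ids)
  support <- if (nrow(edges)) {
    data.frame(gene_i = gene_ids[edges$i], gene_j = gene_ids[edges$j],
               sign = signs, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_i = character(0), gene_j = character(0),
               sign = numeric(0))
  }
  structure(list(gene_ids = gene_ids, precision = omega, support = support,
                 hub_genes = hub_genes,
                 partial_corr_magnitude = magnitude),
            class = "PrecisionModel")
}

#' @export
print.PrecisionModel <- function(x, ...) {
  cat("PrecisionModel:", length(x$gene_ids), "genes,",
      nrow(x$support), "support edges,",
      length(x$hub_genes), "hubs\n")
  invisible(x)
}

#' Partial correlations implied by a precision matrix
#'
#' The analytic identity rho_ij = -omega_ij / sqrt(omega_ii * omega_jj).
#' Used to verify planted structure; the estimation route lives in
#' [partial_correlations()].
#'
#' @param precision symmetric positive-definite matrix.
#' @return matrix of partial correlations with unit diagonal.
#' @export
precision_to_pcor <- function(precision) {
  d <- 1 / sqrt(diag(precision))
  pc <- -(d %o% d) * precision
  diag(pc) <- 1
  pc
}

#' Construct an ExpressionStudy container
#'
#' @param values gene-by-sample numeric matrix (log2 scale).
#' @param condition character vector (one per sample) of condition labels.
#' @param dataset_id dataset label.
#' @return an `ExpressionStudy` object.
#' @export
expression_study <- function(values, condition, dataset_id = "dataset") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)),
            length(condition) == ncol(values))
  if (anyNA(values)) stop("expression matrix contains missing values")
  names(condition) <- colnames(values)
  structure(list(gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 values = values,
                 condition = condition,
                 dataset_id = dataset_id),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy", sQuote(x$dataset_id), ":",
      length(x$gene_ids), "genes x", length(x$sample_ids), "samples (",
      paste(sprintf("%s=%d", names(table(x$condition)),
                    as.integer(table(x$condition))), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Simulate one condition from a precision model
#'
#' Draws `n_samples` multivariate-normal samples with covariance equal to
#' the inverse of the model precision and mean `baseline_mean` plus the
#' per-gene `mean_shift`.
#'
#' @param model a `PrecisionModel`.
#' @param n_samples number of samples (>= 3).
#' @param mean_shift named numeric vector of log2 mean shifts (subset of
#'   genes; missing genes shift 0).
#' @param baseline_mean baseline log2 mean (default 8, typical microarray
#'   scale).
#' @param seed integer seed.
#' @param condition condition label for all samples.
#' @param dataset_id dataset label.
#' @param sample_prefix prefix for generated sample ids.
#' @param gene_sd optional per-gene noise scale (scalar or named vector):
#'   rows are multiplied by it, giving heterogeneous variances while
#'   leaving all correlations and partial correlations unchanged. Default
#'   1 (homogeneous unit variance before precision inflation).
#' @return an `ExpressionStudy` with a single condition.
#' @export
simulate_condition <- function(model, n_samples, mean_shift = NULL,
                               baseline_mean = 8, seed = 1L,
                               condition = "normal",
                               dataset_id = "synthetic",
                               sample_prefix = condition,
                               gene_sd = NULL) {
  stopifnot(inherits(model, "PrecisionModel"))
  if (n_samples < 3L) stop("n_samples must be >= 3")
  p <- length(model$gene_ids)
  sigma <- tryCatch(solve(model$precision),
                    error = function(e) stop("singular precision matrix"))
  cl <- chol(sigma)
  mu <- rep(baseline_mean, p)
  names(mu) <- model$gene_ids
  if (!is.null(mean_shift)) {
    bad <- setdiff(names(mean_shift), model$gene_ids)
    if (length(bad)) stop("mean_shift names not in model: ",
                          paste(bad, collapse = ", "))
    mu[names(mean_shift)] <- mu[names(mean_shift)] + mean_shift
  }
  set.seed(derive_seed(seed, 1L))
  z <- matrix(stats::rnorm(n_samples * p), nrow = n_samples)
  x <- t(z %*% cl)                 # p x n, centered
  if (!is.null(gene_sd)) {
    s <- rep(1, p); names(s) <- model$gene_ids
    if (!is.null(names(gene_sd))) s[names(gene_sd)] <- gene_sd
    else s[] <- gene_sd
    if (any(s <= 0)) stop("gene_sd must be positive")
    x <- x * s
  }
  x <- x + mu
  rownames(x) <- model$gene_ids
  colnames(x) <- sprintf("%s_%03d", sample_prefix, seq_len(n_samples))
  expression_study(x, rep(condition, n_samples), dataset_id)
}

#' Default parameters of the two-condition generator
#'
#' Defaults mirror the data regime the pipeline targets: 154 genes, 84
#' normal and 210 cancer samples, a handful of shared and
#' condition-specific hubs with moderate partial correlations, and 30
#' differentially expressed genes with a 2 log2-unit shift.
#'
#' @param ... overrides of any default.
#' @return named list of generator parameters.
#' @export
two_condition_params <- function(...) {
  p <- list(n_genes = 154L, n_normal = 84L, n_cancer = 210L,
            n_shared_hubs = 2L, n_cancer_hubs = 3L, n_normal_hubs = 2L,
            hub_degree = 6L, shared_hub_degree = NULL,
            background_edges = 80L,
            partial_corr_magnitude = 0.3,
            n_de_genes = 30L, de_shift = 2, de_genes = NULL,
            baseline_mean = 8, dataset_id = "synthetic-1", seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown generator parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

# Build the normal/cancer PrecisionModel pair sharing hub skeleton,
# background edges and edge signs; only condition-specific hub edges
# differ between the two conditions.
make_condition_models <- function(params) {
  n <- params$n_genes
  gene_ids <- default_gene_ids(n)
  # shared (backbone) hubs may be better connected than the
  # condition-specific ones; default: same degree
  shared_deg <- params$shared_hub_degree %||% params$hub_degree
  n_hub_tot <- params$n_shared_hubs + params$n_cancer_hubs +
    params$n_normal_hubs
  if (n_hub_tot > 0L && max(params$hub_degree, shared_deg) > n - n_hub_tot)
    stop("hub_degree exceeds the number of available non-hub partners")
  set.seed(derive_seed(params$seed, 2L))
  hub_idx <- if (n_hub_tot > 0L) sample.int(n, n_hub_tot) else integer(0)
  shared_hubs <- hub_idx[seq_len(params$n_shared_hubs)]
  cancer_hubs <- hub_idx[params$n_shared_hubs +
                           seq_len(params$n_cancer_hubs)]
  normal_hubs <- hub_idx[params$n_shared_hubs + params$n_cancer_hubs +
                           seq_len(params$n_normal_hubs)]
  non_hubs <- setdiff(seq_len(n), hub_idx)
  spoke_edges <- function(hubs, degree) {
    ei <- integer(0); ej <- integer(0)
    for (h in hubs) {
      sp <- sample(non_hubs, degree)
      ei <- c(ei, rep(h, degree)); ej <- c(ej, sp)
    }
    data.frame(i = pmin(ei, ej), j = pmax(ei, ej))
  }
  shared_e <- spoke_edges(shared_hubs, shared_deg)
  cancer_e <- spoke_edges(cancer_hubs, params$hub_degree)
  normal_e <- spoke_edges(normal_hubs, params$hub_degree)
  if (params$background_edges > 0L) {
    taken <- paste(c(shared_e$i, cancer_e$i, normal_e$i),
                   c(shared_e$j, cancer_e$j, normal_e$j))
    all_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    all_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    # background edges are shared between conditions, so they must not
    # touch a condition-specific hub: those genes are connected only
    # through their own condition's hub edges
    spec_hubs <- c(cancer_hubs, normal_hubs)
    free <- which(!(paste(all_i, all_j) %in% taken) &
                    !(all_i %in% spec_hubs) & !(all_j %in% spec_hubs))
    pick <- sample(free, params$background_edges)
    bg_e <- data.frame(i = all_i[pick], j = all_j[pick])
  } else bg_e <- data.frame(i = integer(0), j = integer(0))
  # one sign per edge, reused wherever the edge appears
  all_e <- rbind(shared_e, cancer_e, normal_e, bg_e)
  all_s <- sample(c(-1, 1), nrow(all_e), replace = TRUE)
  idx_n <- c(seq_len(nrow(shared_e)),
             nrow(shared_e) + nrow(cancer_e) + seq_len(nrow(normal_e)),
             nrow(shared_e) + nrow(cancer_e) + nrow(normal_e) +
               seq_len(nrow(bg_e)))
  idx_c <- c(seq_len(nrow(shared_e) + nrow(cancer_e)),
             nrow(shared_e) + nrow(cancer_e) + nrow(normal_e) +
               seq_len(nrow(bg_e)))
  normal_model <- build_precision_from_edges(
    gene_ids, all_e[idx_n, , drop = FALSE], all_s[idx_n],
    params$partial_corr_magnitude,
    hub_genes = gene_ids[sort(c(shared_hubs, normal_hubs))])
  cancer_model <- build_precision_from_edges(
    gene_ids, all_e[idx_c, , drop = FALSE], all_s[idx_c],
    params$partial_corr_magnitude,
    hub_genes = gene_ids[sort(c(shared_hubs, cancer_hubs))])
  list(normal = normal_model, cancer = cancer_model)
}

#' Generate a two-condition expression study with known truth
#'
#' Draws the normal condition from the normal precision model with no mean
#' shifts and the cancer condition from the cancer model with the planted
#' differential-expression shifts, then concatenates the samples.
#'
#' @param params generator settings from [two_condition_params()].
#' @return list with `study` (an `ExpressionStudy`) and `truth` (a
#'   `SyntheticTruth`: `normal_model`, `cancer_model`, `de_genes` named
#'   shift vector, `cancer_specific_hubs`).
#' @export
make_two_condition_study <- function(params = two_condition_params()) {
  models <- make_condition_models(params)
  gene_ids <- models$normal$gene_ids
  if (is.null(params$de_genes)) {
    set.seed(derive_seed(params$seed, 3L))
    de_idx <- if (params$n_de_genes > 0L)
      sample.int(length(gene_ids), params$n_de_genes) else integer(0)
    de_genes <- stats::setNames(
      sample(c(-1, 1), length(de_idx), replace = TRUE) *
        abs(params$de_shift),
      gene_ids[de_idx])
  } else {
    de_genes <- params$de_genes
    stopifnot(all(names(de_genes) %in% gene_ids))
  }
  if (length(de_genes) && any(abs(de_genes) < 1))
    stop("planted |shift| must be >= 1 log2 unit")
  truth <- structure(
    list(normal_model = models$normal, cancer_model = models$cancer,
         de_genes = de_genes,
         cancer_specific_hubs = setdiff(models$cancer$hub_genes,
                                        models$normal$hub_genes)),
    class = "SyntheticTruth")
  study <- draw_two_condition(truth, params$n_normal, params$n_cancer,
                              params$baseline_mean, params$dataset_id,
                              params$seed)
  list(study = study, truth = truth)
}

# sample both conditions from an existing truth and bind them
draw_two_condition <- function(truth, n_normal, n_cancer, baseline_mean,
                               dataset_id, seed) {
  normal <- simulate_condition(truth$normal_model, n_normal,
                               mean_shift = NULL,
                               baseline_mean = baseline_mean,
                               seed = derive_seed(seed, 10L),
                               condition = "normal",
                               dataset_id = dataset_id)
  cancer <- simulate_condition(truth$cancer_model, n_cancer,
                               mean_shift = truth$de_genes,
                               baseline_mean = baseline_mean,
                               seed = derive_seed(seed, 11L),
                               condition = "cancer",
                               dataset_id = dataset_id)
  vals <- cbind(normal$values, cancer$values)
  colnames(vals) <- paste0(dataset_id, "_", colnames(vals))
  expression_study(vals,
                   c(normal$condition, cancer$condition),
                   dataset_id)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", length(x$normal_model$gene_ids), "genes;",
      length(x$de_genes), "DE genes;",
      length(x$cancer_specific_hubs), "cancer-specific hubs\n")
  invisible(x)
}

#' Generate independent datasets sharing one synthetic truth
#'
#' Emulates a multi-series meta-analysis: each dataset is drawn from the
#' same pair of precision models and the same planted shifts, differing
#' only in sampling noise and sample sizes.
#'
#' @param truth a `SyntheticTruth`.
#' @param n_datasets number of datasets.
#' @param per_dataset_sizes list of `c(n_normal, n_cancer)` pairs.
#' @param seeds integer vector of per-dataset seeds.
#' @param baseline_mean baseline log2 mean.
#' @return list of `ExpressionStudy` objects.
#' @export
make_multi_dataset <- function(truth, n_datasets, per_dataset_sizes, seeds,
                               baseline_mean = 8) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (length(per_dataset_sizes) != n_datasets ||
      length(seeds) != n_datasets)
    stop("n_datasets, per_dataset_sizes and seeds lengths differ")
  lapply(seq_len(n_datasets), function(d) {
    sz <- per_dataset_sizes[[d]]
    draw_two_condition(truth, sz[[1]], sz[[2]], baseline_mean,
                       dataset_id = sprintf("synthetic-%d", d),
                       seed = seeds[[d]])
  })
}
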