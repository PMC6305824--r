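# Differential-connectivity selection: the top betweenness fraction of
# each condition's network, removal of the shared hubs, and the remaining
# cancer-specific hubs as differentially connected genes (DCGs).

#' Select the top betweenness fraction of a ranked universe
#'
#' Returns the first `floor(q * N)` nodes of the ranked order, where N is
#' the universe size. With N = 154 and q = 0.40 this yields 61 genes.
#'
#' @param ranked_nodes character vector of node ids in rank order (or a
#'   `CentralityTable`, whose order is used).
#' @param q fraction in (0, 1\] (default 0.40).
#' @return character vector of length `floor(q * N)`.
#' @export
select_top_fraction <- function(ranked_nodes, q = 0.40) {
  if (inherits(ranked_nodes, "data.frame")) ranked_nodes <- ranked_nodes$node
  if (!(q > 0 && q <= 1)) stop("q must lie in (0, 1]")
  n_sel <- floor(q * length(ranked_nodes))
  if (n_sel == 0L)
    stop("floor(q * N) = 0: the selection would be empty")
  ranked_nodes[seq_len(n_sel)]
}

#' Differentially connected genes from two top-hub sets
#'
#' DCGs are the cancer-top genes absent from the normal-top set; the
#' shared genes (the overlap) are removed. The normal-specific complement
#' is reported alongside but not labelled DCG.
#'
#' @param cancer_top character vector: top-fraction hubs of the cancer
#'   network.
#' @param normal_top character vector: top-fraction hubs of the normal
#'   network.
#' @param fraction the fraction used to produce the top sets (metadata).
#' @return a `DcgResult`: list with `cancer_top`, `normal_top`, `overlap`,
#'   `dcgs`, `normal_specific`, `fraction`.
#' @export
dcg_set <- function(cancer_top, normal_top, fraction = 0.40) {
  overlap <- intersect(cancer_top, normal_top)
  structure(list(cancer_top = cancer_top, normal_top = normal_top,
                 overlap = sort(overlap),
                 dcgs = sort(setdiff(cancer_top, overlap)),
                 normal_specific = sort(setdiff(normal_top, overlap)),
                 fraction = fraction),
            class = "DcgResult")
}

#' @export
print.DcgResult <- function(x, ...) {
  cat("DcgResult: |cancer_top| =", length(x$cancer_top),
      "|normal_top| =", length(x$normal_top),
      "|overlap| =", length(x$overlap),
      "|DCGs| =", length(x$dcgs), "\n")
  invisible(x)
}

#' Configuration of the differential-connectivity pipeline
#'
#' Defaults are the thresholds the pipeline was designed around:
#' fold-change > 2.0 or < 0.5, adjusted p < 0.01, 1500 retained edges,
#' top 40% betweenness cut.
#'
#' @param fc_hi,fc_lo,alpha DEG thresholds.
#' @param k number of top-ranked edges retained per network.
#' @param q betweenness top fraction.
#' @param gene_filter `"mutual"` restricts the networks to the mutual-DEG
#'   universe; `"all"` uses every gene (needed e.g. for null studies with
#'   no DEGs).
#' @param seed integer seed recorded in the report (analysis stages are
#'   deterministic; randomness lives in the generator).
#' @param verbose log per-stage cardinalities to stderr.
#' @return named list of validated settings.
#' @export
pipeline_config <- function(fc_hi = 2.0, fc_lo = 0.5, alpha = 0.01,
                            k = 1500L, q = 0.40,
                            gene_filter = c("mutual", "all"),
                            seed = NA_integer_, verbose = FALSE) {
  gene_filter <- match.arg(gene_filter)
  if (!(fc_lo > 0 && fc_lo < 1 && fc_hi > 1)) stop("need 0 < fc_lo < 1 < fc_hi")
  if (!(alpha > 0 && alpha < 1)) stop("need 0 < alpha < 1")
  if (!(q > 0 && q <= 1)) stop("need 0 < q <= 1")
  if (k < 1L) stop("need k >= 1")
  list(fc_hi = fc_hi, fc_lo = fc_lo, alpha = alpha, k = as.integer(k),
       q = q, gene_filter = gene_filter, seed = seed, verbose = verbose)
}

pipe_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] ", stage), ...)
}

#' Run the full differential-connectivity pipeline
#'
#' Stages: per-dataset DEG calling, intersection into mutual DEGs,
#' per-condition shrinkage GGM on the gene universe (samples pooled across
#' datasets within condition), top-k edge retention, graph construction,
#' exact betweenness, top-fraction hub selection, and DCG extraction by
#' overlap removal.
#'
#' @param studies list of `ExpressionStudy` objects (>= 1).
#' @param config settings from [pipeline_config()].
#' @return a `DcgAnalysis`: list with `deg_tables`, `mutual`, `universe`,
#'   `models`, `networks`, `centrality`, `dcg`, `report` (per-stage
#'   cardinalities and the config echo).
#' @export
run_pipeline <- function(studies, config = pipeline_config()) {
  if (inherits(studies, "ExpressionStudy")) studies <- list(studies)
  if (!length(studies)) stop("need at least one study")
  t0 <- proc.time()[["elapsed"]]
  vb <- isTRUE(config$verbose)

  deg_tables <- lapply(studies, deg_table, fc_hi = config$fc_hi,
                       fc_lo = config$fc_lo, alpha = config$alpha)
  pipe_log(vb, "deg", "per-dataset DEG counts: ",
           paste(vapply(deg_tables, function(t) sum(t$is_deg),
                        integer(1)), collapse = ", "))
  mutual <- withCallingHandlers(
    mutual_degs(deg_tables),
    warning = function(w) if (!vb) invokeRestart("muffleWarning"))
  pipe_log(vb, "intersect", length(mutual$genes), " mutual DEGs")

  universe <- if (config$gene_filter == "mutual") mutual$genes
              else sort(studies[[1]]$gene_ids)
  if (!length(universe))
    stop("pipeline aborted at stage 'intersect': empty mutual-DEG set ",
         "(consider gene_filter = \"all\")")

  pool <- function(cond) {
    do.call(cbind, lapply(studies, function(s)
      s$values[universe, s$condition == cond, drop = FALSE]))
  }
  fit_stage <- function(cond) {
    x <- pool(cond)
    model <- fit_ggm(x, condition = cond)
    pipe_log(vb, "ggm", cond, ": n = ", ncol(x), ", lambda* = ",
             signif(model$lambda_star, 4))
    model
  }
  models <- list(normal = fit_stage("normal"), cancer = fit_stage("cancer"))

  networks <- lapply(models, function(m) {
    kept <- suppressWarnings(top_k_edges(m$edges, config$k))
    build_graph(kept, universe, condition = m$condition)
  })
  centrality <- lapply(networks, betweenness_centrality)
  tops <- lapply(centrality, select_top_fraction, q = config$q)
  dcg <- dcg_set(tops$cancer, tops$normal, fraction = config$q)
  pipe_log(vb, "dcg", "|top| = ", length(tops$cancer), ", |overlap| = ",
           length(dcg$overlap), ", |DCGs| = ", length(dcg$dcgs))

  report <- list(
    config = config[c("fc_hi", "fc_lo", "alpha", "k", "q",
                      "gene_filter", "seed")],
    tool_version = as.character(utils::packageVersion("dcgnet")),
    n_datasets = length(studies),
    degs_per_dataset = as.list(mutual$per_dataset_counts),
    n_mutual_degs = length(mutual$genes),
    universe_size = length(universe),
    lambda = lapply(models, function(m) m$lambda_star),
    edge_counts = lapply(networks, function(n) nrow(n$edges)),
    top_set_size = length(tops$cancer),
    overlap_size = length(dcg$overlap),
    dcg_count = length(dcg$dcgs),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3))

  structure(list(deg_tables = deg_tables, mutual = mutual,
                 universe = universe, models = models,
                 networks = networks, centrality = centrality,
                 dcg = dcg, report = report),
            class = "DcgAnalysis")
}

#' @export
print.DcgAnalysis <- function(x, ...) {
  r <- x$report
  cat("DcgAnalysis:", r$n_datasets, "dataset(s);",
      r$n_mutual_degs, "mutual DEGs; universe", r$universe_size, "\n")
  cat("  lambda*: normal =", signif(r$lambda$normal, 4),
      ", cancer =", signif(r$lambda$cancer, 4), "\n")
  cat("  top", r$top_set_size, "hubs/condition; overlap",
      r$overlap_size, "; DCGs", r$dcg_count, "\n")
  invisible(x)
}
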