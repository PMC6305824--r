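# Run configuration (simple key = value text format) and the run report.

config_domains <- list(
  fc_hi = function(v) v > 1,
  fc_lo = function(v) v > 0 && v < 1,
  alpha = function(v) v > 0 && v < 1,
  k = function(v) v >= 1 && v == floor(v),
  q = function(v) v > 0 && v <= 1,
  seed = function(v) is.finite(v) && v == floor(v),
  gene_filter = function(v) v %in% c("mutual", "all"),
  out_dir = function(v) nzchar(v)
)

#' Load a pipeline configuration file
#'
#' Plain `key = value` lines; `#` starts a comment; unknown keys and
#' out-of-domain values are errors. Missing keys take the defaults
#' (fc_hi 2.0, fc_lo 0.5, alpha 0.01, k 1500, q 0.40).
#'
#' @param path config file path.
#' @return a validated config list as from [pipeline_config()], plus
#'   `out_dir` if given.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("unparseable config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(config_domains))
      stop("unknown config key: ", key)
    if (!key %in% c("gene_filter", "out_dir")) {
      val <- suppressWarnings(as.numeric(val))
      if (is.na(val)) stop("non-numeric value for key: ", key)
    }
    if (!config_domains[[key]](val))
      stop("out-of-domain value for key ", key, ": ", m[3])
    kv[[key]] <- val
  }
  cfg <- pipeline_config(
    fc_hi = kv$fc_hi %||% 2.0, fc_lo = kv$fc_lo %||% 0.5,
    alpha = kv$alpha %||% 0.01, k = kv$k %||% 1500L,
    q = kv$q %||% 0.40, gene_filter = kv$gene_filter %||% "mutual",
    seed = if (is.null(kv$seed)) NA_integer_ else as.integer(kv$seed))
  if (!is.null(kv$out_dir)) cfg$out_dir <- kv$out_dir
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration as key = value lines
#'
#' @param config list from [pipeline_config()] or [load_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  keys <- intersect(c("fc_hi", "fc_lo", "alpha", "k", "q", "gene_filter",
                      "seed", "out_dir"), names(config))
  keys <- keys[!vapply(keys, function(k) is.null(config[[k]]) ||
                         (is.numeric(config[[k]]) && is.na(config[[k]])),
                       logical(1))]
  writeLines(sprintf("%s = %s", keys,
                     vapply(config[keys], as.character, character(1))),
             path)
  invisible(config)
}

#' Emit the run report as JSON and a plain-text summary
#'
#' Validates the report-internal arithmetic (DCG count = top size -
#' overlap size) and writes a machine-readable JSON plus a mirrored text
#' table. Timestamps live in a single `generated_at` field so two
#' identical runs differ in at most that field.
#'
#' @param bundle a `DcgAnalysis` from [run_pipeline()].
#' @param json_path output JSON path (NULL to skip).
#' @param text_path output text path (NULL to skip).
#' @return the report list, invisibly.
#' @export
emit_report <- function(bundle, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(bundle, "DcgAnalysis"))
  r <- bundle$report
  if (r$dcg_count != r$top_set_size - r$overlap_size)
    stop("internal error: DCG count ", r$dcg_count,
         " != top set size ", r$top_set_size, " - overlap ",
         r$overlap_size)
  report <- c(r, list(
    dcgs = bundle$dcg$dcgs,
    overlap_genes = bundle$dcg$overlap,
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(text_path)) {
    txt <- c(
      "differential-connectivity run report",
      sprintf("  datasets:        %d", r$n_datasets),
      sprintf("  DEGs/dataset:    %s",
              paste(unlist(r$degs_per_dataset), collapse = ", ")),
      sprintf("  mutual DEGs:     %d", r$n_mutual_degs),
      sprintf("  universe:        %d genes (filter: %s)",
              r$universe_size, r$config$gene_filter),
      sprintf("  lambda*:         normal %.4f, cancer %.4f",
              r$lambda$normal, r$lambda$cancer),
      sprintf("  retained edges:  normal %d, cancer %d (k = %d)",
              r$edge_counts$normal, r$edge_counts$cancer, r$config$k),
      sprintf("  top %.0f%% hubs:    %d per condition",
              100 * r$config$q, r$top_set_size),
      sprintf("  overlap removed: %d", r$overlap_size),
      sprintf("  DCGs:            %d", r$dcg_count),
      sprintf("  DCG genes:       %s",
              paste(bundle$dcg$dcgs, collapse = ", ")))
    writeLines(txt, text_path)
  }
  invisible(report)
}
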