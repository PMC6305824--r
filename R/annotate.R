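# Downstream characterization of a DCG set: overlaps with curated gene
# lists, hypergeometric over-/under-representation against gene-set
# collections (GMT), and TF lookup from a TRRUST-style regulon table.

#' Read a GMT gene-set collection
#'
#' Standard format: one set per line, `set_name TAB description TAB
#' gene1 TAB gene2 ...`. Identifiers are whitespace-stripped and matched
#' case-sensitively.
#'
#' @param path GMT file path.
#' @param source label recorded on the collection.
#' @return a `GeneSetCollection`: list with `sets` (named list of
#'   character vectors) and `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set: ", f[1])
    if (f[1] %in% names(sets)) stop("duplicate set name: ", f[1])
    sets[[f[1]]] <- genes
  }
  gene_set_collection(sets, source)
}

#' Construct a GeneSetCollection from a named list
#'
#' @param sets named list of character vectors.
#' @param source label.
#' @return a `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, source = "collection") {
  stopifnot(is.list(sets), length(names(sets)) == length(sets),
            !anyDuplicated(names(sets)))
  if (any(!vapply(sets, length, integer(1))))
    stop("gene sets must be non-empty")
  structure(list(sets = sets, source = source),
            class = "GeneSetCollection")
}

#' Overlaps of a query set with curated gene lists
#'
#' Exact intersections plus, when exactly two lists are supplied, the
#' seven-cell Venn partition of (query, list1, list2).
#'
#' @param query character vector of gene ids.
#' @param lists a `GeneSetCollection` or named list of character vectors.
#' @return list with `per_list` (per-list `overlap`, `count`, `coverage` =
#'   count / |query|) and `venn` (7 named cells, or NULL unless two
#'   lists).
#' @export
overlap_counts <- function(query, lists) {
  if (inherits(lists, "GeneSetCollection")) lists <- lists$sets
  query <- unique(trimws(query))
  per_list <- lapply(lists, function(s) {
    ov <- sort(intersect(query, s))
    list(overlap = ov, count = length(ov),
         coverage = if (length(query)) length(ov) / length(query) else NA)
  })
  venn <- NULL
  if (length(lists) == 2L) {
    a <- query; b <- unique(lists[[1]]); c_ <- unique(lists[[2]])
    cell <- function(ina, inb, inc) {
      u <- union(a, union(b, c_))
      keep <- (u %in% a) == ina & (u %in% b) == inb & (u %in% c_) == inc
      sort(u[keep])
    }
    venn <- list(query_only = cell(TRUE, FALSE, FALSE),
                 list1_only = cell(FALSE, TRUE, FALSE),
                 list2_only = cell(FALSE, FALSE, TRUE),
                 query_list1 = cell(TRUE, TRUE, FALSE),
                 query_list2 = cell(TRUE, FALSE, TRUE),
                 list1_list2 = cell(FALSE, TRUE, TRUE),
                 all_three = cell(TRUE, TRUE, TRUE))
  }
  list(per_list = per_list, venn = venn)
}

#' Hypergeometric over- and under-representation test
#'
#' For each set S in the collection, with N = |universe|, K = |S within
#' the universe|, n = |query| and k = |query and S|, computes the upper
#' tail `p_over = P[X >= k]` and lower tail `p_under = P[X <= k]` of
#' `X ~ Hypergeometric(N, K, n)`, with Benjamini-Hochberg q-values across
#' the collection for each tail.
#'
#' @param query character vector, must be a subset of `universe`.
#' @param collection a `GeneSetCollection` (or named list).
#' @param universe character vector of all testable genes.
#' @return data.frame with columns `set_name`, `set_size`,
#'   `overlap_count`, `expected`, `p_over`, `p_under`, `q_value` (BH over
#'   `p_over`), `q_under`.
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  if (inherits(collection, "GeneSetCollection"))
    collection <- collection$sets
  universe <- unique(trimws(universe))
  query <- unique(trimws(query))
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(trimws(collection[[nm]])), universe)
    K <- length(s)
    k <- length(intersect(query, s))
    data.frame(set_name = nm, set_size = K, overlap_count = k,
               expected = n * K / N,
               p_over = stats::phyper(k - 1, K, N - K, n,
                                      lower.tail = FALSE),
               p_under = stats::phyper(k, K, N - K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_over)
  out$q_under <- bh_adjust(out$p_under)
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Read a TRRUST-style regulon table
#'
#' Tab-separated `TF TAB target TAB mode` (extra columns such as PubMed
#' references are ignored); `mode` is mapped onto
#' activation/repression/unknown. Malformed rows are skipped with a
#' message naming the line number. Duplicate (tf, target, mode) triples
#' are removed.
#'
#' @param path TSV file path.
#' @return a `RegulonTable` data.frame with columns `tf`, `target`,
#'   `mode`.
#' @export
read_regulon_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3L || !nzchar(f[1]) || !nzchar(f[2])) {
      message("regulon line ", i, " malformed; skipped")
      next
    }
    mode <- tolower(f[3])
    mode <- if (grepl("^activ", mode)) "activation"
            else if (grepl("^repress", mode)) "repression"
            else "unknown"
    recs[[length(recs) + 1L]] <- data.frame(tf = f[1], target = f[2],
                                            mode = mode,
                                            stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(regulon_table(data.frame(tf = character(0),
                                    target = character(0),
                                    mode = character(0))))
  regulon_table(do.call(rbind, recs))
}

#' Construct a RegulonTable, deduplicating triples
#'
#' @param records data.frame with columns `tf`, `target`, `mode`.
#' @return a `RegulonTable` data.frame.
#' @export
regulon_table <- function(records) {
  stopifnot(all(c("tf", "target", "mode") %in% names(records)))
  records <- unique(records[, c("tf", "target", "mode")])
  rownames(records) <- NULL
  class(records) <- c("RegulonTable", "data.frame")
  records
}

#' Transcription factors regulating a DCG set
#'
#' @param dcgs character vector of gene ids.
#' @param regulons a `RegulonTable` (or compatible data.frame).
#' @return list with `per_gene` (named list: distinct TFs per DCG with a
#'   target), `per_gene_counts`, `per_tf` (named list: DCG targets per
#'   TF), `shared_regulators` (TFs regulating >= 2 DCGs, with their
#'   targets).
#' @export
regulators_of <- function(dcgs, regulons) {
  if (!is.data.frame(regulons)) stop("regulons must be a data.frame")
  regulons <- regulon_table(regulons)
  dcgs <- unique(trimws(dcgs))
  hit <- regulons[regulons$target %in% dcgs, , drop = FALSE]
  per_gene <- lapply(stats::setNames(nm = sort(unique(hit$target))),
                     function(g) sort(unique(hit$tf[hit$target == g])))
  per_tf <- lapply(stats::setNames(nm = sort(unique(hit$tf))),
                   function(tf)
                     sort(unique(hit$target[hit$tf == tf])))
  shared <- per_tf[vapply(per_tf, length, integer(1)) >= 2L]
  list(per_gene = per_gene,
       per_gene_counts = vapply(per_gene, length, integer(1)),
       per_tf = per_tf,
       shared_regulators = shared)
}
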