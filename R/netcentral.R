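# Undirected, unweighted graph construction from a retained edge list and
# exact betweenness centrality. The graph container and the Brandes
# single-source accumulation are provided by igraph; the test suite checks
# the result against an independent all-pairs BFS enumeration oracle.

#' Build a simple undirected gene network
#'
#' Self-loops are dropped and duplicate (unordered) edges deduplicated,
#' each with a warning; nodes of the universe without edges are retained
#' as isolates.
#'
#' @param edges data.frame with columns `gene_i`, `gene_j` (extra columns
#'   ignored).
#' @param universe character vector of all node identifiers.
#' @param condition label carried on the network.
#' @return a `GeneNetwork`: list with `graph` (igraph), `nodes`, `edges`
#'   (cleaned data.frame), `condition`.
#' @export
build_graph <- function(edges, universe, condition = "condition") {
  stopifnot(is.data.frame(edges), all(c("gene_i", "gene_j") %in%
                                        names(edges)))
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("universe contains duplicate ids")
  ends <- unique(c(edges$gene_i, edges$gene_j))
  out <- setdiff(ends, universe)
  if (length(out))
    stop("edge endpoint(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  loops <- edges$gene_i == edges$gene_j
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- pair_key(edges$gene_i, edges$gene_j)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) removed")
    edges <- edges[!dup, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_i", "gene_j"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = universe, stringsAsFactors = FALSE))
  structure(list(graph = g, nodes = universe, edges = edges,
                 condition = condition),
            class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat("GeneNetwork (", x$condition, "): ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Exact betweenness centrality of every node
#'
#' Unnormalized shortest-path betweenness
#' `b(v) = sum_{s != v != t} sigma_st(v) / sigma_st` over unordered pairs
#' (endpoints excluded; unreachable pairs contribute nothing). The
#' downstream top-fraction cut depends only on ranks, so unnormalized
#' scores are the default; `normalized = TRUE` divides by
#' `(n-1)(n-2)/2`.
#'
#' @param network a `GeneNetwork`.
#' @param normalized divide by the number of non-endpoint pairs.
#' @return a `CentralityTable` data.frame with columns `node`,
#'   `betweenness`, `degree`, `rank` (dense, descending betweenness, ties
#'   broken lexicographically), ordered by rank.
#' @export
betweenness_centrality <- function(network, normalized = FALSE) {
  stopifnot(inherits(network, "GeneNetwork"))
  b <- igraph::betweenness(network$graph, directed = FALSE,
                           normalized = FALSE)
  if (normalized) {
    n <- length(b)
    if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  }
  deg <- igraph::degree(network$graph)
  tab <- data.frame(node = names(b), betweenness = unname(b),
                    degree = unname(deg), stringsAsFactors = FALSE)
  rank_nodes(tab)
}

#' Order a centrality table and assign dense ranks
#'
#' Nodes are sorted by betweenness descending with lexicographic
#' tie-break on the node id; `rank` is the dense rank of the score (equal
#' scores share a rank; the next distinct score takes the next rank).
#'
#' @param table data.frame with columns `node` and `betweenness`.
#' @return the table ordered, with a `rank` column, class
#'   `CentralityTable`.
#' @export
rank_nodes <- function(table) {
  stopifnot(all(c("node", "betweenness") %in% names(table)))
  o <- order(-table$betweenness, table$node, method = "radix")
  tab <- table[o, , drop = FALSE]
  # dense rank: index of each distinct score in descending order
  tab$rank <- match(tab$betweenness, unique(tab$betweenness))
  rownames(tab) <- NULL
  class(tab) <- c("CentralityTable", "data.frame")
  tab
}
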