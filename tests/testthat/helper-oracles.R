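# Independent oracles, written with deliberately naive loops so they share
# no code path with the package implementations they check.

# literal BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) ps[j] * m / j)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exact betweenness by explicit enumeration of all shortest paths (BFS
# distances + recursive backtracking); adj is a symmetric 0/1 matrix
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        nb <- which(adj[u, ] == 1)
        new <- nb[is.infinite(d[nb])]
        d[new] <- d[u] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    d
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (is.infinite(d[t])) next
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1]] <<- acc
          return(invisible())
        }
        preds <- which(adj[v, ] == 1 & d == d[v] - 1)
        for (u in preds) walk(u, c(u, acc))
      }
      walk(t, t)
      sigma <- length(paths)
      interior <- unlist(lapply(paths, function(pp)
        pp[pp != s & pp != t]))
      if (length(interior)) {
        tab <- table(interior)
        idx <- as.integer(names(tab))
        b[idx] <- b[idx] + as.numeric(tab) / sigma
      }
    }
  }
  b
}

# literal evaluation of the analytic shrinkage-intensity formula
oracle_lambda <- function(x) {
  n <- ncol(x); p <- nrow(x)
  xs <- x
  for (i in seq_len(p)) xs[i, ] <- (x[i, ] - mean(x[i, ])) / sd(x[i, ])
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    w <- xs[i, ] * xs[j, ]
    r <- sum(w) / (n - 1)
    num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
    den <- den + r^2
  }
  if (den == 0) 1 else min(1, max(0, num / den))
}

# hypergeometric upper tail P[X >= k] by summing choose() terms
oracle_hyper_over <- function(N, K, nq, k) {
  kk <- k:min(K, nq)
  sum(choose(K, kk) * choose(N - K, nq - kk)) / choose(N, nq)
}

oracle_hyper_under <- function(N, K, nq, k) {
  lo <- max(0, nq - (N - K))
  if (k < lo) return(0)
  kk <- lo:k
  sum(choose(K, kk) * choose(N - K, nq - kk)) / choose(N, nq)
}

# small ExpressionStudy built directly from per-condition matrices
toy_study <- function(normal, cancer, genes = NULL) {
  p <- nrow(normal)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(p))
  vals <- cbind(normal, cancer)
  rownames(vals) <- genes
  colnames(vals) <- c(sprintf("n%02d", seq_len(ncol(normal))),
                      sprintf("c%02d", seq_len(ncol(cancer))))
  expression_study(vals, rep(c("normal", "cancer"),
                             c(ncol(normal), ncol(cancer))), "toy")
}

# the frozen generator world used by the recovery / null criteria
recovery_params <- function(seed, null = FALSE) {
  two_condition_params(
    n_genes = 30L, n_normal = 200L, n_cancer = 200L,
    n_shared_hubs = 4L,
    n_cancer_hubs = if (null) 0L else 1L,
    n_normal_hubs = 0L, hub_degree = 6L, background_edges = 12L,
    partial_corr_magnitude = 0.3,
    n_de_genes = 0L,
    de_genes = if (null) NULL else
      stats::setNames(rep(2, 30), sprintf("g%04d", 1:30)),
    seed = seed)
}

random_graph_adj <- function(n, p_edge = 0.35) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  adj
}

adj_to_edges <- function(adj, ids) {
  w <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  data.frame(gene_i = ids[w[, 1]], gene_j = ids[w[, 2]],
             stringsAsFactors = FALSE)
}
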