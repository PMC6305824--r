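test_that("sample correlation handles exact and degenerate cases", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3))
  r <- sample_correlation(x)
  expect_equal(r["a", "b"], -1)
  expect_equal(r["a", "c"], 1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  xz <- rbind(a = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(sample_correlation(xz), "flat")
  expect_error(sample_correlation(x[, 1:2]), ">= 3")
})

test_that("shrinkage intensity follows the analytic formula", {
  # exactly orthogonal genes: zero denominator -> lambda = 1 by convention
  x0 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(shrinkage_lambda(x0), 1)

  # fixture matrix vs literal brute-force evaluation
  set.seed(101)
  fx <- matrix(rnorm(60), 6, 10)
  expect_equal(shrinkage_lambda(fx), oracle_lambda(fx), tolerance = 1e-12)

  # lambda decreases with sample size when true correlations are strong
  m <- make_precision_model(10, 1, 6, 0, 0.4, seed = 4)
  small <- simulate_condition(m, 30, seed = 21)$values
  big <- simulate_condition(m, 1000, seed = 21)$values
  expect_lt(shrinkage_lambda(big), shrinkage_lambda(small))

  # clipping property over random inputs
  set.seed(8)
  for (rep in 1:20) {
    x <- matrix(rnorm(5 * sample(3:12, 1)), nrow = 5)
    l <- shrinkage_lambda(x)
    expect_true(l >= 0 && l <= 1)
  }
  expect_error(shrinkage_lambda(fx[, 1:2]), ">= 3")
})

test_that("partial correlations match the defining identities", {
  expect_equal(partial_correlations(diag(4)), diag(4))

  # p = 2: partial equals marginal
  set.seed(5)
  for (rep in 1:20) {
    r <- runif(1, -0.95, 0.95)
    m <- matrix(c(1, r, r, 1), 2)
    expect_equal(partial_correlations(m)[1, 2], r, tolerance = 1e-12)
  }

  # p = 3 closed form
  r3 <- matrix(c(1, 0.6, 0.5, 0.6, 1, 0.4, 0.5, 0.4, 1), 3)
  pc <- partial_correlations(r3)
  expect_equal(pc[1, 2],
               (0.6 - 0.5 * 0.4) / sqrt((1 - 0.25) * (1 - 0.16)),
               tolerance = 1e-10)
  for (rep in 1:20) {
    repeat { # rejection-sample a PD 3x3 correlation matrix
      rr <- runif(3, -0.9, 0.9)
      m <- matrix(c(1, rr[1], rr[2], rr[1], 1, rr[3], rr[2], rr[3], 1), 3)
      if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >
            1e-3) break
    }
    pc <- partial_correlations(m)
    expect_equal(pc[1, 2],
                 (rr[1] - rr[2] * rr[3]) /
                   sqrt((1 - rr[2]^2) * (1 - rr[3]^2)),
                 tolerance = 1e-10)
  }
  sing <- matrix(c(1, 1, 1, 1), 2)
  expect_error(partial_correlations(sing), "singular")
})

test_that("fitted model shrinks every off-diagonal toward zero", {
  set.seed(6)
  m <- make_precision_model(8, 1, 4, 3, 0.3, seed = 2)
  x <- simulate_condition(m, 40, seed = 3)$values
  fit <- fit_ggm(x)
  expect_true(fit$lambda_star > 0 && fit$lambda_star < 1)
  raw <- sample_correlation(x)
  off <- upper.tri(raw)
  expect_true(all(abs(fit$shrunk_correlation[off]) <= abs(raw[off])))
  expect_equal(diag(fit$shrunk_correlation), diag(raw))
})

test_that("edge ranking is by |pcor| with lexicographic tie-break", {
  pc <- diag(3)
  ids <- c("gB", "gA", "gC")
  dimnames(pc) <- list(ids, ids)
  pc["gB", "gA"] <- pc["gA", "gB"] <- -0.9
  pc["gB", "gC"] <- pc["gC", "gB"] <- 0.5
  pc["gA", "gC"] <- pc["gC", "gA"] <- 0.1
  e <- rank_edges(pc)
  expect_equal(e$gene_i, c("gA", "gB", "gA"))
  expect_equal(e$gene_j, c("gB", "gC", "gC"))
  expect_equal(e$pcor, c(-0.9, 0.5, 0.1))

  # all-zero off-diagonals: pure lexicographic order
  z <- diag(3); dimnames(z) <- list(ids, ids)
  ez <- rank_edges(z)
  expect_equal(paste(ez$gene_i, ez$gene_j),
               c("gA gB", "gA gC", "gB gC"))

  # equal magnitude, opposite signs rank together irrespective of sign
  t2 <- diag(3); dimnames(t2) <- list(ids, ids)
  t2["gA", "gB"] <- t2["gB", "gA"] <- 0.4
  t2["gA", "gC"] <- t2["gC", "gA"] <- -0.4
  et <- rank_edges(t2)
  expect_equal(paste(et$gene_i, et$gene_j)[1:2], c("gA gB", "gA gC"))
})

test_that("top-k retention truncates the ranked list", {
  pc <- diag(4)
  dimnames(pc) <- list(letters[1:4], letters[1:4])
  pc[upper.tri(pc)] <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  pc[lower.tri(pc)] <- t(pc)[lower.tri(pc)]
  e <- rank_edges(pc)
  expect_equal(nrow(top_k_edges(e, 1)), 1L)
  expect_equal(top_k_edges(e, 1)$pcor, max(abs(e$pcor)))
  expect_warning(all_e <- top_k_edges(e, 100), "exceeds")
  expect_equal(nrow(all_e), 6L)
  expect_error(top_k_edges(e, 0), ">= 1")
})

test_that("top-ranked edges recover a planted hub's spokes", {
  m <- make_precision_model(30, 1, 6, 0, 0.3, seed = 30)
  x <- simulate_condition(m, 500, seed = 31)$values
  fit <- fit_ggm(x)
  top20 <- top_k_edges(fit$edges, 20)
  truth_keys <- sort(paste(pmin(m$support$gene_i, m$support$gene_j),
                           pmax(m$support$gene_i, m$support$gene_j)))
  got_keys <- paste(pmin(top20$gene_i, top20$gene_j),
                    pmax(top20$gene_i, top20$gene_j))
  expect_gte(sum(got_keys %in% truth_keys), 5)
})
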