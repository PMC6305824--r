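test_that("edge-free precision model is the identity with empty support", {
  m <- make_precision_model(10, 0, 0, 0, 0.3, seed = 1)
  expect_equal(unname(m$precision), diag(10))
  expect_equal(nrow(m$support), 0L)
  expect_length(m$hub_genes, 0L)
})

test_that("hub-spoke precision plants partial correlations exactly on the support", {
  m <- make_precision_model(5, 1, 4, 0, 0.4, seed = 7)
  expect_equal(nrow(m$support), 4L)
  # brute-force: invert twice is identity; apply the pcor identity directly
  pc <- precision_to_pcor(m$precision)
  for (k in seq_len(nrow(m$support))) {
    expect_equal(abs(pc[m$support$gene_i[k], m$support$gene_j[k]]), 0.4,
                 tolerance = 1e-10)
  }
  off <- abs(pc[upper.tri(pc)])
  expect_equal(sum(off > 1e-10), 4L)
  ev <- eigen(m$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0.05)
})

test_that("precision model generation is deterministic and validates inputs", {
  a <- make_precision_model(20, 2, 3, 5, 0.3, seed = 11)
  b <- make_precision_model(20, 2, 3, 5, 0.3, seed = 11)
  expect_identical(a, b)
  d <- make_precision_model(20, 2, 3, 5, 0.3, seed = 12)
  expect_false(identical(a$precision, d$precision))
  expect_error(make_precision_model(5, 1, 4, 4, 0.3), "edge budget")
  expect_error(make_precision_model(10, 1, 2, 0, 0.7), "partial_corr_magnitude")
  expect_error(make_precision_model(10, 2, 9, 0, 0.3), "non-hub partners")
})

test_that("partial correlations are nonzero exactly on the recorded support", {
  for (s in 1:5) {
    m <- make_precision_model(25, 3, 5, 20, 0.3, seed = s)
    pc <- precision_to_pcor(m$precision)
    on_support <- matrix(FALSE, 25, 25,
                         dimnames = dimnames(m$precision))
    for (k in seq_len(nrow(m$support))) {
      on_support[m$support$gene_i[k], m$support$gene_j[k]] <- TRUE
      on_support[m$support$gene_j[k], m$support$gene_i[k]] <- TRUE
    }
    off <- upper.tri(pc)
    expect_true(all(abs(pc[off][on_support[off]]) > 1e-10))
    expect_true(all(abs(pc[off][!on_support[off]]) < 1e-10))
  }
})

test_that("simulate_condition reproduces means and independence structure", {
  m <- make_precision_model(6, 0, 0, 0, 0.3, seed = 1)
  st <- simulate_condition(m, 2000, mean_shift = c(g0001 = 2.0),
                           baseline_mean = 8, seed = 5)
  expect_equal(dim(st$values), c(6L, 2000L))
  r <- cor(t(st$values))
  expect_true(max(abs(r[upper.tri(r)])) < 0.1)
  expect_equal(mean(st$values["g0001", ]) - 8, 2.0, tolerance = 0.1)
  expect_equal(mean(st$values["g0002", ]) - 8, 0.0, tolerance = 0.1)
  tiny <- simulate_condition(m, 3, seed = 1)
  expect_equal(ncol(tiny$values), 3L)
  expect_error(simulate_condition(m, 2, seed = 1), ">= 3")
  expect_identical(simulate_condition(m, 10, seed = 3)$values,
                   simulate_condition(m, 10, seed = 3)$values)

  # heterogeneous noise scales variances but not correlations
  het <- simulate_condition(m, 2000, seed = 5,
                            gene_sd = c(g0001 = 3))
  expect_equal(sd(het$values["g0001", ]), 3, tolerance = 0.15)
  expect_equal(sd(het$values["g0002", ]), 1, tolerance = 0.05)
})

test_that("two-condition study has the default 84 normal / 210 cancer design", {
  res <- make_two_condition_study(two_condition_params(seed = 2))
  tab <- table(res$study$condition)
  expect_equal(as.integer(tab[["normal"]]), 84L)
  expect_equal(as.integer(tab[["cancer"]]), 210L)
  expect_length(res$study$gene_ids, 154L)
  expect_setequal(res$truth$cancer_specific_hubs,
                  setdiff(res$truth$cancer_model$hub_genes,
                          res$truth$normal_model$hub_genes))
  expect_true(all(abs(res$truth$de_genes) >= 1))
  # determinism: bit-identical rerun
  res2 <- make_two_condition_study(two_condition_params(seed = 2))
  expect_identical(res, res2)
})

test_that("multi-dataset draws share the truth and differ only by noise", {
  params <- two_condition_params(n_genes = 20L, n_normal = 10L,
                                 n_cancer = 12L, n_shared_hubs = 1L,
                                 n_cancer_hubs = 1L, n_normal_hubs = 0L,
                                 hub_degree = 4L, background_edges = 5L,
                                 n_de_genes = 5L, seed = 9)
  res <- make_two_condition_study(params)
  sets <- make_multi_dataset(res$truth, 3L,
                             list(c(10L, 12L), c(10L, 12L), c(20L, 8L)),
                             seeds = c(9L, 10L, 11L))
  expect_length(sets, 3L)
  # first draw reuses the study seed, so it reproduces the original study
  expect_identical(sets[[1]]$values, res$study$values)
  expect_false(identical(sets[[1]]$values, sets[[2]]$values))
  expect_equal(ncol(sets[[3]]$values), 28L)
  expect_error(make_multi_dataset(res$truth, 2L, list(c(5L, 5L)),
                                  seeds = 1:2), "lengths differ")
})
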