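test_that("log2 fold-change is the difference of condition means", {
  st <- toy_study(matrix(8, 3, 4), matrix(c(8, 10, 7), 3, 4))
  lfc <- log2_fold_change(st)
  expect_equal(unname(lfc), c(0, 2, -1))
  # fold_change scale via call_degs
  tab <- call_degs(lfc, p_raw = rep(0.5, 3))
  expect_equal(tab$fold_change, c(1, 4, 0.5))
})

test_that("gene-wise Welch test matches t.test and handles degenerate genes", {
  nrm <- matrix(c(0.0, 0.1, -0.1, 0.05), 1)
  can <- matrix(c(3.0, 3.1, 2.9, 3.05), 1)
  st <- toy_study(nrm, can)
  p <- gene_wise_test(st)
  oracle <- t.test(can[1, ], nrm[1, ], var.equal = FALSE)$p.value
  expect_equal(unname(p), oracle, tolerance = 1e-10)

  # identical samples in both groups -> p = 1
  same <- matrix(1:3, 1)
  expect_equal(unname(gene_wise_test(toy_study(same, same))), 1)

  # zero variance in both groups: equal means p = 1, unequal p = 0
  st0 <- toy_study(matrix(c(2, 2, 2, 5, 5, 5), 2, 3, byrow = TRUE),
                   matrix(c(2, 2, 2, 7, 7, 7), 2, 3, byrow = TRUE))
  expect_equal(unname(gene_wise_test(st0)), c(1, 0))

  # random studies against the stats::t.test oracle
  set.seed(42)
  for (rep in 1:5) {
    nrm <- matrix(rnorm(5 * 7), 5, 7)
    can <- matrix(rnorm(5 * 9, sd = 1.5), 5, 9)
    p <- gene_wise_test(toy_study(nrm, can))
    for (g in 1:5)
      expect_equal(unname(p[g]),
                   t.test(can[g, ], nrm[g, ], var.equal = FALSE)$p.value,
                   tolerance = 1e-10)
  }
})

test_that("BH adjustment matches both the worked example and oracles", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (rep in 1:200) {
    p <- runif(sample(1:20, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p) && all(q <= 1))
  }
})

test_that("DEG calls use strict thresholds", {
  lfc <- log2(c(4.0, 1.0, 0.25, 2.0, 4.0))
  p_adj <- c(0.001, 0.001, 0.001, 1e-4, 0.01)
  tab <- call_degs(lfc, p_raw = p_adj, p_adj = p_adj)
  # fold_change 2.0 exactly and p_adj 0.01 exactly are both excluded
  expect_equal(tab$is_deg, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_error(call_degs(lfc, p_adj, p_adj, fc_lo = 1.2), "fc_lo")
  expect_error(call_degs(lfc, p_adj, p_adj, alpha = 0), "alpha")
})

test_that("tightening thresholds never adds a DEG", {
  set.seed(13)
  for (rep in 1:20) {
    lfc <- rnorm(50, sd = 2)
    p <- runif(50)
    base <- call_degs(lfc, p, fc_hi = 2, fc_lo = 0.5, alpha = 0.05)
    tighter <- list(
      call_degs(lfc, p, fc_hi = 2, fc_lo = 0.5, alpha = 0.01),
      call_degs(lfc, p, fc_hi = 3, fc_lo = 0.3, alpha = 0.05))
    for (t2 in tighter)
      expect_true(all(which(t2$is_deg) %in% which(base$is_deg)))
  }
})

test_that("mutual DEGs are the intersection across datasets", {
  mk <- function(degs, universe = c("g1", "g2", "g3"), id = "d") {
    call_degs(setNames(ifelse(universe %in% degs, 2, 0), universe),
              p_raw = rep(1e-6, length(universe)),
              p_adj = rep(1e-6, length(universe)), dataset_id = id)
  }
  m <- mutual_degs(list(mk(c("g1", "g2"), id = "a"),
                        mk(c("g2", "g3"), id = "b"),
                        mk("g2", id = "c")))
  expect_equal(m$genes, "g2")
  expect_equal(unname(m$per_dataset_counts), c(2L, 2L, 1L))
  expect_named(m$per_dataset_counts, c("a", "b", "c"))
  # idempotence
  t1 <- mk(c("g1", "g3"))
  expect_equal(mutual_degs(list(t1, t1, t1))$genes, c("g1", "g3"))
  expect_error(mutual_degs(list()), "empty")
  expect_warning(mutual_degs(list(mk("g1"), mk("g2"))), "empty")
})

test_that("gene order permutation permutes DE outputs identically", {
  set.seed(3)
  nrm <- matrix(rnorm(40), 8, 5, dimnames = list(sprintf("g%d", 1:8)))
  can <- matrix(rnorm(48, mean = 1), 8, 6)
  st <- toy_study(nrm, can)
  perm <- sample(8)
  stp <- expression_study(st$values[perm, ], unname(st$condition), "toy")
  expect_equal(gene_wise_test(stp), gene_wise_test(st)[perm])
  expect_equal(log2_fold_change(stp), log2_fold_change(st)[perm])
})
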