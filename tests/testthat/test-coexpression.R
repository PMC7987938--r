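# Mutual information estimation, top-k pruning, permutation calibration,
# DPI pruning.

test_that("MI matches closed forms on canonical tables", {
  # independent 2x2: all four bin combinations equally frequent
  x <- c(0, 0, 1, 1)
  y <- c(0, 1, 0, 1)
  expect_equal(mutual_information(x, y, bins = 2), 0)

  # identical vectors with distinct values: diagonal table, MI = ln 2
  x <- 1:8
  expect_equal(mutual_information(x, x, bins = 2), log(2))

  # constant vector: single occupied bin, MI 0 with warning
  expect_warning(mi0 <- mutual_information(rep(1, 10), 1:10, bins = 2),
                 "constant")
  expect_equal(mi0, 0)

  expect_error(mutual_information(1:3, 1:3, bins = 2), "n >= 2")
})

test_that("estimator equals the brute-force oracle on random instances", {
  set.seed(100)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    b <- sample(2:5, 1)
    if (i %% 2 == 0) {
      x <- rnorm(n); y <- 0.8 * x + 0.6 * rnorm(n)
    } else {
      x <- sample(0:3, n, replace = TRUE)   # heavy ties
      y <- sample(0:3, n, replace = TRUE)
    }
    expect_lt(abs(mutual_information(x, y, bins = b) - oracle_mi(x, y, b)),
              1e-12)
  }
})

test_that("MI is symmetric and bounded", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(20:80, 1)
    b <- sample(2:6, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    mxy <- mutual_information(x, y, bins = b)
    expect_identical(mxy, mutual_information(y, x, bins = b))
    expect_gte(mxy, 0)
    expect_lte(mxy, log(b))
  }
})

test_that("pairwise MI covers all pairs and honors the chunking contract", {
  set.seed(102)
  m <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(paste0("g", 1:5), NULL))
  all_pairs <- pairwise_mi(m, bins = 3)
  expect_equal(nrow(all_pairs), choose(5, 2))

  # results computed in two disjoint pair chunks agree with the full run
  pr <- t(combn(paste0("g", 1:5), 2))
  chunk1 <- pairwise_mi(m, bins = 3,
                        pairs = data.frame(a = pr[1:5, 1], b = pr[1:5, 2]))
  chunk2 <- pairwise_mi(m, bins = 3,
                        pairs = data.frame(a = pr[6:10, 1], b = pr[6:10, 2]))
  combined <- rbind(chunk1, chunk2)
  key <- function(d) paste(d$gene_a, d$gene_b)
  expect_setequal(key(combined), key(all_pairs))
  expect_equal(combined$mi[match(key(all_pairs), key(combined))],
               all_pairs$mi, tolerance = 1e-12)

  # duplicated gene rows reach the log(bins) ceiling (n divisible by bins)
  m2 <- rbind(a = rnorm(30), b = numeric(30))
  m2["b", ] <- m2["a", ]
  mi <- pairwise_mi(m2, bins = 3)
  expect_equal(mi$mi, log(3), tolerance = 1e-12)

  expect_error(pairwise_mi(m[1, , drop = FALSE]), "2 genes")
})

test_that("scalar and all-pairs paths agree with default bin count", {
  set.seed(103)
  m <- matrix(rnorm(8 * 49), 8, 49, dimnames = list(paste0("g", 1:8), NULL))
  ap <- pairwise_mi(m)              # default bins = floor(sqrt(49)) = 7
  for (r in sample(nrow(ap), 10)) {
    expect_equal(ap$mi[r],
                 mutual_information(m[ap$gene_a[r], ], m[ap$gene_b[r], ],
                                    bins = 7),
                 tolerance = 1e-12)
  }
})

test_that("top-k keeps the strongest edges with lexicographic tie-break", {
  res <- data.frame(gene_a = c("x", "a", "a"), gene_b = c("y", "b", "c"),
                    mi = c(0.5, 0.5, 0.3))
  expect_equal(nrow(top_k_edges(res, 0)), 0L)
  top1 <- top_k_edges(res, 1)
  expect_equal(top1$gene_a, "a")
  expect_equal(top1$gene_b, "b")
  expect_equal(nrow(top_k_edges(res, 3)), 3L)
  expect_warning(all4 <- top_k_edges(res, 4), "exceeds")
  expect_equal(nrow(all4), 3L)
  expect_error(top_k_edges(res, -1), ">= 0")
})

test_that("permutation threshold is a monotone null quantile", {
  set.seed(104)
  m <- matrix(rnorm(40 * 64), 40, 64, dimnames = list(paste0("g", 1:40), NULL))
  cal <- permutation_threshold(m, n_perm = 400L, p_target = 0.5, seed = 8L)
  expect_equal(cal$threshold, median(cal$null))
  thr <- cal$mi_threshold_at
  expect_gte(thr(1e-4), thr(1e-2))
  expect_gte(thr(1e-2), thr(0.5))
  expect_error(thr(0), "> 0")
  expect_error(permutation_threshold(m, n_perm = 5L), "n_perm")
  expect_error(permutation_threshold(m, p_target = 0), "p_target")
  # deterministic in the seed
  cal2 <- permutation_threshold(m, n_perm = 400L, p_target = 0.5, seed = 8L)
  expect_identical(cal$null, cal2$null)
})

test_that("DPI pruning removes weak triangle edges and is idempotent", {
  tri <- coexpression_network(c("a", "a", "b"), c("b", "c", "c"),
                              c(0.9, 0.8, 0.1))
  pruned <- dpi_prune(tri, tolerance = 0)
  expect_equal(nrow(pruned), 2L)
  expect_false(any(pruned$mi == 0.1))
  expect_equal(dpi_prune(pruned, 0), pruned)

  expect_equal(nrow(dpi_prune(tri, tolerance = 1)), 3L)

  chain <- coexpression_network(c("a", "b"), c("b", "c"), c(0.9, 0.1))
  expect_equal(dpi_prune(chain, 0), chain)

  expect_error(dpi_prune(tri, tolerance = 2), "tolerance")
})
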