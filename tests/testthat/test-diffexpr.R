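# Moderated-t differential expression, BH adjustment, trend classification.

make_groups <- function(n_genes, n1 = 10, n2 = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2), 5, 1), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)), NULL))
  list(m = m, cond = rep(c("baseline", "altered"), c(n1, n2)))
}

test_that("moderated t degenerates correctly", {
  gg <- make_groups(50, seed = 2)
  # force one gene to have exactly equal group means
  gg$m[1, ] <- c(1:10, 10:1)
  de <- moderated_t(gg$m, gg$cond)
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$t[1], 0)
  expect_equal(de$p[1], 1)
  expect_error(moderated_t(gg$m, rep("one", 20)), "2 levels")
  expect_error(moderated_t(gg$m[, 1:11], rep(c("a", "b"), c(10, 1))),
               ">= 2 samples")
})

test_that("equal per-gene variances leave moderated variances near s^2", {
  set.seed(3)
  base <- rnorm(40)
  m <- t(vapply(1:300, function(g) base + rnorm(1, 0, 3), numeric(40)))
  rownames(m) <- paste0("g", 1:300)
  cond <- rep(c("a", "b"), each = 20)
  de <- moderated_t(m, cond)
  expect_true(is.infinite(attr(de, "d0")))
  s2 <- var(base[1:20]) * 0 + {  # pooled variance identical for all genes
    v1 <- var(base[1:20]); v2 <- var(base[21:40])
    (19 * v1 + 19 * v2) / 38
  }
  expect_equal(attr(de, "s0_sq"), s2, tolerance = 0.05)
})

test_that("BH adjustment matches the closed forms and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("DEG calls use an inclusive lfc boundary and strict p", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.5, 2, -1.6, 0.2),
                   adj_p = c(0.009, 0.01, 0.001, 0.0001))
  got <- call_degs(de)
  expect_equal(got$call, c("up", "ns", "down", "ns"))
})

test_that("planted fold changes are recovered at the stated thresholds", {
  cfg <- synthetic_config(seed = 19L)
  lay <- build_genome(cfg)
  tr <- planted_truth(cfg, lay)
  b <- simulate_counts(lay, cfg, "baseline", "trans_dominant")
  a <- simulate_counts(lay, cfg, "altered", "trans_dominant")
  ppb <- preprocess_counts(b, lay$genes)
  ppa <- preprocess_counts(a, lay$genes)
  shared <- intersect(rownames(ppb$matrix), rownames(ppa$matrix))
  m <- cbind(ppb$matrix[shared, ], ppa$matrix[shared, ])
  cond <- factor(rep(c("baseline", "altered"), each = cfg$n_samples),
                 levels = c("baseline", "altered"))
  de <- call_degs(moderated_t(m, cond))

  strong <- tr$de$gene_id[abs(tr$de$lfc) >= 3 & tr$de$gene_id %in% shared]
  called <- de$gene_id[de$call != "ns"]
  expect_gte(mean(strong %in% called), 0.9)
  # recovered signs agree with the planted ones for recalled strong genes
  hit <- intersect(strong, called)
  planted_sign <- sign(tr$de$lfc[match(hit, tr$de$gene_id)])
  got_sign <- sign(de$log2fc[match(hit, de$gene_id)])
  expect_true(all(planted_sign == got_sign))
})

test_that("p-values track limma on shared data", {
  skip_if_not_installed("limma")
  gg <- make_groups(300, n1 = 15, n2 = 15, seed = 6)
  gg$m[1:30, 16:30] <- gg$m[1:30, 16:30] + 2   # real effects
  de <- moderated_t(gg$m, gg$cond)
  design <- cbind(1, as.integer(factor(gg$cond)) - 1)
  fit <- limma::eBayes(limma::lmFit(gg$m, design))
  expect_gt(cor(-log10(de$p), -log10(fit$p.value[, 2]),
                method = "spearman"), 0.95)
})

test_that("trend classification is exhaustive and mode-sensitive", {
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   log2fc = c(2, 1, -2, 0, -1),
                   adj_p = c(0.001, 0.5, 0.001, 0.9, 0.2))
  de <- call_degs(de)                      # a: up, c: down, rest ns
  net <- coexpression_network(c("a", "a", "c", "a", "b"),
                              c("b", "c", "e", "d", "e"),
                              c(5, 4, 3, 2, 1) / 10)
  t_sign <- trend_classify_edges(net, de, "sign")
  tr <- function(tab, a, b)
    as.character(tab$trend[tab$gene_a == a & tab$gene_b == b])
  expect_equal(tr(t_sign, "a", "b"), "same-trend-up")
  expect_equal(tr(t_sign, "a", "c"), "opposite-trend")
  expect_equal(tr(t_sign, "c", "e"), "same-trend-down")
  expect_equal(tr(t_sign, "a", "d"), "involves-ns")   # zero lfc endpoint

  t_sig <- trend_classify_edges(net, de, "significant-only")
  expect_equal(tr(t_sig, "a", "b"), "involves-ns")    # b is ns
  expect_equal(tr(t_sig, "a", "c"), "opposite-trend")

  for (mode in c("sign", "significant-only")) {
    tt <- trend_classify_edges(net, de, mode)
    expect_equal(sum(table(tt$trend)), nrow(net))
  }

  expect_error(trend_classify_edges(
    coexpression_network("a", "zz", 1), de), "zz")
})

test_that("trend summaries report cis-only counts with annotation", {
  ann <- toy_annotation()
  de <- data.frame(gene_id = ann$gene_id,
                   log2fc = c(2, 1, -1, 3, -2, 1, 2, -1),
                   adj_p = rep(0.001, 8))
  de <- call_degs(de)
  net <- coexpression_network(c("g1", "g1", "g5"), c("g2", "g5", "g6"),
                              c(0.9, 0.8, 0.7))
  tt <- trend_classify_edges(net, de, "sign", annotation = ann)
  s <- attr(tt, "summary")
  expect_equal(sum(s$cis_only), 2L)        # g1-g2 and g5-g6 are cis
  expect_equal(sum(s$all), 3L)
})
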