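# Genomic edge classification and cis/trans statistics.

test_that("edges are classified by chromosome, arm and cytoband", {
  ann <- toy_annotation()
  # g3,g4: chr1 q1/q2 (same arm, different band); g1,g2: chr1 p2/p1;
  # g5: chr2 p2
  net <- coexpression_network(c("g3", "g1", "g1", "g2"),
                              c("g4", "g3", "g5", "g1"),
                              c(0.9, 0.8, 0.7, 0.6))
  cls <- classify_edges(net, ann)
  row <- function(a, b) cls[cls$gene_a == a & cls$gene_b == b, ]

  r <- row("g3", "g4")               # same arm, different band
  expect_true(r$same_chromosome && r$same_arm && !r$same_cytoband)
  expect_equal(as.character(r$category), "cis-intra-arm-inter-band")
  expect_equal(r$distance_bp, 20e6)

  r <- row("g1", "g3")               # p vs q arm
  expect_true(r$same_chromosome && !r$same_arm)
  expect_equal(as.character(r$category), "cis-inter-arm")

  r <- row("g1", "g5")               # chr1 vs chr2
  expect_false(r$same_chromosome)
  expect_equal(as.character(r$category), "trans")
  expect_true(is.na(r$distance_bp))

  r <- row("g1", "g2")               # both p arm, different bands
  expect_equal(as.character(r$category), "cis-intra-arm-inter-band")

  expect_error(classify_edges(
    coexpression_network("g1", "zz", 1), ann), "zz")
})

test_that("same-cytoband edges are classified intra-band", {
  ann <- toy_annotation()
  ann$cytoband[ann$gene_id %in% c("g1", "g2")] <- "p1"
  cls <- classify_edges(coexpression_network("g1", "g2", 1), ann)
  expect_equal(as.character(cls$category), "cis-intra-band")
  expect_true(cls$same_arm && cls$same_cytoband)
})

test_that("classification is exhaustive and order/orientation invariant", {
  ann <- toy_annotation()
  for (seed in 1:5) {
    net <- random_network(12L, ann$gene_id, seed)
    cls <- cis_fraction(classify_edges(net, ann))
    expect_equal(sum(cls$totals), cls$n_edges)

    shuf <- net[sample(nrow(net)), ]
    swapped <- coexpression_network(shuf$gene_b, shuf$gene_a, shuf$mi)
    cls2 <- classify_edges(swapped, ann)
    cls1 <- classify_edges(net, ann)
    expect_equal(cls1[order(cls1$gene_a, cls1$gene_b), ],
                 cls2[order(cls2$gene_a, cls2$gene_b), ],
                 ignore_attr = TRUE)
  }
})

test_that("cis fractions follow edge counts", {
  ann <- toy_annotation()
  all_cis <- coexpression_network(c("g1", "g1"), c("g2", "g3"), c(1, 0.5))
  expect_equal(cis_fraction(classify_edges(all_cis, ann))$cis_fraction, 1)

  mixed <- coexpression_network(c("g1", "g1"), c("g2", "g5"), c(1, 0.5))
  expect_equal(cis_fraction(classify_edges(mixed, ann))$cis_fraction, 0.5)

  expect_error(cis_fraction(classify_edges(
    coexpression_network(character(0), character(0), numeric(0)), ann)),
    "empty")
})

test_that("cutoff sweep is prefix-nested and consistent with the full network", {
  cc <- small_cohort(seed = 31L)
  pp <- preprocess_counts(cc$counts, cc$layout$genes)
  mi <- pairwise_mi(pp$matrix)
  ann <- cc$layout$genes

  full <- cis_fraction(classify_edges(
    suppressWarnings(top_k_edges(mi, nrow(mi))), ann))$cis_fraction
  sw <- cutoff_sweep(mi, ann, k_values = nrow(mi))
  expect_equal(sw$cis_fraction, full)

  sw2 <- cutoff_sweep(mi, ann, k_values = c(10L, 20L))
  k10 <- top_k_edges(mi, 10); k20 <- top_k_edges(mi, 20)
  key <- function(n) paste(n$gene_a, n$gene_b)
  expect_true(all(key(k10) %in% key(k20)))
  expect_equal(sw2$cis_fraction[1],
               cis_fraction(classify_edges(k10, ann))$cis_fraction)
  expect_warning(cutoff_sweep(mi, ann, k_values = nrow(mi) + 10L),
                 "truncated")
})

test_that("identical summaries compare as null; Fisher matches enumeration", {
  ann <- toy_annotation()
  net <- random_network(14L, ann$gene_id, 2L)
  s <- cis_fraction(classify_edges(net, ann))
  cmp <- compare_cis_trans(s, s)
  expect_equal(cmp$fisher_odds_ratio, 1, tolerance = 1e-6)
  # toy genome has 2 chromosomes, below the signed-rank minimum
  expect_true(is.na(cmp$wilcoxon_p))
  expect_match(cmp$note, "fewer than 6")

  # pooled Fisher p equals the exhaustive hypergeometric oracle
  mk <- function(cis, trans) {
    structure(list(n_edges = cis + trans,
                   cis_fraction = cis / (cis + trans),
                   totals = c(trans = trans, cis = cis),
                   per_chromosome = data.frame(chrom = character(0),
                                               cis_fraction = numeric(0))),
              class = "cistrans_summary")
  }
  cmp2 <- compare_cis_trans(mk(90, 10), mk(10, 90))
  expect_equal(cmp2$fisher_p, oracle_fisher(90, 10, 10, 90),
               tolerance = 1e-9)
})

test_that("paired per-chromosome comparison reports a Wilcoxon p-value", {
  cfg <- synthetic_config(n_genes = 120L, n_chromosomes = 8L, seed = 17L)
  lay <- build_genome(cfg)
  netA <- random_network(150L, lay$genes$gene_id, 5L)
  netB <- random_network(150L, lay$genes$gene_id, 6L)
  sA <- cis_fraction(classify_edges(netA, lay$genes))
  sB <- cis_fraction(classify_edges(netB, lay$genes))
  self <- compare_cis_trans(sA, sA)
  expect_equal(self$wilcoxon_p, 1)
  cross <- compare_cis_trans(sA, sB)
  expect_true(is.finite(cross$wilcoxon_p))
  expect_true(cross$wilcoxon_p >= 0 && cross$wilcoxon_p <= 1)
})

test_that("cytoband proximity test detects pure intra-band networks", {
  # one chromosome, 4 bands x 5 genes, a 5-cycle inside each band
  G <- 20L
  ann <- data.frame(
    gene_id = sprintf("g%02d", 1:G),
    chrom = "chr1",
    start = seq(1e6, 96e6, length.out = G),
    end = seq(1e6, 96e6, length.out = G) + 1e4,
    gc = 0.5, biotype = "protein_coding",
    cytoband = rep(c("p2", "p1", "q1", "q2"), each = 5),
    arm = rep(c("p", "p", "q", "q"), each = 5),
    stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(0:3, function(b) {
    ids <- sprintf("g%02d", b * 5 + 1:5)
    data.frame(a = ids, b = ids[c(2:5, 1)])
  }))
  net <- coexpression_network(edges$a, edges$b, runif(nrow(edges), 0.5, 1))
  res <- cytoband_proximity_test(net, ann, n_rewire = 99L, seed = 3L)
  expect_equal(res$p_value, 1 / 100)
  expect_gt(res$enrichment, 1)
  expect_error(cytoband_proximity_test(net, ann, n_rewire = 50L), "99")
})

test_that("cytoband proximity test is calibrated on random networks", {
  cfg <- synthetic_config(n_genes = 40L, n_chromosomes = 2L, seed = 23L)
  lay <- build_genome(cfg)
  pvals <- vapply(1:50, function(s) {
    net <- random_network(60L, lay$genes$gene_id, 1000L + s)
    cytoband_proximity_test(net, lay$genes, n_rewire = 99L,
                            seed = s)$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.10)
})
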