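# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# -- MI oracle: explicit double loop over contingency cells ------------------
# Discretization re-derived from first principles: the i-th smallest value
# (ties resolved by original position) goes to bin ceiling(i * bins / n).
oracle_mi <- function(x, y, bins) {
  n <- length(x)
  bin_of <- function(v) {
    b <- integer(n)
    ord <- order(v, seq_along(v))      # stable: ties by original index
    for (i in seq_len(n)) b[ord[i]] <- ceiling(i * bins / n)
    b
  }
  bx <- bin_of(x); by <- bin_of(y)
  mi <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      pij <- sum(bx == i & by == j) / n
      pi_ <- sum(bx == i) / n
      p_j <- sum(by == j) / n
      if (pij > 0) mi <- mi + pij * log(pij / (pi_ * p_j))
    }
  }
  mi
}

# -- BH oracle: literal step-up definition -----------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  adj[ord] <- p[ord] * m / seq_len(m)
  # monotonicity enforcement from the largest rank down
  for (i in rev(seq_len(m - 1)))
    adj[ord[i]] <- min(adj[ord[i]], adj[ord[i + 1]])
  pmin(adj, 1)
}

# -- Fisher oracle: exhaustive hypergeometric tail ---------------------------
# two-sided p: sum of probabilities of all tables (fixed margins) no more
# probable than the observed one
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# -- component oracle: label propagation to a fixed point --------------------
oracle_components <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  lab <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- edges$gene_a[r]; b <- edges$gene_b[r]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[a] <- m; lab[b] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(lab), lab)
}

# -- fixtures ----------------------------------------------------------------
# a deterministic toy annotation: two chromosomes, two arms, two bands/arm
toy_annotation <- function() {
  data.frame(
    gene_id = paste0("g", 1:8),
    chrom = rep(c("chr1", "chr2"), each = 4),
    start = rep(c(10L, 30L, 60L, 80L) * 1000000L, 2),
    end = rep(c(10L, 30L, 60L, 80L) * 1000000L, 2) + 10000L,
    gc = seq(0.4, 0.54, by = 0.02),
    biotype = "protein_coding",
    cytoband = rep(c("p2", "p1", "q1", "q2"), 2),
    arm = rep(c("p", "p", "q", "q"), 2),
    stringsAsFactors = FALSE)
}

random_network <- function(n_edges, genes, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(genes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  coexpression_network(pairs[pick, 1], pairs[pick, 2],
                       signif(runif(length(pick), 0.01, 2), 6))
}

small_cohort <- function(seed = 3L, structure = "cis_dominant",
                         n_genes = 80L, n_samples = 40L) {
  cfg <- synthetic_config(n_genes = n_genes, n_chromosomes = 4L,
                          n_samples = n_samples,
                          trans_modules = c(12L, 12L), seed = seed)
  lay <- build_genome(cfg)
  list(config = cfg, layout = lay,
       counts = simulate_counts(lay, cfg, "baseline", structure))
}
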