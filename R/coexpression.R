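# Mutual-information co-expression inference.
#
# The estimator is the plug-in MI on equal-frequency bins: each expression
# profile is discretized into b bins of (near-)equal occupancy, ties broken
# by stable rank (original sample order), and MI is the contingency-table
# sum p(i,j) * ln[ p(i,j) / (p(i) p(j)) ] in nats, with 0 ln 0 := 0.
# Being rank-based it is invariant to the monotone normalization steps, and
# deterministic, so it can be checked cell-by-cell against a brute-force
# oracle. Default bin count is floor(sqrt(n_samples)).

#' Discretize a vector into equal-frequency bins
#'
#' Ties are broken by stable rank (original index order), so bin occupancies
#' depend only on `n` and `bins` and the result is deterministic.
#' @param x numeric vector.
#' @param bins bin count.
#' @return integer vector of bin indices in `1:bins`.
#' @export
discretize_ef <- function(x, bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / n))
}

#' Plug-in mutual information of two sample vectors
#'
#' @param x,y numeric vectors of equal length `n >= 2 * bins`.
#' @param bins number of equal-frequency bins; default
#'   `floor(sqrt(length(x)))`.
#' @return MI in nats (non-negative, at most `log(bins)`). A constant
#'   vector occupies a single bin, giving MI 0 with a warning.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  bins <- as.integer(bins)
  if (n < 2L * bins) stopf("need n >= 2*bins (n=%d, bins=%d)", n, bins)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warnf("constant vector: MI is 0 (single occupied bin)")
    return(0)
  }
  mi_from_bins(discretize_ef(x, bins), discretize_ef(y, bins), bins, n)
}

#' All-pairs mutual information
#'
#' Computes MI for every unordered gene pair (or for an explicit subset of
#' pairs, the chunking contract: results from disjoint pair chunks
#' concatenate to the full set independent of order).
#'
#' @param matrix expression matrix, genes x samples (>= 2 genes).
#' @param bins bin count; default `floor(sqrt(n_samples))` (at least 2).
#' @param pairs optional 2-column matrix/data.frame of gene IDs or row
#'   indices restricting computation to those pairs.
#' @return data.frame with columns `gene_a`, `gene_b` (canonical order) and
#'   `mi`, one row per pair; `choose(n_genes, 2)` rows when `pairs` is NULL.
#' @export
pairwise_mi <- function(matrix, bins = NULL, pairs = NULL) {
  G <- nrow(matrix)
  if (G < 2L) stopf("need at least 2 genes")
  n <- ncol(matrix)
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  bins <- as.integer(bins)
  if (n < 2L * bins) stopf("need n >= 2*bins (n=%d, bins=%d)", n, bins)
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("gene", seq_len(G))

  D <- t(apply(matrix, 1L, discretize_ef, bins = bins))  # G x n bins

  if (!is.null(pairs)) {
    pa <- pairs[[1]]; pb <- pairs[[2]]
    ia <- if (is.numeric(pa)) as.integer(pa) else match(as.character(pa), ids)
    ib <- if (is.numeric(pb)) as.integer(pb) else match(as.character(pb), ids)
    if (anyNA(ia) || anyNA(ib)) stopf("pair gene not found in matrix")
    mi <- vapply(seq_along(ia), function(p)
      mi_from_bins(D[ia[p], ], D[ib[p], ], bins, n), numeric(1))
    cp <- canonical_pairs(ids[ia], ids[ib])
    return(data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b, mi = mi,
                      stringsAsFactors = FALSE))
  }

  # fast path: per-bin indicator crossproducts give all-pairs cell counts
  marg <- matrix(0, G, bins)
  ind <- vector("list", bins)
  for (k in seq_len(bins)) {
    Ik <- t(D == k) * 1          # n x G indicator
    ind[[k]] <- Ik
    marg[, k] <- colSums(Ik)
  }
  M <- matrix(0, G, G)
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      C <- crossprod(ind[[i]], ind[[j]])     # G x G: count of (bin i, bin j)
      term <- (C / n) * log(C * n / outer(marg[, i], marg[, j]))
      term[C == 0] <- 0
      M <- M + term
    }
  }
  iu <- which(upper.tri(M), arr.ind = TRUE)
  cp <- canonical_pairs(ids[iu[, 1L]], ids[iu[, 2L]])
  data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
             mi = pmax(0, M[iu]), stringsAsFactors = FALSE)
}

# MI from pre-binned vectors. Cell terms are summed in sorted order, a
# canonical order invariant to transposing the contingency table, so
# MI(x, y) == MI(y, x) bitwise; the plug-in value is clamped at 0.
mi_from_bins <- function(dx, dy, bins, n) {
  joint <- tabulate((dx - 1L) * bins + dy, nbins = bins * bins)
  mx <- tabulate(dx, nbins = bins)
  my <- tabulate(dy, nbins = bins)
  i <- rep(seq_len(bins), each = bins)
  j <- rep(seq_len(bins), times = bins)
  pos <- joint > 0L
  # single-log product form: the marginal product commutes, so the term is
  # bitwise invariant under transposition of the table
  terms <- (joint[pos] / n) *
    log(joint[pos] * n / (mx[i[pos]] * my[j[pos]]))
  max(0, sum(sort(terms)))
}

#' Keep the k strongest edges
#'
#' @param results data.frame from [pairwise_mi()] (columns gene_a, gene_b,
#'   mi).
#' @param k number of edges to keep; ties at the cut broken
#'   lexicographically by gene pair.
#' @return a [coexpression_network()] with ranks `1:k`.
#' @export
top_k_edges <- function(results, k) {
  if (k < 0) stopf("k must be >= 0")
  if (k > nrow(results)) {
    warnf("k (%d) exceeds available pairs (%d); returning all",
          k, nrow(results))
    k <- nrow(results)
  }
  net <- coexpression_network(results$gene_a, results$gene_b, results$mi)
  net <- net[seq_len(k), , drop = FALSE]
  class(net) <- c("coexpression_network", "data.frame")
  net
}

#' Permutation calibration of the MI null
#'
#' Builds a null MI distribution by permuting the sample labels of one
#' member of randomly drawn gene pairs, then exposes a threshold function:
#' for p-values at or above 1/(pool size) the threshold is the empirical
#' `1 - p` quantile; smaller p-values are extrapolated with an exponential
#' fit to the tail above the null's 95th percentile (threshold
#' `u + log(q_u / p) / rate`, with `q_u` the exceedance probability of the
#' anchor `u` and `rate` the reciprocal mean exceedance).
#'
#' @param matrix expression matrix, genes x samples.
#' @param n_perm number of permuted pairs (>= 10).
#' @param p_target default p-value at which `threshold` is reported.
#' @param seed integer seed.
#' @param bins bin count passed to the estimator.
#' @return list of class `null_calibration` with `null` (sorted null MI
#'   values), `threshold` (at `p_target`), `mi_threshold_at(p)` function,
#'   and the tail-fit parameters `anchor`, `q_anchor`, `rate`.
#' @export
permutation_threshold <- function(matrix, n_perm = 1000L, p_target = 0.01,
                                  seed = 1L, bins = NULL) {
  if (n_perm < 10L) stopf("n_perm must be >= 10")
  if (p_target <= 0) stopf("p_target must be > 0")
  G <- nrow(matrix)
  n <- ncol(matrix)
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    g <- sample.int(G, 2L)
    mutual_information(matrix[g[1L], ], matrix[g[2L], sample.int(n)],
                       bins = bins)
  }, numeric(1))
  null <- sort(null)
  u <- stats::quantile(null, 0.95, names = FALSE)
  exc <- null[null > u] - u
  rate <- if (length(exc) >= 2L && mean(exc) > 0) 1 / mean(exc) else Inf
  q_u <- mean(null > u)
  thr_at <- function(p) {
    if (any(p <= 0)) stopf("p must be > 0")
    vapply(p, function(pp) {
      if (pp >= 1 / length(null)) {
        stats::quantile(null, 1 - pp, names = FALSE)
      } else if (is.finite(rate)) {
        u + log(q_u / pp) / rate
      } else {
        max(null)
      }
    }, numeric(1))
  }
  structure(list(null = null, threshold = thr_at(p_target),
                 p_target = p_target, mi_threshold_at = thr_at,
                 anchor = u, q_anchor = q_u, rate = rate, seed = seed,
                 n_perm = n_perm),
            class = "null_calibration")
}

#' Data-processing-inequality pruning (optional, off by default)
#'
#' For every triangle in the network, marks the weakest edge for removal
#' when its MI is below `(1 - tolerance)` times the smaller of the other two
#' edges' MI; all marked edges are removed together, making the operation
#' order-independent and idempotent.
#'
#' @param network a `coexpression_network`.
#' @param tolerance in `[0, 1]`; 1 disables pruning.
#' @return pruned `coexpression_network`.
#' @export
dpi_prune <- function(network, tolerance = 0) {
  if (tolerance < 0 || tolerance > 1) stopf("tolerance must be in [0, 1]")
  if (nrow(network) < 3L || tolerance == 1) return(network)
  g <- network_to_igraph(network)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3L)
  if (ncol(tri) == 0L) return(network)
  drop_keys <- character(0)
  vn <- igraph::V(g)$name
  key <- canonical_pairs(network$gene_a, network$gene_b)$key
  mi_of <- stats::setNames(network$mi, key)
  for (t in seq_len(ncol(tri))) {
    v <- vn[tri[, t]]
    ek <- c(canonical_pairs(v[1], v[2])$key,
            canonical_pairs(v[1], v[3])$key,
            canonical_pairs(v[2], v[3])$key)
    w <- mi_of[ek]
    weakest <- which.min(w)
    others <- min(w[-weakest])
    if (w[weakest] < (1 - tolerance) * others)
      drop_keys <- c(drop_keys, ek[weakest])
  }
  keep <- !(key %in% drop_keys)
  net <- network[keep, , drop = FALSE]
  coexpression_network(net$gene_a, net$gene_b, net$mi)
}
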