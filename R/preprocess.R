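# Count preprocessing ahead of MI inference.
#
# Fixed pipeline order: mean-CPM filter on raw counts -> GC full-quantile
# correction -> length full-quantile correction -> TMM scaling -> log2(x+1).
# Every step is deterministic.

#' Counts per million
#'
#' @param matrix non-negative matrix, genes x samples.
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(matrix) {
  cs <- colSums(matrix)
  zero <- which(cs == 0)
  if (length(zero))
    stopf("all-zero sample(s): %s",
          paste(colnames(matrix)[zero], collapse = ", "))
  sweep(matrix, 2L, cs, "/") * 1e6
}

#' Remove low-expression genes
#'
#' Retains genes whose mean CPM across all samples is at least `threshold`
#' (so a gene with mean CPM exactly at the threshold is kept). Order is
#' preserved.
#'
#' @param matrix raw count matrix, genes x samples.
#' @param threshold mean-CPM cutoff (default 10).
#' @return list with `matrix` (filtered counts) and `removed` (character
#'   vector of dropped gene IDs).
#' @export
filter_low_expression <- function(matrix, threshold = 10) {
  mean_cpm <- rowMeans(cpm(matrix))
  keep <- mean_cpm >= threshold
  if (!any(keep)) stopf("no genes pass the CPM filter (threshold %g)",
                        threshold)
  list(matrix = matrix[keep, , drop = FALSE],
       removed = rownames(matrix)[!keep])
}

#' Trimmed-mean-of-M scaling factors
#'
#' Per-sample scaling factors in the trimmed-mean-of-M-values style: for each
#' sample, M- and A-values against a reference sample are computed on genes
#' nonzero in both; the M-values are trimmed 30% two-sided and the A-values
#' 5% two-sided; the factor is 2 to the inverse-variance-weighted mean of the
#' retained M-values (delta-method binomial weights). M is computed on the
#' raw values, so the factor absorbs sequencing depth as well as composition
#' bias; dividing each column by its factor normalizes both at once. Factors
#' are rescaled so their geometric mean is 1. The reference defaults to the
#' sample whose upper-quartile CPM is closest to the mean upper-quartile.
#'
#' @param matrix count matrix, genes x samples (>= 2 samples).
#' @param ref_sample optional reference column name or index.
#' @return named numeric vector of positive per-sample factors with
#'   geometric mean 1.
#' @export
tmm_factors <- function(matrix, ref_sample = NULL) {
  n <- ncol(matrix)
  if (n < 2L) stopf("TMM needs at least 2 samples")
  if (is.null(ref_sample)) {
    uq <- apply(cpm(matrix), 2L, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(matrix))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1L || ref > n) stopf("invalid ref_sample")
  }
  yr <- matrix[, ref]
  Nr <- sum(yr)
  f <- vapply(seq_len(n), function(k) {
    if (k == ref) return(1)
    yk <- matrix[, k]
    ok <- yk > 0 & yr > 0
    if (!any(ok)) stopf("no genes nonzero in both sample %d and reference", k)
    M <- log2(yk[ok] / yr[ok])
    A <- 0.5 * log2(as.numeric(yk[ok]) * as.numeric(yr[ok]))
    nk <- sum(yk)
    w <- 1 / ((nk - yk[ok]) / (nk * yk[ok]) + (Nr - yr[ok]) / (Nr * yr[ok]))
    ng <- length(M)
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    loM <- floor(ng * 0.15); loA <- floor(ng * 0.025)
    keep <- rM > loM & rM <= ng - loM & rA > loA & rA <= ng - loA
    if (!any(keep)) stopf("no genes survive TMM trimming for sample %d", k)
    2 ^ (sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(matrix))
}

#' Full-quantile normalization within covariate bins
#'
#' Splits genes into `n_bins` equal-frequency bins of the covariate
#' (typically GC fraction or gene length) and, within each sample, replaces
#' each bin's values by the cross-bin mean quantile profile, so all bins of a
#' sample share the same value distribution. Rank order within each bin is
#' preserved (ties broken by original gene order), and the procedure is
#' deterministic.
#'
#' @param matrix expression matrix, genes x samples.
#' @param gc numeric covariate, one value per gene (row).
#' @param n_bins number of equal-frequency bins (default 10).
#' @return matrix of the same shape and dimnames.
#' @export
gc_quantile_normalize <- function(matrix, gc, n_bins = 10) {
  G <- nrow(matrix)
  if (length(gc) != G) stopf("covariate length != number of genes")
  if (G < n_bins) stopf("fewer genes (%d) than bins (%d)", G, n_bins)
  # quantile breaks collapsed over ties: genes with identical covariate
  # values never straddle a bin boundary, and a constant covariate yields a
  # single (degenerate) bin
  brks <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE, type = 7))
  bin <- if (length(brks) < 2L) rep(1L, G)
         else as.integer(cut(gc, brks, include.lowest = TRUE))
  out <- matrix
  probs_of <- function(m) if (m == 1L) 0.5 else (seq_len(m) - 1) / (m - 1)
  for (j in seq_len(ncol(matrix))) {
    v <- matrix[, j]
    by_bin <- split(seq_len(G), bin)
    sorted <- lapply(by_bin, function(idx) sort(v[idx]))
    # reference quantile function: mean across bins, each bin's empirical
    # quantile function evaluated on a common fine grid
    grid <- probs_of(max(lengths(by_bin)))
    ref <- rowMeans(vapply(sorted, function(s)
      stats::quantile(s, probs = grid, names = FALSE, type = 7),
      numeric(length(grid))))
    for (b in seq_along(by_bin)) {
      idx <- by_bin[[b]]
      m <- length(idx)
      r <- rank(v[idx], ties.method = "first")
      newvals <- stats::approx(grid, ref, xout = probs_of(m),
                               rule = 2)$y
      out[idx, j] <- newvals[r]
    }
  }
  out
}

#' Preprocess a count matrix for MI inference
#'
#' Runs the full normalization path: mean-CPM filter on raw counts, GC
#' full-quantile correction, gene-length full-quantile correction, TMM
#' scaling, then `log2(x + 1)`. Because within-bin full-quantile
#' normalization replaces each value by a reference quantile at its
#' within-bin rank, its output resolution equals the number of genes per
#' bin; the effective bin count is therefore capped so every bin holds at
#' least 100 genes (one bin on very small panels), leaving `gc_bins`
#' untouched at genome scale.
#'
#' @param counts raw count matrix, genes x samples.
#' @param annotation gene annotation (provides `gc`, `start`, `end`).
#' @param cpm_threshold mean-CPM filter cutoff (default 10).
#' @param gc_bins covariate bins for the quantile steps (default 10).
#' @return list with `matrix` (log2 normalized expression) and `report`
#'   (class `normalization_report`: `genes_removed`, `tmm_factors`,
#'   `gc_bins`).
#' @export
preprocess_counts <- function(counts, annotation, cpm_threshold = 10,
                              gc_bins = 10) {
  check_annotation(annotation)
  missing_ann <- setdiff(rownames(counts), annotation$gene_id)
  if (length(missing_ann))
    stopf("gene(s) missing from annotation: %s",
          paste(utils::head(missing_ann, 5), collapse = ", "))
  flt <- filter_low_expression(counts, cpm_threshold)
  m <- flt$matrix
  ann <- annotation[match(rownames(m), annotation$gene_id), ]
  # the quantile transform's output resolution equals bin occupancy, so the
  # bin count is capped to keep >= 100 genes per bin on small panels
  nb <- max(1L, min(gc_bins, floor(nrow(m) / 100)))
  m <- gc_quantile_normalize(m, ann$gc, nb)
  m <- gc_quantile_normalize(m, ann$end - ann$start + 1, nb)
  f <- tmm_factors(m)
  m <- sweep(m, 2L, f, "/")
  report <- structure(list(genes_removed = length(flt$removed),
                           removed = flt$removed,
                           tmm_factors = f, gc_bins = nb),
                      class = "normalization_report")
  list(matrix = log2(m + 1), report = report)
}

#' Write a normalization report as key/value TSV
#' @param report a `normalization_report`.
#' @param path output path.
#' @export
write_normalization_report <- function(report, path) {
  lines <- c(paste0("genes_removed\t", report$genes_removed),
             paste0("gc_bins\t", report$gc_bins),
             paste0("tmm_factor_min\t", signif(min(report$tmm_factors), 6)),
             paste0("tmm_factor_max\t", signif(max(report$tmm_factors), 6)))
  writeLines(lines, path)
  invisible(path)
}
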