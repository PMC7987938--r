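# Two-group moderated-t differential expression and expression-trend edge
# classification.
#
# Per gene, on log2(x+1) expression: the fold change is the difference of
# group means, the pooled within-group variance is shrunk toward a global
# prior by empirical Bayes — the prior (d0, s0^2) estimated by method of
# moments on log s^2 across genes, using the moments of log F(d, d0) — and
# the t statistic is referred to a t distribution with d0 + d degrees of
# freedom.

# numeric inverse of trigamma via Newton iteration (monotone decreasing)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Moderated t-test for two groups
#'
#' @param matrix log-scale expression matrix, genes x samples (use
#'   [preprocess_counts()] output or any log2 values).
#' @param condition per-sample labels with exactly two levels; the log2
#'   fold change is `altered - baseline`, i.e. second level minus first
#'   level of `factor(condition)`, with at least 2 samples per group.
#' @return data.frame of class `de_result`: `gene_id`, `avg_expr`,
#'   `log2fc`, `t`, `p`, `adj_p`, and placeholder `call` (all `"ns"`; see
#'   [call_degs()]). Attributes `d0` and `s0_sq` carry the fitted prior.
#' @export
moderated_t <- function(matrix, condition) {
  cond <- factor(condition)
  if (nlevels(cond) != 2L) stopf("condition must have exactly 2 levels")
  g1 <- which(cond == levels(cond)[1L])
  g2 <- which(cond == levels(cond)[2L])
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stopf("each group needs >= 2 samples")
  m1 <- rowMeans(matrix[, g1, drop = FALSE])
  m2 <- rowMeans(matrix[, g2, drop = FALSE])
  v1 <- apply(matrix[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(matrix[, g2, drop = FALSE], 1L, stats::var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d

  # method of moments on z = log s^2: if s^2 ~ s0^2 F(d, d0) then
  # E z = log s0^2 + psi(d/2) - psi(d0/2) - log(d/2) + log(d0/2)
  # Var z = psi'(d/2) + psi'(d0/2)
  pos <- s2 > 0
  z <- log(s2[pos])
  vz <- stats::var(z)
  excess <- vz - trigamma(d / 2)
  if (is.na(excess) || excess <= 1e-8) {
    d0 <- Inf
    s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(z) - digamma(d / 2) + digamma(d0 / 2) +
                   log(d / 2) - log(d0 / 2))
  }
  s2_tilde <- if (is.finite(d0)) (d0 * s0_sq + d * s2) / (d0 + d)
              else rep(s0_sq, length(s2))
  lfc <- m2 - m1
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, 0)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene_id = rownames(matrix),
                    avg_expr = rowMeans(matrix),
                    log2fc = lfc, t = tstat, p = p,
                    adj_p = bh_adjust(p),
                    call = "ns", stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, order-preserving by original index.
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' Up if `log2fc >= +lfc_threshold` and `adj_p < p_threshold`; down if
#' `log2fc <= -lfc_threshold` and `adj_p < p_threshold`; otherwise ns. The
#' fold-change boundary is inclusive, the p boundary strict.
#'
#' @param de a `de_result` from [moderated_t()].
#' @param lfc_threshold absolute log2 fold-change threshold (default 1.5).
#' @param p_threshold adjusted-p threshold (default 0.01).
#' @return the `de_result` with `call` filled in.
#' @export
call_degs <- function(de, lfc_threshold = 1.5, p_threshold = 0.01) {
  de$call <- ifelse(de$log2fc >= lfc_threshold & de$adj_p < p_threshold,
                    "up",
                    ifelse(de$log2fc <= -lfc_threshold &
                             de$adj_p < p_threshold, "down", "ns"))
  de
}

TREND_CLASSES <- c("same-trend-up", "same-trend-down", "opposite-trend",
                   "involves-ns")

#' Classify edges by differential-expression trend concordance
#'
#' In `mode = "sign"` the trend is the sign of the fold change regardless of
#' significance: both positive gives same-trend-up, both negative
#' same-trend-down, strictly opposite signs opposite-trend, and a zero fold
#' change on either side involves-ns. In `mode = "significant-only"` any
#' `"ns"` call on either endpoint gives involves-ns, and same-trend classes
#' use the up/down calls.
#'
#' @param network a `coexpression_network`.
#' @param de a `de_result` covering every network gene (with calls for
#'   `significant-only` mode).
#' @param mode `"sign"` (default) or `"significant-only"`.
#' @param annotation optional gene annotation; when supplied, per-chromosome
#'   and cis-only counts are attached.
#' @return data.frame with the network columns plus `trend` (factor over
#'   the four classes); attribute `summary` holds counts per class, and per
#'   (chromosome, class) on cis edges when annotation is given.
#' @export
trend_classify_edges <- function(network, de,
                                 mode = c("sign", "significant-only"),
                                 annotation = NULL) {
  mode <- match.arg(mode)
  idx_a <- match(network$gene_a, de$gene_id)
  idx_b <- match(network$gene_b, de$gene_id)
  if (anyNA(idx_a) || anyNA(idx_b))
    stopf("edge gene(s) without DE record: %s",
          paste(unique(c(network$gene_a[is.na(idx_a)],
                         network$gene_b[is.na(idx_b)])), collapse = ", "))
  if (mode == "sign") {
    sa <- sign(de$log2fc[idx_a])
    sb <- sign(de$log2fc[idx_b])
    trend <- ifelse(sa == 0 | sb == 0, "involves-ns",
                    ifelse(sa == sb,
                           ifelse(sa > 0, "same-trend-up", "same-trend-down"),
                           "opposite-trend"))
  } else {
    ca <- de$call[idx_a]
    cb <- de$call[idx_b]
    trend <- ifelse(ca == "ns" | cb == "ns", "involves-ns",
                    ifelse(ca == cb,
                           ifelse(ca == "up", "same-trend-up",
                                  "same-trend-down"),
                           "opposite-trend"))
  }
  out <- data.frame(network[, c("gene_a", "gene_b", "mi", "rank")],
                    trend = factor(trend, levels = TREND_CLASSES),
                    stringsAsFactors = FALSE)
  summ <- list(all = table(out$trend))
  if (!is.null(annotation)) {
    cls <- classify_edges(network, annotation)
    cis <- cls$same_chromosome
    summ$cis_only <- table(out$trend[cis])
    summ$per_chromosome <- as.data.frame(
      table(chrom = cls$chrom_a[cis], trend = out$trend[cis]),
      stringsAsFactors = FALSE)
  }
  attr(out, "summary") <- summ
  out
}

#' Write a DE table as TSV
#' @param de a `de_result`.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene_id", "avg_expr", "log2fc", "p", "adj_p",
                            "call")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
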