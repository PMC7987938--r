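# Genomic classification of co-expression edges.
#
# Every edge is classified into one of four mutually exclusive, exhaustive
# categories: trans (different chromosomes), cis-inter-arm (same chromosome,
# different arms), cis-intra-arm-inter-band (same arm, different cytobands),
# cis-intra-band (same cytoband). Genomic distance uses gene START
# positions, consistent with assigning genes to cytobands by start.

EDGE_CATEGORIES <- c("trans", "cis-inter-arm", "cis-intra-arm-inter-band",
                     "cis-intra-band")

#' Classify network edges by genomic relation
#'
#' @param network a `coexpression_network`.
#' @param annotation gene annotation data.frame covering every network gene.
#' @return data.frame (one row per edge) with the network columns plus
#'   `same_chromosome`, `same_arm`, `same_cytoband` (logical; arm/cytoband
#'   are NA for trans edges), `distance_bp` (|start_a - start_b|, NA for
#'   trans) and `category` (factor over the four categories).
#' @export
classify_edges <- function(network, annotation) {
  check_annotation(annotation)
  genes <- unique(c(network$gene_a, network$gene_b))
  missing <- setdiff(genes, annotation$gene_id)
  if (length(missing))
    stopf("unannotated gene(s): %s", paste(missing, collapse = ", "))
  if (!"arm" %in% names(annotation)) annotation$arm <- band_arm(annotation$cytoband)
  ia <- match(network$gene_a, annotation$gene_id)
  ib <- match(network$gene_b, annotation$gene_id)
  same_chr <- annotation$chrom[ia] == annotation$chrom[ib]
  same_arm <- ifelse(same_chr,
                     annotation$arm[ia] == annotation$arm[ib], NA)
  same_band <- ifelse(same_chr,
                      annotation$arm[ia] == annotation$arm[ib] &
                        annotation$cytoband[ia] == annotation$cytoband[ib],
                      NA)
  dist <- ifelse(same_chr,
                 abs(annotation$start[ia] - annotation$start[ib]), NA)
  category <- ifelse(!same_chr, "trans",
                     ifelse(!same_arm, "cis-inter-arm",
                            ifelse(!same_band, "cis-intra-arm-inter-band",
                                   "cis-intra-band")))
  out <- data.frame(network[, c("gene_a", "gene_b", "mi", "rank")],
                    chrom_a = annotation$chrom[ia],
                    chrom_b = annotation$chrom[ib],
                    same_chromosome = same_chr,
                    same_arm = same_arm,
                    same_cytoband = same_band,
                    distance_bp = dist,
                    category = factor(category, levels = EDGE_CATEGORIES),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cis fraction and per-chromosome breakdown
#'
#' @param table edge-class table from [classify_edges()].
#' @return list of class `cistrans_summary`: `n_edges`, `totals` (named
#'   counts over the four categories), `cis_fraction`, and
#'   `per_chromosome` (data.frame chrom, cis_edges, total_edges_touching,
#'   cis_fraction — cis edges keyed by their chromosome; the denominator is
#'   all edges with at least one gene on that chromosome).
#' @export
cis_fraction <- function(table) {
  if (nrow(table) == 0L) stopf("empty edge-class table")
  totals <- table(table$category)
  cis <- table$same_chromosome
  chroms <- sort(unique(c(table$chrom_a, table$chrom_b)))
  per <- do.call(rbind, lapply(chroms, function(ch) {
    touch <- table$chrom_a == ch | table$chrom_b == ch
    data.frame(chrom = ch,
               cis_edges = sum(cis & table$chrom_a == ch),
               total_edges_touching = sum(touch),
               cis_fraction = sum(cis & table$chrom_a == ch) / sum(touch),
               stringsAsFactors = FALSE)
  }))
  structure(list(n_edges = nrow(table),
                 totals = stats::setNames(as.integer(totals), names(totals)),
                 cis_fraction = sum(cis) / nrow(table),
                 per_chromosome = per),
            class = "cistrans_summary")
}

#' Cis fraction across top-k cutoffs
#'
#' Classifies the full MI stream once, sorts by descending MI (ties broken
#' lexicographically) and reads the cis fraction of each top-k prefix, so
#' the edge set at a smaller k is always nested in that of a larger k.
#'
#' @param mi_stream data.frame from [pairwise_mi()].
#' @param annotation gene annotation.
#' @param k_values integer vector of cutoffs (default
#'   `c(1000, 2000, 5000, 10000, 20000, 50000, 100000)`).
#' @return data.frame with columns `k` and `cis_fraction`; cutoffs beyond
#'   the number of pairs are truncated with a warning.
#' @export
cutoff_sweep <- function(mi_stream, annotation,
                         k_values = c(1000L, 2000L, 5000L, 10000L,
                                      20000L, 50000L, 100000L)) {
  npairs <- nrow(mi_stream)
  if (any(k_values > npairs)) {
    warnf("cutoff(s) beyond %d pairs truncated", npairs)
    k_values <- unique(pmin(k_values, npairs))
  }
  net <- coexpression_network(mi_stream$gene_a, mi_stream$gene_b,
                              mi_stream$mi)
  cls <- classify_edges(net, annotation)
  cum_cis <- cumsum(cls$same_chromosome[order(cls$rank)])
  data.frame(k = as.integer(k_values),
             cis_fraction = cum_cis[k_values] / k_values)
}

#' Compare cis/trans composition between two networks
#'
#' Two complementary tests: a pooled Fisher exact test on the 2x2 table of
#' (cis, trans) counts by network, and a two-sided Wilcoxon signed-rank test
#' on paired per-chromosome cis fractions. The signed-rank test needs at
#' least 6 chromosomes; with fewer, only the Fisher test is reported and the
#' report carries a note.
#'
#' @param summaryA,summaryB `cistrans_summary` objects over the same
#'   chromosome naming.
#' @return list with `fisher_p`, `fisher_odds_ratio`, `wilcoxon_p` (NA when
#'   unavailable) and `note`.
#' @export
compare_cis_trans <- function(summaryA, summaryB) {
  cisA <- round(summaryA$cis_fraction * summaryA$n_edges)
  cisB <- round(summaryB$cis_fraction * summaryB$n_edges)
  tab <- matrix(c(cisA, summaryA$n_edges - cisA,
                  cisB, summaryB$n_edges - cisB), 2L, byrow = TRUE,
                dimnames = list(c("A", "B"), c("cis", "trans")))
  ft <- stats::fisher.test(tab)
  chroms <- intersect(summaryA$per_chromosome$chrom,
                      summaryB$per_chromosome$chrom)
  # mitochondrial and scaffold entries stay in the pooled totals but are
  # excluded from the per-chromosome paired test
  chroms <- chroms[!chroms %in% c("MT", "chrM", "chrMT") &
                     !grepl("_", chroms, fixed = TRUE)]
  note <- ""
  wp <- NA_real_
  if (length(chroms) < 6L) {
    note <- "fewer than 6 shared chromosomes: Wilcoxon signed-rank omitted"
  } else {
    fa <- summaryA$per_chromosome$cis_fraction[
      match(chroms, summaryA$per_chromosome$chrom)]
    fb <- summaryB$per_chromosome$cis_fraction[
      match(chroms, summaryB$per_chromosome$chrom)]
    d <- fa - fb
    if (all(d == 0)) {
      wp <- 1
    } else {
      wp <- suppressWarnings(
        stats::wilcox.test(fa, fb, paired = TRUE, exact = FALSE)$p.value)
    }
  }
  list(fisher_p = ft$p.value,
       fisher_odds_ratio = unname(ft$estimate),
       wilcoxon_p = wp,
       contingency = tab,
       note = note)
}

#' Cytoband proximity permutation test
#'
#' Tests whether cis edges concentrate within cytobands beyond what the
#' chromosome-level edge placement implies. The null preserves each
#' chromosome's cis edge count and degree sequence: each chromosome's cis
#' subgraph is rewired degree-preservingly `n_rewire` times, and the
#' intra-cytoband edge count is recounted. Empirical p-value
#' `(1 + #{null >= observed}) / (1 + n_rewire)`.
#'
#' @param network a `coexpression_network` with at least one cis edge.
#' @param annotation gene annotation.
#' @param n_rewire number of rewired null networks (>= 99).
#' @param seed integer seed.
#' @return list with `p_value`, `enrichment` (observed / mean null),
#'   `observed` and `null` counts.
#' @export
cytoband_proximity_test <- function(network, annotation, n_rewire = 999L,
                                    seed = 1L) {
  if (n_rewire < 99L) stopf("n_rewire must be >= 99 for usable resolution")
  cls <- classify_edges(network, annotation)
  cis <- cls[cls$same_chromosome, , drop = FALSE]
  if (nrow(cis) == 0L) stopf("network has no cis edge")
  observed <- sum(cis$same_cytoband)
  band_of <- stats::setNames(paste(annotation$chrom, annotation$cytoband),
                             annotation$gene_id)
  set.seed(seed)
  chroms <- unique(cis$chrom_a)
  subgraphs <- lapply(chroms, function(ch) {
    e <- cis[cis$chrom_a == ch, c("gene_a", "gene_b")]
    igraph::graph_from_data_frame(e, directed = FALSE)
  })
  null <- vapply(seq_len(n_rewire), function(r) {
    tot <- 0L
    for (g in subgraphs) {
      ne <- igraph::ecount(g)
      if (ne < 2L) {
        el <- igraph::as_edgelist(g, names = TRUE)
      } else {
        gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10L * ne))
        el <- igraph::as_edgelist(gr, names = TRUE)
      }
      tot <- tot + sum(band_of[el[, 1L]] == band_of[el[, 2L]])
    }
    tot
  }, integer(1))
  list(p_value = (1 + sum(null >= observed)) / (1 + n_rewire),
       enrichment = observed / mean(null),
       observed = observed, null = null)
}

#' Write a cis/trans summary as long-format TSV
#' @param summary a `cistrans_summary`.
#' @param path output path.
#' @param network_name label written in the first column.
#' @export
write_cistrans_summary <- function(summary, path, network_name = "network") {
  tot <- data.frame(network = network_name, category = names(summary$totals),
                    chrom = "all", count = unname(summary$totals),
                    fraction = unname(summary$totals) / summary$n_edges,
                    stringsAsFactors = FALSE)
  per <- data.frame(network = network_name, category = "cis",
                    chrom = summary$per_chromosome$chrom,
                    count = summary$per_chromosome$cis_edges,
                    fraction = summary$per_chromosome$cis_fraction,
                    stringsAsFactors = FALSE)
  utils::write.table(rbind(tot, per), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
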