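# Network intersection, connected components, and subsampling robustness.

#' Intersect two co-expression networks
#'
#' Edge identity is the unordered gene pair; MI weights are ignored. Shared
#' percentages are computed against each network's own edge count (they
#' coincide under the fixed top-k design).
#'
#' @param A,B `coexpression_network` objects.
#' @return list of class `comparison_report`: `shared_genes`,
#'   `shared_edges`, `pct_shared_edges_A`, `pct_shared_edges_B`,
#'   `pct_shared_edges` (the common value when |A| = |B|, else the mean),
#'   plus per-network `components`.
#' @export
intersect_networks <- function(A, B) {
  keyA <- canonical_pairs(A$gene_a, A$gene_b)$key
  keyB <- canonical_pairs(B$gene_a, B$gene_b)$key
  genesA <- unique(c(A$gene_a, A$gene_b))
  genesB <- unique(c(B$gene_a, B$gene_b))
  shared_edges <- length(intersect(keyA, keyB))
  pctA <- if (nrow(A)) 100 * shared_edges / nrow(A) else 0
  pctB <- if (nrow(B)) 100 * shared_edges / nrow(B) else 0
  structure(list(shared_genes = length(intersect(genesA, genesB)),
                 shared_edges = shared_edges,
                 pct_shared_edges_A = pctA,
                 pct_shared_edges_B = pctB,
                 pct_shared_edges = mean(c(pctA, pctB)),
                 components = list(A = connected_components(A),
                                   B = connected_components(B))),
            class = "comparison_report")
}

#' Fold ratio of two shared-edge percentages
#'
#' @param pct_1,pct_2 percentages; `pct_2` must be positive.
#' @return `pct_1 / pct_2` (unrounded; rounding to the nearest integer is a
#'   presentation choice). `pct_2 = 0` yields NA with a warning.
#' @export
fold_ratio <- function(pct_1, pct_2) {
  if (pct_2 == 0) {
    warnf("fold ratio undefined: second percentage is 0")
    return(NA_real_)
  }
  pct_1 / pct_2
}

#' Connected components of a network
#'
#' Components are sorted by gene count descending, ties broken by edge count
#' descending then by lexicographically smallest member.
#'
#' @param network a `coexpression_network`.
#' @return list with `components` (list of lists: `size_genes`,
#'   `size_edges`, `members` sorted) and `giant_fraction` (largest component
#'   gene count over total gene count; 0 for an empty network).
#' @export
connected_components <- function(network) {
  if (nrow(network) == 0L)
    return(list(components = list(), giant_fraction = 0))
  g <- network_to_igraph(network)
  memb <- igraph::components(g)$membership
  comp_ids <- unique(memb)
  comps <- lapply(comp_ids, function(ci) {
    members <- sort(names(memb)[memb == ci])
    in_comp <- network$gene_a %in% members
    list(size_genes = length(members),
         size_edges = sum(in_comp),
         members = members)
  })
  ord <- order(-vapply(comps, `[[`, integer(1), "size_genes"),
               -vapply(comps, `[[`, integer(1), "size_edges"),
               vapply(comps, function(c) c$members[1L], character(1)))
  comps <- comps[ord]
  list(components = comps,
       giant_fraction = comps[[1L]]$size_genes / length(memb))
}

#' Filter components by size
#'
#' Keeps components with strictly more than `min_genes` genes.
#' @param components result of [connected_components()] or its `components`
#'   element.
#' @param min_genes strict lower bound on gene count (default 10).
#' @return filtered component list.
#' @export
component_filter <- function(components, min_genes = 10) {
  if (is.list(components) && !is.null(components$components))
    components <- components$components
  Filter(function(c) c$size_genes > min_genes, components)
}

#' Subsampling robustness of the cis fraction
#'
#' Repeats the whole inference on random sample subsets: each replicate
#' draws `n_samples` columns without replacement (fresh draw per replicate,
#' child seeds derived from the master seed), runs preprocessing, all-pairs
#' MI, top-k pruning and cis-fraction computation.
#'
#' @param counts raw count matrix with at least `n_samples` columns.
#' @param annotation gene annotation.
#' @param n_samples columns per replicate (default 100).
#' @param n_reps replicates (default 10).
#' @param k edges kept per replicate network (default 10000).
#' @param seed master seed.
#' @param cpm_threshold,gc_bins,bins passed through to the pipeline stages.
#' @return list with `fractions` (length `n_reps`), `mean`, `min`, `max`.
#' @export
subsample_robustness <- function(counts, annotation, n_samples = 100L,
                                 n_reps = 10L, k = 10000L, seed = 1L,
                                 cpm_threshold = 10, gc_bins = 10,
                                 bins = NULL) {
  if (n_samples > ncol(counts))
    stopf("n_samples (%d) exceeds available columns (%d)",
          n_samples, ncol(counts))
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_reps)
  fractions <- vapply(seq_len(n_reps), function(r) {
    set.seed(child_seeds[r])
    cols <- sample.int(ncol(counts), n_samples)
    sub <- counts[, cols, drop = FALSE]
    pp <- preprocess_counts(sub, annotation, cpm_threshold, gc_bins)
    mi <- pairwise_mi(pp$matrix, bins = bins)
    net <- suppressWarnings(top_k_edges(mi, k))
    cis_fraction(classify_edges(net, annotation))$cis_fraction
  }, numeric(1))
  list(fractions = fractions, mean = mean(fractions),
       min = min(fractions), max = max(fractions))
}

#' Write a comparison report and component gene lists
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if absent); writes `comparison.tsv`
#'   and one `component_<net>_<i>.txt` gene list per retained component.
#' @param min_genes component size filter for the exported lists.
#' @export
write_comparison_report <- function(report, dir, min_genes = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(metric = c("shared_genes", "shared_edges",
                              "pct_shared_edges_A", "pct_shared_edges_B"),
                   value = c(report$shared_genes, report$shared_edges,
                             report$pct_shared_edges_A,
                             report$pct_shared_edges_B))
  utils::write.table(df, file.path(dir, "comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(report$components)) {
    comps <- component_filter(report$components[[nm]], min_genes)
    for (i in seq_along(comps))
      writeLines(comps[[i]]$members,
                 file.path(dir, sprintf("component_%s_%d.txt", nm, i)))
  }
  invisible(dir)
}
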