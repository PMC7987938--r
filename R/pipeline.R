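# End-to-end orchestration: simulate (optional) -> preprocess -> network ->
# classify -> compare -> differential expression -> trend classification,
# with every artifact written to an output directory and a single summary
# holding the headline statistics.

#' Pipeline configuration
#'
#' Defaults mirror the analysis design: top-10,000-edge networks, cutoff
#' sweep from 1,000 to 100,000 edges, mean-CPM filter at 10, DEG thresholds
#' |log2FC| >= 1.5 and BH-adjusted p < 0.01, and 10 subsamples of 100
#' columns for the robustness check.
#'
#' @param counts named list of count-matrix paths (one per cohort), or NULL
#'   to simulate.
#' @param annotation path to the annotation table, or NULL to simulate.
#' @param out_dir output directory.
#' @param simulate list passed to [synthetic_config()] when simulating.
#' @param cpm_threshold,gc_bins preprocessing options.
#' @param mi_bins,k,dpi,dpi_tolerance MI and pruning options.
#' @param k_sweep cutoff sweep values.
#' @param n_rewire cytoband proximity permutations.
#' @param subsample_n,subsample_reps robustness options (NULL disables).
#' @param lfc_threshold,p_threshold DEG thresholds.
#' @param seed master seed, recorded in every output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, annotation = NULL,
                            out_dir = "cistransnet_out",
                            simulate = list(),
                            cpm_threshold = 10, gc_bins = 10,
                            mi_bins = NULL, k = 10000L,
                            dpi = FALSE, dpi_tolerance = 0,
                            k_sweep = c(1000L, 2000L, 5000L, 10000L,
                                        20000L, 50000L, 100000L),
                            n_rewire = 999L,
                            subsample_n = NULL, subsample_reps = 10L,
                            lfc_threshold = 1.5, p_threshold = 0.01,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' With `counts = NULL` the pipeline simulates two cohorts from one genome
#' layout: a trans-dominant baseline cohort and a cis-dominant altered
#' cohort (the normal-like and tumor-like regimes). With paths supplied, the
#' named count matrices are read against the annotation. Each cohort is
#' preprocessed and a top-k MI network inferred and classified; the first
#' two cohorts are intersected and compared, and differential expression
#' plus trend classification is run across the two conditions.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with per-cohort networks, summaries, the
#'   comparison report, DE results and the summary table; artifacts are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(cfg$counts)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    scfg <- do.call(synthetic_config, sim_args)
    layout <- build_genome(scfg)
    annotation <- layout$genes
    counts <- list(
      baseline = simulate_counts(layout, scfg, "baseline", "trans_dominant"),
      altered = simulate_counts(layout, scfg, "altered", "cis_dominant"))
    write_annotation(annotation, file.path(cfg$out_dir, "annotation.tsv"))
    for (nm in names(counts))
      write_expression(counts[[nm]],
                       file.path(cfg$out_dir, paste0("counts_", nm, ".tsv")))
  } else {
    if (is.null(cfg$annotation)) stopf("annotation path is required")
    if (!file.exists(cfg$annotation))
      stopf("annotation path '%s' not found", cfg$annotation)
    missing <- Filter(function(p) !file.exists(p), unlist(cfg$counts))
    if (length(missing))
      stopf("count path(s) not found: %s", paste(missing, collapse = ", "))
    annotation <- read_annotation(cfg$annotation)
    counts <- lapply(cfg$counts, read_expression, annotation = annotation)
  }

  cohorts <- names(counts)
  nets <- list(); summaries <- list(); logs <- list(); norm <- list()
  for (nm in cohorts) {
    pp <- preprocess_counts(counts[[nm]], annotation,
                            cpm_threshold = cfg$cpm_threshold,
                            gc_bins = cfg$gc_bins)
    norm[[nm]] <- pp
    mi <- pairwise_mi(pp$matrix, bins = cfg$mi_bins)
    net <- suppressWarnings(top_k_edges(mi, cfg$k))
    if (isTRUE(cfg$dpi)) net <- dpi_prune(net, cfg$dpi_tolerance)
    nets[[nm]] <- net
    cls <- classify_edges(net, annotation)
    summaries[[nm]] <- cis_fraction(cls)
    sweep_tab <- suppressWarnings(
      cutoff_sweep(mi, annotation, cfg$k_sweep))
    write_network(net, file.path(cfg$out_dir,
                                 paste0("network_", nm, ".tsv")), "edge-tsv")
    write_cistrans_summary(summaries[[nm]],
                           file.path(cfg$out_dir,
                                     paste0("cistrans_", nm, ".tsv")), nm)
    utils::write.table(sweep_tab,
                       file.path(cfg$out_dir, paste0("sweep_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_normalization_report(pp$report,
                               file.path(cfg$out_dir,
                                         paste0("normalization_", nm, ".tsv")))
    logs[[nm]] <- sweep_tab
  }

  result <- list(networks = nets, summaries = summaries, sweeps = logs,
                 seed = cfg$seed)

  result$proximity <- lapply(cohorts, function(nm) {
    if (sum(summaries[[nm]]$totals[-1L]) == 0L) return(NULL)
    cytoband_proximity_test(nets[[nm]], annotation,
                            n_rewire = cfg$n_rewire, seed = cfg$seed)
  })
  names(result$proximity) <- cohorts

  if (length(cohorts) >= 2L) {
    a <- cohorts[1L]; b <- cohorts[2L]
    cmp <- intersect_networks(nets[[a]], nets[[b]])
    tests <- compare_cis_trans(summaries[[a]], summaries[[b]])
    write_comparison_report(cmp, file.path(cfg$out_dir, "comparison"))
    result$comparison <- cmp
    result$tests <- tests

    expr_all <- cbind(norm[[a]]$matrix[
      intersect(rownames(norm[[a]]$matrix), rownames(norm[[b]]$matrix)), ,
      drop = FALSE],
      norm[[b]]$matrix[
        intersect(rownames(norm[[a]]$matrix), rownames(norm[[b]]$matrix)), ,
        drop = FALSE])
    cond <- factor(rep(c(a, b), c(ncol(norm[[a]]$matrix),
                                  ncol(norm[[b]]$matrix))),
                   levels = c(a, b))  # fold change is cohort2 - cohort1
    de <- call_degs(moderated_t(expr_all, cond),
                    cfg$lfc_threshold, cfg$p_threshold)
    write_de_table(de, file.path(cfg$out_dir, "de_table.tsv"))
    shared_net <- nets[[b]]
    shared_net <- shared_net[shared_net$gene_a %in% de$gene_id &
                               shared_net$gene_b %in% de$gene_id, ,
                             drop = FALSE]
    trend <- trend_classify_edges(shared_net, de, "sign", annotation)
    result$de <- de
    result$trend_summary <- attr(trend, "summary")
  }

  # with four cohorts (two phenotype pairs, the tumor/normal design) the
  # two intersections are compared by their fold ratio
  if (length(cohorts) >= 4L) {
    cmp2 <- intersect_networks(nets[[cohorts[3L]]], nets[[cohorts[4L]]])
    result$comparison2 <- cmp2
    result$fold_ratio <- fold_ratio(cmp2$pct_shared_edges,
                                    result$comparison$pct_shared_edges)
  }

  if (!is.null(cfg$subsample_n)) {
    nm <- cohorts[min(2L, length(cohorts))]
    result$subsample <- subsample_robustness(
      counts[[nm]], annotation, n_samples = cfg$subsample_n,
      n_reps = cfg$subsample_reps, k = cfg$k, seed = cfg$seed,
      cpm_threshold = cfg$cpm_threshold, gc_bins = cfg$gc_bins,
      bins = cfg$mi_bins)
  }

  result$summary_table <- pipeline_summary_table(result, cohorts)
  utils::write.table(result$summary_table,
                     file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(result$summary_table$metric,
                   result$summary_table$value, sep = ": "),
             file.path(cfg$out_dir, "summary.txt"))
  invisible(result)
}

# headline statistics as a two-column table
pipeline_summary_table <- function(result, cohorts) {
  rows <- list(data.frame(metric = "seed", value = result$seed))
  for (nm in cohorts) {
    s <- result$summaries[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c(paste0("cis_fraction_", nm),
                 paste0("n_edges_", nm),
                 paste0("giant_fraction_", nm)),
      value = c(round(s$cis_fraction, 6), s$n_edges,
                round(connected_components(result$networks[[nm]])$giant_fraction, 6)))
  }
  if (!is.null(result$comparison)) {
    cmp <- result$comparison
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("shared_genes", "shared_edges", "pct_shared_edges"),
      value = c(cmp$shared_genes, cmp$shared_edges,
                round(cmp$pct_shared_edges, 4)))
  }
  for (nm in names(result$proximity)) {
    pr <- result$proximity[[nm]]
    if (is.null(pr)) next
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c(paste0("cytoband_proximity_p_", nm),
                 paste0("cytoband_enrichment_", nm)),
      value = round(c(pr$p_value, pr$enrichment), 6))
  }
  if (!is.null(result$fold_ratio)) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "fold_ratio", value = round(result$fold_ratio, 4))
  }
  if (!is.null(result$de)) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("degs_up", "degs_down"),
      value = c(sum(result$de$call == "up"), sum(result$de$call == "down")))
  }
  if (!is.null(result$trend_summary)) {
    tt <- result$trend_summary$all
    rows[[length(rows) + 1L]] <- data.frame(
      metric = paste0("trend_", gsub("-", "_", names(tt))),
      value = as.integer(tt))
  }
  if (!is.null(result$subsample)) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("subsample_cis_min", "subsample_cis_mean",
                 "subsample_cis_max"),
      value = round(c(result$subsample$min, result$subsample$mean,
                      result$subsample$max), 6))
  }
  do.call(rbind, rows)
}
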