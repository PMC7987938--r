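# Readers and writers for expression matrices, gene annotation and networks.
#
# Conventions: genomic coordinates are 1-based closed intervals (BioMart
# style); a gene belongs to the cytoband containing its START position; MI
# weights are serialized with 6 significant digits and edge ranks are always
# recomputed on read (descending MI, ties broken lexicographically by
# gene pair).

#' Construct a co-expression network from an edge table
#'
#' Canonicalizes pair order (gene_a < gene_b lexicographically), rejects
#' self-edges, deduplicates symmetric duplicates, and assigns 1-based ranks
#' by descending MI with lexicographic tie-breaking.
#'
#' @param gene_a,gene_b character vectors of gene IDs.
#' @param mi numeric MI weights (nats).
#' @return data.frame of class `coexpression_network` with columns
#'   `gene_a`, `gene_b`, `mi`, `rank`, sorted by rank.
#' @export
coexpression_network <- function(gene_a, gene_b, mi) {
  if (length(gene_a) == 0L) {
    net <- data.frame(gene_a = character(0), gene_b = character(0),
                      mi = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
    class(net) <- c("coexpression_network", "data.frame")
    return(net)
  }
  cp <- canonical_pairs(gene_a, gene_b)
  if (any(cp$gene_a == cp$gene_b))
    stopf("self-edge(s) not allowed: %s",
          paste(unique(cp$gene_a[cp$gene_a == cp$gene_b]), collapse = ", "))
  keep <- !duplicated(cp$key)
  net <- data.frame(gene_a = cp$gene_a[keep], gene_b = cp$gene_b[keep],
                    mi = as.numeric(mi)[keep], stringsAsFactors = FALSE)
  ord <- order(-net$mi, net$gene_a, net$gene_b)
  net <- net[ord, ]
  net$rank <- seq_len(nrow(net))
  rownames(net) <- NULL
  class(net) <- c("coexpression_network", "data.frame")
  net
}

#' Read an expression matrix
#'
#' Expects a tab-separated file whose first column holds gene IDs and whose
#' header row holds sample IDs. Genes absent from `annotation` are dropped
#' (a message reports how many); gene order is otherwise preserved.
#'
#' @param path file path.
#' @param annotation gene annotation data.frame (see [build_genome()]
#'   `$genes` for the expected columns).
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, annotation) {
  check_annotation(annotation)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("expression file '%s' has no sample columns", path)
  ids <- as.character(tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicated gene ID(s) in '%s': %s", path,
          paste(dup, collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad))
      stopf("non-numeric value in '%s' at line %d, column '%s'",
            path, bad[1L] + 1L, names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  keep <- ids %in% annotation$gene_id
  if (any(!keep))
    message(sum(!keep), " gene(s) absent from annotation dropped")
  m[keep, , drop = FALSE]
}

#' Write an expression matrix
#'
#' Tab-separated, gene IDs in a first column named `gene_id`, sample IDs as
#' the header row.
#' @param matrix numeric matrix, genes x samples.
#' @param path output path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene annotation table
#' @param annotation annotation data.frame.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  check_annotation(annotation)
  cols <- c("gene_id", "chrom", "start", "end", "gc", "biotype", "cytoband")
  utils::write.table(annotation[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#' @param path tab-separated file with columns gene_id, chrom, start, end,
#'   gc, biotype, cytoband.
#' @return annotation data.frame with a derived `arm` column.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ann$arm <- band_arm(ann$cytoband)
  check_annotation(ann)
  ann
}

#' Write a co-expression network
#'
#' Supported formats: `edge-tsv` (columns gene_a, gene_b, mi, rank; MI with
#' 6 significant digits), `SIF` (Cytoscape simple interaction format, lines
#' `gene_a coexp gene_b`, weights dropped) and `GraphML` (via igraph, MI as
#' edge attribute `mi`). edge-tsv and GraphML round-trip through
#' [read_network()].
#'
#' @param network a `coexpression_network`.
#' @param path output path.
#' @param format one of `"edge-tsv"`, `"SIF"`, `"GraphML"`.
#' @export
write_network <- function(network, path, format = c("edge-tsv", "SIF",
                                                    "GraphML")) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    df <- data.frame(gene_a = network$gene_a, gene_b = network$gene_b,
                     mi = signif(network$mi, 6), rank = network$rank)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "SIF") {
    lines <- paste(network$gene_a, "coexp", network$gene_b, sep = "\t")
    writeLines(lines, path)
  } else {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a co-expression network
#'
#' Canonicalizes pair order, deduplicates, and re-derives ranks (see
#' [coexpression_network()]). SIF is write-only: it carries no MI weight, so
#' a read could not satisfy the rank/weight consistency invariant.
#'
#' @param path input path.
#' @param format `"edge-tsv"` or `"GraphML"`.
#' @return a `coexpression_network`.
#' @export
read_network <- function(path, format = c("edge-tsv", "GraphML", "SIF")) {
  format <- match.arg(format)
  if (format == "SIF")
    stopf("SIF is write-only: it carries no MI weights")
  if (format == "edge-tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L)
      return(coexpression_network(character(0), character(0), numeric(0)))
    return(coexpression_network(tab$gene_a, tab$gene_b, tab$mi))
  }
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L)
    return(coexpression_network(character(0), character(0), numeric(0)))
  coexpression_network(el[, 1L], el[, 2L], igraph::edge_attr(g, "mi"))
}

# network -> igraph with MI edge attribute (keeps isolated-node-free graph)
network_to_igraph <- function(network) {
  nodes <- sort(unique(c(network$gene_a, network$gene_b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$gene_a, to = network$gene_b,
               mi = signif(network$mi, 6)),
    directed = FALSE, vertices = nodes)
  g
}
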