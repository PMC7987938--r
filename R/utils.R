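#' @keywords internal
"_PACKAGE"

# shared validation helpers

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Canonical key for an unordered gene pair
#'
#' Orders each pair lexicographically (gene_a < gene_b) and pastes with a
#' separator, giving a stable identity for edge-set operations.
#' @param a,b character vectors of gene IDs.
#' @return list with components `gene_a`, `gene_b` (reordered) and `key`.
#' @keywords internal
canonical_pairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  list(gene_a = ga, gene_b = gb, key = paste(ga, gb, sep = "\r"))
}

# validate an annotation data.frame (one row per gene)
check_annotation <- function(annotation) {
  need <- c("gene_id", "chrom", "start", "end", "gc", "biotype", "cytoband")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stopf("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stopf("annotation has duplicated gene IDs")
  if (any(annotation$start > annotation$end))
    stopf("annotation has start > end")
  invisible(annotation)
}

# chromosome arm read from the cytoband name prefix
band_arm <- function(cytoband) substr(as.character(cytoband), 1L, 1L)
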