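# Synthetic genomes and count matrices with planted cis/trans covariance.
#
# The generator emulates two co-expression regimes seen in tumor vs normal
# lung transcriptomes: a "cis_dominant" regime in which correlation is
# concentrated within cytobands and decays with genomic distance along each
# chromosome, and a "trans_dominant" regime in which correlation lives in
# gene modules that span chromosomes. Latent multivariate-Gaussian values are
# mapped through a Gaussian copula to negative-binomial counts with variable
# library sizes, so every downstream step (CPM filtering, TMM, MI inference)
# sees realistic count data whose ground truth is known.

#' Synthetic-cohort configuration
#'
#' Collects every tunable of the synthetic generator. Defaults describe a
#' small desk-scale cohort: 200 genes on 5 chromosomes, 100 samples per
#' condition, strong within-cytoband correlation (`rho_band = 0.9`) for the
#' cis-dominant regime and four cross-chromosome modules at `rho_trans = 0.7`
#' for the trans-dominant regime, 10% of genes differentially expressed with
#' log2 fold changes of SD 2, negative-binomial dispersion 0.15 and library
#' sizes between 5 and 20 million reads.
#'
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes; must not exceed `n_genes`.
#' @param bands_per_arm cytobands on each of the p and q arms.
#' @param n_samples samples per condition.
#' @param rho_band latent correlation between genes sharing a cytoband
#'   (cis-dominant regime), in `[0, 1)`.
#' @param decay_length bp scale of the within-chromosome correlation decay:
#'   two genes on one chromosome at start-distance `d` get latent correlation
#'   `rho_band * exp(-d / decay_length)`.
#' @param rho_trans latent correlation within a cross-chromosome module
#'   (trans-dominant regime), in `[0, 1)`.
#' @param trans_modules integer vector of module sizes; genes are dealt into
#'   modules round-robin across chromosomes so every module spans several.
#' @param lfc_sd standard deviation of planted log2 fold changes.
#' @param frac_de fraction of genes given a nonzero planted fold change.
#' @param nb_dispersion negative-binomial dispersion (1/size); must be > 0.
#' @param libsize_range length-2 numeric, min and max sample library size.
#' @param seed integer seed; every generator output is deterministic in it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200L, n_chromosomes = 5L,
                             bands_per_arm = 2L, n_samples = 100L,
                             rho_band = 0.9, decay_length = 1e7,
                             rho_trans = 0.7,
                             trans_modules = c(30L, 30L, 20L, 20L),
                             lfc_sd = 2, frac_de = 0.1,
                             nb_dispersion = 0.15,
                             libsize_range = c(5e6, 2e7), seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              bands_per_arm = as.integer(bands_per_arm),
              n_samples = as.integer(n_samples),
              rho_band = rho_band, decay_length = decay_length,
              rho_trans = rho_trans,
              trans_modules = as.integer(trans_modules),
              lfc_sd = lfc_sd, frac_de = frac_de,
              nb_dispersion = nb_dispersion,
              libsize_range = as.numeric(libsize_range),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_genes < cfg$n_chromosomes)
    stopf("invalid config: n_genes (%d) < n_chromosomes (%d)",
          cfg$n_genes, cfg$n_chromosomes)
  if (cfg$rho_band < 0 || cfg$rho_band >= 1)
    stopf("invalid config: rho_band must be in [0, 1)")
  if (cfg$rho_trans < 0 || cfg$rho_trans >= 1)
    stopf("invalid config: rho_trans must be in [0, 1)")
  if (cfg$n_samples < 2L)
    stopf("invalid config: n_samples must be >= 2")
  if (cfg$nb_dispersion <= 0)
    stopf("invalid config: nb_dispersion must be > 0")
  if (cfg$frac_de < 0 || cfg$frac_de > 1)
    stopf("invalid config: frac_de must be in [0, 1]")
  if (length(cfg$libsize_range) != 2L ||
      cfg$libsize_range[1] > cfg$libsize_range[2])
    stopf("invalid config: libsize_range must be (min, max)")
  invisible(cfg)
}

CHROM_LENGTH_BP <- 1e8  # all synthetic chromosomes share this length

#' Build a synthetic genome layout
#'
#' Lays out `n_chromosomes` chromosomes of 100 Mb, each split into a p and a
#' q arm of `bands_per_arm` equal-width cytobands (named `p<k>`/`q<k>`, p
#' bands preceding q bands by coordinate, numbered outward from the
#' centromere as in cytogenetic convention). Genes are dealt round-robin
#' across chromosomes, placed uniformly, given lengths of 1-100 kb, GC
#' fractions uniform in `[0.35, 0.65]`, and mostly protein-coding biotypes.
#' Each gene belongs to the cytoband containing its start position.
#'
#' @param config a [synthetic_config()].
#' @return list of class `genome_layout` with `chromosomes` (data.frame:
#'   name, length_bp), `cytobands` (data.frame: chrom, band, start, end) and
#'   `genes` — an annotation data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `gc`, `biotype`, `cytoband`, `arm` (1-based closed
#'   intervals).
#' @export
build_genome <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  nc <- config$n_chromosomes
  B <- config$bands_per_arm
  chroms <- data.frame(name = paste0("chr", seq_len(nc)),
                       length_bp = rep(CHROM_LENGTH_BP, nc),
                       stringsAsFactors = FALSE)

  # band order along the chromosome: pB ... p1 | q1 ... qB
  band_names <- c(paste0("p", rev(seq_len(B))), paste0("q", seq_len(B)))
  width <- CHROM_LENGTH_BP / (2L * B)
  bands <- do.call(rbind, lapply(chroms$name, function(ch) {
    data.frame(chrom = ch, band = band_names,
               start = round(width * (seq_len(2L * B) - 1L)) + 1,
               end = round(width * seq_len(2L * B)),
               stringsAsFactors = FALSE)
  }))

  G <- config$n_genes
  chrom_of <- chroms$name[((seq_len(G) - 1L) %% nc) + 1L]
  start <- integer(G)
  for (ch in chroms$name) {
    idx <- which(chrom_of == ch)
    start[idx] <- sort(sample.int(CHROM_LENGTH_BP - 100001L, length(idx)))
  }
  len <- sample(1000:100000, G, replace = TRUE)
  gend <- pmin(start + len - 1L, CHROM_LENGTH_BP)
  gc <- round(runif(G, 0.35, 0.65), 4)
  biotype <- sample(c("protein_coding", "lincRNA", "pseudogene"), G,
                    replace = TRUE, prob = c(0.8, 0.1, 0.1))
  gene_id <- sprintf("g%04d", seq_len(G))

  band_idx <- pmin(floor((start - 1) / width) + 1L, 2L * B)
  cytoband <- band_names[band_idx]

  genes <- data.frame(gene_id = gene_id, chrom = chrom_of, start = start,
                      end = gend, gc = gc, biotype = biotype,
                      cytoband = cytoband, arm = band_arm(cytoband),
                      stringsAsFactors = FALSE)
  # keep a genomic sort so cis blocks are contiguous in the matrix
  genes <- genes[order(match(genes$chrom, chroms$name), genes$start), ]
  rownames(genes) <- NULL

  structure(list(chromosomes = chroms, cytobands = bands, genes = genes),
            class = "genome_layout")
}

# latent correlation matrix for one regime; symmetric with unit diagonal
latent_correlation <- function(layout, config, structure) {
  genes <- layout$genes
  G <- nrow(genes)
  S <- diag(1, G)
  if (structure == "cis_dominant") {
    for (ch in unique(genes$chrom)) {
      idx <- which(genes$chrom == ch)
      if (length(idx) < 2L) next
      d <- abs(outer(genes$start[idx], genes$start[idx], "-"))
      blk <- config$rho_band * exp(-d / config$decay_length)
      same_band <- outer(genes$cytoband[idx], genes$cytoband[idx], "==")
      blk[same_band] <- config$rho_band
      diag(blk) <- 1
      S[idx, idx] <- blk
    }
  } else if (structure == "trans_dominant") {
    mods <- trans_module_membership(layout, config)
    eps <- 0.02 * (config$rho_trans > 0)  # weak global factor
    S[] <- eps
    for (m in unique(mods[!is.na(mods)])) {
      idx <- which(!is.na(mods) & mods == m)
      S[idx, idx] <- config$rho_trans
    }
    diag(S) <- 1
  } else {
    stopf("unknown structure label '%s'", structure)
  }
  psd_repair(S)
}

# module membership for the trans regime: genes are dealt in
# chromosome-interleaved order (first gene of each chromosome, then second,
# ...) so every module spans several chromosomes
trans_module_membership <- function(layout, config) {
  genes <- layout$genes
  G <- nrow(genes)
  within_rank <- stats::ave(genes$start, genes$chrom,
                            FUN = function(x) rank(x, ties.method = "first"))
  deal_order <- order(within_rank, match(genes$chrom,
                                         layout$chromosomes$name))
  sizes <- config$trans_modules
  mods <- rep(NA_integer_, G)
  pos <- 1L
  for (m in seq_along(sizes)) {
    take <- seq.int(pos, length.out = min(sizes[m], G - pos + 1L))
    if (length(take) == 0L) break
    mods[deal_order[take]] <- m
    pos <- pos + sizes[m]
  }
  mods
}

# nearest-PSD repair by clipping negative eigenvalues at zero and
# renormalizing to unit diagonal
psd_repair <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(S)
  v <- pmax(e$values, 0)
  R <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(R), .Machine$double.eps))
  R <- R / outer(d, d)
  (R + t(R)) / 2
}

#' Planted ground truth for a synthetic cohort
#'
#' Records everything needed to score recovery: which genes carry a planted
#' log2 fold change (and its sign and size), the trans-module membership, and
#' the expected latent correlation matrix for each regime.
#'
#' @param config a [synthetic_config()].
#' @param layout the matching [build_genome()] layout.
#' @return list with `de` (data.frame gene_id, lfc, sign), `modules`
#'   (integer per gene, NA if unassigned), `sigma_cis`, `sigma_trans`
#'   (expected latent correlation matrices), and `baseline_mean` (per-gene
#'   expected relative abundance).
#' @export
planted_truth <- function(config, layout) {
  validate_config(config)
  genes <- layout$genes
  G <- nrow(genes)
  set.seed(config$seed + 1L)
  n_de <- round(config$frac_de * G)
  de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
  lfc <- numeric(G)
  lfc[de_idx] <- stats::rnorm(n_de, 0, config$lfc_sd)
  base_mu <- exp(stats::rnorm(G, log(200), 1.2))  # relative abundances
  list(de = data.frame(gene_id = genes$gene_id[de_idx],
                       lfc = lfc[de_idx],
                       sign = sign(lfc[de_idx]),
                       stringsAsFactors = FALSE),
       lfc_all = stats::setNames(lfc, genes$gene_id),
       modules = stats::setNames(trans_module_membership(layout, config),
                                 genes$gene_id),
       sigma_cis = latent_correlation(layout, config, "cis_dominant"),
       sigma_trans = latent_correlation(layout, config, "trans_dominant"),
       baseline_mean = stats::setNames(base_mu, genes$gene_id))
}

#' Simulate a count matrix with planted covariance structure
#'
#' Draws latent per-gene Gaussians with the regime's correlation matrix (see
#' [synthetic_config()]), shifts `frac_de` genes by their planted log2 fold
#' change when `condition = "altered"`, and maps each latent value through a
#' Gaussian copula to a negative-binomial count with per-sample library
#' sizes drawn uniformly from `libsize_range`. The copula is rank-preserving,
#' so planted correlation survives monotone normalization downstream.
#'
#' @param layout a [build_genome()] layout.
#' @param config the matching [synthetic_config()].
#' @param condition `"baseline"` or `"altered"` (altered adds the planted
#'   fold changes).
#' @param structure `"cis_dominant"` or `"trans_dominant"`.
#' @param n_samples optional override of `config$n_samples`.
#' @return integer matrix, genes x samples, with gene IDs as rownames and
#'   sample IDs `<condition>_s<k>` as colnames.
#' @export
simulate_counts <- function(layout, config,
                            condition = c("baseline", "altered"),
                            structure = c("cis_dominant", "trans_dominant"),
                            n_samples = NULL) {
  validate_config(config)
  condition <- match.arg(condition)
  structure <- match.arg(structure)
  genes <- layout$genes
  G <- nrow(genes)
  n <- if (is.null(n_samples)) config$n_samples else as.integer(n_samples)

  truth <- planted_truth(config, layout)
  S <- if (structure == "cis_dominant") truth$sigma_cis else truth$sigma_trans

  # seed streams separated per (condition, structure) so cohorts differ
  set.seed(config$seed + 7L * match(condition, c("baseline", "altered")) +
             13L * match(structure, c("cis_dominant", "trans_dominant")))
  L <- chol(S + diag(1e-8, G))
  Z <- t(L) %*% matrix(stats::rnorm(G * n), G, n)  # latent genes x samples

  mu_rel <- truth$baseline_mean
  if (condition == "altered") mu_rel <- mu_rel * 2 ^ truth$lfc_all
  p_g <- mu_rel / sum(mu_rel)

  libsize <- stats::runif(n, config$libsize_range[1], config$libsize_range[2])
  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, G, n, dimnames = list(genes$gene_id,
                                             paste0(condition, "_s", seq_len(n))))
  U <- stats::pnorm(Z)
  for (j in seq_len(n)) {
    mu_j <- p_g * libsize[j]
    counts[, j] <- as.integer(stats::qnbinom(U[, j], size = size, mu = mu_j))
  }
  counts
}
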