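# Synthetic-data generator: every pipeline input, with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a two-progenitor RI panel whose strains are fixed homozygous mosaics of
# the parental genomes, strain-mean expression in which planted modules are
# driven by single-marker genotypes, two-strain transcript sets with the
# planted merge/filter cases the assembly rules act on, probe sets with
# alignment/variant contamination, annotation term sets with one planted
# enriched term, and a phenotypic QTL catalog with LOD values straddling
# the reporting threshold.

#' Specification of one planted co-expression module
#'
#' @param size number of member genes.
#' @param qtl_marker genome-wide marker index (column of the genotype
#'   matrix) whose genotype drives the module.
#' @param qtl_effect_fraction expected squared correlation between the
#'   module's latent driver and the marker genotype, in `[0, 1)`.
#' @param gene_loading_range range the per-gene loadings on the driver are
#'   drawn from (uniform).
#' @param noise_sd standard deviation of per-gene independent noise.
#' @return a `module_spec` list.
#' @export
module_spec <- function(size, qtl_marker, qtl_effect_fraction = 0.6,
                        gene_loading_range = c(0.75, 0.95), noise_sd = 0.5) {
  stopifnot(size >= 1, qtl_marker >= 1,
            qtl_effect_fraction >= 0, qtl_effect_fraction < 1,
            length(gene_loading_range) == 2L,
            gene_loading_range[1] <= gene_loading_range[2],
            noise_sd >= 0)
  structure(list(size = as.integer(size),
                 qtl_marker = as.integer(qtl_marker),
                 qtl_effect_fraction = qtl_effect_fraction,
                 gene_loading_range = gene_loading_range,
                 noise_sd = noise_sd),
            class = "module_spec")
}

default_module_specs <- function(markers_total = 150L) {
  # five modules of sizes 10-40 planted on well-separated markers
  anchors <- round(markers_total * c(0.05, 0.25, 0.45, 0.65, 0.85)) + 1L
  anchors <- pmin(pmax(anchors, 1L), markers_total)
  list(module_spec(40, anchors[1]),
       module_spec(30, anchors[2]),
       module_spec(25, anchors[3]),
       module_spec(15, anchors[4]),
       module_spec(10, anchors[5]))
}

#' Simulation configuration
#'
#' Holds every knob of the synthetic study. Defaults mirror the design of
#' an HXB/BXH-style RI liver study: 21 strains, a biallelic marker map of
#' 10 chromosomes x 15 markers, five planted modules of sizes 10-40 whose
#' drivers explain 60% of marker-genotype variance, and 80 unstructured
#' background genes.
#'
#' @param seed integer seed; all stage streams derive from it.
#' @param n_strains number of RI strains.
#' @param n_chromosomes,markers_per_chromosome marker map dimensions.
#' @param recomb_prob probability that adjacent markers on a chromosome
#'   derive from different progenitors (per-interval switch probability of
#'   the genotype mosaic).
#' @param module_specs list of [module_spec()] objects.
#' @param n_background_genes number of unstructured noise genes.
#' @param replicates_per_strain array samples per strain.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_strains = 21L,
                              n_chromosomes = 10L,
                              markers_per_chromosome = 15L,
                              recomb_prob = 0.1,
                              module_specs = NULL,
                              n_background_genes = 80L,
                              replicates_per_strain = 3L) {
  if (n_strains < 1 || n_chromosomes < 1 || markers_per_chromosome < 1 ||
      n_background_genes < 0 || replicates_per_strain < 1)
    stop("simulation_config: dimensions must be positive")
  if (recomb_prob < 0 || recomb_prob > 1)
    stop("simulation_config: recomb_prob must be in [0, 1]")
  m_total <- as.integer(n_chromosomes) * as.integer(markers_per_chromosome)
  if (is.null(module_specs)) module_specs <- default_module_specs(m_total)
  stopifnot(all(vapply(module_specs, inherits, logical(1), "module_spec")))
  bad <- vapply(module_specs, function(s) s$qtl_marker > m_total, logical(1))
  if (any(bad))
    stop("simulation_config: qtl_marker index beyond the marker map")
  structure(list(seed = as.integer(seed),
                 n_strains = as.integer(n_strains),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 recomb_prob = recomb_prob,
                 module_specs = module_specs,
                 n_background_genes = as.integer(n_background_genes),
                 replicates_per_strain = as.integer(replicates_per_strain)),
            class = "simulation_config")
}

#' Simulate RI-panel genotypes (strain distribution patterns)
#'
#' Each strain x chromosome is a first-order Markov mosaic of the two
#' progenitor alleles: the first marker is Bernoulli(0.5) and each
#' subsequent marker switches progenitor with probability `recomb_prob`.
#' RI strains are homozygous, so alleles are coded 0/1.
#'
#' @param config a [simulation_config()].
#' @return a `genotype_matrix`: list with `alleles` (strains x markers 0/1
#'   matrix) and `map` (data.frame marker, chrom, pos_bp).
#' @export
simulate_ri_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "ri_genotypes"))
  n <- config$n_strains
  nc <- config$n_chromosomes
  mpc <- config$markers_per_chromosome
  m_total <- nc * mpc

  alleles <- matrix(NA_integer_, n, m_total)
  col0 <- 0L
  for (ch in seq_len(nc)) {
    start <- matrix(stats::rbinom(n, 1L, 0.5), n, 1L)
    if (mpc > 1L) {
      flips <- matrix(stats::rbinom(n * (mpc - 1L), 1L, config$recomb_prob),
                      n, mpc - 1L)
      # cumulative-sum-mod-2 of (initial state, flips) gives the Markov mosaic
      states <- t(apply(cbind(start, flips), 1L, cumsum)) %% 2L
    } else {
      states <- start
    }
    alleles[, col0 + seq_len(mpc)] <- as.integer(states)
    col0 <- col0 + mpc
  }

  strains <- sprintf("strain_%02d", seq_len(n))
  map <- data.frame(
    marker = sprintf("chr%d_m%02d", rep(seq_len(nc), each = mpc),
                     rep(seq_len(mpc), nc)),
    chrom = sprintf("chr%d", rep(seq_len(nc), each = mpc)),
    pos_bp = rep(seq_len(mpc) * 2e6, nc),
    stringsAsFactors = FALSE)
  dimnames(alleles) <- list(strains, map$marker)
  structure(list(alleles = alleles, map = map), class = "genotype_matrix")
}

#' Simulate a module-structured strain-mean expression panel
#'
#' For each planted module a latent driver
#' `d = sqrt(f) * standardized genotype + sqrt(1 - f) * N(0, 1)` is drawn
#' (`f` = `qtl_effect_fraction`), and each member gene is
#' `loading * d + noise_sd * N(0, 1)`. Background genes are independent
#' standard normal noise. The truth record stores the planted membership,
#' drivers and QTL markers so downstream stages can be scored.
#'
#' @param genotypes a `genotype_matrix`.
#' @param config a [simulation_config()].
#' @return list with `expression` (strains x genes matrix) and `truth`
#'   (list: `membership` data.frame (gene, module), `qtl_marker` integer
#'   vector per module, `drivers` strains x modules matrix).
#' @export
simulate_expression_panel <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "expression_panel"))
  n <- nrow(genotypes$alleles)
  specs <- config$module_specs
  sizes <- vapply(specs, `[[`, integer(1), "size")
  n_genes <- sum(sizes) + config$n_background_genes
  genes <- sprintf("g%04d", seq_len(n_genes))

  expr <- matrix(NA_real_, n, n_genes,
                 dimnames = list(rownames(genotypes$alleles), genes))
  membership <- integer(n_genes)
  drivers <- matrix(NA_real_, n, length(specs))
  col <- 0L
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    g <- genotypes$alleles[, s$qtl_marker]
    if (stats::sd(g) == 0)
      stop("planted qtl marker is monomorphic in this panel; reseed or move it")
    gz <- (g - mean(g)) / stats::sd(g)
    d <- sqrt(s$qtl_effect_fraction) * gz +
      sqrt(1 - s$qtl_effect_fraction) * stats::rnorm(n)
    drivers[, k] <- d
    loadings <- stats::runif(s$size, s$gene_loading_range[1],
                             s$gene_loading_range[2])
    noise <- matrix(stats::rnorm(n * s$size, sd = s$noise_sd), n, s$size)
    expr[, col + seq_len(s$size)] <- outer(d, loadings) + noise
    membership[col + seq_len(s$size)] <- k
    col <- col + s$size
  }
  if (config$n_background_genes > 0L)
    expr[, col + seq_len(config$n_background_genes)] <-
      stats::rnorm(n * config$n_background_genes)

  truth <- list(
    membership = data.frame(gene = genes, module = membership,
                            stringsAsFactors = FALSE),
    qtl_marker = vapply(specs, `[[`, integer(1), "qtl_marker"),
    drivers = drivers)
  list(expression = expr, truth = truth)
}
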