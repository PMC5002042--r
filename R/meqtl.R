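# Module eigengene QTL mapping: marker regression, permutation-based
# genome-wide thresholds, selection of genetically driven modules.

#' Marker-regression LOD scores for a trait
#'
#' Regresses the eigengene (or any strain-level trait) on each biallelic
#' marker and converts the fit to a LOD score,
#' `LOD = (n/2) log10(RSS0/RSS1) = (n/2) log10(1/(1 - R^2))`. Markers
#' where either genotype class has fewer than 2 strains are skipped
#' (LOD = NA); a perfect fit yields `Inf`.
#'
#' @param E named numeric vector over strains.
#' @param genotypes a `genotype_matrix`; strains must match `E`.
#' @return data.frame (marker, chrom, pos_bp, lod).
#' @export
marker_regression_lod <- function(E, genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  G <- genotypes$alleles
  if (!is.null(names(E))) {
    stopifnot(all(names(E) %in% rownames(G)))
    G <- G[names(E), , drop = FALSE]
  } else {
    stopifnot(length(E) == nrow(G))
  }
  if (stats::sd(E) == 0) stop("marker_regression_lod: constant trait")
  n <- length(E)
  ones <- colSums(G)
  usable <- ones >= 2L & (n - ones) >= 2L
  r <- suppressWarnings(as.numeric(stats::cor(E, G)))
  lod <- ifelse(usable, (n / 2) * log10(1 / (1 - r^2)), NA_real_)
  data.frame(marker = colnames(G),
             chrom = genotypes$map$chrom,
             pos_bp = genotypes$map$pos_bp,
             lod = lod, stringsAsFactors = FALSE)
}

# peak of a LOD curve (first marker at the maximum)
lod_peak <- function(scan) {
  i <- which.max(scan$lod)
  list(index = i, marker = scan$marker[i], chrom = scan$chrom[i],
       pos_bp = scan$pos_bp[i], lod = scan$lod[i])
}

#' Permutation-based genome-wide significance
#'
#' Shuffles the trait across strains `n_perm` times against the full
#' marker map, records each permutation's genome-wide maximum LOD, and
#' returns the empirical `1 - alpha` quantile as the genome-wide
#' threshold. The genome-wide p-value of the observed peak is the
#' fraction of permutation maxima at or above it, reported as
#' `< 1/n_perm` when no permutation exceeds the peak.
#'
#' @param E named numeric trait over strains.
#' @param genotypes a `genotype_matrix`.
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide significance level.
#' @param seed integer seed for the permutation stream.
#' @return list: `scan`, `peak`, `threshold`, `genome_wide_p`, `p_label`,
#'   `perm_max` (the permutation maxima), `n_perm`.
#' @export
permutation_threshold <- function(E, genotypes, n_perm = 1000L,
                                  alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 100L)
  scan <- marker_regression_lod(E, genotypes)
  peak <- lod_peak(scan)

  G <- genotypes$alleles
  if (!is.null(names(E))) G <- G[names(E), , drop = FALSE]
  n <- length(E)
  ones <- colSums(G)
  usable <- ones >= 2L & (n - ones) >= 2L
  Gu <- G[, usable, drop = FALSE]

  set.seed(stage_seed(seed, "meqtl_permutations"))
  P <- vapply(seq_len(n_perm), function(i) sample(as.numeric(E)), numeric(n))
  R <- stats::cor(P, Gu)                 # n_perm x usable markers
  lodM <- (n / 2) * log10(1 / (1 - R^2))
  perm_max <- apply(lodM, 1L, max)

  count <- sum(perm_max >= peak$lod)
  p <- count / n_perm
  list(scan = scan, peak = peak,
       threshold = stats::quantile(perm_max, 1 - alpha, names = FALSE),
       genome_wide_p = p,
       p_label = if (count == 0L) sprintf("<%g", 1 / n_perm)
                 else format(p, digits = 3),
       perm_max = perm_max, n_perm = n_perm)
}

#' Scan every module eigengene for meQTLs
#'
#' @param eigengenes strains x modules matrix.
#' @param genotypes a `genotype_matrix`.
#' @param n_perm,alpha,seed passed to [permutation_threshold()].
#' @param shared_permutations reuse one permutation stream for every
#'   module (the default; cheaper and standard) or draw a fresh stream
#'   per module.
#' @return list of per-module scan results plus a `summary` data.frame
#'   (module, peak_marker, chrom, pos_bp, lod, threshold, genome_wide_p).
#' @export
meqtl_scan <- function(eigengenes, genotypes, n_perm = 1000L, alpha = 0.05,
                       seed = 1L, shared_permutations = TRUE) {
  mods <- colnames(eigengenes) %||% as.character(seq_len(ncol(eigengenes)))
  scans <- lapply(seq_len(ncol(eigengenes)), function(j) {
    E <- stats::setNames(eigengenes[, j], rownames(eigengenes))
    s <- if (shared_permutations) seed else stage_seed(seed, mods[j])
    permutation_threshold(E, genotypes, n_perm = n_perm, alpha = alpha,
                          seed = s)
  })
  names(scans) <- mods
  summary <- data.frame(
    module = mods,
    peak_marker = vapply(scans, function(s) s$peak$marker, character(1)),
    chrom = vapply(scans, function(s) s$peak$chrom, character(1)),
    pos_bp = vapply(scans, function(s) s$peak$pos_bp, numeric(1)),
    lod = vapply(scans, function(s) s$peak$lod, numeric(1)),
    threshold = vapply(scans, function(s) s$threshold, numeric(1)),
    genome_wide_p = vapply(scans, function(s) s$genome_wide_p, numeric(1)),
    p_label = vapply(scans, function(s) s$p_label, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(scans = scans, summary = summary)
}

#' Select genetically driven modules
#'
#' A module is genetically driven when its eigengene explains more than
#' `var_min` of the module variance and its meQTL reaches genome-wide
#' significance (`genome_wide_p < p_max`). Both inequalities are strict.
#'
#' @param module_summary data.frame with `module` and
#'   `variance_explained` (from [module_summaries()]).
#' @param qtl_summary data.frame with `module` and `genome_wide_p` (from
#'   [meqtl_scan()]).
#' @param var_min variance-explained threshold.
#' @param p_max genome-wide p-value threshold.
#' @return merged data.frame of the selected modules.
#' @export
select_genetically_driven <- function(module_summary, qtl_summary,
                                      var_min = 0.5, p_max = 0.05) {
  m <- merge(module_summary, qtl_summary, by = "module")
  m[m$variance_explained > var_min & m$genome_wide_p < p_max, ,
    drop = FALSE]
}
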