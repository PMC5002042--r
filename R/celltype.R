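# Cell-type characterization: two-way ANOVA differential expression
# across isolated liver cell types, and relative-to-Kupffer display
# statistics.

#' Two-way ANOVA for cell-type differential expression
#'
#' Fits `value ~ cell_type * strain` per gene and tests, with a single
#' F-statistic, the joint null that all cell-type main effects and
#' cell-type x strain interactions are zero — i.e., no cell-type-related
#' expression difference, whether strain dependent or independent — by
#' comparison against the strain-only model. P-values are corrected
#' across genes with Benjamini-Hochberg; genes with `q < fdr_max` are
#' flagged differential. Per-effect F-tests from the full decomposition
#' are also reported.
#'
#' @param panel long data.frame with columns `gene`, `cell_type`,
#'   `strain`, `replicate`, `value` (log2 scale).
#' @param fdr_max FDR threshold for the differential flag.
#' @return data.frame per gene: `F`, `p`, `q`, `differential`, plus
#'   per-effect `F_cell`, `p_cell`, `F_interaction`, `p_interaction`.
#' @export
celltype_anova <- function(panel, fdr_max = 0.05) {
  need <- c("gene", "cell_type", "strain", "replicate", "value")
  stopifnot(all(need %in% names(panel)))
  tab <- table(panel$gene, panel$cell_type, panel$strain)
  if (any(tab < 2L))
    stop("celltype_anova: need >= 2 replicates per (gene, cell type, strain)")
  by_gene <- split(panel, panel$gene)
  rows <- lapply(by_gene, function(d) {
    d$cell_type <- factor(d$cell_type)
    d$strain <- factor(d$strain)
    full <- stats::lm(value ~ cell_type * strain, data = d)
    null <- stats::lm(value ~ strain, data = d)
    cmp <- stats::anova(null, full)
    a <- stats::anova(full)
    data.frame(gene = d$gene[1L],
               F = cmp$F[2L], p = cmp$`Pr(>F)`[2L],
               F_cell = a["cell_type", "F value"],
               p_cell = a["cell_type", "Pr(>F)"],
               F_interaction = a["cell_type:strain", "F value"],
               p_interaction = a["cell_type:strain", "Pr(>F)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$differential <- out$q < fdr_max
  out[, c("gene", "F", "p", "q", "differential", "F_cell", "p_cell",
          "F_interaction", "p_interaction")]
}

#' Estimated cell x strain means per gene
#'
#' @param panel long data.frame as in [celltype_anova()].
#' @return data.frame (gene, cell_type, strain, mean) on the input (log2)
#'   scale.
#' @export
celltype_means <- function(panel) {
  agg <- stats::aggregate(value ~ gene + cell_type + strain, panel, mean)
  names(agg)[names(agg) == "value"] <- "mean"
  agg
}

#' Expression relative to the Kupffer-cell average
#'
#' Converts log2 cell x strain means to the linear scale and divides each
#' (cell type, strain) value by the gene's across-strain mean Kupffer
#' expression, so a ratio of 2 means twice the average Kupffer-cell
#' expression. Also reports, per gene, whether the Kupffer mean is the
#' maximum over cell types and the percent difference of Kupffer versus
#' each other cell type, `100 (KC/c - 1)`.
#'
#' @param means data.frame (gene, cell_type, strain, mean) on log2 scale.
#' @param kc_cell label of the Kupffer-cell level.
#' @param denominator `"across"` (default): KC mean across strains;
#'   `"within"`: each strain uses its own KC value.
#' @return list: `ratios` (gene, cell_type, strain, ratio),
#'   `gene_summary` (gene, kc_highest), `percent_diff` (gene, cell_type,
#'   percent_diff vs KC).
#' @export
relative_expression_profile <- function(means, kc_cell = "KC",
                                        denominator = c("across",
                                                        "within")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("gene", "cell_type", "strain", "mean") %in% names(means)),
            kc_cell %in% means$cell_type)
  means$linear <- 2^means$mean

  kc <- means[means$cell_type == kc_cell, , drop = FALSE]
  kc_across <- tapply(kc$linear, kc$gene, mean)
  if (denominator == "across") {
    means$denom <- as.numeric(kc_across[means$gene])
  } else {
    key <- paste(kc$gene, kc$strain)
    means$denom <- kc$linear[match(paste(means$gene, means$strain), key)]
  }
  means$ratio <- means$linear / means$denom

  cellmeans <- stats::aggregate(linear ~ gene + cell_type, means, mean)
  wide <- stats::reshape(cellmeans, idvar = "gene", timevar = "cell_type",
                         direction = "wide")
  cells <- sub("^linear\\.", "", names(wide)[-1L])
  mat <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(mat) <- cells
  rownames(mat) <- wide$gene
  kc_highest <- colnames(mat)[max.col(mat, ties.method = "first")] == kc_cell

  other <- setdiff(cells, kc_cell)
  pd <- do.call(rbind, lapply(other, function(cc)
    data.frame(gene = rownames(mat), cell_type = cc,
               percent_diff = 100 * (mat[, kc_cell] / mat[, cc] - 1),
               stringsAsFactors = FALSE)))
  rownames(pd) <- NULL
  list(ratios = means[, c("gene", "cell_type", "strain", "ratio")],
       gene_summary = data.frame(gene = rownames(mat),
                                 kc_highest = kc_highest,
                                 stringsAsFactors = FALSE),
       percent_diff = pd)
}
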