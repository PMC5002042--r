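# Probe integrity masking and probe-set -> gene-cluster mapping.

#' Filter probes to high-integrity status
#'
#' Drops probes that do not align perfectly and singularly to the genome,
#' or that overlap a sequence variant (SNP, small insertion or deletion)
#' between the two progenitor strains; probe sets with fewer than
#' `min_probes_per_set` surviving probes are eliminated entirely.
#'
#' @param probes data.frame with columns `probe_id`, `probeset_id`,
#'   `alignment_count`, `perfect_alignment`, `variant_overlap`.
#' @param min_probes_per_set minimum surviving probes per set.
#' @return list: `probes` (surviving rows), `probesets` (surviving ids),
#'   `eliminated_probesets`.
#' @export
filter_probes <- function(probes, min_probes_per_set = 3L) {
  need <- c("probe_id", "probeset_id", "alignment_count",
            "perfect_alignment", "variant_overlap")
  stopifnot(all(need %in% names(probes)))
  keep <- probes$alignment_count == 1L & probes$perfect_alignment &
    !probes$variant_overlap
  surv <- probes[keep, , drop = FALSE]
  counts <- table(surv$probeset_id)
  good_sets <- names(counts)[counts >= min_probes_per_set]
  list(probes = surv[surv$probeset_id %in% good_sets, , drop = FALSE],
       probesets = good_sets,
       eliminated_probesets = setdiff(unique(probes$probeset_id), good_sets))
}

#' Map probe sets to gene clusters
#'
#' A probe set is assigned to a gene only when its targeted interval lies
#' exclusively and entirely within that gene: fully contained in the
#' gene's exonic union and contained in no other gene. Genes that receive
#' at least one probe set become gene clusters.
#'
#' @param probesets data.frame with `probeset_id`, `chrom`, `start`, `end`.
#' @param genes a `gene_groups` object.
#' @return data.frame (`probeset_id`, `gene_id`) of assignments.
#' @export
map_probesets_to_gene_clusters <- function(probesets, genes) {
  stopifnot(inherits(genes, "gene_groups"),
            all(c("probeset_id", "chrom", "start", "end") %in%
                  names(probesets)))
  if (nrow(probesets) == 0L)
    return(data.frame(probeset_id = character(0), gene_id = character(0)))
  ps <- GenomicRanges::GRanges(probesets$chrom,
                               IRanges::IRanges(probesets$start,
                                                probesets$end))
  ex <- genes$exons
  gx <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  # containment in a union of disjoint exonic blocks == containment in one
  # reduced block, so type = "within" on the reduced exon table suffices
  ov <- GenomicRanges::findOverlaps(ps, gx, type = "within")
  hits <- data.frame(probeset = S4Vectors::queryHits(ov),
                     gene = ex$gene_id[S4Vectors::subjectHits(ov)])
  hits <- hits[!duplicated(hits), , drop = FALSE]
  n_genes <- tapply(hits$gene, hits$probeset, function(g) length(unique(g)))
  unique_ps <- as.integer(names(n_genes)[n_genes == 1L])
  hits <- hits[hits$probeset %in% unique_ps, , drop = FALSE]
  data.frame(probeset_id = probesets$probeset_id[hits$probeset],
             gene_id = hits$gene, stringsAsFactors = FALSE)
}

#' Build gene-cluster expression matrices and apply the detection filter
#'
#' Summarizes each gene cluster as the mean of its probe sets' log2
#' intensities per sample, removes clusters detected above background
#' (DABG p below `detect_p`) in fewer than `detect_fraction` of samples,
#' and computes strain means. A cluster's per-sample DABG p is the
#' minimum over its probe sets (detected when any probe set is detected).
#'
#' @param assignment probeset -> gene table from
#'   [map_probesets_to_gene_clusters()].
#' @param intensity,dabg probesets x samples matrices (log2 intensities,
#'   DABG p-values).
#' @param sample_strain named character vector mapping sample -> strain.
#' @param detect_p DABG detection p-value cutoff.
#' @param detect_fraction minimum fraction of detected samples
#'   (inclusive).
#' @return list: `samples` (clusters x samples), `strain_means`
#'   (strains x clusters), `detected_fraction`, `removed`.
#' @export
build_expression_matrix <- function(assignment, intensity, dabg,
                                    sample_strain, detect_p = 1e-4,
                                    detect_fraction = 0.05) {
  stopifnot(identical(dim(intensity), dim(dabg)),
            all(colnames(intensity) %in% names(sample_strain)))
  asg <- assignment[assignment$probeset_id %in% rownames(intensity), ,
                    drop = FALSE]
  if (nrow(asg) == 0L) stop("no assigned probe sets with intensities")
  strains <- unique(unname(sample_strain[colnames(intensity)]))
  if (any(table(factor(unname(sample_strain[colnames(intensity)]),
                       levels = strains)) == 0L))
    stop("strain without samples")

  by_gene <- split(asg$probeset_id, asg$gene_id)
  expr <- t(vapply(by_gene, function(psids)
    colMeans(intensity[psids, , drop = FALSE]),
    numeric(ncol(intensity))))
  clp <- t(vapply(by_gene, function(psids)
    apply(dabg[psids, , drop = FALSE], 2L, min),
    numeric(ncol(dabg))))

  det_frac <- rowMeans(clp < detect_p)
  keep <- det_frac >= detect_fraction
  expr_kept <- expr[keep, , drop = FALSE]

  strain_of <- unname(sample_strain[colnames(expr_kept)])
  # one row per strain, one column per surviving cluster
  strain_means <- vapply(seq_len(nrow(expr_kept)), function(i)
    tapply(expr_kept[i, ], strain_of, mean),
    numeric(length(unique(strain_of))))
  strain_means <- matrix(strain_means, nrow = length(unique(strain_of)),
                         dimnames = list(sort(unique(strain_of)),
                                         rownames(expr_kept)))
  list(samples = expr_kept,
       strain_means = strain_means,
       detected_fraction = det_frac,
       removed = rownames(expr)[!keep])
}
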