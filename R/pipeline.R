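# End-to-end orchestration on synthetic data, plus scoring against the
# generator's truth records. Stage outputs are plain files so partial
# reruns and diffing are easy; the whole run is a pure function of
# (config, seed).

#' Pipeline configuration
#'
#' Bundles the simulation config with every stage parameter at its
#' documented default.
#'
#' @param sim a [simulation_config()].
#' @param outdir output directory (`NULL` = no files written).
#' @param fpkm_min,length_min high-confidence transcript filter.
#' @param end_tolerance single-exon merge tolerance (bp).
#' @param coverage_min,stop_fraction iterative-reduction parameters.
#' @param detect_p,detect_fraction DABG detection filter.
#' @param power soft-thresholding exponent.
#' @param min_module_size,cut_height,split_alpha tree-cut
#'   parameters.
#' @param merge_cor eigengene merge threshold.
#' @param n_perm,alpha permutation scan parameters.
#' @param var_min variance-explained threshold for driven modules.
#' @param connection_threshold |r| threshold for connection counts.
#' @param min_annotated,min_term_hits,enrich_alpha enrichment gates.
#' @param lod_min phenotypic-QTL catalog LOD threshold.
#' @param fdr_max cell-type ANOVA FDR threshold.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(), outdir = NULL,
                            fpkm_min = 1, length_min = 300,
                            end_tolerance = 100,
                            coverage_min = 50, stop_fraction = 0.05,
                            detect_p = 1e-4, detect_fraction = 0.05,
                            power = 7, min_module_size = 5L,
                            cut_height = 0.99, split_alpha = 1,
                            merge_cor = 0.75,
                            n_perm = 1000L, alpha = 0.05,
                            var_min = 0.5, connection_threshold = 0.5,
                            min_annotated = 10L, min_term_hits = 2L,
                            enrich_alpha = 0.05, lod_min = 10,
                            fdr_max = 0.05) {
  stopifnot(inherits(sim, "simulation_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes the five-step workflow: (1) assemble the combined two-strain
#' transcriptome, (2) mask probes and build the gene-cluster expression
#' matrix, (3) construct the co-expression network and detect/merge
#' modules on the strain-mean panel, (4) map module eigengenes to markers
#' and select genetically driven modules, then (5) refine driven modules
#' by partial correlation and interpret them against annotations, the
#' phenotypic QTL catalog and the cell-type panel. All inputs are drawn
#' from the synthetic-data generator; outputs and a manifest are written
#' under `config$outdir` when set.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (`simulated`, `assembly`, `mask`,
#'   `network`, `meqtl`, `refined`, `enrichment`, `qtl_overlap`,
#'   `celltype`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  res <- list()

  # stage 1: simulate all inputs
  genotypes <- simulate_ri_genotypes(sim)
  panel <- simulate_expression_panel(genotypes, sim)
  txs <- simulate_strain_transcriptomes(sim)
  res$simulated <- list(genotypes = genotypes, panel = panel,
                        transcriptomes = txs)

  # stage 2: transcriptome assembly
  hc_a <- filter_high_confidence(txs$tx_a, config$fpkm_min,
                                 config$length_min)
  hc_b <- filter_high_confidence(txs$tx_b, config$fpkm_min,
                                 config$length_min)
  merged <- merge_strain_transcriptomes(hc_a, hc_b, config$end_tolerance)
  mass <- collapse_mass_profile(txs$mass, merged$provenance)
  reduced <- iterative_reduction(merged$transcripts, mass,
                                 config$coverage_min, config$stop_fraction)
  genes <- group_into_genes(reduced$transcripts)
  res$assembly <- list(high_confidence = list(A = hc_a, B = hc_b),
                       merged = merged, reduction = reduced, genes = genes)

  # stage 3: probe mask and gene-cluster expression
  probe_data <- simulate_probe_data(genes, sim)
  pf <- filter_probes(probe_data$probes)
  psets <- probe_data$probesets[probe_data$probesets$probeset_id %in%
                                  pf$probesets, , drop = FALSE]
  assignment <- map_probesets_to_gene_clusters(psets, genes)
  exprs <- build_expression_matrix(assignment, probe_data$intensity,
                                   probe_data$dabg,
                                   probe_data$sample_strain,
                                   config$detect_p, config$detect_fraction)
  res$mask <- list(probe_data = probe_data, filtered = pf,
                   assignment = assignment, expression = exprs)

  # stage 4: co-expression network on the strain-mean panel
  expr <- panel$expression
  net <- adjacency_matrix(expr, config$power)
  tom <- tom_similarity(net$A)
  labels <- detect_modules(1 - tom, config$min_module_size,
                           config$cut_height, config$split_alpha)
  labels <- merge_similar_modules(labels, expr, config$merge_cor)
  mods <- module_summaries(expr, labels, net)
  res$network <- list(net = net, tom = tom, labels = labels,
                      modules = mods,
                      scale_free = scale_free_fit(net$k))

  # stage 5: meQTL mapping and module selection
  qtl <- meqtl_scan(mods$eigengenes, genotypes, n_perm = config$n_perm,
                    alpha = config$alpha, seed = sim$seed)
  driven <- select_genetically_driven(mods$summary, qtl$summary,
                                      config$var_min, config$alpha)
  res$meqtl <- list(qtl = qtl, driven = driven)

  # stage 6: partial-correlation refinement of driven modules
  res$refined <- lapply(stats::setNames(driven$module, driven$module),
                        function(m) {
    z <- genotypes$alleles[, qtl$scans[[as.character(m)]]$peak$marker]
    refine_module_network(expr[, mods$members[[as.character(m)]],
                               drop = FALSE],
                          z, config$connection_threshold)
  })

  # stage 7: enrichment and phenotypic QTL overlap
  ann <- simulate_annotation_and_qtl_catalog(panel$truth, genotypes, sim)
  res$enrichment <- lapply(stats::setNames(driven$module, driven$module),
                           function(m)
    overrepresentation_test(mods$members[[as.character(m)]],
                            ann$annotations, ann$reference,
                            config$min_annotated, config$min_term_hits,
                            config$enrich_alpha))
  res$qtl_overlap <- lapply(stats::setNames(driven$module, driven$module),
                            function(m) {
    pk <- qtl$scans[[as.character(m)]]$peak
    phenotypic_qtl_overlap(pk$chrom, pk$pos_bp, ann$catalog, config$lod_min)
  })
  res$annotation_inputs <- ann

  # stage 8: cell-type characterization
  ct <- simulate_celltype_expression(sim)
  ct_stats <- celltype_anova(ct$panel, config$fdr_max)
  ct_rel <- relative_expression_profile(celltype_means(ct$panel))
  res$celltype <- list(data = ct, stats = ct_stats, relative = ct_rel)

  res$manifest <- build_manifest(config, res)
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config)
  invisible(res)
}

build_manifest <- function(config, res) {
  list(package = "rixnet",
       package_version = as.character(utils::packageVersion("rixnet")),
       seed = config$sim$seed,
       parameters = config[setdiff(names(config), c("sim", "outdir"))],
       simulation = config$sim[setdiff(names(config$sim), "module_specs")],
       stages = c("simulate", "assemble", "mask", "network", "meqtl",
                  "refine", "interpret", "celltype"),
       n_transcripts = nrow(res$assembly$reduction$transcripts$transcripts),
       n_genes = nrow(res$assembly$genes$genes),
       n_gene_clusters = nrow(res$mask$expression$samples),
       n_modules = nrow(res$network$modules$summary),
       n_driven = nrow(res$meqtl$driven))
}

write_pipeline_outputs <- function(res, config) {
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out, ...)
  write_transcript_gtf(res$assembly$reduction$transcripts,
                       p("transcriptome.gtf"),
                       gene_ids = stats::setNames(
                         res$assembly$genes$assignment$gene_id,
                         res$assembly$genes$assignment$transcript_id))
  write_tsv(res$assembly$genes$genes, p("genes.tsv"))
  write_tsv(res$mask$assignment, p("probeset_gene_map.tsv"))
  write_matrix_tsv(res$mask$expression$strain_means,
                   p("cluster_strain_means.tsv"), "strain")
  write_tsv(data.frame(gene = names(res$network$labels),
                       module = unname(res$network$labels)),
            p("module_labels.tsv"))
  write_matrix_tsv(res$network$modules$eigengenes, p("eigengenes.tsv"),
                   "strain")
  write_tsv(res$network$modules$summary, p("module_summary.tsv"))
  write_tsv(res$meqtl$qtl$summary, p("meqtl_summary.tsv"))
  write_tsv(res$meqtl$driven, p("driven_modules.tsv"))
  for (m in names(res$refined))
    write_tsv(res$refined[[m]]$stats, p(sprintf("refined_module_%s.tsv", m)))
  for (m in names(res$enrichment))
    write_tsv(res$enrichment[[m]], p(sprintf("enrichment_module_%s.tsv", m)))
  write_tsv(res$celltype$stats, p("celltype_anova.tsv"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out)
}

#' Score pipeline outputs against the generator's truth records
#'
#' @param res result of [run_pipeline()].
#' @return list: `module_ari` (adjusted Rand index of detected vs planted
#'   labels over all panel genes), `meqtl_hit_rate` (fraction of planted
#'   module QTLs recovered within one marker by a significant detected
#'   module), `enrichment_top_rank` (best rank of the planted term across
#'   driven modules mapped to the planted module), `filter_confusion`
#'   (planted vs actual low-coverage drop decisions).
#' @export
score_against_truth <- function(res) {
  truth <- res$simulated$panel$truth
  labels <- res$network$labels
  tr <- truth$membership$module[match(names(labels),
                                      truth$membership$gene)]
  ari <- mclust::adjustedRandIndex(tr, labels)

  # map each planted module to the detected module capturing most of it
  qtl_sum <- res$meqtl$qtl$summary
  map <- res$simulated$genotypes$map
  hit <- logical(length(truth$qtl_marker))
  mapped_module <- rep(NA_integer_, length(truth$qtl_marker))
  for (k in seq_along(truth$qtl_marker)) {
    genes_k <- truth$membership$gene[truth$membership$module == k]
    det <- labels[genes_k]
    det <- det[det > 0L]
    if (length(det) == 0L) next
    m <- as.integer(names(sort(table(det), decreasing = TRUE))[1L])
    mapped_module[k] <- m
    row <- qtl_sum[qtl_sum$module == m, ]
    if (nrow(row) != 1L || row$genome_wide_p >= 0.05) next
    peak_idx <- match(row$peak_marker, map$marker)
    hit[k] <- abs(peak_idx - truth$qtl_marker[k]) <= 1L
  }

  ann <- res$annotation_inputs
  rank_planted <- NA_integer_
  pm <- mapped_module[ann$planted_module]
  if (!is.na(pm) && as.character(pm) %in% names(res$enrichment)) {
    enr <- res$enrichment[[as.character(pm)]]
    if (nrow(enr) > 0L)
      rank_planted <- match(ann$planted_term, enr$term)
  }

  tx_truth <- res$simulated$transcriptomes$truth
  dropped <- res$assembly$reduction$dropped
  planted <- tx_truth$low_coverage
  considered <- c(res$assembly$reduction$transcripts$transcripts$transcript_id,
                  dropped)
  tp <- sum(planted %in% dropped)
  fp <- length(setdiff(dropped, planted))
  fn <- length(setdiff(planted, dropped))
  tn <- length(considered) - tp - fp - fn
  list(module_ari = ari,
       meqtl_hit_rate = mean(hit),
       enrichment_top_rank = rank_planted,
       filter_confusion = c(tp = tp, fp = fp, fn = fn, tn = tn,
                            precision = if (tp + fp > 0) tp / (tp + fp)
                                        else NA_real_,
                            recall = if (tp + fn > 0) tp / (tp + fn)
                                     else NA_real_))
}
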