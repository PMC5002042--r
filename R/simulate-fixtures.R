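# Fixture generators for the assembly, masking, annotation and cell-type
# stages. Each planted case is recorded in a truth object so downstream
# decisions (merge / filter / map / enrich) can be scored exactly.

#' Simulate two-strain transcript sets with planted assembly cases
#'
#' Emits per-strain transcript models containing every case the assembly
#' rules must handle: multi-exon pairs with identical splice junctions
#' (must merge), single-exon pairs with start/stop offsets at and beyond
#' the 100 bp tolerance, opposite-strand overlaps (must not merge),
#' within-strain isoforms sharing a junction (same gene, never merged
#' across strains), low-FPKM and short decoys removed by the
#' high-confidence filter, and low-coverage decoys (10% of the surviving
#' transcriptome) removed by iterative reduction. A read-mass profile with
#' shared-mass groups accompanies the transcripts.
#'
#' @param config a [simulation_config()]; only the seed is used.
#' @return list with `tx_a`, `tx_b` (per-strain `transcript_set`s),
#'   `mass` (a `read_mass_profile` keyed by original transcript ids) and
#'   `truth` (planted pairs, filter decoys, expected gene labels).
#' @export
simulate_strain_transcriptomes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "strain_transcriptomes"))

  tx <- list(); ex <- list(); mass <- list()
  pairs <- list(); gene_of <- character(0)
  locus <- 0L
  new_locus <- function() {
    locus <<- locus + 1L
    list(chrom = sprintf("chr%d", (locus - 1L) %% 4L + 1L),
         base = 1e6 * ((locus - 1L) %/% 4L + 1L) + 2e4 * locus,
         gene = sprintf("locus_%02d", locus))
  }
  add_tx <- function(id, strain, chrom, strand, fpkm, exons, gene) {
    tx[[length(tx) + 1L]] <<- data.frame(
      transcript_id = id, strain = strain, chrom = chrom, strand = strand,
      fpkm = fpkm, stringsAsFactors = FALSE)
    ex[[length(ex) + 1L]] <<- data.frame(
      transcript_id = id, start = exons[, 1], end = exons[, 2])
    gene_of[id] <<- gene
  }
  add_mass <- function(id, strain, m, grp = NA_character_, gm = NA_real_) {
    mass[[length(mass) + 1L]] <<- data.frame(
      transcript_id = id, strain = strain, unique_mass = m,
      shared_group_id = grp, group_mass = gm, stringsAsFactors = FALSE)
  }
  multiexon <- function(base, s_off = 0, e_off = 0) {
    cbind(base + c(0 + s_off, 2000, 4000), base + c(499, 2599, 4799 + e_off))
  }
  # a merged multi-exon A/B pair with per-strain coverage targets
  mm_pair <- function(cov_a, cov_b, tag) {
    L <- new_locus()
    ida <- sprintf("A_%s", tag); idb <- sprintf("B_%s", tag)
    exa <- multiexon(L$base); exb <- multiexon(L$base, s_off = 80, e_off = 60)
    add_tx(ida, "A", L$chrom, "+", stats::runif(1, 2, 200), exa, L$gene)
    add_tx(idb, "B", L$chrom, "+", stats::runif(1, 2, 200), exb, L$gene)
    len_a <- sum(exa[, 2] - exa[, 1] + 1)
    add_mass(ida, "A", cov_a * len_a)
    add_mass(idb, "B", cov_b * len_a)
    pairs[[length(pairs) + 1L]] <<- data.frame(
      tx_a = ida, tx_b = idb, must_merge = TRUE, case = "multiexon",
      stringsAsFactors = FALSE)
    paste(sort(c(ida, idb)), collapse = "+")
  }
  se_pair <- function(off_start, off_end, must_merge, case, tag,
                      same_gene = must_merge) {
    L <- new_locus()
    ida <- sprintf("A_%s", tag); idb <- sprintf("B_%s", tag)
    exa <- cbind(L$base, L$base + 999)
    exb <- cbind(L$base + off_start, L$base + 999 + off_end)
    gene_b <- if (same_gene) L$gene else paste0(L$gene, "_b")
    add_tx(ida, "A", L$chrom, "+", stats::runif(1, 2, 200), exa, L$gene)
    add_tx(idb, "B", L$chrom, "+", stats::runif(1, 2, 200), exb, gene_b)
    add_mass(ida, "A", stats::runif(1, 80, 300) * 1000)
    add_mass(idb, "B", stats::runif(1, 80, 300) * 1000)
    pairs[[length(pairs) + 1L]] <<- data.frame(
      tx_a = ida, tx_b = idb, must_merge = must_merge, case = case,
      stringsAsFactors = FALSE)
  }

  # 16 well-covered must-merge multi-exon pairs
  for (i in 1:16) mm_pair(stats::runif(1, 80, 300), stats::runif(1, 80, 300),
                          sprintf("mm%02d", i))
  # single-exon pairs within the 100 bp tolerance (inclusive boundary)
  sc_off <- list(c(0, 0), c(50, 50), c(100, 100), c(100, 0), c(30, 99),
                 c(77, 13))
  for (i in seq_along(sc_off))
    se_pair(sc_off[[i]][1], sc_off[[i]][2], TRUE, "single_close",
            sprintf("sc%02d", i))
  # beyond tolerance but identical stop site: not merged, same gene
  se_pair(101, 0, FALSE, "single_far_samestop", "sf01", same_gene = TRUE)
  se_pair(120, 0, FALSE, "single_far_samestop", "sf02", same_gene = TRUE)
  # beyond tolerance on both ends: not merged, separate genes
  se_pair(150, 180, FALSE, "single_far", "sf03")
  se_pair(101, 101, FALSE, "single_far", "sf04")
  # opposite-strand overlaps with identical junctions: never merged
  for (i in 1:3) {
    L <- new_locus()
    ida <- sprintf("A_os%02d", i); idb <- sprintf("B_os%02d", i)
    exa <- multiexon(L$base)
    add_tx(ida, "A", L$chrom, "+", stats::runif(1, 2, 200), exa, L$gene)
    add_tx(idb, "B", L$chrom, "-", stats::runif(1, 2, 200), exa,
           paste0(L$gene, "_rev"))
    len <- sum(exa[, 2] - exa[, 1] + 1)
    add_mass(ida, "A", stats::runif(1, 80, 300) * len)
    add_mass(idb, "B", stats::runif(1, 80, 300) * len)
    pairs[[length(pairs) + 1L]] <- data.frame(
      tx_a = ida, tx_b = idb, must_merge = FALSE, case = "opposite_strand",
      stringsAsFactors = FALSE)
  }
  # within-strain isoform pairs sharing a junction; shared-mass group
  for (i in 1:4) {
    L <- new_locus()
    id1 <- sprintf("A_iso%02da", i); id2 <- sprintf("A_iso%02db", i)
    ex1 <- cbind(L$base + c(0, 2000), L$base + c(499, 2599))
    ex2 <- cbind(L$base + c(250, 2000), L$base + c(499, 2899))
    add_tx(id1, "A", L$chrom, "+", stats::runif(1, 2, 200), ex1, L$gene)
    add_tx(id2, "A", L$chrom, "+", stats::runif(1, 2, 200), ex2, L$gene)
    grp <- sprintf("grp_iso%02d", i)
    add_mass(id1, "A", stats::runif(1, 80, 300) * 1100, grp, 5e4)
    add_mass(id2, "A", stats::runif(1, 80, 300) * 1150, grp, 5e4)
  }
  # one rescue case: coverage below threshold in one strain only
  rescue_id <- mm_pair(60, 10, "rescue")
  # low-coverage decoys: below 50 in both strains (10% of survivors)
  decoy_ids <- vapply(1:5, function(i)
    mm_pair(stats::runif(1, 5, 20), stats::runif(1, 5, 20),
            sprintf("dec%02d", i)), character(1))
  # high-confidence filter decoys
  hc <- list()
  for (i in 1:4) {
    L <- new_locus()
    id <- sprintf("A_lowfpkm%02d", i)
    add_tx(id, "A", L$chrom, "+", stats::runif(1, 0.1, 0.9),
           cbind(L$base, L$base + 999), L$gene)
    add_mass(id, "A", 1e5)
    hc[[length(hc) + 1L]] <- data.frame(transcript_id = id,
                                        reason = "low_fpkm")
  }
  short_len <- c(150, 220, 280, 300)  # 300 bp does not exceed the minimum
  for (i in 1:4) {
    L <- new_locus()
    id <- sprintf("A_short%02d", i)
    add_tx(id, "A", L$chrom, "+", stats::runif(1, 2, 200),
           cbind(L$base, L$base + short_len[i] - 1), L$gene)
    add_mass(id, "A", 1e5)
    hc[[length(hc) + 1L]] <- data.frame(transcript_id = id, reason = "short")
  }

  txdf <- do.call(rbind, tx); exdf <- do.call(rbind, ex)
  massdf <- read_mass_profile(do.call(rbind, mass))
  a <- txdf$strain == "A"
  list(
    tx_a = transcript_set(txdf[a, ], exdf[exdf$transcript_id %in%
                                            txdf$transcript_id[a], ]),
    tx_b = transcript_set(txdf[!a, ], exdf[exdf$transcript_id %in%
                                             txdf$transcript_id[!a], ]),
    mass = massdf,
    truth = list(pairs = do.call(rbind, pairs),
                 hc_decoys = do.call(rbind, hc),
                 low_coverage = decoy_ids,
                 rescue = rescue_id,
                 gene_of = gene_of))
}

#' Simulate probe and probe-set records plus intensity/DABG matrices
#'
#' Probe sets are planted inside genes (clean), across gene boundaries,
#' inside the overlap of two genes, or intergenic; some probes carry
#' multi-alignment, imperfect-alignment or variant-overlap flags, and some
#' probe sets lose enough probes to fall under the survivor minimum.
#' Intensities are gene signal + probe-set effect + noise on the log2
#' scale; planted "absent" gene clusters get uniform DABG p-values so the
#' detection filter removes them.
#'
#' @param genes a `gene_groups` object (see [group_into_genes()]).
#' @param config a [simulation_config()].
#' @param frac_absent fraction of genes planted as unexpressed.
#' @return list with `probes`, `probesets`, `intensity`, `dabg`,
#'   `sample_strain`, `truth`.
#' @export
simulate_probe_data <- function(genes, config, frac_absent = 0.15) {
  stopifnot(inherits(genes, "gene_groups"), inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "probe_data"))
  gexon <- genes$exons
  gids <- genes$genes$gene_id

  probes <- list(); psets <- list(); truth <- list()
  add_pset <- function(pid, gene, chrom, start, status,
                       n_bad = 0L, bad_kind = "multi") {
    psets[[length(psets) + 1L]] <<- data.frame(
      probeset_id = pid, chrom = chrom, start = start, end = start + 79,
      stringsAsFactors = FALSE)
    offs <- c(0, 20, 40, 55)
    for (j in 1:4) {
      bad <- j <= n_bad
      probes[[length(probes) + 1L]] <<- data.frame(
        probe_id = sprintf("%s_p%d", pid, j), probeset_id = pid,
        alignment_count = if (bad && bad_kind == "multi") 2L else 1L,
        perfect_alignment = !(bad && bad_kind == "imperfect"),
        variant_overlap = bad && bad_kind == "variant",
        chrom = chrom, start = start + offs[j], end = start + offs[j] + 24,
        stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      probeset_id = pid, gene_id = gene, status = status,
      stringsAsFactors = FALSE)
  }

  bad_kinds <- c("multi", "imperfect", "variant")
  for (i in seq_along(gids)) {
    g <- gids[i]
    exi <- gexon[gexon$gene_id == g & (gexon$end - gexon$start + 1) >= 120, ,
                 drop = FALSE]
    if (nrow(exi) == 0L) next
    e <- exi[1L, ]
    # clean probe set fully inside the first wide exonic block
    add_pset(sprintf("ps_%03d_a", i), g, e$chrom, e$start + 10, "retain")
    # every third gene: one contaminated probe (set still has 3 survivors)
    if (i %% 3L == 0L)
      add_pset(sprintf("ps_%03d_b", i), g, e$chrom, e$start + 15, "retain",
               n_bad = 1L, bad_kind = bad_kinds[(i %/% 3L) %% 3L + 1L])
    # every fifth gene: probe set losing 2 probes -> eliminated
    if (i %% 5L == 0L)
      add_pset(sprintf("ps_%03d_c", i), g, e$chrom, e$start + 20,
               "eliminated_probeset", n_bad = 2L, bad_kind = "variant")
    # every fourth gene: probe set crossing the gene's exon boundary
    if (i %% 4L == 0L) {
      last <- exi[nrow(exi), ]
      add_pset(sprintf("ps_%03d_d", i), g, last$chrom, last$end - 29,
               "excluded_boundary")
    }
  }
  # probe sets inside the exonic overlap of two genes -> ambiguous
  ov <- gene_exon_overlaps(genes, min_width = 100L)
  if (nrow(ov) > 0L) {
    for (i in seq_len(min(4L, nrow(ov))))
      add_pset(sprintf("ps_amb_%02d", i), NA_character_, ov$chrom[i],
               ov$start[i] + 5, "excluded_ambiguous")
  }
  # intergenic probe sets far from every gene
  for (i in 1:3)
    add_pset(sprintf("ps_int_%02d", i), NA_character_, "chr9",
             5e7 + i * 1e4, "intergenic")

  probes <- do.call(rbind, probes)
  psets <- do.call(rbind, psets)
  truthdf <- do.call(rbind, truth)

  # intensity + DABG matrices over strains x replicates
  n_s <- config$n_strains; reps <- config$replicates_per_strain
  samples <- sprintf("strain_%02d_r%d", rep(seq_len(n_s), each = reps),
                     rep(seq_len(reps), n_s))
  sample_strain <- stats::setNames(
    sprintf("strain_%02d", rep(seq_len(n_s), each = reps)), samples)
  absent <- gids[stats::runif(length(gids)) < frac_absent]
  gene_mu <- stats::setNames(stats::rnorm(length(gids), 8, 1), gids)
  strain_eff <- matrix(stats::rnorm(length(gids) * n_s, 0, 0.5),
                       length(gids), n_s, dimnames = list(gids, NULL))
  intensity <- matrix(NA_real_, nrow(psets), length(samples),
                      dimnames = list(psets$probeset_id, samples))
  dabg <- intensity
  ps_gene <- truthdf$gene_id[match(psets$probeset_id, truthdf$probeset_id)]
  for (r in seq_len(nrow(psets))) {
    g <- ps_gene[r]
    ps_eff <- stats::rnorm(1, 0, 0.3)
    if (is.na(g) || g %in% absent) {
      intensity[r, ] <- stats::rnorm(length(samples), 3, 0.5)
      dabg[r, ] <- stats::runif(length(samples))
    } else {
      mu <- gene_mu[g] + strain_eff[g, rep(seq_len(n_s), each = reps)]
      intensity[r, ] <- mu + ps_eff + stats::rnorm(length(samples), 0, 0.2)
      lowp <- 10^(-stats::runif(length(samples), 5, 9))
      miss <- stats::runif(length(samples)) < 0.02
      dabg[r, ] <- ifelse(miss, stats::runif(length(samples)), lowp)
    }
  }
  list(probes = probes, probesets = psets, intensity = intensity,
       dabg = dabg, sample_strain = sample_strain,
       truth = list(probesets = truthdf, absent_genes = absent))
}

#' Simulate gene-set annotations and a phenotypic QTL catalog
#'
#' Produces GMT-style term sets with one term planted to be enriched in a
#' chosen module (containing over half of its genes), the remaining terms
#' random, and a QTL catalog whose intervals do and do not contain the
#' planted meQTL peaks, with LOD values straddling the reporting
#' threshold of 10.
#'
#' @param panel_truth truth component of [simulate_expression_panel()].
#' @param genotypes the `genotype_matrix` the panel was built on.
#' @param config a [simulation_config()].
#' @param n_terms number of annotation terms.
#' @param planted_module module index the enriched term is planted in.
#' @return list with `annotations` (named list of gene vectors),
#'   `reference` (gene universe), `catalog` (data.frame name, trait,
#'   chrom, start, end, lod), `planted_term`, `planted_module`.
#' @export
simulate_annotation_and_qtl_catalog <- function(panel_truth, genotypes,
                                                config, n_terms = 30L,
                                                planted_module = 1L) {
  stopifnot(!is.null(panel_truth$membership), inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "annotation_catalog"))
  genes <- panel_truth$membership$gene
  mod_genes <- genes[panel_truth$membership$module == planted_module]
  if (length(mod_genes) == 0L) stop("planted module has no genes")

  planted <- c(sample(mod_genes, ceiling(0.6 * length(mod_genes))),
               sample(setdiff(genes, mod_genes), 5L))
  anns <- list(term_planted = planted)
  for (i in seq_len(n_terms - 1L))
    anns[[sprintf("term_%03d", i)]] <-
      sample(genes, sample(10:30, 1L))

  traits <- c("body weight", "blood pressure", "insulin level",
              "bone mineral density", "arthritis severity")
  cat_rows <- list()
  for (k in seq_along(panel_truth$qtl_marker)) {
    mk <- genotypes$map[panel_truth$qtl_marker[k], ]
    cat_rows[[length(cat_rows) + 1L]] <- data.frame(
      name = sprintf("qtl_hit_%02d", k), trait = sample(traits, 1L),
      chrom = mk$chrom, start = mk$pos_bp - 5e6, end = mk$pos_bp + 5e6,
      lod = stats::runif(1, 12, 40), stringsAsFactors = FALSE)
    cat_rows[[length(cat_rows) + 1L]] <- data.frame(
      name = sprintf("qtl_weak_%02d", k), trait = sample(traits, 1L),
      chrom = mk$chrom, start = mk$pos_bp - 5e6, end = mk$pos_bp + 5e6,
      lod = stats::runif(1, 3, 9.5), stringsAsFactors = FALSE)
    cat_rows[[length(cat_rows) + 1L]] <- data.frame(
      name = sprintf("qtl_off_%02d", k), trait = sample(traits, 1L),
      chrom = mk$chrom, start = mk$pos_bp + 1e7, end = mk$pos_bp + 1.5e7,
      lod = stats::runif(1, 12, 40), stringsAsFactors = FALSE)
  }
  list(annotations = anns, reference = genes,
       catalog = do.call(rbind, cat_rows),
       planted_term = "term_planted", planted_module = planted_module)
}

#' Simulate a cell-type x strain x replicate expression panel
#'
#' Additive log2-scale model: gene mean + strain effect + planted
#' cell-type effects (for a known differential subset, half of which get a
#' dominant Kupffer-cell effect, and a sub-subset strain-dependent
#' effects) + replicate noise. The truth record lists differential genes,
#' the cell type with maximal mean, and interaction status.
#'
#' @param config a [simulation_config()]; only the seed is used.
#' @param n_genes number of genes.
#' @param n_differential genes with planted cell-type effects.
#' @param effect_sd scale of planted cell effects (log2 units).
#' @param replicates replicates per (cell type, strain).
#' @return list with `panel` (long data.frame: gene, cell_type, strain,
#'   replicate, value) and `truth`.
#' @export
simulate_celltype_expression <- function(config, n_genes = 200L,
                                         n_differential = 40L,
                                         effect_sd = 1.5, replicates = 4L) {
  stopifnot(inherits(config, "simulation_config"), replicates >= 2)
  set.seed(stage_seed(config$seed, "celltype_expression"))
  cells <- c("HC", "HSC", "SEC", "KC")
  strains <- c("A", "B")
  genes <- sprintf("ct_g%04d", seq_len(n_genes))
  diff_genes <- genes[seq_len(n_differential)]
  kc_genes <- diff_genes[seq_len(n_differential %/% 2L)]
  int_genes <- diff_genes[seq(1L, n_differential, by = 3L)]

  grid <- expand.grid(cell_type = cells, strain = strains,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  rows <- vector("list", n_genes)
  truth <- data.frame(gene = genes, differential = genes %in% diff_genes,
                      kc_max = FALSE, interaction = genes %in% int_genes,
                      max_cell = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    mu <- stats::rnorm(1, 8, 1)
    strain_eff <- stats::setNames(stats::rnorm(2, 0, 0.3), strains)
    cell_eff <- stats::setNames(rep(0, 4), cells)
    int_eff <- matrix(0, 4, 2, dimnames = list(cells, strains))
    if (g %in% diff_genes) {
      cell_eff[] <- stats::rnorm(4, 0, effect_sd)
      if (g %in% kc_genes)
        cell_eff["KC"] <- max(cell_eff) + 1
      if (g %in% int_genes)
        int_eff[, "A"] <- stats::rnorm(4, 0, effect_sd)
    }
    val <- mu + strain_eff[grid$strain] + cell_eff[grid$cell_type] +
      int_eff[cbind(grid$cell_type, grid$strain)] +
      stats::rnorm(nrow(grid), 0, 0.3)
    rows[[i]] <- data.frame(gene = g, grid, value = as.numeric(val),
                            stringsAsFactors = FALSE)
    cm <- cell_eff + rowMeans(int_eff)
    truth$max_cell[i] <- names(which.max(cm))
    truth$kc_max[i] <- truth$max_cell[i] == "KC"
  }
  list(panel = do.call(rbind, rows), truth = truth)
}
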