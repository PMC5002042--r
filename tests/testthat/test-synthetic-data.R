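# Synthetic-data generator: genotype mosaic structure, planted expression
# modules, truth-record sufficiency, reproducibility.

test_that("RI genotype mosaic follows the Markov switch model", {
  # no recombination: every chromosome of every strain is constant
  cfg0 <- simulation_config(seed = 5, recomb_prob = 0,
                            n_chromosomes = 3, markers_per_chromosome = 10)
  g0 <- simulate_ri_genotypes(cfg0)
  for (ch in unique(g0$map$chrom)) {
    sub <- g0$alleles[, g0$map$chrom == ch, drop = FALSE]
    expect_true(all(apply(sub, 1L, function(x) length(unique(x)) == 1L)))
  }

  # free recombination: adjacent-marker agreement near 1/2
  cfg5 <- simulation_config(seed = 5, n_strains = 400, recomb_prob = 0.5,
                            n_chromosomes = 2, markers_per_chromosome = 30)
  g5 <- simulate_ri_genotypes(cfg5)
  agree <- mean(sapply(unique(g5$map$chrom), function(ch) {
    sub <- g5$alleles[, g5$map$chrom == ch, drop = FALSE]
    mean(sub[, -1L] == sub[, -ncol(sub)])
  }))
  expect_equal(agree, 0.5, tolerance = 0.05)

  # marginal allele frequency 0.5 at large n: each marker is a
  # Bernoulli(0.5) sample of 500 strains (sd 0.022), so nearly all
  # markers sit within 0.05 of one half and the overall mean is tight
  cfgN <- simulation_config(seed = 11, n_strains = 500, recomb_prob = 0.1)
  gN <- simulate_ri_genotypes(cfgN)
  dev <- abs(colMeans(gN$alleles) - 0.5)
  expect_lt(mean(dev > 0.05), 0.05)
  expect_lt(max(dev), 0.1)
  expect_equal(mean(gN$alleles), 0.5, tolerance = 0.01)
})

test_that("genotype simulation is deterministic in the seed and validates", {
  cfg <- simulation_config(seed = 9)
  expect_identical(simulate_ri_genotypes(cfg), simulate_ri_genotypes(cfg))
  g1 <- simulate_ri_genotypes(simulation_config(seed = 1))
  g2 <- simulate_ri_genotypes(simulation_config(seed = 2))
  expect_false(identical(g1$alleles, g2$alleles))
  expect_error(simulation_config(n_strains = 0), "positive")
  expect_error(simulation_config(recomb_prob = 1.5), "recomb_prob")
  # positions strictly increase within chromosomes
  for (ch in unique(g1$map$chrom))
    expect_true(all(diff(g1$map$pos_bp[g1$map$chrom == ch]) > 0))
  expect_true(all(g1$alleles %in% c(0L, 1L)))
})

test_that("planted module drivers carry the configured genotype variance", {
  # zero effect: driver uncorrelated with the marker on average
  r0 <- sapply(1:200, function(s) {
    cfg <- simulation_config(seed = s, n_strains = 20,
      module_specs = list(module_spec(5, 10, qtl_effect_fraction = 0)),
      n_background_genes = 0)
    g <- simulate_ri_genotypes(cfg)
    p <- simulate_expression_panel(g, cfg)
    cor(p$truth$drivers[, 1], g$alleles[, 10])
  })
  expect_equal(mean(r0), 0, tolerance = 0.03)

  # degenerate deterministic case: genes equal standardized genotype
  cfg1 <- simulation_config(seed = 3, n_strains = 20,
    module_specs = list(module_spec(4, 10, qtl_effect_fraction = 1 - 1e-12,
                                    gene_loading_range = c(1, 1),
                                    noise_sd = 0)),
    n_background_genes = 0)
  g1 <- simulate_ri_genotypes(cfg1)
  p1 <- simulate_expression_panel(g1, cfg1)
  gz <- unname(scale(g1$alleles[, 10])[, 1])
  for (j in 1:4) expect_equal(unname(p1$expression[, j]), gz,
                              tolerance = 1e-5)

  # variance decomposition: R^2(driver, genotype) near the planted 0.5
  # (Monte-Carlo mean over seeds; single large-sample draws sit within
  # about two sampling standard deviations of 0.5)
  r2 <- sapply(1:10, function(s) {
    cfgL <- simulation_config(seed = s, n_strains = 1000,
      module_specs = list(module_spec(5, 40, qtl_effect_fraction = 0.5)),
      n_background_genes = 0)
    gL <- simulate_ri_genotypes(cfgL)
    pL <- simulate_expression_panel(gL, cfgL)
    cor(pL$truth$drivers[, 1], gL$alleles[, 40])^2
  })
  expect_lt(abs(mean(r2) - 0.5), 0.05)
  expect_true(all(abs(r2 - 0.5) < 0.1))
})

test_that("expression panel truth record is complete and consistent", {
  cfg <- simulation_config(seed = 4)
  g <- simulate_ri_genotypes(cfg)
  p <- simulate_expression_panel(g, cfg)
  sizes <- vapply(cfg$module_specs, `[[`, integer(1), "size")
  expect_identical(ncol(p$expression),
                   sum(sizes) + cfg$n_background_genes)
  expect_identical(as.integer(table(p$truth$membership$module)[-1L]),
                   sizes)
  expect_identical(p$truth$membership$gene, colnames(p$expression))
  expect_length(p$truth$qtl_marker, length(sizes))
  # invalid marker index is rejected up front
  expect_error(simulation_config(
    module_specs = list(module_spec(5, 9999))), "marker")
})

test_that("transcriptome fixture plants the documented merge and filter cases", {
  cfg <- simulation_config(seed = 2)
  tx <- simulate_strain_transcriptomes(cfg)
  tr <- tx$truth
  expect_true(all(c("pairs", "hc_decoys", "low_coverage", "gene_of") %in%
                    names(tr)))
  # identical-junction pairs are marked must-merge by construction
  expect_true(all(tr$pairs$must_merge[tr$pairs$case == "multiexon"]))
  # the 100/101 bp boundary is planted on both sides
  expect_true(any(tr$pairs$case == "single_close" & tr$pairs$must_merge))
  expect_true(any(grepl("single_far", tr$pairs$case) & !tr$pairs$must_merge))
  expect_true(any(tr$pairs$case == "opposite_strand" & !tr$pairs$must_merge))
  # every planted transcript has a truth gene label
  ids <- c(tx$tx_a$transcripts$transcript_id,
           tx$tx_b$transcripts$transcript_id)
  expect_true(all(ids %in% names(tr$gene_of)))
  # byte-identical regeneration under the same seed
  expect_identical(tx, simulate_strain_transcriptomes(cfg))
})

test_that("cell-type panel plants calibrated null genes and known effects", {
  cfg <- simulation_config(seed = 6)
  ct <- simulate_celltype_expression(cfg, n_genes = 60, n_differential = 12)
  expect_identical(sum(ct$truth$differential), 12L)
  # planted Kupffer-dominant genes have KC as max cell in truth
  kc <- ct$truth$gene[ct$truth$kc_max]
  expect_gt(length(kc), 0L)
  agg <- aggregate(value ~ gene + cell_type,
                   ct$panel[ct$panel$gene %in% kc, ], mean)
  for (g in kc) {
    sub <- agg[agg$gene == g, ]
    expect_identical(sub$cell_type[which.max(sub$value)], "KC")
  }
  # balanced design: equal cells per (cell, strain)
  expect_true(all(table(ct$panel$gene, ct$panel$cell_type,
                        ct$panel$strain) == 4L))
})
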