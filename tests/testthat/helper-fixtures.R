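# Shared builders for small in-code fixtures.

# transcript_set from a compact spec: list(id = list(strain, chrom, strand,
# fpkm, exons-matrix))
make_ts <- function(spec) {
  tx <- do.call(rbind, lapply(names(spec), function(id) {
    s <- spec[[id]]
    data.frame(transcript_id = id, strain = s$strain, chrom = s$chrom,
               strand = s$strand, fpkm = s$fpkm, stringsAsFactors = FALSE)
  }))
  ex <- do.call(rbind, lapply(names(spec), function(id) {
    e <- spec[[id]]$exons
    data.frame(transcript_id = id, start = e[, 1], end = e[, 2])
  }))
  transcript_set(tx, ex)
}

simple_tx <- function(strain = "A", chrom = "chr1", strand = "+", fpkm = 10,
                      exons = cbind(1000, 2500)) {
  list(strain = strain, chrom = chrom, strand = strand, fpkm = fpkm,
       exons = exons)
}

# mass profile rows
mass_row <- function(id, strain, unique_mass, grp = NA_character_,
                     gm = NA_real_) {
  data.frame(transcript_id = id, strain = strain, unique_mass = unique_mass,
             shared_group_id = grp, group_mass = gm,
             stringsAsFactors = FALSE)
}

# strains x genes expression with two planted correlated blocks on top of
# noise
blocky_expression <- function(n_strains = 30, block_sizes = c(20, 20),
                              n_noise = 20, within_cor = 0.9, seed = 42) {
  set.seed(seed)
  cols <- list()
  truth <- integer(0)
  for (b in seq_along(block_sizes)) {
    d <- rnorm(n_strains)
    lam <- sqrt(within_cor)
    cols[[b]] <- sapply(seq_len(block_sizes[b]), function(i)
      lam * d + sqrt(1 - lam^2) * rnorm(n_strains))
    truth <- c(truth, rep(b, block_sizes[b]))
  }
  x <- cbind(do.call(cbind, cols),
             matrix(rnorm(n_strains * n_noise), n_strains))
  truth <- c(truth, rep(0L, n_noise))
  colnames(x) <- sprintf("g%03d", seq_len(ncol(x)))
  list(expression = x, truth = truth)
}
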