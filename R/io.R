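# Plain-text I/O for genotype matrices and QTL catalogs.

#' Write / read a genotype matrix as TSV
#'
#' Two files: `<stem>_alleles.tsv` (strain x marker 0/1 table with a
#' leading `strain` column) and `<stem>_map.tsv` (marker, chrom, pos_bp).
#'
#' @param genotypes a `genotype_matrix`.
#' @param stem path stem.
#' @return `read_genotype_tsv`: a `genotype_matrix`.
#' @export
write_genotype_tsv <- function(genotypes, stem) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  write_matrix_tsv(genotypes$alleles, paste0(stem, "_alleles.tsv"), "strain")
  write_tsv(genotypes$map, paste0(stem, "_map.tsv"))
  invisible(stem)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(stem) {
  al <- read_tsv(paste0(stem, "_alleles.tsv"), check.names = FALSE)
  map <- read_tsv(paste0(stem, "_map.tsv"))
  alleles <- as.matrix(al[, -1L, drop = FALSE])
  rownames(alleles) <- al[[1L]]
  storage.mode(alleles) <- "integer"
  stopifnot(identical(colnames(alleles), map$marker))
  structure(list(alleles = alleles, map = map), class = "genotype_matrix")
}

#' Write / read a phenotypic QTL catalog as TSV
#'
#' Columns: name, trait, chrom, start, end, lod.
#'
#' @param catalog data.frame in the above layout.
#' @param file path.
#' @return `read_qtl_catalog`: the catalog data.frame.
#' @export
write_qtl_catalog <- function(catalog, file) {
  need <- c("name", "trait", "chrom", "start", "end", "lod")
  stopifnot(all(need %in% names(catalog)))
  write_tsv(catalog[, need], file)
}

#' @rdname write_qtl_catalog
#' @export
read_qtl_catalog <- function(file) read_tsv(file)
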