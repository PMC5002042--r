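# Biological interpretation of modules: gene-set overrepresentation
# (binomial tail with Bonferroni adjustment) and overlap of meQTL peaks
# with a phenotypic QTL catalog.

#' Gene-set overrepresentation test for a module
#'
#' For each annotation term, counts module genes annotated to the term
#' and compares against the reference rate with an exact binomial tail:
#' `p_raw = P(X >= k)`, `X ~ Binomial(n, m/N)` where `n` is the number of
#' module genes in the reference, `m` the term's genes in the reference
#' and `N` the reference size. A Bonferroni adjustment over the terms
#' actually tested is applied. Modules with fewer than `min_annotated`
#' annotated genes are not tested (underpowered), and a term is only
#' flagged significant when at least `min_term_hits` module genes carry
#' it, guarding against single-gene artifacts.
#'
#' @param module_genes character vector of module gene ids.
#' @param annotations named list of gene vectors (GMT-style term sets).
#' @param reference gene universe: the genes included in the network
#'   analysis.
#' @param min_annotated minimum annotated module genes for testing.
#' @param min_term_hits minimum module genes per reported term.
#' @param alpha adjusted-p significance threshold.
#' @param method `"binomial"` (default) or `"hypergeometric"` tail.
#' @return data.frame (term, k, n, m, N, fold, p_raw, p_adjusted,
#'   significant), sorted by adjusted then raw p; zero rows with
#'   attribute `tested = FALSE` when the module fails the
#'   `min_annotated` gate.
#' @export
overrepresentation_test <- function(module_genes, annotations, reference,
                                    min_annotated = 10L, min_term_hits = 2L,
                                    alpha = 0.05,
                                    method = c("binomial",
                                               "hypergeometric")) {
  method <- match.arg(method)
  stopifnot(is.list(annotations), length(annotations) > 0L)
  mod <- intersect(unique(module_genes), reference)
  if (length(mod) == 0L)
    stop("overrepresentation_test: module disjoint from the reference set")
  N <- length(unique(reference))
  n <- length(mod)

  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      m = integer(0), N = integer(0), fold = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0))
  annotated <- intersect(mod, unique(unlist(annotations)))
  if (length(annotated) < min_annotated) {
    message(sprintf(
      "module skipped: %d annotated gene(s), fewer than the minimum %d",
      length(annotated), min_annotated))
    attr(empty, "tested") <- FALSE
    return(empty)
  }

  rows <- lapply(names(annotations), function(term) {
    tg <- intersect(unique(annotations[[term]]), reference)
    m <- length(tg)
    if (m == 0L) return(NULL)
    k <- length(intersect(tg, mod))
    p_raw <- if (method == "binomial")
      stats::pbinom(k - 1L, n, m / N, lower.tail = FALSE)
    else
      stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, m = m, N = N,
               fold = (k / n) / (m / N), p_raw = p_raw,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    attr(empty, "tested") <- TRUE
    return(empty)
  }
  rows$p_adjusted <- pmin(1, rows$p_raw * nrow(rows))
  rows$significant <- rows$p_adjusted < alpha & rows$k >= min_term_hits
  rows <- rows[order(rows$p_adjusted, rows$p_raw, rows$term), ]
  rownames(rows) <- NULL
  attr(rows, "tested") <- TRUE
  rows
}

#' Phenotypic QTLs overlapping an meQTL peak
#'
#' Returns catalog entries whose interval contains the peak position on
#' the same chromosome and whose LOD meets `lod_min` (inclusive), sorted
#' by decreasing LOD. Malformed intervals are skipped with a warning.
#'
#' @param peak_chrom,peak_pos peak coordinates.
#' @param catalog data.frame (name, trait, chrom, start, end, lod).
#' @param lod_min minimum catalog LOD (inclusive).
#' @return the overlapping subset of `catalog`.
#' @export
phenotypic_qtl_overlap <- function(peak_chrom, peak_pos, catalog,
                                   lod_min = 10) {
  need <- c("name", "trait", "chrom", "start", "end", "lod")
  stopifnot(all(need %in% names(catalog)))
  bad <- is.na(catalog$start) | is.na(catalog$end) |
    catalog$start > catalog$end
  if (any(bad)) {
    warning(sprintf("skipping %d malformed catalog interval(s)", sum(bad)))
    catalog <- catalog[!bad, , drop = FALSE]
  }
  hit <- catalog$chrom == peak_chrom & catalog$start <= peak_pos &
    catalog$end >= peak_pos & catalog$lod >= lod_min
  out <- catalog[hit, , drop = FALSE]
  out[order(-out$lod), , drop = FALSE]
}

#' Read or write GMT gene-set files
#'
#' Reading delegates to `fgsea::gmtPathways()`; writing emits the
#' standard three-plus columns (term, description, genes...).
#'
#' @param file path.
#' @param annotations named list of gene-id vectors.
#' @param descriptions optional named descriptions (defaults to `"na"`).
#' @return `read_gmt`: named list of gene vectors.
#' @export
read_gmt <- function(file) fgsea::gmtPathways(file)

#' @rdname read_gmt
#' @export
write_gmt <- function(annotations, file, descriptions = NULL) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  lines <- vapply(names(annotations), function(term) {
    desc <- descriptions[[term]] %||% "na"
    paste(c(term, desc, annotations[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
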