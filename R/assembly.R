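# Combined two-strain transcriptome assembly: high-confidence filtering,
# cross-strain merging, gene grouping, and coverage-based iterative
# reduction.

#' Filter transcripts to high-confidence status
#'
#' Retains transcripts with expression at or above `fpkm_min` and a
#' transcribed length strictly exceeding `length_min` base pairs (the
#' length a fragment must exceed to survive the RNA extraction and
#' library size-selection steps).
#'
#' @param ts a `transcript_set`.
#' @param fpkm_min minimum FPKM (inclusive).
#' @param length_min minimum length in bp (exclusive).
#' @return the filtered `transcript_set`, order preserved.
#' @export
filter_high_confidence <- function(ts, fpkm_min = 1, length_min = 300) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(ts$transcripts) == 0L) return(ts)
  if (any(is.na(ts$transcripts$fpkm)))
    stop("filter_high_confidence: missing FPKM values")
  if (any(ts$transcripts$fpkm < 0))
    stop("filter_high_confidence: negative FPKM")
  len <- transcript_lengths(ts)
  keep <- ts$transcripts$fpkm >= fpkm_min & len > length_min
  subset_transcript_set(ts, ts$transcripts$transcript_id[keep])
}

subset_transcript_set <- function(ts, ids) {
  transcript_set(ts$transcripts[ts$transcripts$transcript_id %in% ids, ,
                                drop = FALSE],
                 ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE])
}

#' Merge two strain-specific transcriptomes
#'
#' An A/B transcript pair is merged when the transcripts overlap on the
#' same chromosome, are on the same strand (or at least one strand is
#' undesignated), and either (1) all splice junctions match, or (2) both
#' are single-exon and their start and stop sites are each within
#' `end_tolerance` bp (inclusive). Merged transcripts take the union span
#' and the shared junction chain; transcripts from the same strain are
#' never merged directly, though several may join through a shared partner.
#'
#' @param tx_a,tx_b high-confidence `transcript_set`s for the two strains.
#' @param end_tolerance single-exon start/stop tolerance in bp.
#' @return list with `transcripts` (combined `transcript_set`; merged
#'   entries have strain `"merged"` and id `memberA+memberB`) and
#'   `provenance` (data.frame transcript_id, source_id, source_strain).
#' @export
merge_strain_transcriptomes <- function(tx_a, tx_b, end_tolerance = 100) {
  stopifnot(inherits(tx_a, "transcript_set"), inherits(tx_b, "transcript_set"))
  comb <- combine_transcript_sets(tx_a, tx_b)
  n_a <- nrow(tx_a$transcripts)
  sp <- transcript_spans(comb)
  jx <- transcript_junctions(comb)
  nex <- lengths(jx) + 1L

  gr <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  ov <- GenomicRanges::findOverlaps(gr[seq_len(n_a)],
                                    gr[-seq_len(n_a)], ignore.strand = TRUE)
  ia <- S4Vectors::queryHits(ov)
  ib <- S4Vectors::subjectHits(ov) + n_a
  ok <- strands_compatible(sp$strand[ia], sp$strand[ib])
  rule1 <- nex[ia] > 1L & nex[ib] > 1L &
    mapply(function(x, y) length(x) == length(y) && all(x == y),
           jx[ia], jx[ib])
  rule2 <- nex[ia] == 1L & nex[ib] == 1L &
    abs(sp$start[ia] - sp$start[ib]) <= end_tolerance &
    abs(sp$end[ia] - sp$end[ib]) <= end_tolerance
  keep <- ok & (rule1 | rule2)
  edges <- cbind(ia[keep], ib[keep])

  ids <- comb$transcripts$transcript_id
  comp <- rep(seq_along(ids), 1L)
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }

  out_tx <- list(); out_ex <- list(); prov <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1L) {
      i <- members
      id <- ids[i]
      out_tx[[length(out_tx) + 1L]] <-
        comb$transcripts[i, , drop = FALSE]
      out_ex[[length(out_ex) + 1L]] <-
        comb$exons[comb$exons$transcript_id == id, , drop = FALSE]
      prov[[length(prov) + 1L]] <- data.frame(
        transcript_id = id, source_id = id,
        source_strain = comb$transcripts$strain[i], stringsAsFactors = FALSE)
      next
    }
    mids <- sort(ids[members])
    new_id <- paste(mids, collapse = "+")
    span_s <- min(sp$start[members]); span_e <- max(sp$end[members])
    juncs <- jx[[ids[members[1L]]]]
    if (length(juncs) > 0L) {
      d <- as.numeric(sub("-.*", "", juncs))
      a <- as.numeric(sub(".*-", "", juncs))
      exons <- data.frame(transcript_id = new_id,
                          start = c(span_s, a), end = c(d, span_e))
    } else {
      exons <- data.frame(transcript_id = new_id,
                          start = span_s, end = span_e)
    }
    strand <- setdiff(unique(sp$strand[members]), "*")
    if (length(strand) != 1L) strand <- "*"
    out_tx[[length(out_tx) + 1L]] <- data.frame(
      transcript_id = new_id, strain = "merged",
      chrom = sp$chrom[members[1L]], strand = strand,
      fpkm = max(comb$transcripts$fpkm[members]), stringsAsFactors = FALSE)
    out_ex[[length(out_ex) + 1L]] <- exons
    prov[[length(prov) + 1L]] <- data.frame(
      transcript_id = new_id, source_id = ids[members],
      source_strain = comb$transcripts$strain[members],
      stringsAsFactors = FALSE)
  }
  list(transcripts = transcript_set(do.call(rbind, out_tx),
                                    do.call(rbind, out_ex)),
       provenance = do.call(rbind, prov))
}

combine_transcript_sets <- function(tx_a, tx_b) {
  if (any(tx_a$transcripts$transcript_id %in% tx_b$transcripts$transcript_id))
    stop("strain transcript sets share transcript ids")
  transcript_set(rbind(tx_a$transcripts, tx_b$transcripts),
                 rbind(tx_a$exons, tx_b$exons))
}

#' Group transcripts into genes
#'
#' Two transcripts belong to the same gene when their transcription start
#' sites match exactly, their transcription stop sites match exactly, or
#' at least one splice junction matches exactly (same chromosome,
#' compatible strands). Genes are the connected components of the
#' resulting graph, so membership is transitive; transcripts with no
#' qualifying partner form singleton genes.
#'
#' @param ts a `transcript_set` (typically the merged transcriptome).
#' @return a `gene_groups` object: list with `genes` (gene_id, chrom,
#'   strand, start, end, n_transcripts), `assignment` (transcript_id,
#'   gene_id) and `exons` (reduced exonic union per gene).
#' @export
group_into_genes <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  sp <- transcript_spans(ts)
  jx <- transcript_junctions(ts)
  n <- nrow(sp)
  if (n == 0L) stop("group_into_genes: empty transcript set")

  # candidate pairs share an exact coordinate key on one chromosome
  keys <- rbind(
    data.frame(i = seq_len(n), key = paste0(sp$chrom, ":S", sp$start)),
    data.frame(i = seq_len(n), key = paste0(sp$chrom, ":E", sp$end)),
    if (sum(lengths(jx)) > 0L)
      data.frame(i = rep(seq_len(n), lengths(jx)),
                 key = paste0(sp$chrom[rep(seq_len(n), lengths(jx))], ":J",
                              unlist(jx))))
  edges <- do.call(rbind, lapply(split(keys$i, keys$key), function(is) {
    is <- unique(is)
    if (length(is) < 2L) return(NULL)
    t(utils::combn(is, 2L))
  }))
  if (!is.null(edges)) {
    ok <- strands_compatible(sp$strand[edges[, 1]], sp$strand[edges[, 2]])
    edges <- edges[ok, , drop = FALSE]
  }
  comp <- seq_len(n)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }

  # order genes by genomic position for stable ids
  comp_start <- tapply(sp$start, comp, min)
  comp_chr <- tapply(sp$chrom, comp, function(x) x[1L])
  ord <- order(comp_chr, comp_start)
  gene_id_of <- stats::setNames(sprintf("gene_%04d", order(ord)),
                                names(comp_start))
  assignment <- data.frame(transcript_id = sp$transcript_id,
                           gene_id = unname(gene_id_of[as.character(comp)]),
                           stringsAsFactors = FALSE)

  ex <- ts$exons
  ex$gene_id <- assignment$gene_id[match(ex$transcript_id,
                                         assignment$transcript_id)]
  ex$chrom <- sp$chrom[match(ex$transcript_id, sp$transcript_id)]
  red <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    ir <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = BiocGenerics::start(ir), end = BiocGenerics::end(ir),
               stringsAsFactors = FALSE)
  }))
  rownames(red) <- NULL

  genes <- do.call(rbind, lapply(split(seq_len(n), assignment$gene_id),
                                 function(is) {
    strand <- setdiff(unique(sp$strand[is]), "*")
    data.frame(gene_id = assignment$gene_id[is[1L]],
               chrom = sp$chrom[is[1L]],
               strand = if (length(strand) == 1L) strand else "*",
               start = min(sp$start[is]), end = max(sp$end[is]),
               n_transcripts = length(is), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  genes <- genes[order(genes$gene_id), ]
  structure(list(genes = genes, assignment = assignment, exons = red),
            class = "gene_groups")
}

#' @export
print.gene_groups <- function(x, ...) {
  cat(sprintf("gene_groups: %d genes over %d transcripts\n",
              nrow(x$genes), nrow(x$assignment)))
  invisible(x)
}

# exonic regions shared between two different genes (used to plant
# ambiguous probe sets)
gene_exon_overlaps <- function(genes, min_width = 1L) {
  stopifnot(inherits(genes, "gene_groups"))
  ex <- genes$exons
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  ov <- GenomicRanges::findOverlaps(gr, gr)
  ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
  ov <- ov[ex$gene_id[S4Vectors::queryHits(ov)] !=
             ex$gene_id[S4Vectors::subjectHits(ov)]]
  if (length(ov) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
  out <- data.frame(chrom = ex$chrom[i],
                    start = pmax(ex$start[i], ex$start[j]),
                    end = pmin(ex$end[i], ex$end[j]),
                    stringsAsFactors = FALSE)
  out[out$end - out$start + 1 >= min_width, , drop = FALSE]
}

#' Collapse a read-mass profile onto merged transcript ids
#'
#' After cross-strain merging, reads that mapped to an original transcript
#' belong to its merged product: unique masses are summed per (merged id,
#' strain) and shared-group memberships are re-keyed.
#'
#' @param mass a `read_mass_profile` keyed by original transcript ids.
#' @param provenance provenance table from [merge_strain_transcriptomes()].
#' @return a `read_mass_profile` keyed by merged transcript ids.
#' @export
collapse_mass_profile <- function(mass, provenance) {
  stopifnot(inherits(mass, "read_mass_profile"))
  new_id <- provenance$transcript_id[match(mass$transcript_id,
                                           provenance$source_id)]
  keep <- !is.na(new_id)
  m <- mass[keep, , drop = FALSE]
  m$transcript_id <- new_id[keep]
  agg <- stats::aggregate(unique_mass ~ transcript_id + strain, m, sum)
  grp <- m[!is.na(m$shared_group_id),
           c("transcript_id", "strain", "shared_group_id", "group_mass")]
  grp <- grp[!duplicated(grp), , drop = FALSE]
  out <- merge(agg, grp, by = c("transcript_id", "strain"), all.x = TRUE)
  read_mass_profile(out)
}

#' Quantitate transcript coverage with shared-mass reallocation
#'
#' Coverage is the average read mass per nucleotide: (unique mass +
#' allocated shared mass) / length. Shared group mass is split among a
#' group's surviving members proportionally to their current coverage
#' estimates, iterated to a fixed point; a group whose members all have
#' zero coverage is split equally.
#'
#' @param ts `transcript_set` of surviving transcripts.
#' @param mass a `read_mass_profile` covering every transcript in `ts`.
#' @param tolerance fixed-point convergence tolerance on coverage.
#' @param max_iter iteration cap.
#' @return matrix of coverage, transcripts x strains.
#' @export
quantitate_coverage <- function(ts, mass, tolerance = 1e-6, max_iter = 100L) {
  stopifnot(inherits(ts, "transcript_set"), inherits(mass, "read_mass_profile"))
  ids <- ts$transcripts$transcript_id
  if (!all(ids %in% mass$transcript_id))
    stop("quantitate_coverage: transcripts missing from the mass profile: ",
         paste(utils::head(setdiff(ids, mass$transcript_id)), collapse = ", "))
  strains <- sort(unique(mass$strain))
  len <- transcript_lengths(ts)
  cov <- matrix(0, length(ids), length(strains),
                dimnames = list(ids, strains))
  for (s in strains) {
    ms <- mass[mass$strain == s & mass$transcript_id %in% ids, , drop = FALSE]
    u <- stats::setNames(rep(0, length(ids)), ids)
    u[ms$transcript_id] <- u[ms$transcript_id] + ms$unique_mass
    groups <- split(ms[!is.na(ms$shared_group_id), , drop = FALSE],
                    ms$shared_group_id[!is.na(ms$shared_group_id)])
    groups <- Filter(function(g) nrow(g) > 0L, groups)
    cv <- u / len[ids]
    for (it in seq_len(max_iter)) {
      alloc <- stats::setNames(rep(0, length(ids)), ids)
      for (g in groups) {
        members <- g$transcript_id
        gm <- g$group_mass[1L]
        w <- cv[members]
        w <- if (sum(w) == 0) rep(1 / length(members), length(members))
             else w / sum(w)
        alloc[members] <- alloc[members] + gm * w
      }
      cv_new <- (u + alloc) / len[ids]
      if (max(abs(cv_new - cv)) < tolerance) { cv <- cv_new; break }
      cv <- cv_new
    }
    cov[, s] <- cv
  }
  cov
}

#' Iteratively reduce the combined transcriptome by coverage
#'
#' Repeatedly quantitates the current transcript set and drops transcripts
#' whose coverage is below `coverage_min` in every strain, until fewer
#' than `stop_fraction` of the remaining transcripts fall below the
#' threshold.
#'
#' @param ts combined `transcript_set`.
#' @param mass matching `read_mass_profile`.
#' @param coverage_min reads-per-nucleotide threshold.
#' @param stop_fraction stop when the marked fraction is below this.
#' @param ... passed to [quantitate_coverage()].
#' @return list: `transcripts` (surviving `transcript_set`), `coverage`
#'   (final matrix), `dropped` (ids removed), `n_iterations`.
#' @export
iterative_reduction <- function(ts, mass, coverage_min = 50,
                                stop_fraction = 0.05, ...) {
  stopifnot(inherits(ts, "transcript_set"))
  dropped <- character(0)
  it <- 0L
  repeat {
    it <- it + 1L
    if (nrow(ts$transcripts) == 0L) {
      warning("iterative_reduction: no transcripts survive")
      return(list(transcripts = ts,
                  coverage = matrix(0, 0, 0), dropped = dropped,
                  n_iterations = it))
    }
    cov <- quantitate_coverage(ts, mass, ...)
    below <- rowSums(cov >= coverage_min) == 0L
    if (mean(below) < stop_fraction)
      return(list(transcripts = ts, coverage = cov, dropped = dropped,
                  n_iterations = it))
    dropped <- c(dropped, rownames(cov)[below])
    ts <- subset_transcript_set(ts, rownames(cov)[!below])
  }
}
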