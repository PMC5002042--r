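# Transcript containers and GTF / read-mass I/O.
#
# A transcript_set holds two tables: one row per transcript (id, strain of
# origin, chromosome, strand, FPKM) and one row per exon (transcript_id,
# start, end). Coordinates are 1-based inclusive, the GTF convention, so
# import/export is a straight mapping onto GRanges.

#' Construct a transcript set
#'
#' @param transcripts data.frame with columns `transcript_id`, `strain`,
#'   `chrom`, `strand` (`+`, `-` or `*` for undesignated), `fpkm`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (1-based inclusive); exons of a transcript must be sorted and
#'   non-overlapping.
#' @return a `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons) {
  need_t <- c("transcript_id", "strain", "chrom", "strand", "fpkm")
  need_e <- c("transcript_id", "start", "end")
  stopifnot(all(need_t %in% names(transcripts)), all(need_e %in% names(exons)))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript ids")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon rows refer to unknown transcripts")
  if (any(exons$end < exons$start)) stop("exon with end < start")
  ord <- order(match(exons$transcript_id, transcripts$transcript_id),
               exons$start)
  exons <- exons[ord, need_e, drop = FALSE]
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L &&
        any(exons$start[idx][-1L] <= exons$end[idx][-length(idx)]))
      stop("overlapping exons within a transcript")
  }
  rownames(transcripts) <- NULL
  rownames(exons) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts (%d exons) on %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

#' Transcript lengths (sum of exon widths, bp)
#'
#' @param ts a `transcript_set`.
#' @return named integer vector over transcripts.
#' @export
transcript_lengths <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  w <- ts$exons$end - ts$exons$start + 1
  len <- tapply(w, ts$exons$transcript_id, sum)
  out <- as.integer(len[ts$transcripts$transcript_id])
  names(out) <- ts$transcripts$transcript_id
  out
}

# genomic span (min start, max end) per transcript, in transcript order
transcript_spans <- function(ts) {
  s <- tapply(ts$exons$start, ts$exons$transcript_id, min)
  e <- tapply(ts$exons$end, ts$exons$transcript_id, max)
  ids <- ts$transcripts$transcript_id
  data.frame(transcript_id = ids,
             chrom = ts$transcripts$chrom,
             strand = ts$transcripts$strand,
             start = as.numeric(s[ids]), end = as.numeric(e[ids]),
             stringsAsFactors = FALSE)
}

# splice junctions as "donorEnd-acceptorStart" strings, list per transcript
transcript_junctions <- function(ts) {
  ids <- ts$transcripts$transcript_id
  ex <- split(ts$exons, ts$exons$transcript_id)
  out <- lapply(ids, function(id) {
    e <- ex[[id]]
    if (is.null(e) || nrow(e) < 2L) return(character(0))
    paste0(e$end[-nrow(e)], "-", e$start[-1L])
  })
  names(out) <- ids
  out
}

#' Write a transcript set as GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id`,
#' `source_strain` and `FPKM` attributes.
#'
#' @param ts a `transcript_set`.
#' @param file output path.
#' @param gene_ids optional named vector transcript_id -> gene_id; defaults
#'   to the transcript id.
#' @return the file path, invisibly.
#' @export
write_transcript_gtf <- function(ts, file, gene_ids = NULL) {
  stopifnot(inherits(ts, "transcript_set"))
  i <- match(ts$exons$transcript_id, ts$transcripts$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = ts$transcripts$chrom[i],
    ranges = IRanges::IRanges(ts$exons$start, ts$exons$end),
    strand = ts$transcripts$strand[i])
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "rixnet"
  tx <- ts$exons$transcript_id
  S4Vectors::mcols(gr)$gene_id <-
    if (is.null(gene_ids)) tx else unname(gene_ids[tx])
  S4Vectors::mcols(gr)$transcript_id <- tx
  S4Vectors::mcols(gr)$source_strain <- ts$transcripts$strain[i]
  S4Vectors::mcols(gr)$FPKM <- ts$transcripts$fpkm[i]
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Read a transcript set from GTF
#'
#' Uses the `exon` features; `transcript_id` is required, `source_strain`
#' and `FPKM` are honoured when present.
#'
#' @param file GTF path.
#' @param strain strain label to use when the file carries none.
#' @return a `transcript_set`.
#' @export
read_transcript_gtf <- function(file, strain = NA_character_) {
  gr <- rtracklayer::import(file, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id)) stop("GTF lacks transcript_id attributes")
  ex <- data.frame(transcript_id = as.character(mc$transcript_id),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  meta <- data.frame(transcript_id = ex$transcript_id,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(BiocGenerics::strand(gr)),
                     strain = if (!is.null(mc$source_strain))
                       as.character(mc$source_strain) else strain,
                     fpkm = if (!is.null(mc$FPKM))
                       as.numeric(mc$FPKM) else NA_real_,
                     stringsAsFactors = FALSE)
  meta <- meta[!duplicated(meta$transcript_id), ]
  transcript_set(
    transcripts = meta[, c("transcript_id", "strain", "chrom", "strand",
                           "fpkm")],
    exons = ex)
}

#' Read/write a read-mass profile
#'
#' The profile is a flat table with one row per (transcript, strain):
#' `transcript_id`, `strain`, `unique_mass` (read-nucleotides mapping only
#' to that transcript) and optional `shared_group_id`/`group_mass` for
#' reads shared among several transcripts (`NA` when the transcript has no
#' shared mass; the group mass is repeated on every member row).
#'
#' @param x data.frame in the above layout.
#' @param file path.
#' @return `read_mass_profile` (a validated data.frame).
#' @export
read_mass_profile <- function(x) {
  need <- c("transcript_id", "strain", "unique_mass")
  stopifnot(all(need %in% names(x)))
  if (is.null(x$shared_group_id)) x$shared_group_id <- NA_character_
  if (is.null(x$group_mass)) x$group_mass <- NA_real_
  if (any(x$unique_mass < 0, na.rm = TRUE) ||
      any(x$group_mass < 0, na.rm = TRUE))
    stop("read masses must be non-negative")
  class(x) <- c("read_mass_profile", "data.frame")
  x
}

#' @rdname read_mass_profile
#' @export
write_read_mass_tsv <- function(x, file) write_tsv(x, file)

#' @rdname read_mass_profile
#' @export
read_read_mass_tsv <- function(file) read_mass_profile(read_tsv(file))
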