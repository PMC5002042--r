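# Unsigned weighted co-expression network: adjacency, scale-free fit,
# topological overlap, dynamic tree cutting, eigengenes, module merging
# and connectivity statistics.

#' Build the unsigned weighted adjacency
#'
#' Similarity is the absolute pairwise Pearson correlation of gene
#' expression across strains; adjacency raises it to a soft-thresholding
#' `power` (default 7) so that weak correlations are suppressed and the
#' connectivity distribution approximates a scale-free network.
#' Zero-variance genes are removed with a warning.
#'
#' @param expr strains x genes expression matrix (strain means).
#' @param power soft-thresholding exponent.
#' @return a `coexpression_network`: list with `genes`, `S` (|r|), `A`
#'   (|r|^power, unit diagonal), `k` (connectivity, diagonal excluded)
#'   and `power`.
#' @export
adjacency_matrix <- function(expr, power = 7) {
  stopifnot(is.matrix(expr), nrow(expr) >= 4L, power > 0)
  v <- apply(expr, 2L, stats::var)
  if (any(v == 0)) {
    warning(sprintf("removing %d zero-variance gene(s)", sum(v == 0)))
    expr <- expr[, v > 0, drop = FALSE]
  }
  S <- abs(stats::cor(expr))
  A <- S^power
  diag(A) <- 1
  diag(S) <- 1
  k <- colSums(A) - 1
  structure(list(genes = colnames(expr), S = S, A = A, k = k, power = power),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, power %g, mean k = %.3f\n",
              length(x$genes), x$power, mean(x$k)))
  invisible(x)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivity into `n_bins` equal-width bins and regresses
#' log10(frequency) on log10(mean bin connectivity). A scale-free network
#' gives a high R-squared and a negative slope; this diagnostic reports
#' (rather than chooses) the fixed soft threshold.
#'
#' @param k connectivity vector.
#' @param n_bins number of bins.
#' @return list with `r_squared`, `slope`, `table` (per-bin mean k and
#'   frequency) and `flag` (`"ok"` or `"degenerate"` when all k equal).
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  stopifnot(is.numeric(k), length(k) >= 2L)
  if (stats::sd(k) == 0)
    return(list(r_squared = NA_real_, slope = NA_real_, table = NULL,
                flag = "degenerate"))
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 2L)
    return(list(r_squared = NA_real_, slope = NA_real_, table = NULL,
                flag = "degenerate"))
  df <- data.frame(log_k = log10(kmean[keep]),
                   log_p = log10(freq[keep] / length(k)))
  fit <- stats::lm(log_p ~ log_k, data = df)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       table = df, flag = "ok")
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' `l_ij = sum_u A_iu A_uj` over shared neighbours `u != i, j`, unit
#' diagonal. Combines the direct connection between two genes with the
#' similarity of their neighbourhoods, damping spurious pairwise
#' correlations.
#'
#' @param A symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return TOM matrix, same dimension, unit diagonal.
#' @export
tom_similarity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  if (min(A) < 0 || max(A) > 1) stop("adjacency entries must be in [0, 1]")
  A0 <- A
  diag(A0) <- 0
  L <- A0 %*% A0
  k <- rowSums(A0)
  denom <- outer(k, k, pmin) + 1 - A0
  stopifnot(all(denom > 0))
  tom <- (L + A0) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect co-expression modules by dynamic tree cutting
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' followed by a two-stage dynamic cut. The initial static cut severs all
#' merges above `cut_height` (an absolute dissimilarity; TOM
#' dissimilarities live in `[0, 1]`, and merges near 1 join effectively
#' unrelated genes). Each resulting large cluster is then refined
#' recursively: internal merges whose height exceeds the cluster's mean
#' merge height plus `split_alpha` standard deviations are severed, and
#' the split is accepted only when it produces at least two parts of
#' `min_module_size` or more — a homogeneous module only sheds outlying
#' clumps at such a cut, so it is kept intact. Accepted parts that are
#' large and internally tighter than their parent are refined further.
#' Genes in clusters smaller than `min_module_size` are left unassigned
#' (label 0).
#'
#' @param D dissimilarity matrix (1 - TOM).
#' @param min_module_size smallest admissible module.
#' @param cut_height absolute dissimilarity height of the static cut.
#' @param split_alpha standard-deviation multiplier of the split rule.
#' @return integer module labels named by gene (0 = unassigned), numbered
#'   1..K by decreasing module size.
#' @export
detect_modules <- function(D, min_module_size = 5L,
                           cut_height = 0.99, split_alpha = 1) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  genes <- rownames(D) %||% sprintf("g%d", seq_len(n))
  if (n < min_module_size)
    return(stats::setNames(integer(n), genes))

  hc <- stats::hclust(stats::as.dist(D), method = "average")
  lab0 <- stats::cutree(hc, h = cut_height)

  # refine one cluster: sever every internal merge whose height exceeds
  # the cluster's mean merge height + split_alpha sd (a multiway cut);
  # accept the split only when >= 2 parts reach min_module_size (a
  # homogeneous cluster only sheds sub-minimum clumps, and is kept
  # whole); recurse into large parts that are tighter than the parent
  split_cluster <- function(idx) {
    if (length(idx) < 2L * min_module_size) return(list(idx))
    subD <- D[idx, idx, drop = FALSE]
    sh <- stats::hclust(stats::as.dist(subD), method = "average")
    hts <- sh$height
    thr <- mean(hts) + split_alpha * stats::sd(hts)
    if (!is.finite(thr) || max(hts) <= thr) return(list(idx))
    parts <- stats::cutree(sh, h = thr)
    sizes <- tabulate(parts)
    if (sum(sizes >= min_module_size) < 2L) return(list(idx))
    whole <- mean_upper(subD)
    out <- list()
    for (pp in seq_len(max(parts))) {
      ip <- idx[parts == pp]
      tighter <- length(ip) >= 2L &&
        isTRUE(mean_upper(D[ip, ip, drop = FALSE]) < whole)
      out <- c(out,
               if (length(ip) >= 2L * min_module_size && tighter)
                 split_cluster(ip)
               else list(ip))
    }
    out
  }

  leaves <- list()
  for (cl in sort(unique(lab0))) {
    idx <- which(lab0 == cl)
    leaves <- c(leaves,
                if (length(idx) >= min_module_size) split_cluster(idx)
                else list(idx))
  }
  keep <- lengths(leaves) >= min_module_size
  labels <- stats::setNames(integer(n), genes)
  mods <- leaves[keep]
  if (length(mods) > 0L) {
    ord <- order(-lengths(mods), vapply(mods, min, numeric(1)))
    for (m in seq_along(ord)) labels[mods[[ord[m]]]] <- m
  }
  labels
}

#' Module eigengene and variance explained
#'
#' Standardizes each member gene across strains and takes the leading
#' left-singular vector over strains as the eigengene (unit norm, first
#' principal component of the module), sign-oriented to correlate
#' positively with the module's mean standardized expression.
#' `variance_explained` is the leading eigenvalue fraction.
#'
#' @param expr strains x members expression matrix.
#' @return list with `eigengene` (vector over strains, unit norm) and
#'   `variance_explained`.
#' @export
module_eigengene <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L, nrow(expr) >= 3L)
  X <- scale(expr)
  if (any(!is.finite(X)))
    stop("module_eigengene: zero-variance member gene")
  sv <- svd(X)
  if (sv$d[1L] == 0) stop("module_eigengene: rank-zero module")
  e <- sv$u[, 1L]
  ref <- rowMeans(X)
  s <- sum(e * ref)
  if (s < 0 || (s == 0 && e[1L] < 0)) e <- -e
  list(eigengene = stats::setNames(e, rownames(expr)),
       variance_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively joins the module pair whose eigengenes have the highest
#' absolute correlation at or above `merge_cor`, recomputing eigengenes
#' after each join, until no pair qualifies. On exit all pairwise
#' eigengene correlations are below the threshold.
#'
#' @param labels integer module labels (0 = unassigned).
#' @param expr strains x genes expression matrix (all genes).
#' @param merge_cor eigengene correlation threshold (inclusive).
#' @return relabelled integer vector, modules renumbered 1..K by
#'   decreasing size.
#' @export
merge_similar_modules <- function(labels, expr, merge_cor = 0.75) {
  stopifnot(length(labels) == ncol(expr))
  labels <- as.integer(labels)
  names(labels) <- colnames(expr)
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    E <- vapply(mods, function(m)
      module_eigengene(expr[, labels == m, drop = FALSE])$eigengene,
      numeric(nrow(expr)))
    C <- abs(stats::cor(E))
    diag(C) <- 0
    if (max(C) < merge_cor) break
    hit <- which(C == max(C), arr.ind = TRUE)[1L, ]
    a <- mods[min(hit)]; b <- mods[max(hit)]
    labels[labels == b] <- a
  }
  relabel_by_size(labels)
}

relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods) == 0L) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  first <- vapply(mods, function(m) which(labels == m)[1L], integer(1))
  ord <- mods[order(-sizes, first)]
  out <- labels
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}

#' Intramodular connectivity, hub gene and connection counts
#'
#' `kIM_i` is the sum of a gene's adjacency weights to co-members; the
#' hub gene attains the maximum (ties broken by lexicographically
#' smallest id). The connection count is the number of co-members whose
#' absolute correlation with the gene exceeds `cor_threshold`.
#'
#' @param members character vector of member gene ids.
#' @param A adjacency matrix over all genes (unit diagonal).
#' @param S similarity (|r|) matrix over all genes.
#' @param cor_threshold connection threshold on |r| (strict).
#' @return list with `stats` (data.frame gene, k_im, connection_count)
#'   and `hub`.
#' @export
connectivity_stats <- function(members, A, S, cor_threshold = 0.5) {
  stopifnot(length(members) >= 2L, all(members %in% rownames(A)))
  Am <- A[members, members, drop = FALSE]
  Sm <- S[members, members, drop = FALSE]
  diag(Am) <- 0
  diag(Sm) <- 0
  k_im <- rowSums(Am)
  conn <- rowSums(Sm > cor_threshold)
  hub <- sort(members[k_im == max(k_im)])[1L]
  list(stats = data.frame(gene = members, k_im = unname(k_im),
                          connection_count = unname(as.integer(conn)),
                          stringsAsFactors = FALSE),
       hub = hub)
}

#' Summarize all modules of a network
#'
#' Convenience wrapper producing one summary row per module plus the
#' eigengene matrix.
#'
#' @param expr strains x genes expression matrix.
#' @param labels module labels from [detect_modules()] /
#'   [merge_similar_modules()].
#' @param net `coexpression_network` over the same genes.
#' @return list: `summary` (data.frame module, size, variance_explained,
#'   hub), `eigengenes` (strains x modules), `members` (list),
#'   `connectivity` (per-module stats).
#' @export
module_summaries <- function(expr, labels, net) {
  mods <- sort(unique(labels[labels > 0L]))
  members <- lapply(mods, function(m) colnames(expr)[labels == m])
  names(members) <- as.character(mods)
  eg <- lapply(members, function(g)
    module_eigengene(expr[, g, drop = FALSE]))
  conn <- lapply(members, function(g)
    connectivity_stats(g, net$A, net$S))
  E <- vapply(eg, `[[`, numeric(nrow(expr)), "eigengene")
  rownames(E) <- rownames(expr)
  list(summary = data.frame(
         module = mods,
         size = lengths(members),
         variance_explained = vapply(eg, `[[`, numeric(1),
                                     "variance_explained"),
         hub = vapply(conn, `[[`, character(1), "hub"),
         stringsAsFactors = FALSE),
       eigengenes = E,
       members = members,
       connectivity = conn)
}
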