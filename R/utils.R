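# Internal helpers shared across pipeline stages.

#' Derive a deterministic per-stage seed
#'
#' Every stochastic stage draws from its own pseudo-random stream derived
#' from the user seed and the stage name, so that re-running a single stage
#' reproduces it exactly regardless of what ran before.
#'
#' @param seed integer user seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code)) %% 100003L
  # keep all arithmetic inside the exactly-representable double range
  as.integer(((as.numeric(seed) %% 2147483647) * 69621 + h) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# strand compatibility: identical, or at least one side undesignated
strands_compatible <- function(a, b) {
  a == b | a == "*" | b == "*"
}

write_tsv <- function(x, file) {
  utils::write.table(x, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

read_tsv <- function(file, ...) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE, ...)
}

# write a numeric matrix with a leading id column so it round-trips as TSV
write_matrix_tsv <- function(m, file, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_tsv(df, file)
}

mean_upper <- function(m) {
  if (nrow(m) < 2L) return(NA_real_)
  mean(m[upper.tri(m)])
}
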