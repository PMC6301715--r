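# Flat-file IO: TSV count matrices (feature id first, then one column per
# sample named condition_repN), FASTA via Biostrings, JASPAR-style PWM text.

#' Read a TSV count matrix
#'
#' First column is the feature id; remaining columns are samples named
#' `condition_repN`.
#'
#' @param path TSV file path
#' @return integer matrix with feature rownames and sample colnames
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(m < 0)) stop("negative counts in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix as TSV
#'
#' @param m matrix with rownames (features) and colnames (samples)
#' @param path output path
#' @param id_col name for the feature-id column
#' @export
write_count_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Condition labels parsed from sample names
#'
#' Sample columns follow the `condition_repN` convention; everything before
#' the final `_repN` is the condition.
#'
#' @param samples character vector of sample names
#' @return character vector of conditions
#' @export
sample_conditions <- function(samples) sub("_rep[0-9]+$", "", samples)

#' Columns of a count matrix belonging to one condition
#'
#' @param m count matrix with `condition_repN` column names
#' @param condition condition label
#' @return character vector of matching sample names
#' @export
condition_samples <- function(m, condition) {
  s <- colnames(m)[sample_conditions(colnames(m)) == condition]
  if (length(s) == 0) stop("no samples for condition ", condition)
  s
}

#' Write named DNA sequences as FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file path
#' @return named character vector
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
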