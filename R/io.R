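#' Read and write feature-by-sample abundance tables
#'
#' Abundance tables are plain TSV: one row per feature, a header row of
#' sample ids, and the first column (`feature`) holding feature ids.
#'
#' @param path file path.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  stopifnot_matrix(m)
  m
}

#' @rdname read_abundance_tsv
#' @param x numeric matrix with feature rownames and sample colnames.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot_matrix(x)
  df <- data.frame(feature = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata tables
#'
#' Metadata is TSV with one row per sample and columns `sample_id`,
#' `dog_id`, `breed`, `sex`, `condition` (LN/OW), `diet` (Base/HPLC/LPHC),
#' `timepoint` (baseline/post) and `cohort`.
#'
#' @param path file path.
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_metadata_tsv
#' @param metadata data.frame of sample covariates.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
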