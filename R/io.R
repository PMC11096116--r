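#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path Path to the file.
#' @return Numeric genes x samples matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in expression matrix")
  if (anyNA(m)) stop("missing values in expression matrix")
  m
}

#' Read a gene-to-category label table from TSV
#'
#' Two columns, `gene` and `category`, with header.
#' @param path Path to the file.
#' @return Data frame with columns `gene` and `category`.
#' @export
read_gene_categories <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "category") %in% names(df)))
  df[, c("gene", "category")]
}

#' Read a directed hit score table from TSV
#'
#' Four columns, `query`, `subject`, `score`, `evalue`, with header.
#' @param path Path to the file.
#' @return Data frame suitable for [rbbh_pairs()].
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("query", "subject", "score", "evalue") %in% names(df)))
  df
}

write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
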