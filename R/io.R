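#' Read an expression matrix from delimited text
#'
#' Expects a header row of array labels and a first column of gene (or probe)
#' identifiers; all remaining cells must be numeric or the declared missing
#' token. The original gene and array order is preserved.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @param missing_token String marking a missing cell (default `"NA"`).
#' @param array_time Optional numeric vector of per-array covariates.
#' @return An [expression_matrix()] with `NA` for missing cells.
#' @export
read_expression_matrix <- function(path, sep = "\t", missing_token = "NA",
                                   array_time = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected a gene-id column plus at least one array")
  labels <- colnames(raw)[-1L]
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop("duplicated array label(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells == missing_token] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell '%s' at gene '%s' (row %d), array '%s' (column %d)",
      cells[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]], bad[1L, 1L],
      labels[bad[1L, 2L]], bad[1L, 2L]))
  }
  dimnames(num) <- list(ids, labels)
  expression_matrix(num, array_time = array_time)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: header row of array labels, first
#' column of gene identifiers, missing cells written as `missing_token`.
#'
#' @param mat An [expression_matrix()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @param missing_token String to write for missing cells.
#' @param id_column Name for the gene-identifier column header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, sep = "\t",
                                    missing_token = "NA",
                                    id_column = "gene_id") {
  mat <- assert_expr_mat(mat)
  df <- data.frame(rownames(mat), unclass(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = missing_token)
  invisible(path)
}
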