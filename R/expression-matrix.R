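#' Construct an expression matrix
#'
#' The central container of the package: a numeric genes-by-arrays matrix of
#' log-scale expression values with unique gene identifiers as row names and
#' unique array labels as column names. An optional per-array covariate
#' (typically the time point, in hours or days) is carried along and used to
#' orient eigengene signs and direction labels downstream.
#'
#' @param values Numeric matrix (genes in rows, arrays in columns). `NA`
#'   entries mark missing measurements.
#' @param gene_ids Character vector of row identifiers. Defaults to the row
#'   names of `values`.
#' @param array_labels Character vector of column labels. Defaults to the
#'   column names of `values`.
#' @param array_time Optional numeric vector, one value per array.
#' @param polished Logical; `TRUE` only after [two_way_polish()], in which
#'   case every row is centred with unit sum of squares.
#' @return An object of class `expr_mat`: the numeric matrix with attributes
#'   `array_time` and `polished`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("a", 1:3)))
#' expression_matrix(m)
expression_matrix <- function(values, gene_ids = rownames(values),
                              array_labels = colnames(values),
                              array_time = NULL, polished = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(array_labels)) array_labels <- paste0("array_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  array_labels <- as.character(array_labels)
  if (length(gene_ids) != nrow(values)) {
    stop("length of `gene_ids` (", length(gene_ids),
         ") does not match the row count (", nrow(values), ")")
  }
  if (length(array_labels) != ncol(values)) {
    stop("length of `array_labels` (", length(array_labels),
         ") does not match the column count (", ncol(values), ")")
  }
  dup <- array_labels[duplicated(array_labels)]
  if (length(dup)) {
    stop("duplicated array label(s): ", paste(unique(dup), collapse = ", "))
  }
  if (!is.null(array_time)) {
    if (length(array_time) != ncol(values)) {
      stop("`array_time` must have one value per array")
    }
    array_time <- as.numeric(array_time)
  }
  dimnames(values) <- list(gene_ids, array_labels)
  structure(values,
            array_time = array_time,
            polished = isTRUE(polished),
            class = c("expr_mat", "matrix", "array"))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d arrays%s%s\n",
              nrow(x), ncol(x),
              if (anyNA(x)) sprintf(", %d missing cells", sum(is.na(x))) else "",
              if (attr(x, "polished")) ", polished" else ""))
  n <- min(nrow(x), 5L)
  m <- min(ncol(x), 6L)
  print(round(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], 3))
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more genes\n", sep = "")
  invisible(x)
}

#' @export
`[.expr_mat` <- function(x, i, j, ..., drop = FALSE) {
  tm <- attr(x, "array_time")
  out <- unclass(x)[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  if (!is.null(tm)) {
    tm <- if (missing(j)) tm else tm[j]
  }
  expression_matrix(out, array_time = tm, polished = attr(x, "polished"))
}

is_polished <- function(x) isTRUE(attr(x, "polished"))

array_time <- function(x) attr(x, "array_time")

# internal: keep attributes when replacing values wholesale
replace_values <- function(x, values, polished = attr(x, "polished")) {
  expression_matrix(values, array_time = attr(x, "array_time"),
                    polished = polished)
}

assert_expr_mat <- function(mat) {
  if (!inherits(mat, "expr_mat")) {
    if (is.matrix(mat) && is.numeric(mat)) return(expression_matrix(mat))
    stop("expected an `expr_mat` (see `expression_matrix()`)")
  }
  mat
}
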