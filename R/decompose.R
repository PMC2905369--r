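#' Singular value decomposition of a polished expression matrix
#'
#' Computes the thin SVD `A = U diag(s) V'`. The columns of `V` are the
#' eigengenes — fundamental expression patterns over the arrays — and the
#' columns of `U` carry the per-gene loadings on each pattern. Signs are
#' made deterministic by [orient_signs()], using the array time covariate
#' when the matrix carries one.
#'
#' @param mat A polished [expression_matrix()] with `n >= m >= 2`.
#' @param orient Logical; apply the deterministic sign convention
#'   (default `TRUE`).
#' @return An object of class `svd_result` with elements `d` (singular
#'   values, descending), `u` (n x m gene loadings), `v` (m x m eigengenes),
#'   `variance_fraction`, `gene_ids`, `array_labels`, `array_time`.
#' @export
decompose_expression <- function(mat, orient = TRUE) {
  mat <- assert_expr_mat(mat)
  if (!all(is.finite(mat))) stop("matrix contains non-finite entries")
  if (nrow(mat) < ncol(mat) || ncol(mat) < 2L) {
    stop("need n >= m >= 2 (genes x arrays)")
  }
  if (!is_polished(mat)) {
    warning("matrix is not polished; eigengenes may be dominated by scale effects")
  }
  s <- svd(unclass(mat))
  res <- structure(list(
    d = s$d,
    u = `dimnames<-`(s$u, list(rownames(mat), NULL)),
    v = s$v,
    variance_fraction = s$d^2 / sum(s$d^2),
    gene_ids = rownames(mat),
    array_labels = colnames(mat),
    array_time = array_time(mat)),
    class = "svd_result")
  if (orient) res <- orient_signs(res) else res
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("SVD of %d genes x %d arrays\n", nrow(x$u), length(x$d)))
  k <- min(length(x$d), 6L)
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "),
      if (length(x$d) > k) "..." else "", "\n")
  invisible(x)
}

#' Cumulative variance explained by the leading components
#'
#' @param res An `svd_result`.
#' @param k Number of leading components.
#' @return `sum(s_j^2, j <= k) / sum(s_j^2)`.
#' @export
variance_explained <- function(res, k) {
  stopifnot(inherits(res, "svd_result"))
  if (k < 1 || k > length(res$d)) stop("`k` must be in 1..", length(res$d))
  sum(res$variance_fraction[seq_len(k)])
}

#' Deterministic sign orientation of SVD components
#'
#' The SVD leaves the joint sign of each `(u_j, v_j)` pair arbitrary. Each
#' pair is flipped so that the eigengene correlates non-negatively with the
#' per-array covariate (time) when one is available, and otherwise so that
#' the largest-magnitude element of `v_j` is positive. The reconstruction
#' `U diag(s) V'` is unchanged.
#'
#' @param res An `svd_result`.
#' @param covariate Optional numeric covariate per array; defaults to the
#'   `array_time` stored in the result.
#' @return The oriented `svd_result`.
#' @export
orient_signs <- function(res, covariate = res$array_time) {
  stopifnot(inherits(res, "svd_result"))
  m <- nrow(res$v)
  if (!is.null(covariate) && length(covariate) != m) {
    stop("`covariate` must have one value per array")
  }
  for (j in seq_len(ncol(res$v))) {
    vj <- res$v[, j]
    flip <- if (!is.null(covariate) && stats::sd(covariate) > 0) {
      stats::cor(vj, covariate) < 0
    } else {
      vj[which.max(abs(vj))] < 0
    }
    if (isTRUE(flip)) {
      res$v[, j] <- -vj
      res$u[, j] <- -res$u[, j]
    }
  }
  res
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Eigengene profiles as a tibble
#'
#' One row per (component, array) with the eigengene value, ready for
#' plotting or TSV export.
#'
#' @param x An `svd_result`.
#' @param n_components Number of leading components to include (default 4).
#' @param ... Unused.
#' @method tidy svd_result
#' @export
tidy.svd_result <- function(x, n_components = 4, ...) {
  k <- min(n_components, length(x$d))
  tibble::tibble(
    component = rep(seq_len(k), each = length(x$array_labels)),
    array = rep(x$array_labels, k),
    time = if (is.null(x$array_time)) NA_real_ else rep(x$array_time, k),
    eigengene = as.vector(x$v[, seq_len(k)]),
    variance_fraction = rep(x$variance_fraction[seq_len(k)],
                            each = length(x$array_labels)))
}

#' @method glance svd_result
#' @export
glance.svd_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$u),
    n_arrays = length(x$d),
    var_1 = x$variance_fraction[1L],
    var_2 = if (length(x$d) >= 2) sum(x$variance_fraction[1:2]) else NA_real_)
}

#' Plot leading eigengene profiles
#'
#' @param object An `svd_result`.
#' @param n_components Number of leading eigengenes to draw (default 4).
#' @param ... Unused.
#' @return A ggplot object: eigengene value against array (or time), one
#'   panel per component, annotated with its variance fraction.
#' @method autoplot svd_result
#' @export
autoplot.svd_result <- function(object, n_components = 4, ...) {
  df <- tidy(object, n_components)
  df$x <- if (all(is.na(df$time))) {
    match(df$array, object$array_labels)
  } else {
    df$time
  }
  df$panel <- sprintf("eigengene %d (%.0f%%)", df$component,
                      100 * df$variance_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$eigengene)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = if (all(is.na(df$time))) "array" else "time",
                  y = "eigengene value")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
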