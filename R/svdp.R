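#' SVD-p: F-calibrated dominance of the leading component
#'
#' Measures how much of a gene-subset matrix is explained by its leading
#' singular triplet, calibrated against an F distribution so that cluster
#' size and tightness are balanced. Under the rank-one bilinear model
#' `A = s u v' + E` there are `r + c - 2` free parameters, giving degrees of
#' freedom `df1 = r + c - 2` and `df2 = rc - 2r - c + 2`. The statistic is
#' the variance ratio
#' \deqn{\hat F = s_1^2 / (\|A\|_F^2 - s_1^2)}
#' and SVD-p is the upper-tail probability of \eqn{\hat F} under
#' F(df1, df2); the matrix dimensions enter through the degrees of freedom,
#' so a large cluster scores lower (more dominant) than a small cluster of
#' the same tightness. `method = "scaled"` instead refers the mean-square
#' ratio \eqn{(s_1^2/df1) / ((\|A\|_F^2 - s_1^2)/df2)} to the same F, for
#' sensitivity checks. SVD-p is a ranking criterion, not a frequentist
#' p-value.
#'
#' @param mat Numeric matrix, `r >= 3` rows, `c >= 2` columns, with
#'   `rc - 2r - c + 2 >= 1`; the pipeline always passes polished
#'   (centred) data.
#' @param method `"ratio"` (default) or `"scaled"`; see Details.
#' @return An object of class `svdp_result`: list with `f_value`, `df1`,
#'   `df2`, `svd_p`, `method`. An exactly rank-one matrix has
#'   `f_value = Inf` and `svd_p = 0`.
#' @export
#' @examples
#' svdp(matrix(rnorm(50), 10, 5))
svdp <- function(mat, method = c("ratio", "scaled")) {
  method <- match.arg(method)
  if (inherits(mat, "expr_mat")) mat <- unclass(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("`mat` must be a numeric matrix")
  r <- nrow(mat)
  c <- ncol(mat)
  df1 <- r + c - 2L
  df2 <- r * c - 2L * r - c + 2L
  if (r < 3L || c < 2L || df2 < 1L) {
    stop("invalid dimensions for SVD-p: r=", r, ", c=", c,
         " (need r >= 3, c >= 2, rc - 2r - c + 2 >= 1)")
  }
  total <- sum(mat^2)
  if (total == 0) stop("all-zero matrix")
  s1sq <- svd(mat, nu = 0, nv = 0)$d[1L]^2
  resid <- max(total - s1sq, 0)
  f_value <- if (resid <= total * 1e-14) {
    Inf
  } else if (method == "ratio") {
    s1sq / resid
  } else {
    (s1sq / df1) / (resid / df2)
  }
  p <- if (is.infinite(f_value)) 0 else
    stats::pf(f_value, df1, df2, lower.tail = FALSE)
  structure(list(f_value = f_value, df1 = df1, df2 = df2, svd_p = p,
                 method = method),
            class = "svdp_result")
}

#' @export
print.svdp_result <- function(x, ...) {
  cat(sprintf("SVD-p: F = %.4g on (%d, %d) df, p = %.4g [%s]\n",
              x$f_value, x$df1, x$df2, x$svd_p, x$method))
  invisible(x)
}

#' SVD-p over an ordered list of gene-subset matrices
#'
#' Element-wise [svdp()], used to trace the cutoff-sweep curve of nested
#' subsets.
#'
#' @param mats List of numeric matrices (typically nested gene subsets).
#' @param method Passed to [svdp()].
#' @return A list of `svdp_result`, one per matrix; errors are annotated
#'   with the subset index.
#' @export
svdp_profile <- function(mats, method = c("ratio", "scaled")) {
  method <- match.arg(method)
  lapply(seq_along(mats), function(i) {
    tryCatch(svdp(mats[[i]], method = method),
             error = function(e) stop("subset ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
}
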