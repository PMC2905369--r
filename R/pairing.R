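#' Correlate eigengenes across two data sets
#'
#' Pearson correlation of every candidate eigengene of data set 1 with every
#' candidate of data set 2, over the aligned arrays, with the two-sided
#' significance from the t transform `t = r sqrt((m-2)/(1-r^2))` on `m - 2`
#' degrees of freedom.
#'
#' @param res1,res2 `svd_result` objects with the same number of arrays in
#'   matched condition order.
#' @param candidates1,candidates2 Eigengene indices to consider (default:
#'   all components).
#' @return A tibble with columns `idx1`, `idx2`, `r`, `p_value`.
#' @export
correlate_eigengenes <- function(res1, res2,
                                 candidates1 = seq_along(res1$d),
                                 candidates2 = seq_along(res2$d)) {
  stopifnot(inherits(res1, "svd_result"), inherits(res2, "svd_result"))
  m <- nrow(res1$v)
  if (nrow(res2$v) != m) {
    stop("data sets have ", m, " and ", nrow(res2$v), " arrays; ",
         "align the conditions of the two designs before pairing")
  }
  grid <- expand.grid(idx1 = candidates1, idx2 = candidates2)
  r <- mapply(function(i, j) stats::cor(res1$v[, i], res2$v[, j]),
              grid$idx1, grid$idx2)
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = m - 2, lower.tail = FALSE)
  tibble::tibble(idx1 = as.integer(grid$idx1), idx2 = as.integer(grid$idx2),
                 r = as.numeric(r), p_value = p)
}

new_pattern_pair <- function(idx1, idx2, r, p_value, kind) {
  structure(list(idx1 = as.integer(idx1), idx2 = as.integer(idx2),
                 r = r, p_value = p_value,
                 sign = if (is.na(r)) NA_integer_ else as.integer(sign(r)),
                 kind = kind),
            class = "pattern_pair")
}

#' @export
print.pattern_pair <- function(x, ...) {
  if (x$kind == "matched") {
    cat(sprintf("pattern pair (%d, %d): r = %.3f, p = %.3g\n",
                x$idx1, x$idx2, x$r, x$p_value))
  } else {
    cat(sprintf("unmatched pattern pair (%d, %d) [%s]\n",
                x$idx1, x$idx2, x$kind))
  }
  invisible(x)
}

#' Form pattern pairs by greedy one-to-one matching
#'
#' Pairs passing both the correlation magnitude and significance thresholds
#' are matched greedily in order of descending `|r|`; each eigengene index is
#' used at most once per side. Negative correlations are legal pairs — the
#' sign is carried forward to orient the two-way chart.
#'
#' @param table Correlation table from [correlate_eigengenes()].
#' @param alpha Significance threshold (default 0.01).
#' @param min_abs_r Minimum `|r|` (default 0.6).
#' @return List of `pattern_pair` objects (possibly empty), kind
#'   `"matched"`.
#' @export
form_pairs <- function(table, alpha = 0.01, min_abs_r = 0.6) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  pass <- table[abs(table$r) >= min_abs_r & table$p_value < alpha, , drop = FALSE]
  pass <- pass[order(-abs(pass$r)), , drop = FALSE]
  pairs <- list()
  used1 <- integer()
  used2 <- integer()
  for (i in seq_len(nrow(pass))) {
    if (pass$idx1[i] %in% used1 || pass$idx2[i] %in% used2) next
    pairs[[length(pairs) + 1L]] <- new_pattern_pair(
      pass$idx1[i], pass$idx2[i], pass$r[i], pass$p_value[i], "matched")
    used1 <- c(used1, pass$idx1[i])
    used2 <- c(used2, pass$idx2[i])
  }
  pairs
}

#' Pair a meaningful eigengene that has no partner
#'
#' When a biologically meaningful pattern exists in only one data set, it is
#' paired with the highest-index eigengene of the other data set whose
#' primary cluster is empty (falling back to the last component when every
#' PCL is occupied). The resulting chart has genes loading on one axis only,
#' so any modules it yields are divergent by construction.
#'
#' @param res_other `svd_result` of the other data set.
#' @param pcls_other `pcl_set` of the other data set.
#' @param idx Index of the unmatched eigengene (in its own data set).
#' @param kind `"unmatched-1only"` if the pattern lives in data set 1,
#'   `"unmatched-2only"` if in data set 2.
#' @param fallback_last Use the last component when no PCL is empty
#'   (default `TRUE`).
#' @return A `pattern_pair` with undefined `r` (`NA`).
#' @export
pair_unmatched <- function(res_other, pcls_other, idx,
                           kind = c("unmatched-1only", "unmatched-2only"),
                           fallback_last = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(res_other, "svd_result"), inherits(pcls_other, "pcl_set"))
  m <- length(res_other$d)
  empties <- pcls_other$empty_indices
  partner <- if (length(empties)) {
    max(empties)
  } else if (fallback_last) {
    m
  } else {
    stop("no empty primary cluster in the partner data set")
  }
  if (kind == "unmatched-1only") {
    new_pattern_pair(idx, partner, NA_real_, NA_real_, kind)
  } else {
    new_pattern_pair(partner, idx, NA_real_, NA_real_, kind)
  }
}
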