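#' Remove genes with too many missing values
#'
#' Drops every gene whose number of missing cells exceeds `max_missing`
#' (interpreted as a fraction of the array count when `max_missing < 1`).
#' The conventional threshold for ten-array series is three missing values.
#'
#' @param mat An [expression_matrix()].
#' @param max_missing Maximum tolerated missing count per gene (default 3),
#'   or a fraction in (0, 1) of the number of arrays.
#' @return The filtered matrix. Removed genes are recorded in the
#'   `removal_log` attribute (a tibble of `gene_id`, `reason`).
#' @export
filter_missing <- function(mat, max_missing = 3) {
  mat <- assert_expr_mat(mat)
  if (max_missing < 0) stop("`max_missing` must be >= 0")
  limit <- if (max_missing > 0 && max_missing < 1) {
    max_missing * ncol(mat)
  } else {
    max_missing
  }
  nmiss <- rowSums(is.na(mat))
  drop <- nmiss > limit
  if (all(drop)) stop("all genes exceed the missing-value limit")
  out <- mat[!drop, , drop = FALSE]
  attr(out, "removal_log") <- tibble::tibble(
    gene_id = rownames(mat)[drop],
    reason = sprintf("missing %d of %d arrays", nmiss[drop], ncol(mat)))
  out
}

#' Impute missing values by k nearest neighbours
#'
#' For each missing cell, the k genes nearest in Euclidean distance over
#' mutually observed arrays (among genes observed at the target array) donate
#' the unweighted mean of their values at that array. Distances are scaled to
#' a per-column mean square so genes with few co-observed columns are
#' comparable. When fewer than `k` usable neighbours exist the row mean is
#' used, with a warning. Observed cells are never altered.
#'
#' @param mat An [expression_matrix()] with missing cells.
#' @param k Number of neighbours (default 10).
#' @return The matrix with no missing cells.
#' @export
knn_impute <- function(mat, k = 10) {
  mat <- assert_expr_mat(mat)
  if (k < 1) stop("`k` must be >= 1")
  if (!anyNA(mat)) return(mat)
  vals <- unclass(mat)
  if (any(rowSums(!is.na(vals)) == 0L)) {
    stop("gene(s) with no observed values cannot be imputed: ",
         paste(rownames(vals)[rowSums(!is.na(vals)) == 0L], collapse = ", "))
  }
  filled <- vals
  miss <- which(is.na(vals), arr.ind = TRUE)
  for (i in unique(miss[, 1L])) {
    cols <- miss[miss[, 1L] == i, 2L]
    obs_i <- !is.na(vals[i, ])
    for (j in cols) {
      cand <- which(!is.na(vals[, j]))
      cand <- setdiff(cand, i)
      if (length(cand) < k) {
        warning("gene '", rownames(vals)[i], "': fewer than k=", k,
                " candidate neighbours; falling back to the row mean")
        filled[i, j] <- mean(vals[i, ], na.rm = TRUE)
        next
      }
      d2 <- vapply(cand, function(g) {
        co <- obs_i & !is.na(vals[g, ])
        if (!any(co)) return(Inf)
        mean((vals[i, co] - vals[g, co])^2)
      }, numeric(1))
      nb <- cand[order(d2)[seq_len(k)]]
      if (all(is.infinite(d2))) {
        warning("gene '", rownames(vals)[i],
                "': no co-observed neighbours; falling back to the row mean")
        filled[i, j] <- mean(vals[i, ], na.rm = TRUE)
      } else {
        filled[i, j] <- mean(vals[nb, j])
      }
    }
  }
  replace_values(mat, filled)
}

#' Collapse probe rows to gene symbols
#'
#' Multiple probes mapping to the same gene symbol are combined by the
#' arithmetic mean of their expression values, per array. Probes absent from
#' the mapping are kept under their own identifier (with a warning) or
#' dropped, according to `unmapped`.
#'
#' @param mat An [expression_matrix()] whose rows are probes.
#' @param probe_to_gene Named character vector: names are probe ids, values
#'   gene symbols.
#' @param unmapped `"keep"` (default) or `"drop"` for probes without a
#'   mapping entry.
#' @return An [expression_matrix()] with one row per gene symbol, in order of
#'   first appearance.
#' @export
collapse_probes <- function(mat, probe_to_gene, unmapped = c("keep", "drop")) {
  mat <- assert_expr_mat(mat)
  unmapped <- match.arg(unmapped)
  probes <- rownames(mat)
  sym <- probe_to_gene[probes]
  missing_map <- is.na(sym)
  if (any(missing_map)) {
    if (unmapped == "drop") {
      mat <- mat[!missing_map, , drop = FALSE]
      sym <- sym[!missing_map]
    } else {
      warning(sum(missing_map), " probe(s) missing from the mapping kept as-is")
      sym[missing_map] <- probes[missing_map]
    }
  }
  groups <- split(seq_along(sym), factor(sym, levels = unique(sym)))
  vals <- unclass(mat)
  out <- t(vapply(groups, function(idx) colMeans(vals[idx, , drop = FALSE]),
                  numeric(ncol(mat))))
  dimnames(out) <- list(names(groups), colnames(mat))
  replace_values(mat, out)
}

#' Remove genes lacking expression change
#'
#' On log2-scale data, drops genes whose maximum fold change across arrays is
#' below `min_fold`, i.e. whose range `max - min` is smaller than
#' `log2(min_fold)`.
#'
#' @param mat An [expression_matrix()] on log2 scale, no missing cells.
#' @param min_fold Minimum fold change to retain a gene (default 2).
#' @return The filtered matrix, with a `removal_log` attribute.
#' @export
fold_change_filter <- function(mat, min_fold = 2) {
  mat <- assert_expr_mat(mat)
  if (min_fold <= 1) stop("`min_fold` must be > 1")
  vals <- unclass(mat)
  rng <- apply(vals, 1L, function(x) diff(range(x, na.rm = TRUE)))
  drop <- rng < log2(min_fold)
  if (all(drop)) stop("no gene reaches the fold-change threshold")
  out <- mat[!drop, , drop = FALSE]
  attr(out, "removal_log") <- tibble::tibble(
    gene_id = rownames(mat)[drop],
    reason = sprintf("max fold change %.3g < %g", 2^rng[drop], min_fold))
  out
}

#' Iterative two-way polishing
#'
#' Prepares a matrix for SVD by alternating column and row standardisation.
#' One iteration (i) centres each column and divides by its standard
#' deviation (n-1 denominator), then (ii) centres each row and divides by the
#' row's root sum of squares. After the final iteration every row has zero
#' mean and unit L2 norm. Two iterations (the default) are enough for the
#' map to be essentially idempotent on typical expression data.
#'
#' @param mat An [expression_matrix()] with no missing cells, at least 3 rows
#'   and 3 columns.
#' @param iterations Number of column-then-row sweeps (default 2).
#' @return The polished matrix (`polished` attribute set).
#' @export
two_way_polish <- function(mat, iterations = 2) {
  mat <- assert_expr_mat(mat)
  if (anyNA(mat)) stop("polishing requires a complete matrix; impute first")
  if (nrow(mat) < 3L || ncol(mat) < 3L) {
    stop("polishing needs at least 3 genes and 3 arrays")
  }
  vals <- unclass(mat)
  for (it in seq_len(iterations)) {
    csd <- apply(vals, 2L, stats::sd)
    if (any(csd == 0)) {
      stop("zero-variance column at iteration ", it, ": ",
           paste(colnames(vals)[csd == 0], collapse = ", "))
    }
    vals <- scale(vals, center = TRUE, scale = csd)
    rss <- sqrt(rowSums((vals - rowMeans(vals))^2))
    if (any(rss == 0)) {
      stop("zero-norm row at iteration ", it, ": ",
           paste(rownames(vals)[rss == 0], collapse = ", "))
    }
    vals <- (vals - rowMeans(vals)) / rss
  }
  attributes(vals)[c("scaled:center", "scaled:scale")] <- NULL
  replace_values(mat, vals, polished = TRUE)
}
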