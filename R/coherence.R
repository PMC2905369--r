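#' Average pairwise correlation of a gene set
#'
#' Mean Pearson correlation over all unordered pairs of the given genes,
#' computed across arrays — the module-tightness summary reported alongside
#' each module.
#'
#' @param mat An [expression_matrix()].
#' @param genes Character vector of at least two gene ids present in `mat`.
#' @return A single correlation in `[-1, 1]`.
#' @export
avg_pairwise_corr <- function(mat, genes) {
  mat <- assert_expr_mat(mat)
  genes <- unique(genes)
  absent <- setdiff(genes, rownames(mat))
  if (length(absent)) stop("gene(s) absent from matrix: ",
                           paste(utils::head(absent, 5), collapse = ", "))
  if (length(genes) < 2L) stop("need at least two genes")
  sub <- unclass(mat)[genes, , drop = FALSE]
  flat <- apply(sub, 1L, stats::sd) == 0
  if (any(flat)) stop("constant gene row(s), correlation undefined: ",
                      paste(genes[flat], collapse = ", "))
  cm <- stats::cor(t(sub))
  mean(cm[upper.tri(cm)])
}

#' Empirical null probability for a module's coherence
#'
#' Samples `n_sets` random gene sets (sizes uniform in `size_range`, genes
#' drawn without replacement from the full analysed universe), computes the
#' average pairwise correlation of each, and returns the add-one estimator
#' `(1 + #null >= observed) / (n_sets + 1)` — never exactly zero, with
#' resolution `1/(n_sets + 1)`.
#'
#' @param mat An [expression_matrix()] (the analysed gene universe).
#' @param observed Observed average pairwise correlation.
#' @param n_sets Number of null sets (default 500).
#' @param size_range Two integers, low and high null-set size
#'   (default `c(10, 500)`); capped at the gene count with a warning.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `empirical_p`, `null` (the sampled null correlations),
#'   `n_sets`.
#' @export
empirical_null_p <- function(mat, observed, n_sets = 500,
                             size_range = c(10, 500), seed = NULL) {
  mat <- assert_expr_mat(mat)
  if (n_sets < 1) stop("`n_sets` must be >= 1")
  n <- nrow(mat)
  if (size_range[2] > n) {
    warning("null-set sizes capped at the gene count (", n, ")")
    size_range[2] <- n
  }
  size_range[1] <- min(size_range[1], size_range[2])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ids <- rownames(mat)
  null <- vapply(seq_len(n_sets), function(i) {
    sz <- sample(size_range[1]:size_range[2], 1L)
    avg_pairwise_corr(mat, sample(ids, sz))
  }, numeric(1))
  list(empirical_p = (1 + sum(null >= observed)) / (n_sets + 1),
       null = null, n_sets = n_sets)
}

#' Coherence assessment of every module in a result
#'
#' Appends to the module report the average within-module correlation in
#' each data set and its empirical null probability.
#'
#' @param result An `svdppcs_result`.
#' @param mat1,mat2 The (preprocessed, unpolished or polished) expression
#'   matrices the pipeline was run on.
#' @param n_sets Null sets per data set (default 500).
#' @param size_range Null-set size range (default `c(10, 500)`).
#' @param seed Integer seed (default 1).
#' @return Tibble: pair indices, module label, classification, size,
#'   `corr1`, `corr2`, `empirical_p1`, `empirical_p2`.
#' @export
module_coherence <- function(result, mat1, mat2, n_sets = 500,
                             size_range = c(10, 500), seed = 1) {
  stopifnot(inherits(result, "svdppcs_result"))
  mat1 <- assert_expr_mat(mat1)
  mat2 <- assert_expr_mat(mat2)
  mods <- module_list(result)
  if (!length(mods)) {
    return(tibble::tibble(module = character(), classification = character(),
                          size = integer(), corr1 = numeric(),
                          corr2 = numeric(), empirical_p1 = numeric(),
                          empirical_p2 = numeric()))
  }
  cls <- unlist(lapply(result$module_sets,
                       function(m) m$info$classification))
  sr1 <- c(size_range[1], min(size_range[2], nrow(mat1)))
  sr2 <- c(size_range[1], min(size_range[2], nrow(mat2)))
  set.seed(seed)
  null1 <- vapply(seq_len(n_sets), function(i) {
    sz <- sample(sr1[1]:sr1[2], 1L)
    avg_pairwise_corr(mat1, sample(rownames(mat1), sz))
  }, numeric(1))
  null2 <- vapply(seq_len(n_sets), function(i) {
    sz <- sample(sr2[1]:sr2[2], 1L)
    avg_pairwise_corr(mat2, sample(rownames(mat2), sz))
  }, numeric(1))
  corr1 <- vapply(mods, function(g) {
    avg_pairwise_corr(mat1, intersect(g, rownames(mat1)))
  }, numeric(1))
  corr2 <- vapply(mods, function(g) {
    avg_pairwise_corr(mat2, intersect(g, rownames(mat2)))
  }, numeric(1))
  tibble::tibble(
    module = names(mods),
    classification = cls,
    size = lengths(mods),
    corr1 = unname(corr1),
    corr2 = unname(corr2),
    empirical_p1 = (1 + vapply(corr1, function(o) sum(null1 >= o), numeric(1))) /
      (n_sets + 1),
    empirical_p2 = (1 + vapply(corr2, function(o) sum(null2 >= o), numeric(1))) /
      (n_sets + 1))
}
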