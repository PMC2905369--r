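#' Generic-clustering baseline: PAM with silhouette model selection
#'
#' Runs partitioning around medoids on the gene rows for each candidate
#' number of clusters and selects the `k` with the largest average
#' silhouette width. Used as the comparison baseline on the simulation
#' benchmark, where flat clustering has to trade the large pattern-free gene
#' group off against the planted classes.
#'
#' @param mat An [expression_matrix()] (raw or polished).
#' @param k_range Candidate cluster counts (default `2:10`).
#' @param metric Dissimilarity metric for [cluster::pam()]
#'   (default `"euclidean"`).
#' @return List with `best_k`, `silhouette` (tibble of `k`,
#'   `avg_silhouette`), and `clustering` (the PAM assignment at `best_k`).
#' @export
compare_pam <- function(mat, k_range = 2:10, metric = "euclidean") {
  mat <- assert_expr_mat(mat)
  vals <- unclass(mat)
  fits <- lapply(k_range, function(k) cluster::pam(vals, k, metric = metric))
  widths <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1))
  best <- which.max(widths)
  list(best_k = k_range[best],
       silhouette = tibble::tibble(k = k_range, avg_silhouette = widths),
       clustering = fits[[best]]$clustering)
}
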