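#' Run the full module-detection pipeline on two data sets
#'
#' Executes the four-step scheme: SVD of each polished matrix, primary
#' clustering by maximum projection, pattern pairing of eigengenes across
#' the data sets, and — for each pattern pair — construction of the two-way
#' chart, data-driven cutoff selection by SVD-p, and chart splitting into
#' conserved and divergent modules. Deterministic given the inputs and
#' parameters.
#'
#' @param mat1,mat2 Preprocessed [expression_matrix()] objects over the same
#'   (aligned) conditions. Unpolished matrices are polished internally with
#'   `polish_iterations` sweeps.
#' @param polish_iterations Two-way polishing iterations (default 2).
#' @param k Explicit number of retained components; default `NULL` retains
#'   by `variance_target`.
#' @param variance_target Cumulative variance for PCL retention
#'   (default 0.60).
#' @param reallocate Reassign genes of discarded PCLs (default `TRUE`).
#' @param candidates1,candidates2 Eigengene indices considered for pairing;
#'   default: the retained components of each data set.
#' @param manual_pairs Optional list of `c(idx1, idx2)` integer pairs that
#'   override the automatic matching (for designs where conditions are
#'   similar but not equivalent and pairing is done by inspecting the
#'   eigengene plots).
#' @param unmatched1,unmatched2 Indices of meaningful eigengenes of data set
#'   1 (resp. 2) without a partner, to be paired with an empty-PCL eigengene
#'   of the other data set (see [pair_unmatched()]).
#' @param alpha,min_abs_r Pairing thresholds (defaults 0.01 and 0.6).
#' @param phi SVD-p threshold for the cutoff sweeps (default 0.05).
#' @param min_genes Sweep floor: minimum genes beyond a candidate cutoff
#'   (default 3).
#' @param min_module_size Minimum size of a reported module (default 5).
#' @param svdp_method `"ratio"` (default) or `"scaled"`, see [svdp()].
#' @param shared_genes Optional ortholog mapping, see [build_chart()].
#' @return An object of class `svdppcs_result`: list with `svd1`, `svd2`,
#'   `pcls1`, `pcls2`, `pair_table`, `pairs`, `module_sets`, `params`, and
#'   `log` (a tibble audit trail of counts, correlations, cutoffs and
#'   module sizes).
#' @export
run_svdppcs <- function(mat1, mat2,
                        polish_iterations = 2,
                        k = NULL, variance_target = 0.60, reallocate = TRUE,
                        candidates1 = NULL, candidates2 = NULL,
                        manual_pairs = NULL,
                        unmatched1 = integer(0), unmatched2 = integer(0),
                        alpha = 0.01, min_abs_r = 0.6,
                        phi = 0.05, min_genes = 3, min_module_size = 5,
                        svdp_method = c("ratio", "scaled"),
                        shared_genes = NULL) {
  svdp_method <- match.arg(svdp_method)
  mat1 <- assert_expr_mat(mat1)
  mat2 <- assert_expr_mat(mat2)
  if (!is_polished(mat1)) mat1 <- two_way_polish(mat1, polish_iterations)
  if (!is_polished(mat2)) mat2 <- two_way_polish(mat2, polish_iterations)

  log_rows <- list()
  note <- function(step, detail, value = NA_real_) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      step = step, detail = detail, value = value)
  }

  svd1 <- decompose_expression(mat1)
  svd2 <- decompose_expression(mat2)
  note("decompose", "variance of first two components, data set 1",
       variance_explained(svd1, min(2L, length(svd1$d))))
  note("decompose", "variance of first two components, data set 2",
       variance_explained(svd2, min(2L, length(svd2$d))))

  pcls1 <- retain_pcls(assign_pcls(svd1), svd1, k = k,
                       variance_target = variance_target,
                       reallocate = reallocate)
  pcls2 <- retain_pcls(assign_pcls(svd2), svd2, k = k,
                       variance_target = variance_target,
                       reallocate = reallocate)
  for (i in pcls1$retained) note("pcl", sprintf("data set 1, PCL-%d size", i),
                                 sum(pcls1$assignments == i))
  for (i in pcls2$retained) note("pcl", sprintf("data set 2, PCL-%d size", i),
                                 sum(pcls2$assignments == i))

  if (is.null(candidates1)) candidates1 <- pcls1$retained
  if (is.null(candidates2)) candidates2 <- pcls2$retained
  pair_table <- correlate_eigengenes(svd1, svd2, candidates1, candidates2)

  pairs <- if (is.null(manual_pairs)) {
    form_pairs(pair_table, alpha = alpha, min_abs_r = min_abs_r)
  } else {
    lapply(manual_pairs, function(pq) {
      row <- pair_table[pair_table$idx1 == pq[1] & pair_table$idx2 == pq[2], ]
      if (!nrow(row)) row <- correlate_eigengenes(svd1, svd2, pq[1], pq[2])
      new_pattern_pair(pq[1], pq[2], row$r, row$p_value, "matched")
    })
  }
  for (u in unmatched1) {
    pairs[[length(pairs) + 1L]] <-
      pair_unmatched(svd2, pcls2, u, "unmatched-1only")
  }
  for (u in unmatched2) {
    pairs[[length(pairs) + 1L]] <-
      pair_unmatched(svd1, pcls1, u, "unmatched-2only")
  }
  for (p in pairs) {
    note("pair", sprintf("(%d, %d) r [%s]", p$idx1, p$idx2, p$kind),
         if (is.na(p$r)) NA_real_ else p$r)
  }
  if (!length(pairs)) warning("no pattern pairs found")

  module_sets <- lapply(pairs, function(p) {
    chart <- build_chart(p, svd1, svd2, pcls1, pcls2,
                         shared_genes = shared_genes)
    note("chart", sprintf("(%d, %d) genes on chart", p$idx1, p$idx2),
         length(chart$gene_ids))
    cuts <- determine_cutoffs(chart, mat1, mat2, phi = phi,
                              min_genes = min_genes, method = svdp_method)
    for (nm in c("a", "b", "c", "d")) {
      note("cutoff", sprintf("(%d, %d) %s", p$idx1, p$idx2, nm), cuts[[nm]])
    }
    ms <- split_chart(chart, cuts, min_module_size = min_module_size)
    for (i in seq_len(nrow(ms$info))) {
      note("module", sprintf("(%d, %d) %s %s", p$idx1, p$idx2,
                             ms$info$label[i], ms$info$classification[i]),
           ms$info$size[i])
    }
    ms
  })

  structure(list(svd1 = svd1, svd2 = svd2, pcls1 = pcls1, pcls2 = pcls2,
                 pair_table = pair_table, pairs = pairs,
                 module_sets = module_sets,
                 params = list(k = k, variance_target = variance_target,
                               reallocate = reallocate, alpha = alpha,
                               min_abs_r = min_abs_r, phi = phi,
                               min_genes = min_genes,
                               min_module_size = min_module_size,
                               svdp_method = svdp_method,
                               polish_iterations = polish_iterations),
                 log = do.call(rbind, log_rows)),
            class = "svdppcs_result")
}

#' @export
print.svdppcs_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "svdPPCS result: %d pattern pair(s), %d module(s) (%d conserved, %d divergent)\n",
    g$n_pairs, g$n_modules, g$n_conserved, g$n_divergent))
  for (i in seq_along(x$module_sets)) print(x$module_sets[[i]])
  invisible(x)
}

#' Module report of a pipeline result
#'
#' @param x An `svdppcs_result`.
#' @param ... Unused.
#' @return Tibble with one row per (module, gene): pair indices, module
#'   label, classification, gene id and its two chart loadings.
#' @method tidy svdppcs_result
#' @export
tidy.svdppcs_result <- function(x, ...) {
  out <- lapply(x$module_sets, tidy)
  out <- do.call(rbind, out)
  if (is.null(out)) tidy.module_set(structure(list(modules = list()),
                                             class = "module_set")) else out
}

#' @method glance svdppcs_result
#' @export
glance.svdppcs_result <- function(x, ...) {
  cls <- unlist(lapply(x$module_sets, function(m) m$info$classification))
  tibble::tibble(
    n_pairs = length(x$pairs),
    n_modules = length(cls),
    n_conserved = sum(startsWith(cls, "conserved")),
    n_divergent = sum(startsWith(cls, "divergent")))
}

#' All modules of a result as one named list
#'
#' @param x An `svdppcs_result`.
#' @return Named list of gene-id vectors; names are
#'   `"<idx1>-<idx2>.<label>"`.
#' @export
module_list <- function(x) {
  stopifnot(inherits(x, "svdppcs_result"))
  out <- list()
  for (ms in x$module_sets) {
    if (!length(ms$modules)) next
    nm <- sprintf("%d-%d.%s", ms$pair$idx1, ms$pair$idx2, names(ms$modules))
    out[nm] <- ms$modules
  }
  out
}
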