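#' Heatmap-ready matrix for a module across both data sets
#'
#' Extracts the module genes from both matrices, concatenates the arrays
#' side by side, and row-standardises (zero mean, unit variance per gene),
#' optionally subsampling large modules to a fixed number of display genes.
#'
#' @param mat1,mat2 Expression matrices of the two data sets.
#' @param module Character vector of gene ids present in both matrices.
#' @param subsample Maximum number of genes to keep (default 20); `Inf`
#'   keeps all.
#' @param seed Seed for the subsample draw (default 1).
#' @return Numeric matrix, module genes x concatenated arrays (data set 1's
#'   columns first, prefixed `d1.`/`d2.`), rows standardised.
#' @export
export_heatmap_matrix <- function(mat1, mat2, module, subsample = 20,
                                  seed = 1) {
  mat1 <- assert_expr_mat(mat1)
  mat2 <- assert_expr_mat(mat2)
  module <- unique(module)
  if (!length(module)) stop("empty module")
  absent <- setdiff(module, intersect(rownames(mat1), rownames(mat2)))
  if (length(absent)) stop("module gene(s) absent from a data set: ",
                           paste(utils::head(absent, 5), collapse = ", "))
  if (length(module) > subsample) {
    set.seed(seed)
    module <- sort(sample(module, subsample))
  }
  combined <- cbind(unclass(mat1)[module, , drop = FALSE],
                    unclass(mat2)[module, , drop = FALSE])
  colnames(combined) <- c(paste0("d1.", colnames(mat1)),
                          paste0("d2.", colnames(mat2)))
  t(scale(t(combined)))
}

#' Write the tabular artifacts of a pipeline run
#'
#' Writes the plot-ready exports of one run to a directory: eigengene
#' profiles and variance tables of both data sets, the PCL membership
#' table, the pattern-pair report, the cutoff traces, the module report
#' (with coherence columns when requested) and a JSON run summary.
#'
#' @param result An `svdppcs_result`.
#' @param outdir Output directory (created if needed).
#' @param mat1,mat2 The matrices the pipeline was run on; required for the
#'   coherence columns.
#' @param coherence Add within-module correlation columns via
#'   [module_coherence()] (default `TRUE` when matrices are given).
#' @param n_sets,seed Passed to [module_coherence()].
#' @return `outdir`, invisibly.
#' @export
write_run_artifacts <- function(result, outdir, mat1 = NULL, mat2 = NULL,
                                coherence = !is.null(mat1), n_sets = 500,
                                seed = 1) {
  stopifnot(inherits(result, "svdppcs_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(tidy(result$svd1, n_components = length(result$svd1$d)),
      "eigengenes_1.tsv")
  tsv(tidy(result$svd2, n_components = length(result$svd2$d)),
      "eigengenes_2.tsv")
  tsv(data.frame(component = seq_along(result$svd1$d),
                 variance_fraction_1 = result$svd1$variance_fraction,
                 variance_fraction_2 = result$svd2$variance_fraction),
      "variance.tsv")
  pcl <- rbind(cbind(data_set = 1L, tidy(result$pcls1)),
               cbind(data_set = 2L, tidy(result$pcls2)))
  tsv(pcl, "pcl_membership.tsv")
  pair_rows <- do.call(rbind, lapply(result$pairs, function(p) {
    data.frame(idx1 = p$idx1, idx2 = p$idx2, r = p$r, p_value = p$p_value,
               kind = p$kind)
  }))
  if (!is.null(pair_rows)) tsv(pair_rows, "pattern_pairs.tsv")
  traces <- do.call(rbind, lapply(result$module_sets, function(ms) {
    do.call(rbind, lapply(names(ms$cutoffs$traces), function(nm) {
      cbind(idx1 = ms$pair$idx1, idx2 = ms$pair$idx2, cutoff = nm,
            as.data.frame(ms$cutoffs$traces[[nm]]))
    }))
  }))
  if (!is.null(traces)) tsv(traces, "cutoff_traces.tsv")
  report <- tidy(result)
  if (coherence && nrow(report)) {
    co <- module_coherence(result, mat1, mat2, n_sets = n_sets, seed = seed)
    co$idx1 <- as.integer(sub("-.*", "", co$module))
    key <- sprintf("%d-%d.%s", report$idx1, report$idx2, report$label)
    report <- cbind(report,
                    co[match(key, co$module),
                       c("corr1", "corr2", "empirical_p1", "empirical_p2")])
  }
  tsv(report, "module_report.tsv")
  summary <- list(
    glance = as.list(glance(result)),
    cutoffs = lapply(result$module_sets, function(ms) {
      list(idx1 = ms$pair$idx1, idx2 = ms$pair$idx2,
           a = ms$cutoffs$a, b = ms$cutoffs$b,
           c = ms$cutoffs$c, d = ms$cutoffs$d)
    }),
    params = result$params)
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv(result$log, "run_log.tsv")
  invisible(outdir)
}
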