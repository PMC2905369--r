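#' Assign genes to primary clusters by maximum projection
#'
#' The projection of gene `i`'s (polished) expression row onto eigengene `j`
#' equals `s_j * u_ij`, so each gene is assigned to the component on which
#' the magnitude `|s_j u_ij|` is largest. Ties break toward the smaller
#' component index (more variance). The resulting primary clusters (PCLs)
#' are mutually exclusive and their sizes are approximately ordered by the
#' eigenvalue magnitudes.
#'
#' @param res An `svd_result` (see [decompose_expression()]).
#' @return An object of class `pcl_set`: list with `assignments` (named
#'   integer vector gene -> component), `retained` (initially all
#'   components), `projections` (n x m magnitude matrix), `sizes`,
#'   `empty_indices`.
#' @export
assign_pcls <- function(res) {
  stopifnot(inherits(res, "svd_result"))
  proj <- sweep(abs(res$u), 2L, res$d, "*")
  idx <- apply(proj, 1L, which.max) # which.max breaks ties toward smaller j
  names(idx) <- res$gene_ids
  m <- length(res$d)
  new_pcl_set(idx, retained = seq_len(m), projections = proj)
}

new_pcl_set <- function(assignments, retained, projections) {
  m <- ncol(projections)
  sizes <- tabulate(assignments, nbins = m)
  names(sizes) <- seq_len(m)
  structure(list(assignments = assignments,
                 retained = sort(unique(retained)),
                 projections = projections,
                 sizes = sizes[as.character(sort(unique(retained)))],
                 empty_indices = which(sizes == 0L)),
            class = "pcl_set")
}

#' @export
print.pcl_set <- function(x, ...) {
  cat("primary clusters:", length(x$assignments), "genes over components {",
      paste(x$retained, collapse = ", "), "}\n")
  print(x$sizes)
  invisible(x)
}

#' Retain leading primary clusters and reallocate the rest
#'
#' Keeps the PCLs of the first `k` eigengenes, where `k` is given explicitly
#' or chosen as the smallest number of components whose cumulative variance
#' reaches `variance_target` (default 0.60). Genes of discarded PCLs are
#' reassigned to the retained component with the next-largest projection
#' magnitude; reallocation can be disabled, in which case those genes are
#' dropped from the cluster set (reintroduction can add noise to the
#' receiving clusters).
#'
#' @param pcls A `pcl_set` from [assign_pcls()].
#' @param res The `svd_result` the clusters were derived from.
#' @param k Explicit number of leading components to retain (overrides
#'   `variance_target`).
#' @param variance_target Cumulative variance fraction for automatic
#'   retention (default 0.60).
#' @param reallocate Reassign genes of discarded PCLs (default `TRUE`).
#' @return The pruned `pcl_set`.
#' @export
retain_pcls <- function(pcls, res, k = NULL, variance_target = 0.60,
                        reallocate = TRUE) {
  stopifnot(inherits(pcls, "pcl_set"), inherits(res, "svd_result"))
  m <- length(res$d)
  if (is.null(k)) {
    k <- which(cumsum(res$variance_fraction) >= variance_target)[1L]
    if (is.na(k)) k <- m
  }
  if (k < 1L || k > m) stop("`k` must be in 1..", m)
  keep <- seq_len(k)
  idx <- pcls$assignments
  out_of_range <- !(idx %in% keep)
  if (any(out_of_range)) {
    if (reallocate) {
      proj <- pcls$projections
      idx[out_of_range] <- vapply(which(out_of_range), function(i) {
        keep[which.max(proj[i, keep])]
      }, integer(1))
    } else {
      idx <- idx[!out_of_range]
    }
  }
  new_pcl_set(idx, retained = keep, projections = pcls$projections)
}

#' @method tidy pcl_set
#' @export
tidy.pcl_set <- function(x, ...) {
  tibble::tibble(
    gene_id = names(x$assignments),
    pcl = unname(x$assignments),
    projection = x$projections[cbind(match(names(x$assignments),
                                           rownames(x$projections)),
                                     x$assignments)])
}

#' Genes belonging to one primary cluster
#'
#' @param pcls A `pcl_set`.
#' @param index Component index.
#' @return Character vector of gene ids (possibly empty).
#' @export
pcl_members <- function(pcls, index) {
  names(pcls$assignments)[pcls$assignments == index]
}
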