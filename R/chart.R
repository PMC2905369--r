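#' Build the two-way chart for a pattern pair
#'
#' Genes belonging to either of the pair's two primary clusters are mapped
#' onto a plane whose y-axis is the data-set-1 left singular vector of the
#' pair and whose x-axis is the data-set-2 left singular vector. For a
#' negatively correlated pair the x loadings are negated, so that a
#' conserved co-expression trend always appears along the main diagonal.
#' Genes present in only one data set's universe are dropped with a logged
#' count.
#'
#' @param pair A `pattern_pair`.
#' @param res1,res2 `svd_result` objects of the two data sets.
#' @param pcls1,pcls2 `pcl_set` objects of the two data sets.
#' @param shared_genes Optional named character vector mapping data-set-1
#'   gene ids to data-set-2 gene ids (orthologs). Default: identity mapping
#'   on the common identifiers.
#' @return An object of class `two_way_chart`: list with `gene_ids` (in
#'   data-set-1 naming), `x`, `y`, `pair`, `n_dropped`.
#' @export
build_chart <- function(pair, res1, res2, pcls1, pcls2, shared_genes = NULL) {
  stopifnot(inherits(pair, "pattern_pair"))
  if (is.null(shared_genes)) {
    common <- intersect(res1$gene_ids, res2$gene_ids)
    shared_genes <- stats::setNames(common, common)
  }
  ids1 <- names(shared_genes)
  members1 <- pcl_members(pcls1, pair$idx1)
  members2 <- pcl_members(pcls2, pair$idx2)
  in_union <- ids1[ids1 %in% members1 | shared_genes %in% members2]
  n_dropped <- sum(!(members1 %in% ids1)) +
    sum(!(members2 %in% shared_genes))
  if (!length(in_union)) stop("empty union of the pair's primary clusters")
  y <- res1$u[in_union, pair$idx1]
  x <- res2$u[shared_genes[in_union], pair$idx2]
  flip <- identical(pair$sign, -1L)
  if (flip) x <- -x
  structure(list(gene_ids = in_union, x = unname(x), y = unname(y),
                 pair = pair, n_dropped = n_dropped),
            class = "two_way_chart")
}

#' @export
print.two_way_chart <- function(x, ...) {
  cat(sprintf("two-way chart for pair (%d, %d): %d genes%s\n",
              x$pair$idx1, x$pair$idx2, length(x$gene_ids),
              if (x$n_dropped) sprintf(" (%d unshared dropped)", x$n_dropped)
              else ""))
  invisible(x)
}

#' Determine one cutoff by the SVD-p line-moving algorithm
#'
#' A line orthogonal to the chosen axis starts at zero and moves outward.
#' At each candidate position (the sorted distinct loading values in that
#' direction, so the sweep is exact) the SVD-p of the expression submatrix
#' of the genes strictly beyond the line — rows from the axis's own data
#' set, all of its arrays — is evaluated. The cutoff is the first position
#' at which SVD-p falls to `phi` or below; if `phi` is never reached, it is
#' the last position at which at least `min_genes` genes remain beyond the
#' line (the assumed lower limit of a module's size).
#'
#' @param chart A `two_way_chart`.
#' @param direction One of `"+y"`, `"-y"`, `"+x"`, `"-x"`.
#' @param data The polished [expression_matrix()] of the data set the axis
#'   belongs to (data set 1 for the y cutoffs, data set 2 for the x
#'   cutoffs); its rows must cover the chart genes.
#' @param phi SVD-p threshold (default 0.05).
#' @param min_genes Sweep floor (default 3).
#' @param method Passed to [svdp()].
#' @return List with `position` (signed cutoff), `reached` (logical: did
#'   SVD-p reach `phi`), `direction`, and `trace` — a tibble of
#'   `(position, n_beyond, svd_p)` for the swept positions.
#' @export
determine_cutoff <- function(chart, direction = c("+y", "-y", "+x", "-x"),
                             data, phi = 0.05, min_genes = 3,
                             method = c("ratio", "scaled")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  stopifnot(inherits(chart, "two_way_chart"))
  if (phi <= 0 || phi >= 1) stop("`phi` must be in (0, 1)")
  if (min_genes < 3) stop("`min_genes` must be >= 3")
  data <- assert_expr_mat(data)
  missing_rows <- setdiff(chart$gene_ids, rownames(data))
  if (length(missing_rows)) {
    stop("expression matrix lacks ", length(missing_rows), " chart gene(s)")
  }
  axis_sign <- if (substr(direction, 1L, 1L) == "-") -1 else 1
  vals <- if (substr(direction, 2L, 2L) == "y") chart$y else chart$x
  vals <- axis_sign * vals
  positions <- c(0, sort(unique(vals[vals > 0])))
  if (sum(vals > 0) < min_genes) {
    stop("degenerate chart: fewer than ", min_genes, " genes beyond zero in ",
         direction)
  }
  trace_pos <- numeric(0)
  trace_n <- integer(0)
  trace_p <- numeric(0)
  cutoff <- NA_real_
  last_ok <- NA_real_
  reached <- FALSE
  for (p in positions) {
    beyond <- chart$gene_ids[vals > p]
    if (length(beyond) < min_genes) break
    sp <- svdp(unclass(data)[beyond, , drop = FALSE], method = method)$svd_p
    trace_pos <- c(trace_pos, p)
    trace_n <- c(trace_n, length(beyond))
    trace_p <- c(trace_p, sp)
    last_ok <- p
    if (sp <= phi) {
      cutoff <- p
      reached <- TRUE
      break
    }
  }
  if (!reached) cutoff <- last_ok
  list(position = axis_sign * cutoff,
       reached = reached,
       direction = direction,
       trace = tibble::tibble(position = axis_sign * trace_pos,
                              n_beyond = trace_n, svd_p = trace_p))
}

#' Determine all four cutoffs of a chart
#'
#' Runs [determine_cutoff()] in the four directions: the y cutoffs `a`
#' (positive) and `b` (negative) on data set 1's matrix, the x cutoffs `c`
#' (positive) and `d` (negative) on data set 2's.
#'
#' @param chart A `two_way_chart`.
#' @param data1,data2 Polished expression matrices of the two data sets.
#' @inheritParams determine_cutoff
#' @return An object of class `chart_cutoffs`: list with `a`, `b`, `c`,
#'   `d`, `reached` (named logical), `traces` (named list of sweep tibbles).
#' @export
determine_cutoffs <- function(chart, data1, data2, phi = 0.05, min_genes = 3,
                              method = c("ratio", "scaled")) {
  method <- match.arg(method)
  dirs <- c(a = "+y", b = "-y", c = "+x", d = "-x")
  res <- lapply(dirs, function(d) {
    determine_cutoff(chart, d, if (substr(d, 2L, 2L) == "y") data1 else data2,
                     phi = phi, min_genes = min_genes, method = method)
  })
  structure(list(a = res$a$position, b = res$b$position,
                 c = res$c$position, d = res$d$position,
                 reached = vapply(res, `[[`, logical(1), "reached"),
                 traces = lapply(res, `[[`, "trace")),
            class = "chart_cutoffs")
}

#' @export
print.chart_cutoffs <- function(x, ...) {
  cat(sprintf("cutoffs: a = %.4f, b = %.4f, c = %.4f, d = %.4f\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

# block layout of the split chart, reading the 3x3 grid row by row from the
# top-left (high y, low x); the center block is excluded
block_table <- function() {
  tibble::tibble(
    label = paste0("M", 1:8),
    y_side = c(1L, 1L, 1L, 0L, 0L, -1L, -1L, -1L),
    x_side = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
    classification = c("divergent-opposite-1up2down", "divergent-1-up",
                       "conserved-up", "divergent-2-down", "divergent-2-up",
                       "conserved-down", "divergent-1-down",
                       "divergent-opposite-1down2up"))
}

#' Split a two-way chart into gene modules
#'
#' The four cutoffs divide the chart into at most nine blocks. The center
#' block (`b <= y <= a` and `d <= x <= c`) holds genes without a strong
#' trend in either data set and is excluded. The remaining blocks are
#' classified by their position: corner blocks on the main diagonal are
#' conserved modules (the co-expression trend appears in both data sets,
#' up-regulated or down-regulated); edge blocks are divergent with the trend
#' in one data set only; off-diagonal corners are divergent with opposite
#' trends. Blocks smaller than `min_module_size` are discarded.
#'
#' @param chart A `two_way_chart`.
#' @param cutoffs A `chart_cutoffs` object (or list with `a`, `b`, `c`, `d`).
#' @param min_module_size Minimum module size (default 5).
#' @return An object of class `module_set`: list with `modules` (named list
#'   of gene-id vectors), `info` (tibble: label, classification, size),
#'   `cutoffs`, `pair`, `chart`.
#' @export
split_chart <- function(chart, cutoffs, min_module_size = 5) {
  stopifnot(inherits(chart, "two_way_chart"))
  a <- cutoffs$a; b <- cutoffs$b; cc <- cutoffs$c; d <- cutoffs$d
  if (!(a >= 0 && b <= 0 && cc >= 0 && d <= 0)) {
    stop("invalid cutoffs: need a >= 0, b <= 0, c >= 0, d <= 0")
  }
  y_side <- ifelse(chart$y > a, 1L, ifelse(chart$y < b, -1L, 0L))
  x_side <- ifelse(chart$x > cc, 1L, ifelse(chart$x < d, -1L, 0L))
  blocks <- block_table()
  members <- lapply(seq_len(nrow(blocks)), function(i) {
    chart$gene_ids[y_side == blocks$y_side[i] & x_side == blocks$x_side[i]]
  })
  names(members) <- blocks$label
  keep <- lengths(members) >= min_module_size
  info <- tibble::tibble(label = blocks$label[keep],
                         classification = blocks$classification[keep],
                         size = unname(lengths(members)[keep]))
  structure(list(modules = members[keep], info = info,
                 cutoffs = cutoffs, pair = chart$pair, chart = chart),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module set for pair (%d, %d): %d module(s)\n",
              x$pair$idx1, x$pair$idx2, length(x$modules)))
  if (nrow(x$info)) print(as.data.frame(x$info), row.names = FALSE)
  invisible(x)
}

#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  if (!length(x$modules)) {
    return(tibble::tibble(idx1 = integer(), idx2 = integer(),
                          label = character(), classification = character(),
                          gene_id = character(), x = numeric(), y = numeric()))
  }
  rows <- lapply(seq_along(x$modules), function(i) {
    g <- x$modules[[i]]
    pos <- match(g, x$chart$gene_ids)
    load_x <- x$chart$x[pos]
    load_y <- x$chart$y[pos]
    tibble::tibble(idx1 = x$pair$idx1, idx2 = x$pair$idx2,
                   label = names(x$modules)[i],
                   classification = x$info$classification[i],
                   gene_id = g, x = load_x, y = load_y)
  })
  do.call(rbind, rows)
}

#' Plot a split two-way chart
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @return A ggplot: gene loadings coloured by module, with the four cutoff
#'   lines.
#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  ch <- object$chart
  df <- tibble::tibble(gene_id = ch$gene_ids, x = ch$x, y = ch$y,
                       module = "(center/discarded)")
  for (i in seq_along(object$modules)) {
    df$module[df$gene_id %in% object$modules[[i]]] <-
      names(object$modules)[i]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$module)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = c(object$cutoffs$a, object$cutoffs$b),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$cutoffs$c, object$cutoffs$d),
                        linetype = 2) +
    ggplot2::labs(x = "loading, data set 2", y = "loading, data set 1")
}
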