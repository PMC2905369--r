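#' Simulate the two-species planted-module benchmark
#'
#' Generates a pair of expression matrices ("mouse" and "human") over a
#' common time grid with six planted co-expression classes of `class_size`
#' genes each, the remaining genes carrying noise only:
#'
#' * C1 — sine curve, present in both species;
#' * C2 — sine curve, mouse only;
#' * C3 — sine curve, human only;
#' * C4 — gamma(9, rate 2) density curve, mouse only;
#' * C5 — the same gamma density with a 1.5 h time shift, human only;
#' * C6 — beta(6, 6) density curve, both species.
#'
#' The sine completes one period over the grid (`sin(2*pi*t/n_arrays)`); the
#' beta density is evaluated at `t/(n_arrays + 1)`. Each profile is
#' standardised to zero mean and unit variance across the grid before being
#' scaled by `amplitude`, so `amplitude/noise_sd` is the per-time-point
#' signal-to-noise ratio. Noise is i.i.d. Gaussian with standard deviation
#' `noise_sd`; a user-supplied pair of residual matrices can stand in for it
#' to mimic correlated array noise.
#'
#' @param n_genes Genes per species (default 338).
#' @param n_arrays Arrays / time points, 1..n hours (default 18).
#' @param class_size Genes per planted class (default 30).
#' @param amplitude Pattern scale after standardisation (default 1.0).
#' @param noise_sd Noise standard deviation (default 0.5).
#' @param seed Integer seed (default 1).
#' @param noise1,noise2 Optional `n_genes x n_arrays` residual matrices to
#'   use as the noise term instead of Gaussian draws.
#' @param gamma_shape,gamma_rate Gamma density parameters (default 9 and 2,
#'   i.e. mode at 4 h); set `gamma_rate` as a scale via
#'   `gamma_rate = 1/scale` if preferred.
#' @param gamma_shift Time shift of the human gamma class in hours
#'   (default 1.5).
#' @return List with `mouse` and `human` ([expression_matrix()] objects,
#'   `array_time` set to the grid) and `truth` (class `sim_truth`: tibble
#'   `class_of_gene`, list `patterns`, `time_grid`, `params`).
#' @export
#' @examples
#' sim <- simulate_pair(seed = 1)
#' table(sim$truth$class_of_gene$class)
simulate_pair <- function(n_genes = 338, n_arrays = 18, class_size = 30,
                          amplitude = 1.0, noise_sd = 0.5, seed = 1,
                          noise1 = NULL, noise2 = NULL,
                          gamma_shape = 9, gamma_rate = 2,
                          gamma_shift = 1.5) {
  if (n_genes < 6 * class_size) {
    stop("`n_genes` must be at least 6 * class_size = ", 6 * class_size)
  }
  if (n_arrays < 4) stop("`n_arrays` must be >= 4")
  t <- seq_len(n_arrays)
  std <- function(p) {
    if (stats::sd(p) == 0) stop("degenerate profile on this grid")
    (p - mean(p)) / stats::sd(p)
  }
  profiles <- list(
    sine = std(sin(2 * pi * t / n_arrays)),
    gamma = std(stats::dgamma(t, gamma_shape, gamma_rate)),
    gamma_shifted = std(stats::dgamma(t + gamma_shift, gamma_shape, gamma_rate)),
    beta = std(stats::dbeta(t / (n_arrays + 1), 6, 6)))

  classes <- c(paste0("C", 1:6), "null")
  class_of <- rep(classes, c(rep(class_size, 6), n_genes - 6 * class_size))
  ids <- sprintf("g%04d", seq_len(n_genes))
  mouse_pattern <- list(C1 = "sine", C2 = "sine", C4 = "gamma", C6 = "beta")
  human_pattern <- list(C1 = "sine", C3 = "sine", C5 = "gamma_shifted",
                        C6 = "beta")

  set.seed(seed)
  draw_noise <- function(supplied) {
    if (!is.null(supplied)) {
      stopifnot(nrow(supplied) == n_genes, ncol(supplied) == n_arrays)
      return(unclass(supplied))
    }
    matrix(stats::rnorm(n_genes * n_arrays, 0, noise_sd), n_genes, n_arrays)
  }
  build <- function(noise, which_pattern) {
    M <- noise
    for (cl in names(which_pattern)) {
      rows <- class_of == cl
      M[rows, ] <- sweep(M[rows, , drop = FALSE], 2L,
                         amplitude * profiles[[which_pattern[[cl]]]], "+")
    }
    dimnames(M) <- list(ids, sprintf("t%02d", t))
    expression_matrix(M, array_time = t)
  }
  mouse <- build(draw_noise(noise1), mouse_pattern)
  human <- build(draw_noise(noise2), human_pattern)

  truth <- structure(list(
    class_of_gene = tibble::tibble(gene_id = ids, class = class_of,
                                   in_mouse = class_of %in% names(mouse_pattern),
                                   in_human = class_of %in% names(human_pattern)),
    patterns = list(mouse = mouse_pattern, human = human_pattern,
                    profiles = profiles),
    time_grid = t,
    params = list(n_genes = n_genes, n_arrays = n_arrays,
                  class_size = class_size, amplitude = amplitude,
                  noise_sd = noise_sd, seed = seed)),
    class = "sim_truth")
  list(mouse = mouse, human = human, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("simulation truth:", nrow(x$class_of_gene), "genes,",
      length(x$time_grid), "time points\n")
  print(table(x$class_of_gene$class))
  invisible(x)
}

#' Score module recovery against the simulation truth
#'
#' Each planted class is matched to the detected module with the largest
#' gene overlap (matching by overlap, not by label). The columns follow the
#' benchmark's bookkeeping: N1 = planted class size, N2 = size of the
#' matched module, N3 = their intersection.
#'
#' @param result An `svdppcs_result`, a `module_set`, or a named list of
#'   gene-id vectors.
#' @param truth A `sim_truth` from [simulate_pair()].
#' @return Tibble: `class`, `module`, `classification` (if available),
#'   `N1`, `N2`, `N3`, `precision` (N3/N2), `recall` (N3/N1).
#' @export
score_recovery <- function(result, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  mods <- if (inherits(result, "svdppcs_result")) {
    module_list(result)
  } else if (inherits(result, "module_set")) {
    stats::setNames(result$modules, names(result$modules))
  } else {
    result
  }
  cls_info <- if (inherits(result, "svdppcs_result")) {
    stats::setNames(
      unlist(lapply(result$module_sets, function(m) m$info$classification)),
      names(mods))
  } else {
    NULL
  }
  classes <- setdiff(unique(truth$class_of_gene$class), "null")
  rows <- lapply(sort(classes), function(cl) {
    genes <- truth$class_of_gene$gene_id[truth$class_of_gene$class == cl]
    if (!length(mods)) {
      return(tibble::tibble(class = cl, module = NA_character_,
                            classification = NA_character_,
                            N1 = length(genes), N2 = 0L, N3 = 0L,
                            precision = NA_real_, recall = 0))
    }
    overlap <- unname(vapply(mods, function(m) length(intersect(m, genes)),
                             integer(1)))
    best <- which.max(overlap)
    tibble::tibble(
      class = cl,
      module = names(mods)[best],
      classification = if (is.null(cls_info)) NA_character_ else
        unname(cls_info[best]),
      N1 = length(genes),
      N2 = length(mods[[best]]),
      N3 = overlap[best],
      precision = overlap[best] / length(mods[[best]]),
      recall = overlap[best] / length(genes))
  })
  do.call(rbind, rows)
}
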