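# shared fixture builders; everything is generated in code at test time

make_mat <- function(values, genes = NULL, arrays = NULL, time = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(arrays)) arrays <- paste0("a", seq_len(ncol(values)))
  dimnames(values) <- list(genes, arrays)
  expression_matrix(values, array_time = time)
}

random_mat <- function(n, m, seed = 1, sd = 1) {
  set.seed(seed)
  make_mat(matrix(rnorm(n * m, sd = sd), n, m))
}

# independent upper-tail probability of the F distribution by quadrature of
# its density (never calls pf)
f_tail_quadrature <- function(f, df1, df2) {
  if (!is.finite(f)) return(0)
  body <- stats::integrate(function(x) stats::df(x, df1, df2), 0, f,
                           rel.tol = 1e-12, abs.tol = 1e-14,
                           subdivisions = 2000L)$value
  max(0, 1 - body)
}

# a chart object plus the matching expression matrix with a planted block of
# `n_block` tightly co-expressed genes at extreme +y loadings; remaining
# genes are noise with small loadings. Used for cutoff-sweep oracle tests.
planted_chart <- function(n_total = 120, n_block = 40, m = 10, seed = 1,
                          tight_sd = 0.05, noise_sd = 1) {
  set.seed(seed)
  pattern <- sin(seq_len(m))
  vals <- matrix(rnorm(n_total * m, sd = noise_sd), n_total, m)
  block <- seq_len(n_block)
  vals[block, ] <- outer(runif(n_block, 0.5, 1.5), pattern) +
    matrix(rnorm(n_block * m, sd = tight_sd), n_block, m)
  data <- make_mat(vals)
  # loadings: block genes extreme positive on y, others near zero; x mirrors
  y <- c(runif(n_block, 0.10, 0.30), runif(n_total - n_block, -0.04, 0.04))
  x <- c(runif(n_block, 0.10, 0.30), runif(n_total - n_block, -0.04, 0.04))
  chart <- structure(list(gene_ids = rownames(data), x = x, y = y,
                          pair = fake_pair(), n_dropped = 0L),
                     class = "two_way_chart")
  list(chart = chart, data = data)
}

fake_pair <- function(idx1 = 1L, idx2 = 1L, r = 0.9, kind = "matched") {
  structure(list(idx1 = idx1, idx2 = idx2, r = r, p_value = 1e-4,
                 sign = if (is.na(r)) NA_integer_ else as.integer(sign(r)),
                 kind = kind),
            class = "pattern_pair")
}

# brute-force sweep: evaluate SVD-p at zero and every distinct loading value,
# in ascending order, mirroring the stated algorithm independently of
# determine_cutoff's loop
brute_force_cutoff <- function(chart, direction, data, phi = 0.05,
                               min_genes = 3, method = "ratio") {
  sgn <- if (substr(direction, 1, 1) == "-") -1 else 1
  vals <- sgn * (if (substr(direction, 2, 2) == "y") chart$y else chart$x)
  grid <- c(0, sort(unique(vals[vals > 0])))
  last_ok <- NA_real_
  for (p in grid) {
    genes <- chart$gene_ids[vals > p]
    if (length(genes) < min_genes) break
    sp <- svdp(unclass(data)[genes, , drop = FALSE], method = method)$svd_p
    last_ok <- p
    if (sp <= phi) return(sgn * p)
  }
  sgn * last_ok
}

# swap the values of a polished matrix while keeping its polished status
replace_polished <- function(values, template) {
  dimnames(values) <- dimnames(template)
  expression_matrix(values, array_time = attr(template, "array_time"),
                    polished = TRUE)
}

# small polished matrix for decomposition tests
polished_random <- function(n = 20, m = 6, seed = 1) {
  two_way_polish(random_mat(n, m, seed))
}
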