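sim_parts <- local({
  sim <- simulate_pair(n_genes = 120, n_arrays = 12, class_size = 15,
                       seed = 5)
  pol1 <- two_way_polish(sim$mouse)
  pol2 <- two_way_polish(sim$human)
  svd1 <- decompose_expression(pol1)
  svd2 <- decompose_expression(pol2)
  pcls1 <- retain_pcls(assign_pcls(svd1), svd1)
  pcls2 <- retain_pcls(assign_pcls(svd2), svd2)
  pairs <- form_pairs(correlate_eigengenes(svd1, svd2,
                                           pcls1$retained, pcls2$retained))
  list(sim = sim, pol1 = pol1, pol2 = pol2, svd1 = svd1, svd2 = svd2,
       pcls1 = pcls1, pcls2 = pcls2, pairs = pairs)
})

test_that("the chart covers the union of the pair's two primary clusters", {
  p <- sim_parts
  pair <- p$pairs[[1]]
  chart <- build_chart(pair, p$svd1, p$svd2, p$pcls1, p$pcls2)
  union_ids <- union(pcl_members(p$pcls1, pair$idx1),
                     pcl_members(p$pcls2, pair$idx2))
  expect_setequal(chart$gene_ids, union_ids)
  # genes in only one side's PCL are still included
  only1 <- setdiff(pcl_members(p$pcls1, pair$idx1),
                   pcl_members(p$pcls2, pair$idx2))
  if (length(only1)) expect_true(all(only1 %in% chart$gene_ids))
  # loadings come straight from the left singular vectors
  i <- match(chart$gene_ids, p$svd1$gene_ids)
  expect_equal(chart$y, unname(p$svd1$u[i, pair$idx1]))
})

test_that("a negative pattern pair flips the x axis so conservation sits on the diagonal", {
  p <- sim_parts
  pair <- p$pairs[[1]]
  neg <- pair
  neg$r <- -abs(pair$r)
  neg$sign <- -1L
  chart_pos <- build_chart(pair, p$svd1, p$svd2, p$pcls1, p$pcls2)
  chart_neg <- build_chart(neg, p$svd1, p$svd2, p$pcls1, p$pcls2)
  expect_equal(chart_neg$x, -chart_pos$x)
  expect_equal(chart_neg$y, chart_pos$y)
})

test_that("genes absent from the shared universe are dropped and counted", {
  p <- sim_parts
  pair <- p$pairs[[1]]
  common <- intersect(p$svd1$gene_ids, p$svd2$gene_ids)
  some <- setdiff(common, pcl_members(p$pcls1, pair$idx1)[1])
  mapping <- setNames(some, some)
  chart <- build_chart(pair, p$svd1, p$svd2, p$pcls1, p$pcls2,
                       shared_genes = mapping)
  expect_false(pcl_members(p$pcls1, pair$idx1)[1] %in% chart$gene_ids)
  expect_gte(chart$n_dropped, 1)
})

test_that("the cutoff sweep equals brute-force evaluation at every distinct loading", {
  pc <- planted_chart(n_total = 150, n_block = 40, m = 10, seed = 13)
  for (dir in c("+y", "-y", "+x", "-x")) {
    got <- determine_cutoff(pc$chart, dir, pc$data)
    want <- brute_force_cutoff(pc$chart, dir, pc$data)
    expect_equal(got$position, want, tolerance = 1e-12)
  }
  # the +y sweep should reach phi with the planted block beyond the line
  got <- determine_cutoff(pc$chart, "+y", pc$data)
  expect_true(got$reached)
  beyond <- pc$chart$gene_ids[pc$chart$y > got$position]
  expect_lte(svdp(unclass(pc$data)[beyond, ])$svd_p, 0.05)
  # and it is the largest sweep set satisfying phi: one step earlier fails
  tr <- got$trace
  if (nrow(tr) > 1) expect_gt(tr$svd_p[nrow(tr) - 1], 0.05)
})

test_that("an unreachable phi falls back to the last position with min_genes beyond", {
  set.seed(33)
  n <- 60; m <- 8
  data <- make_mat(matrix(rnorm(n * m), n, m))
  chart <- structure(list(gene_ids = rownames(data),
                          x = runif(n, -0.3, 0.3), y = runif(n, -0.3, 0.3),
                          pair = fake_pair(), n_dropped = 0L),
                     class = "two_way_chart")
  got <- determine_cutoff(chart, "+y", data, phi = 1e-6, min_genes = 3)
  expect_false(got$reached)
  expect_identical(sum(chart$y > got$position), 3L)
  expect_equal(got$position, brute_force_cutoff(chart, "+y", data, phi = 1e-6),
               tolerance = 1e-12)
})

test_that("charts with too few genes beyond zero are rejected", {
  data <- make_mat(matrix(rnorm(40), 5, 8))
  chart <- structure(list(gene_ids = rownames(data),
                          x = c(-1, -1, -1, 0.1, -2) / 10,
                          y = c(0.1, 0.2, -0.1, -0.2, 0.3),
                          pair = fake_pair(), n_dropped = 0L),
                     class = "two_way_chart")
  expect_error(determine_cutoff(chart, "+x", data), "degenerate")
})

test_that("splitting assigns each gene by the double-threshold predicate", {
  set.seed(44)
  n <- 80
  chart <- structure(list(gene_ids = paste0("g", 1:n),
                          x = runif(n, -0.4, 0.4), y = runif(n, -0.4, 0.4),
                          pair = fake_pair(), n_dropped = 0L),
                     class = "two_way_chart")
  cuts <- list(a = 0.15, b = -0.1, c = 0.2, d = -0.12)
  ms <- split_chart(chart, cuts, min_module_size = 1)
  got <- ms$modules
  # per-gene oracle
  for (i in seq_len(n)) {
    x <- chart$x[i]; y <- chart$y[i]
    inside <- y <= cuts$a && y >= cuts$b && x <= cuts$c && x >= cuts$d
    found <- names(Filter(function(g) chart$gene_ids[i] %in% g, got))
    if (inside) expect_length(found, 0) else expect_length(found, 1)
  }
  # modules are pairwise disjoint
  all_genes <- unlist(got)
  expect_identical(anyDuplicated(all_genes), 0L)
})

test_that("the eight non-center blocks carry the documented classifications", {
  # one gene per block
  pos <- 0.3; neg <- -0.3; mid <- 0
  xy <- rbind(c(neg, pos), c(mid, pos), c(pos, pos),
              c(neg, mid), c(pos, mid),
              c(neg, neg), c(mid, neg), c(pos, neg))
  chart <- structure(list(gene_ids = paste0("g", 1:8),
                          x = xy[, 1], y = xy[, 2],
                          pair = fake_pair(), n_dropped = 0L),
                     class = "two_way_chart")
  cuts <- list(a = 0.1, b = -0.1, c = 0.1, d = -0.1)
  ms <- split_chart(chart, cuts, min_module_size = 1)
  expect_identical(ms$info$label, paste0("M", 1:8))
  expect_identical(lengths(ms$modules), setNames(rep(1L, 8), paste0("M", 1:8)))
  cls <- setNames(ms$info$classification, vapply(ms$modules, `[`, "", 1))
  expect_identical(unname(cls["g3"]), "conserved-up")
  expect_identical(unname(cls["g6"]), "conserved-down")
  expect_identical(unname(cls["g2"]), "divergent-1-up")
  expect_identical(unname(cls["g7"]), "divergent-1-down")
  expect_identical(unname(cls["g5"]), "divergent-2-up")
  expect_identical(unname(cls["g4"]), "divergent-2-down")
  expect_identical(unname(cls["g1"]), "divergent-opposite-1up2down")
  expect_identical(unname(cls["g8"]), "divergent-opposite-1down2up")
})

test_that("all genes in the center yields an empty module set", {
  chart <- structure(list(gene_ids = paste0("g", 1:6),
                          x = runif(6, -0.01, 0.01), y = runif(6, -0.01, 0.01),
                          pair = fake_pair(), n_dropped = 0L),
                     class = "two_way_chart")
  ms <- split_chart(chart, list(a = 0.1, b = -0.1, c = 0.1, d = -0.1))
  expect_length(ms$modules, 0)
  expect_identical(nrow(ms$info), 0L)
})

test_that("modules below the minimum size are discarded", {
  chart <- structure(list(gene_ids = paste0("g", 1:10),
                          x = c(rep(0.3, 6), rep(-0.3, 2), 0, 0),
                          y = c(rep(0.3, 6), rep(0.3, 2), 0, 0),
                          pair = fake_pair(), n_dropped = 0L),
                     class = "two_way_chart")
  cuts <- list(a = 0.1, b = -0.1, c = 0.1, d = -0.1)
  ms <- split_chart(chart, cuts, min_module_size = 5)
  expect_identical(names(ms$modules), "M3") # the 6-gene corner only
})

test_that("raising phi never shrinks the gene set beyond the cutoff", {
  pc <- planted_chart(n_total = 100, n_block = 30, m = 8, seed = 23)
  counts <- vapply(c(0.01, 0.05, 0.2, 0.5), function(phi) {
    cut <- determine_cutoff(pc$chart, "+y", pc$data, phi = phi)$position
    sum(pc$chart$y > cut)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
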