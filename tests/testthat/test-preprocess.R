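test_that("missing-value filter keeps exactly the genes under the threshold", {
  # genes with 0, 1, 3, 4, 5 missing cells out of 10 arrays
  vals <- matrix(rnorm(50), 5, 10)
  for (i in 2:5) vals[i, seq_len(c(0, 1, 3, 4, 5)[i])] <- NA
  mat <- make_mat(vals)
  out <- filter_missing(mat, max_missing = 3)
  expect_identical(rownames(out), c("g1", "g2", "g3"))
  log <- attr(out, "removal_log")
  expect_identical(log$gene_id, c("g4", "g5"))
  # fractional threshold: 0.3 of 10 arrays = 3
  expect_identical(rownames(filter_missing(mat, 0.3)), c("g1", "g2", "g3"))
  expect_error(filter_missing(mat[5, , drop = FALSE], 3), "all genes")
})

test_that("knn imputation matches the brute-force nearest-neighbour oracle", {
  set.seed(42)
  vals <- matrix(rnorm(24), 6, 4)
  truth <- vals
  vals[1, 2] <- NA
  vals[4, 3] <- NA
  mat <- make_mat(vals)
  out <- knn_impute(mat, k = 2)
  expect_false(anyNA(out))
  # observed cells bit-identical
  expect_identical(unclass(out)[!is.na(vals)], vals[!is.na(vals)])
  # oracle: exhaustive distances over co-observed columns
  for (cell in list(c(1, 2), c(4, 3))) {
    i <- cell[1]; j <- cell[2]
    cand <- setdiff(which(!is.na(vals[, j])), i)
    d <- sapply(cand, function(g) {
      co <- !is.na(vals[i, ]) & !is.na(vals[g, ])
      mean((vals[i, co] - vals[g, co])^2)
    })
    nb <- cand[order(d)[1:2]]
    expect_equal(unclass(out)[i, j], mean(vals[nb, j]))
  }
})

test_that("knn imputation reproduces identical neighbours and degenerate fallbacks", {
  # a gene identical to three complete neighbours except one missing cell
  base <- c(1, 2, 3, 4)
  vals <- rbind(base, base, base, base, c(9, 9, 9, 9))
  vals[1, 3] <- NA
  mat <- make_mat(vals)
  out <- knn_impute(mat, k = 3)
  expect_equal(unclass(out)[1, 3], 3)
  # single-gene matrix falls back to the row mean, with a warning
  single <- make_mat(matrix(c(1, NA, 3), 1, 3))
  expect_warning(res <- knn_impute(single, k = 1), "row mean")
  expect_equal(unclass(res)[1, 2], 2)
  # a fully missing row is not imputable
  bad <- make_mat(rbind(c(NA, NA), c(1, 2), c(3, 4)))
  expect_error(knn_impute(bad, k = 1), "no observed values")
})

test_that("probe collapsing averages per gene symbol and keeps columns", {
  vals <- matrix(c(1, 3, 5, 2, 4, 2, 6, 10, 4, 8), 5, 2)
  mat <- make_mat(vals, genes = paste0("p", 1:5))
  map <- c(p1 = "GA", p2 = "GA", p3 = "GB", p4 = "GB", p5 = "GC")
  out <- collapse_probes(mat, map)
  expect_identical(rownames(out), c("GA", "GB", "GC"))
  expect_identical(colnames(out), colnames(mat))
  # oracle: explicit group means
  for (j in 1:2) {
    expect_equal(unclass(out)[, j],
                 c(GA = mean(vals[1:2, j]), GB = mean(vals[3:4, j]),
                   GC = vals[5, j]))
  }
  expect_equal(unclass(out)["GA", 1], 2) # (1 + 3) / 2
  # unmapped probes kept (warn) or dropped
  map2 <- map[1:4]
  expect_warning(kept <- collapse_probes(mat, map2), "missing from the mapping")
  expect_true("p5" %in% rownames(kept))
  dropped <- collapse_probes(mat, map2, unmapped = "drop")
  expect_identical(rownames(dropped), c("GA", "GB"))
})

test_that("fold-change filter removes genes with range below log2(min_fold)", {
  vals <- rbind(c(0, 0.25, 0.5), c(0, 0.5, 1.0), c(0, 1.0, 1.7),
                c(1, 1, 1))
  mat <- make_mat(vals)
  out <- fold_change_filter(mat, min_fold = 2)
  expect_identical(rownames(out), c("g2", "g3")) # ranges 1.0 and 1.7 >= 1
  expect_true("g4" %in% attr(out, "removal_log")$gene_id) # constant gene
  expect_error(fold_change_filter(make_mat(vals[4, , drop = FALSE]), 2),
               "no gene")
})

test_that("one polishing iteration matches a hand-computed two-sweep oracle", {
  set.seed(7)
  vals <- matrix(rnorm(12), 4, 3)
  mat <- make_mat(vals)
  out <- two_way_polish(mat, iterations = 1)
  # oracle: explicit loops
  step <- vals
  for (j in 1:3) step[, j] <- (vals[, j] - mean(vals[, j])) / sd(vals[, j])
  for (i in 1:4) {
    centred <- step[i, ] - mean(step[i, ])
    step[i, ] <- centred / sqrt(sum(centred^2))
  }
  expect_equal(unclass(out), step, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("polishing yields unit-norm centred rows and is idempotent at convergence", {
  mat <- random_mat(10, 5, seed = 3)
  out <- two_way_polish(mat, iterations = 2)
  expect_true(is_polished(out))
  expect_equal(rowSums(unclass(out)), rep(0, 10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rowSums(unclass(out)^2), rep(1, 10), tolerance = 1e-8,
               ignore_attr = TRUE)
  # converged matrices are fixed points of one more iteration
  conv <- two_way_polish(random_mat(50, 10, seed = 11), iterations = 40)
  again <- two_way_polish(conv, iterations = 1)
  expect_lt(max(abs(unclass(again) - unclass(conv))), 1e-6)
})

test_that("degenerate inputs are rejected by name", {
  vals <- matrix(rnorm(12), 4, 3)
  vals[, 2] <- 5
  mat <- make_mat(vals)
  expect_error(two_way_polish(mat), "a2")
  withNA <- make_mat(matrix(c(NA, rnorm(11)), 4, 3))
  expect_error(two_way_polish(withNA), "impute")
  expect_error(two_way_polish(random_mat(2, 3)), "at least 3")
})
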