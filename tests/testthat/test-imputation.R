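test_that("dropouts are filled with within-cluster non-zero gene means", {
  x <- matrix(c(2, 0, 4), 3, 1, dimnames = list(NULL, "g1"))
  expect_equal(as.numeric(impute_with_clusters(x, rep(1, 3))),
               c(2, 3, 4))

  # no zeros: identity
  y <- matrix(1:6, 2, 3, dimnames = list(NULL, paste0("g", 1:3)))
  expect_identical(impute_with_clusters(y, c(1, 2)), y + 0)

  # gene entirely zero within a cluster stays zero there
  z <- matrix(c(0, 0, 3, 5), 4, 1, dimnames = list(NULL, "g1"))
  out <- impute_with_clusters(z, c(1, 1, 2, 2))
  expect_equal(as.numeric(out), c(0, 0, 3, 5))

  # cluster structure respected: means are computed per cluster
  w <- matrix(c(2, 0, 10, 0), 4, 1, dimnames = list(NULL, "g1"))
  out <- impute_with_clusters(w, c(1, 1, 2, 2))
  expect_equal(as.numeric(out), c(2, 2, 10, 10))
})

test_that("with one cluster and one list every zero becomes the global non-zero mean", {
  set.seed(51)
  x <- matrix(rpois(60, 2), 12, 5, dimnames = list(NULL, paste0("g", 1:5)))
  imp <- impute_with_clusters(x, rep(1, 12))
  for (j in seq_len(5)) {
    nz <- x[, j] != 0
    if (any(nz) && any(!nz))
      expect_equal(unname(imp[!nz, j]),
                   rep(mean(x[nz, j]), sum(!nz)))
  }
})

test_that("merging averages per-list estimates over the lists carrying each gene", {
  m1 <- matrix(c(1, 2), 2, 1, dimnames = list(NULL, "gA"))
  # K = 1: identity
  r1 <- merge_imputations(list(m1))
  expect_equal(r1$final, m1)

  # gene in 2 of 3 lists with imputed values 2 and 4 -> 3
  a <- matrix(c(2, 1), 2, 1, dimnames = list(NULL, "gA"))
  b <- matrix(c(4, 1), 2, 1, dimnames = list(NULL, "gA"))
  c3 <- matrix(c(9, 9), 2, 1, dimnames = list(NULL, "gB"))
  r <- merge_imputations(list(a, b, c3))
  expect_equal(unname(r$final[1, "gA"]), 3)
  expect_equal(unname(r$final[, "gB"]), c(9, 9))
  expect_setequal(r$gene_union, c("gA", "gB"))

  # identical matrices: idempotent mean
  r2 <- merge_imputations(list(m1, m1, m1))
  expect_equal(r2$final, m1)

  expect_error(merge_imputations(list(matrix(1, 1, 0))), "empty")
})

test_that("observed entries pass through the whole stage bit-identically", {
  set.seed(52)
  x <- matrix(rpois(200, 1.2) * runif(200), 20, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  cl1 <- rep(1:2, each = 10)
  cl2 <- rep(1:2, times = 10)
  lists <- list(x[, 1:7], x[, 4:10])
  imp <- merge_imputations(list(impute_with_clusters(lists[[1]], cl1),
                                impute_with_clusters(lists[[2]], cl2)),
                           observed = x)
  mask <- imp$observed_mask
  expect_identical(imp$final[mask],
                   x[, imp$gene_union, drop = FALSE][mask])
  # imputed entries are non-negative and every union gene is present
  expect_true(all(imp$final >= 0))
  expect_setequal(imp$gene_union, paste0("g", 1:10))
})

test_that("the merged value lies within the per-list range entrywise", {
  set.seed(53)
  x <- matrix(rpois(100, 1), 10, 10, dimnames = list(NULL, paste0("g", 1:10)))
  labs <- list(rep(1:2, each = 5), rep(1:2, times = 5), rep(c(1, 2), 5))
  per <- lapply(labs, function(l) impute_with_clusters(x, l))
  r <- merge_imputations(per)
  lo <- pmin(per[[1]], per[[2]], per[[3]])
  hi <- pmax(per[[1]], per[[2]], per[[3]])
  expect_true(all(r$final >= lo - 1e-12 & r$final <= hi + 1e-12))
})

test_that("the imputation report gives per-gene fill fractions", {
  x <- matrix(c(0, 1, 2, 2, 0, 0), 3, 2,
              dimnames = list(NULL, c("gA", "gB")))
  imp <- merge_imputations(list(impute_with_clusters(x, rep(1, 3))),
                           observed = x)
  rep <- imputation_report(imp)
  expect_equal(rep$frac_imputed, c(1 / 3, 2 / 3))
})
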