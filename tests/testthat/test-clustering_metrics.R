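test_that("GMM separates far-apart blobs perfectly and is seed-deterministic", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 10, 0.3), 20, 2))
  truth <- rep(1:2, each = 20)
  cl <- gmm_cluster(x, 2, seed = 1)
  expect_equal(ari(truth, cl$labels), 1)
  expect_identical(cl$labels, gmm_cluster(x, 2, seed = 1)$labels)
})

test_that("GMM with as many components as spots isolates every spot", {
  set.seed(32)
  x <- matrix(rnorm(16), 8, 2) * 5
  cl <- gmm_cluster(x, 8, seed = 2)
  expect_equal(length(unique(cl$labels)), 8L)
})

test_that("GMM recovers three Gaussian blobs reliably across seeds", {
  set.seed(33)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60), 30, 2), 2, centers[k, ], `+`)))
  truth <- rep(1:3, each = 30)
  aris <- vapply(1:20, function(s)
    ari(truth, gmm_cluster(x, 3, seed = s)$labels), numeric(1))
  expect_gte(mean(aris), 0.95)
})

test_that("GMM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(34)
  x <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(60, 8, 1), 30, 2))
  ours <- gmm_cluster(x, 2, seed = 1)$labels
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(ari(ours, mc$classification), 1)
})

test_that("ari matches hand-computed and degenerate cases", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c("a", "b", "a", "b"), c(1, 1, 2, 2)),
               ari(c(1, 1, 2, 2), c("a", "b", "a", "b")))  # symmetric
  # one cluster vs all singletons: chance level
  expect_equal(ari(rep(1, 4), 1:4), 0)
  # contingency-table formula evaluated by hand:
  # a = (0,0,1,1), b = (0,1,1,1): sum C(nij,2) = 1, sa = 2, sb = 3,
  # expected = 1, max = 2.5 -> ARI = 0
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0)
  expect_error(ari(1:3, 1:4), "length")
})

test_that("ari agrees with an independent implementation on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(35)
  for (i in 1:25) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("fms and purity match pair and majority counting by hand", {
  expect_equal(fms(1:4 %/% 3, 1:4 %/% 3), 1)
  expect_equal(purity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # a = (0,0,1,1), b = (0,0,0,1): TP = 1, pairs_a = 2, pairs_b = 3
  expect_equal(fms(c(0, 0, 1, 1), c(0, 0, 0, 1)), 1 / sqrt(6))
  # single predicted cluster against k balanced classes
  expect_equal(purity(rep(1:4, each = 5), rep(1, 20)), 1 / 4)
  expect_error(fms(1:3, 1:4), "length")
})

test_that("purity is monotone under refinement of the prediction", {
  set.seed(36)
  truth <- sample(1:3, 40, replace = TRUE)
  pred <- sample(1:3, 40, replace = TRUE)
  p0 <- purity(truth, pred)
  # split one predicted cluster in two: a refinement
  idx <- which(pred == 1)
  refined <- pred
  refined[idx[seq_len(length(idx) %/% 2)]] <- 4
  expect_gte(purity(truth, refined), p0)
})

test_that("rank_methods follows the minimum-rank tie convention", {
  m <- matrix(c(3, 2, 1, 2), 2, 2,
              dimnames = list(c("A", "B"), c("d1", "d2")))
  r <- rank_methods(m)
  expect_equal(unname(r$avg_rank), c(1.5, 1.5))

  tied <- matrix(1, 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  expect_true(all(rank_methods(tied)$ranks == 1L))

  set.seed(37)
  distinct <- matrix(sample(100, 18), 6, 3)
  r <- rank_methods(distinct)
  for (j in 1:3) expect_setequal(r$ranks[, j], 1:6)

  bad <- matrix(c(1, NaN, 2, 3), 2, 2)
  expect_error(rank_methods(bad), "missing")
  expect_error(rank_methods(m[1, , drop = FALSE]), "two methods")
})

test_that("cluster labels export and metrics round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels(c(1, 2, 1), paste0("s", 1:3), f)
  lab <- read_labels(f)
  expect_equal(unname(lab), c("1", "2", "1"))
  expect_equal(names(lab), paste0("s", 1:3))
})
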