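test_that("rank-sum statistics match the worked two-by-two example", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$R_x, 3)
  expect_equal(r$U_x, 0)
  expect_equal(r$U_y, 4)
  expect_equal(r$statistic, 0)
  # standard-form identities
  expect_equal(r$R_x + r$R_y, 4 * 5 / 2)
  expect_equal(r$U_x + r$U_y, 2 * 2)
})

test_that("identical groups give the symmetric U and an uninformative p", {
  r <- rank_sum_test(c(1, 2, 5), c(1, 2, 5))
  expect_equal(r$U_x, r$U_y)
  expect_equal(r$U_x, 9 / 2)
  expect_equal(r$p_value, 1)
  # fully tied values: zero-variance null, p = 1 by convention
  expect_equal(rank_sum_test(rep(2, 3), rep(2, 4))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("U equals brute-force pair counting for all splits up to n = 8", {
  set.seed(41)
  for (n in 3:8) {
    vals <- sample(1:4, n, replace = TRUE)   # small alphabet forces ties
    for (n_x in 1:(n - 1)) {
      splits <- combn(n, n_x)
      for (col in seq_len(ncol(splits))) {
        ix <- splits[, col]
        x <- vals[ix]; y <- vals[-ix]
        r <- rank_sum_test(x, y)
        expect_equal(r$U_x, brute_force_U(x, y))
        expect_equal(r$U_y, brute_force_U(y, x))
        expect_equal(r$R_x + r$R_y, n * (n + 1) / 2)
      }
    }
  }
})

test_that("p-values agree with the reference rank-sum implementation", {
  set.seed(42)
  for (i in 1:20) {
    x <- round(rnorm(15), 1)                 # rounding introduces ties
    y <- round(rnorm(20, 0.3), 1)
    ours <- rank_sum_test(x, y)$p_value
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("a perfectly separating marker ranks first for its cluster", {
  set.seed(43)
  vals <- matrix(abs(rnorm(30 * 6)), 30, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  cl <- rep(1:2, each = 15)
  vals[, 3] <- ifelse(cl == 1, 5 + runif(30), 0)  # cluster-1 marker
  top <- deg_per_cluster(vals, cl, size = 2)
  expect_equal(top[["1"]][1], "g3")
  # saturation: size = n_genes returns every gene
  all6 <- deg_per_cluster(vals, cl, size = 6)
  expect_setequal(all6[["2"]], paste0("g", 1:6))
  expect_error(deg_per_cluster(vals, cl, size = 7), "exceeds")
})

test_that("clusters of size one are skipped with a warning", {
  vals <- matrix(runif(12), 4, 3)
  expect_warning(out <- deg_per_cluster(vals, c(1, 1, 1, 2), 2),
                 "fewer than 2")
  expect_named(out, "1")
})

test_that("planted layer markers are recovered from the truth clustering", {
  # the test is two-sided, so a cluster's top genes mix its own
  # (up-regulated) markers with other layers' markers, which are
  # down-regulated relative to the rest; both are planted signal
  sim <- simulate_layered_tissue(sim_config(grid = c(9, 9), genes = 60,
                                            n_layers = 3,
                                            markers_per_layer = 5,
                                            seed = 44))
  norm <- normalize_counts(sim$dataset)
  top <- deg_per_cluster(norm, sim$truth, size = 5)
  all_markers <- unlist(sim$markers, use.names = FALSE)
  # every top-ranked gene is a planted marker (no false positives)
  expect_true(all(unlist(top) %in% all_markers))
  # each cluster's own markers all sit within the planted-signal band
  rankings <- attr(top, "ranking")
  for (layer in 1:3) {
    own <- sim$markers[[paste0("layer", layer)]]
    pos <- match(own, rankings[[as.character(layer)]]$gene)
    expect_lte(max(pos), length(all_markers))
  }
})

test_that("DEG list selection keeps exactly the sizes inside the window", {
  # engineer a matrix whose top-gene unions have controlled density:
  # markers are dense, filler genes nearly empty
  set.seed(45)
  n <- 40
  cl <- rep(1:2, each = 20)
  dense <- function(k) matrix(5 + runif(n * k), n, k)
  sparse <- function(k) matrix(rbinom(n * k, 1, 0.05) * 3, n, k)
  vals <- cbind(dense(4) * (cl == 1), dense(4) * (cl == 2), sparse(22))
  colnames(vals) <- paste0("g", seq_len(ncol(vals)))
  sel <- select_deg_lists(vals, cl, size_grid = c(4, 10, 20),
                          window = c(0.3, 0.4))
  # oracle: recompute each union rate independently
  rk <- sel$per_cluster_rankings
  for (i in seq_len(nrow(sel$candidates))) {
    s <- sel$candidates$size[i]
    genes <- unique(c(rk[["1"]]$gene[1:s], rk[["2"]]$gene[1:s]))
    rate <- sum(vals[, genes] != 0) / (n * length(genes))
    expect_equal(sel$candidates$nonzero_rate[i], rate)
    expect_equal(sel$candidates$selected[i], rate >= 0.3 && rate <= 0.4)
  }
  expect_true(any(sel$candidates$selected))
  # whenever any size is inside the window, no fallback entry is outside
  rates <- sel$candidates$nonzero_rate[sel$candidates$selected]
  if (any(sel$candidates$nonzero_rate >= 0.3 &
          sel$candidates$nonzero_rate <= 0.4))
    expect_true(all(rates >= 0.3 & rates <= 0.4))
})

test_that("fully dense matrices fall back to the size nearest the window", {
  vals <- matrix(1 + runif(30 * 10), 30, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  cl <- rep(1:2, each = 15)
  expect_message(sel <- select_deg_lists(vals, cl,
                                         size_grid = c(2, 5, 10)),
                 "falling back")
  expect_equal(sum(sel$candidates$selected), 1L)
  expect_length(sel$lists, 1L)
})

test_that("DEG rankings export as a per-cluster TSV", {
  set.seed(46)
  vals <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  sel <- select_deg_lists(vals, rep(1:2, each = 5), size_grid = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_deg_lists(sel, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("cluster", "rank", "gene", "U", "p"))
  expect_equal(nrow(tab), 8L)   # 2 clusters x 4 genes, full ranking
})
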