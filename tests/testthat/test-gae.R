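test_that("attention coefficients: singleton, symmetry, hand-derived case", {
  # singleton neighbourhood: softmax over one score is 1
  g1 <- graph_from_neighbors(list(1L))
  A <- attention_coefficients(matrix(2, 1, 1), matrix(1, 1, 1),
                              c(1, 1), g1)
  expect_equal(A[1, 1], 1)

  # identical features: coefficients uniform over the neighbourhood
  g3 <- graph_from_neighbors(list(1:3, 1:3, 1:3))
  h <- matrix(1, 3, 2)
  A <- attention_coefficients(h, matrix(rnorm(4), 2, 2), rnorm(4), g3)
  expect_equal(as.numeric(A[1, ]), rep(1 / 3, 3))

  # two nodes, 1-dim features h = (1, 2), W = 1, a = (1, 1):
  # scores sigmoid(1+1), sigmoid(1+2); softmax over N_1 = {1, 2}
  g2 <- graph_from_neighbors(list(1:2, 1:2))
  A <- attention_coefficients(matrix(c(1, 2), 2, 1), matrix(1, 1, 1),
                              c(1, 1), g2)
  s2 <- 1 / (1 + exp(-2)); s3 <- 1 / (1 + exp(-3))
  expect_equal(A[1, 2], exp(s3) / (exp(s2) + exp(s3)))
  expect_equal(A[1, 1], exp(s2) / (exp(s2) + exp(s3)))

  # rows sum to one on a random case
  set.seed(3)
  g <- build_knn_graph(matrix(rnorm(24), 12, 2), k = 3)
  A <- attention_coefficients(matrix(rnorm(60), 12, 5),
                              matrix(rnorm(20), 4, 5), rnorm(8), g)
  expect_equal(unname(Matrix::rowSums(A)), rep(1, 12), tolerance = 1e-12)
})

test_that("encoder: zero input with zero biases embeds to zero; toy case matches hand computation", {
  g <- build_knn_graph(matrix(rnorm(12), 6, 2), k = 2)
  cfg <- gae_config(hidden_dim = 8, latent_dim = 3, seed = 5)
  params <- gae_init(4, cfg)
  H <- gae_encode(matrix(0, 6, 4), g, params)
  expect_equal(H, matrix(0, 6, 3), ignore_attr = TRUE)

  # two-node toy, 1-dim everywhere, hand-evaluated chain
  g2 <- graph_from_neighbors(list(1:2, 1:2))
  params <- structure(list(W1 = matrix(1, 1, 1), a1 = matrix(c(1, 1)),
                           b1 = matrix(0), W2 = matrix(2, 1, 1),
                           b2 = matrix(0), V1 = matrix(1, 1, 1),
                           c1 = matrix(0), V2 = matrix(1, 1, 1),
                           a2 = matrix(c(1, 1)), c2 = matrix(0)),
                      class = "gae_params")
  x <- matrix(c(1, 2), 2, 1)
  s2 <- 1 / (1 + exp(-2)); s3 <- 1 / (1 + exp(-3)); s4 <- 1 / (1 + exp(-4))
  a11 <- exp(s2) / (exp(s2) + exp(s3))      # node 1: scores s(1+1), s(1+2)
  a21 <- exp(s3) / (exp(s3) + exp(s4))      # node 2: scores s(2+1), s(2+2)
  h1 <- c(a11 * 1 + (1 - a11) * 2, a21 * 1 + (1 - a21) * 2)  # ELU inactive (>0)
  expected <- 2 * h1                         # W2 = 2, still positive
  expect_equal(as.numeric(gae_encode(x, g2, params)), expected,
               tolerance = 1e-12)
})

test_that("decoder mirrors the encoder dimensions and zero case", {
  g <- build_knn_graph(matrix(rnorm(12), 6, 2), k = 2)
  cfg <- gae_config(hidden_dim = 8, latent_dim = 3, seed = 5)
  params <- gae_init(4, cfg)
  D <- gae_decode(matrix(0, 6, 3), g, params)
  expect_equal(dim(D), c(6L, 4L))
  expect_equal(D, matrix(0, 6, 4), ignore_attr = TRUE)
})

test_that("training reduces reconstruction loss on learnable signal", {
  set.seed(21)
  x <- outer(runif(50), runif(20))           # rank-1 matrix
  g <- build_knn_graph(matrix(rnorm(100), 50, 2), k = 4)
  fit <- train_gae(x, g, gae_config(hidden_dim = 16, latent_dim = 4,
                                    iterations = 150, seed = 2))
  expect_lt(fit$final_loss, fit$loss_history[1])
  expect_length(fit$loss_history, fit$iterations)
})

test_that("training is bit-deterministic under a fixed seed", {
  set.seed(22)
  x <- matrix(abs(rnorm(40 * 12)), 40, 12)
  g <- build_knn_graph(matrix(rnorm(80), 40, 2), k = 3)
  cfg <- gae_config(hidden_dim = 16, latent_dim = 4, iterations = 60,
                    seed = 9)
  f1 <- train_gae(x, g, cfg)
  f2 <- train_gae(x, g, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$embedding, f2$embedding)
})

test_that("the R forward pass reproduces the compiled trainer's output", {
  set.seed(23)
  x <- matrix(abs(rnorm(30 * 10)), 30, 10)
  g <- build_knn_graph(matrix(rnorm(60), 30, 2), k = 3)
  fit <- train_gae(x, g, gae_config(hidden_dim = 12, latent_dim = 4,
                                    iterations = 40, seed = 4))
  H <- gae_encode(x, g, fit$params)
  expect_equal(H, fit$embedding, tolerance = 1e-4, ignore_attr = TRUE)
  D <- gae_decode(H, g, fit$params)
  expect_equal(D, fit$reconstruction, tolerance = 1e-4,
               ignore_attr = TRUE)
  # mean squared error of the reconstruction matches the reported loss
  expect_equal(mean((D - x)^2), fit$final_loss, tolerance = 1e-4)
})

test_that("embeddings separate spatial domains better than raw expression", {
  skip_if_not_installed("cluster")
  sim <- simulate_layered_tissue(sim_config(grid = c(10, 9), genes = 90,
                                            n_layers = 3,
                                            markers_per_layer = 10,
                                            seed = 6))
  d <- filter_genes(sim$dataset, 5)
  norm <- normalize_counts(d)
  g <- build_knn_graph(d$coords)
  fit <- train_gae(norm, g, gae_config(hidden_dim = 64, latent_dim = 16,
                                       iterations = 300, seed = 3))
  sil <- function(m) mean(cluster::silhouette(sim$truth$labels,
                                              dist(m))[, 3])
  expect_gt(sil(fit$embedding), sil(norm$values))
})

test_that("attention rows stay normalized throughout training", {
  set.seed(24)
  x <- matrix(abs(rnorm(40 * 15)), 40, 15)
  g <- build_knn_graph(matrix(rnorm(80), 40, 2), k = 4)
  fit <- train_gae(x, g, gae_config(hidden_dim = 16, latent_dim = 4,
                                    iterations = 80, seed = 2),
                   check_attention = TRUE)
  expect_length(fit$attention_deviation, fit$iterations + 1L)
  expect_lt(max(fit$attention_deviation), 1e-6)
})

test_that("identical spots in complete blocks get identical embeddings", {
  set.seed(25)
  proto <- matrix(abs(rnorm(3 * 8)), 3, 8)
  x <- proto[rep(1:3, each = 4), ]           # 3 blocks of 4 copies
  blocks <- rep(1:3, each = 4)
  g <- graph_from_neighbors(lapply(seq_len(12), function(u)
    which(blocks == blocks[u])))
  fit <- train_gae(x, g, gae_config(hidden_dim = 8, latent_dim = 3,
                                    iterations = 50, seed = 7))
  for (b in 1:3) {
    emb <- fit$embedding[blocks == b, , drop = FALSE]
    expect_lt(max(abs(sweep(emb, 2, emb[1, ]))), 1e-5)
  }
})

test_that("checkpoints round-trip trained parameters", {
  params <- gae_init(5, gae_config(hidden_dim = 6, latent_dim = 2))
  f <- withr::local_tempfile(fileext = ".rds")
  gae_save(params, f)
  expect_equal(gae_load(f), params)
})
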