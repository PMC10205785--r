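#' Graph attention autoencoder configuration
#'
#' The backbone is a 2-layer encoder and a mirrored 2-layer decoder.
#' The attention mechanism is active on the first encoder layer and the
#' last decoder layer; the remaining layers are dense per-node ELU
#' transforms. The encoder input width equals the number of genes of the
#' matrix being embedded; `hidden_dim` and `latent_dim` give the hidden
#' and bottleneck widths (defaults 512 and 32; the 32-dim bottleneck is
#' the spot embedding used for clustering).
#'
#' Training minimizes the mean squared reconstruction error with Adam
#' (learning rate `lr`, L2 weight decay `weight_decay`), full batch, for
#' `iterations` steps. Optionally (`tol > 0`) training stops early once
#' the relative improvement of the loss over a trailing window of
#' `tol_window` steps falls below `tol`; the default `tol = 0` always
#' runs all iterations, because the Adam loss curve plateaus transiently
#' and a window-based test can stop at a plateau the optimizer would
#' still escape.
#'
#' @param hidden_dim hidden layer width, default 512.
#' @param latent_dim embedding width, default 32.
#' @param lr Adam learning rate, default 1e-3.
#' @param weight_decay L2 weight decay, default 1e-5.
#' @param iterations maximum training iterations, default 1000.
#' @param tol relative-improvement early-stopping tolerance; 0 (default)
#'   disables early stopping.
#' @param tol_window trailing window (iterations) for the convergence
#'   check, default 50.
#' @param seed integer seed for the Glorot-uniform parameter
#'   initialization; fixes the whole training trajectory.
#' @return A list of class `gae_config`.
#' @export
gae_config <- function(hidden_dim = 512L, latent_dim = 32L, lr = 1e-3,
                       weight_decay = 1e-5, iterations = 1000L,
                       tol = 0, tol_window = 50L, seed = 1L) {
  stopifnot(hidden_dim >= 1, latent_dim >= 1, lr > 0, weight_decay >= 0,
            iterations >= 1, tol >= 0, tol_window >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim), lr = lr,
                 weight_decay = weight_decay,
                 iterations = as.integer(iterations), tol = tol,
                 tol_window = as.integer(tol_window),
                 seed = as.integer(seed)),
            class = "gae_config")
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize GAE parameters
#'
#' Weight matrices and attention vectors are Glorot-uniform; biases are
#' zero. Deterministic given `cfg$seed`.
#'
#' @param input_dim number of input features (genes).
#' @param cfg a [gae_config].
#' @return A list of class `gae_params` with encoder weights `W1`
#'   (hidden x input), `W2` (latent x hidden), decoder weights `V1`
#'   (hidden x latent), `V2` (input x hidden), attention vectors `a1`
#'   (length 2*hidden) and `a2` (length 2*input), and biases
#'   `b1`, `b2`, `c1`, `c2`.
#' @export
gae_init <- function(input_dim, cfg = gae_config()) {
  h <- cfg$hidden_dim; l <- cfg$latent_dim; g <- as.integer(input_dim)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  p <- list(W1 = glorot(h, g), a1 = glorot(2L * h, 1L),
            b1 = matrix(0, h, 1L),
            W2 = glorot(l, h), b2 = matrix(0, l, 1L),
            V1 = glorot(h, l), c1 = matrix(0, h, 1L),
            V2 = glorot(g, h), a2 = glorot(2L * g, 1L),
            c2 = matrix(0, g, 1L))
  structure(p, class = "gae_params")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

elu <- function(x) ifelse(x > 0, x, expm1(pmin(x, 0)))

#' Attention coefficients of one attention layer
#'
#' For every directed edge (u, v) of the spatial graph, the raw score is
#' the sigmoid of the inner product of the attention vector `a` with the
#' concatenation of the projected features `W h_u` and `W h_v`; the
#' coefficients are the softmax of these scores over the neighbourhood
#' N_u (u included). Each row therefore sums to exactly 1.
#'
#' @param h node feature matrix (spots x features).
#' @param W projection matrix (out_dim x features).
#' @param a attention vector of length `2 * out_dim`.
#' @param graph a [build_knn_graph] result.
#' @return Sparse n x n matrix `A` with `A[u, v] = alpha_uv` on graph
#'   edges.
#' @export
attention_coefficients <- function(h, W, a, graph) {
  h <- as.matrix(h); W <- as.matrix(W); a <- as.numeric(a)
  m <- nrow(W)
  stopifnot(length(a) == 2L * m, ncol(h) == ncol(W))
  Z <- h %*% t(W)
  p <- drop(Z %*% a[seq_len(m)])
  q <- drop(Z %*% a[m + seq_len(m)])
  e <- graph$edges
  stopifnot(all(lengths(graph$neighbors) >= 1L))
  score <- exp(stats::plogis(p[e[, 1L]] + q[e[, 2L]]))
  den <- rowsum(score, e[, 1L])[, 1L]
  alpha <- score / den[match(e[, 1L], sort(unique(e[, 1L])))]
  Matrix::sparseMatrix(i = e[, 1L], j = e[, 2L], x = alpha,
                       dims = c(graph$n_nodes, graph$n_nodes))
}

#' Encode node features to the latent embedding
#'
#' Pure-R forward pass of the encoder: an attention layer (ELU,
#' neighbourhood aggregation) followed by a dense ELU layer down to the
#' latent width. Used for inspection and testing; training itself runs
#' in compiled code.
#'
#' @param x spots-by-genes feature matrix (or `normalized_matrix`).
#' @param graph a [build_knn_graph] result.
#' @param params a [gae_init] / [train_gae] parameter list.
#' @return Spots-by-latent embedding matrix.
#' @export
gae_encode <- function(x, graph, params) {
  x <- expr_values(x)
  stopifnot(ncol(x) == ncol(params$W1))
  Z1 <- x %*% t(params$W1)
  A1 <- attention_coefficients(x, params$W1, params$a1, graph)
  H1 <- elu(as.matrix(A1 %*% Z1) + rep(params$b1[, 1L], each = nrow(x)))
  H2 <- elu(H1 %*% t(params$W2) + rep(params$b2[, 1L], each = nrow(x)))
  check_finite(H2, "encoder layer 2")
  H2
}

#' Decode latent embeddings back to feature space
#'
#' Mirror of [gae_encode]: dense ELU layer up to the hidden width, then
#' an attention layer (with its own attention vector) back to the input
#' width.
#'
#' @param h spots-by-latent embedding matrix.
#' @inheritParams gae_encode
#' @return Spots-by-genes reconstruction.
#' @export
gae_decode <- function(h, graph, params) {
  h <- as.matrix(h)
  stopifnot(ncol(h) == ncol(params$V1))
  D1 <- elu(h %*% t(params$V1) + rep(params$c1[, 1L], each = nrow(h)))
  Z2 <- D1 %*% t(params$V2)
  A2 <- attention_coefficients(D1, params$V2, params$a2, graph)
  D2 <- elu(as.matrix(A2 %*% Z2) + rep(params$c2[, 1L], each = nrow(h)))
  check_finite(D2, "decoder layer 2")
  D2
}

check_finite <- function(m, where) {
  if (!all(is.finite(m)))
    stop("non-finite activations in ", where)
  invisible(m)
}

#' Train the graph attention autoencoder
#'
#' Full-batch Adam training of the autoencoder on the spatial graph,
#' minimizing mean squared reconstruction error. Deterministic given
#' `cfg$seed` (all randomness is in the parameter initialization).
#'
#' @param x spots-by-genes feature matrix (typically a
#'   [normalize_counts] result or an imputed matrix).
#' @param graph a [build_knn_graph] result over the same spots.
#' @param cfg a [gae_config].
#' @param check_attention record, per iteration, the largest deviation of
#'   any node's attention-coefficient sum from 1 (both attention layers).
#' @return A list of class `gae_fit`: `params` (trained [gae_init]
#'   parameter list), `embedding` (spots x latent matrix), `loss_history`
#'   (one entry per iteration run), `final_loss`, `reconstruction`,
#'   `iterations` (iterations actually run; early stopping may end
#'   training before `cfg$iterations`), and `attention_deviation` (empty
#'   unless `check_attention`).
#' @export
train_gae <- function(x, graph, cfg = gae_config(),
                      check_attention = FALSE) {
  x <- expr_values(x)
  x <- as.matrix(x)
  stopifnot(inherits(graph, "spatial_graph"), nrow(x) == graph$n_nodes)
  params <- gae_init(ncol(x), cfg)
  nb <- graph$neighbors
  ptr <- c(0L, cumsum(lengths(nb)))
  idx <- unlist(nb, use.names = FALSE) - 1L
  res <- .adept_train_gae(x, ptr, idx, unclass(params), cfg$lr,
                          cfg$weight_decay, cfg$iterations, cfg$tol,
                          cfg$tol_window, check_attention)
  nl <- length(res$loss_history)
  emb <- res$embedding
  rownames(emb) <- rownames(x)
  structure(list(params = structure(res$params, class = "gae_params"),
                 embedding = emb,
                 loss_history = res$loss_history[-nl],
                 final_loss = res$loss_history[nl],
                 reconstruction = res$reconstruction,
                 attention_deviation = res$attention_deviation,
                 iterations = res$iterations, config = cfg),
            class = "gae_fit")
}

#' @export
print.gae_fit <- function(x, ...) {
  cat("gae_fit: ", nrow(x$embedding), " spots -> ", ncol(x$embedding),
      "-dim embedding\n", sep = "")
  cat("  iterations: ", x$iterations, " (max ", x$config$iterations,
      ")\n", sep = "")
  cat("  loss: ", signif(x$loss_history[1L], 5), " -> ",
      signif(x$final_loss, 5), "\n", sep = "")
  invisible(x)
}

#' Save / load trained GAE parameters
#'
#' @param params a `gae_params` list.
#' @param file checkpoint path.
#' @export
gae_save <- function(params, file) {
  saveRDS(unclass(params), file)
  invisible(file)
}

#' @rdname gae_save
#' @export
gae_load <- function(file) {
  structure(readRDS(file), class = "gae_params")
}
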