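#' Gaussian mixture clustering of latent embeddings
#'
#' Fits a full-covariance Gaussian mixture by EM, initializing the
#' responsibilities from the best of `nstart` k-means restarts, and
#' labels each spot by its maximum posterior component. (Selecting
#' instead among full EM restarts by final log-likelihood is unreliable
#' in a 32-dimensional space with a few hundred spots: the highest
#' likelihood solution tends to be the most overfit covariance, not the
#' best partition.) A small ridge (`reg`) is added to every covariance
#' diagonal; if a covariance still becomes degenerate the fit is
#' retried with the ridge increased a hundred-fold (up to `reg_max`)
#' before failing. Deterministic given `seed`.
#'
#' @param h spots-by-dims embedding matrix (or a [train_gae] fit).
#' @param n_clusters number of mixture components (the number of spatial
#'   domains; supplied by the user, typically the annotated domain
#'   count).
#' @param seed integer RNG seed (controls the k-means initialization).
#' @param nstart k-means initialization restarts, default 10.
#' @param max_iter maximum EM iterations, default 100.
#' @param tol relative log-likelihood convergence tolerance.
#' @param reg covariance ridge, default 1e-6.
#' @param reg_max largest ridge tried on degeneracy, default 1e-2.
#' @return A list of class `cluster_assignment`: integer `labels` in
#'   `1..n_clusters`, `n_clusters`, `seed`, `posterior` matrix,
#'   `loglik`, and mixture `parameters`.
#' @export
gmm_cluster <- function(h, n_clusters, seed = 1L, nstart = 10L,
                        max_iter = 100L, tol = 1e-6, reg = 1e-6,
                        reg_max = 1e-2) {
  if (inherits(h, "gae_fit")) h <- h$embedding
  h <- as.matrix(h)
  n <- nrow(h)
  stopifnot(n_clusters >= 1, n_clusters <= n)
  if (n_clusters == n) {
    # saturated mixture: every spot is its own component
    return(structure(list(labels = seq_len(n), n_clusters = n,
                          seed = as.integer(seed),
                          posterior = diag(n), loglik = NA_real_,
                          parameters = NULL, ridge = reg),
                     class = "cluster_assignment"))
  }
  r <- reg
  repeat {
    fit <- try(gmm_em(h, n_clusters, seed, nstart, max_iter, tol, r),
               silent = TRUE)
    if (!inherits(fit, "try-error")) break
    r <- r * 100
    if (r > reg_max)
      stop("EM covariance degenerate even at ridge ", r / 100, ": ",
           attr(fit, "condition")$message)
  }
  structure(list(labels = fit$labels, n_clusters = as.integer(n_clusters),
                 seed = as.integer(seed), posterior = fit$post,
                 loglik = fit$loglik, parameters = fit$par,
                 ridge = r),
            class = "cluster_assignment")
}

gmm_em <- function(x, G, seed, nstart, max_iter, tol, reg) {
  n <- nrow(x); d <- ncol(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = G, nstart = nstart, iter.max = 50L))
  resp <- matrix(0, n, G)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    nk <- pmax(colSums(resp), 1e-10)
    w <- nk / n
    mu <- crossprod(resp, x) / nk                    # G x d
    logdens <- matrix(0, n, G)
    covs <- vector("list", G)
    for (g in seq_len(G)) {
      xc <- sweep(x, 2L, mu[g, ])
      S <- crossprod(xc * resp[, g], xc) / nk[g] + diag(reg, d)
      L <- chol(S)                                   # fails if degenerate
      covs[[g]] <- S
      z <- backsolve(L, t(xc), transpose = TRUE)     # d x n
      logdens[, g] <- -0.5 * (d * log(2 * pi) + colSums(z^2)) -
        sum(log(diag(L)))
    }
    lw <- sweep(logdens, 2L, log(w), `+`)
    m <- apply(lw, 1L, max)
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(lse)
    resp <- exp(lw - lse)
    if (is.finite(loglik) &&
        abs(ll - loglik) < tol * (abs(ll) + 1e-10)) { loglik <- ll; break }
    loglik <- ll
  }
  labels <- max.col(resp, ties.method = "first")
  list(labels = as.integer(labels), post = resp, loglik = loglik,
       par = list(weights = w, means = mu, covariances = covs))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: ", length(x$labels), " spots in ",
      x$n_clusters, " clusters (seed ", x$seed, ")\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}
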