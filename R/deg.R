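#' One-vs-rest Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Ranks the pooled values (average ranks for ties) and forms the rank
#' sums R_x, R_y of the two groups. The U statistics use the standard
#' rank-sum form `U = R - n(n+1)/2`, which satisfies the identities
#' `R_x + R_y = N(N+1)/2` and `U_x + U_y = n_x n_y`. Significance is
#' driven by `min(U_x, U_y)`; the two-sided p-value uses the normal
#' approximation with tie correction and continuity correction. When
#' every pooled value is tied the test is uninformative and `p = 1`.
#'
#' @param x numeric values in the target cluster (`n_x >= 1`).
#' @param y numeric values in all other clusters (`n_y >= 1`).
#' @return A list of class `rank_sum_result` with `U_x`, `U_y`, `n_x`,
#'   `n_y`, `R_x`, `R_y`, `statistic` (`min(U_x, U_y)`) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  n_x <- length(x); n_y <- length(y)
  if (n_x < 1 || n_y < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  R_x <- sum(r[seq_len(n_x)])
  R_y <- sum(r) - R_x
  U_x <- R_x - n_x * (n_x + 1) / 2
  U_y <- n_x * n_y - U_x
  ties <- table(c(x, y))
  p <- rank_sum_p(min(U_x, U_y), n_x, n_y, sum(ties^3 - ties))
  structure(list(U_x = U_x, U_y = U_y, n_x = n_x, n_y = n_y,
                 R_x = R_x, R_y = R_y, statistic = min(U_x, U_y),
                 p_value = p),
            class = "rank_sum_result")
}

# normal approximation, tie + continuity corrected, for U = min(U_x, U_y)
rank_sum_p <- function(U, n_x, n_y, tie_term) {
  N <- n_x + n_y
  sigma2 <- n_x * n_y / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  mu <- n_x * n_y / 2
  z <- (U - mu + 0.5) / sqrt(sigma2)     # U <= mu, shift towards the mean
  min(1, 2 * stats::pnorm(z))
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat("rank-sum test: U = ", x$statistic, " (U_x = ", x$U_x, ", U_y = ",
      x$U_y, "), n = ", x$n_x, "/", x$n_y, ", p = ",
      signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Per-cluster top differentially expressed genes
#'
#' For every cluster, each gene is tested one-vs-rest with
#' [rank_sum_test] (target cluster vs. all other spots) and genes are
#' ordered by ascending p-value; ties are broken by larger absolute
#' rank-biserial effect size (`2 U_x / (n_x n_y) - 1`), then by gene
#' index. Clusters with fewer than two spots are skipped with a warning.
#'
#' @param x normalized expression ([normalize_counts] result or a
#'   spots-by-genes matrix).
#' @param clusters a [gmm_cluster] result or an integer label vector.
#' @param size number of top genes to return per cluster
#'   (`size <= n_genes`).
#' @return Named list (one element per cluster) of character vectors of
#'   gene ids; the full ranking is attached as attribute `ranking` (a
#'   per-cluster list of data.frames with `gene`, `U`, `p`).
#' @export
deg_per_cluster <- function(x, clusters, size) {
  vals <- as.matrix(expr_values(x))
  labels <- cluster_labels(clusters, nrow(vals))
  if (size > ncol(vals))
    stop("size (", size, ") exceeds the number of genes (", ncol(vals), ")")
  stats_list <- deg_statistics(vals, labels)
  out <- lapply(stats_list, function(df) df$gene[seq_len(size)])
  attr(out, "ranking") <- stats_list
  out
}

cluster_labels <- function(clusters, n) {
  labels <- if (inherits(clusters, "cluster_assignment"))
    clusters$labels else as.integer(factor(clusters))
  if (length(labels) != n)
    stop("cluster labels must cover all ", n, " spots")
  labels
}

# vectorized one-vs-rest rank-sum statistics for every gene and cluster
deg_statistics <- function(vals, labels) {
  n <- nrow(vals); G <- ncol(vals)
  gene_ids <- colnames(vals)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(G))
  rk <- apply(vals, 2L, rank)                     # pooled ranks per gene
  tie_term <- apply(vals, 2L, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  clusters <- sort(unique(labels))
  res <- list()
  for (cl in clusters) {
    idx <- labels == cl
    n_x <- sum(idx); n_y <- n - n_x
    if (n_x < 2L) {
      warning("cluster ", cl, " has fewer than 2 spots; skipped")
      next
    }
    R_x <- colSums(rk[idx, , drop = FALSE])
    U_x <- R_x - n_x * (n_x + 1) / 2
    U <- pmin(U_x, n_x * n_y - U_x)
    p <- vapply(seq_len(G), function(j)
      rank_sum_p(U[j], n_x, n_y, tie_term[j]), numeric(1))
    rb <- abs(2 * U_x / (n_x * n_y) - 1)          # rank-biserial effect
    ord <- order(p, -rb, seq_len(G))
    res[[as.character(cl)]] <-
      data.frame(gene = gene_ids[ord], U = U[ord], p = p[ord],
                 effect = rb[ord], row.names = NULL)
  }
  if (length(res) == 0) stop("no cluster with at least 2 spots")
  res
}

#' Select DEG lists by the non-zero-rate window
#'
#' For every candidate list size, the union over clusters of each
#' cluster's top-`size` genes is formed and the non-zero rate of the
#' expression sub-matrix restricted to that union is computed. Sizes
#' whose rate falls inside `window` (default 0.3--0.4) are selected;
#' each keeps a useful amount of signal while bounding the dropout
#' burden of the resulting matrix. If no size qualifies, the single size
#' whose rate is nearest the window is kept as a fallback (with a
#' message).
#'
#' @param x normalized expression ([normalize_counts] result or matrix).
#' @param clusters a [gmm_cluster] result or label vector.
#' @param size_grid candidate per-cluster list sizes; sizes exceeding the
#'   gene count are dropped (the gene count itself is scanned instead).
#' @param window length-2 numeric non-zero-rate window.
#' @return A list of class `deg_selection`: `candidates` (data.frame with
#'   `size`, `n_union`, `nonzero_rate`, `selected`), `lists` (named list
#'   of selected union gene-id vectors), `per_cluster_rankings`, and
#'   `window`.
#' @export
select_deg_lists <- function(x, clusters,
                             size_grid = c(25, 50, 100, 150, 200, 250,
                                           300, 350, 400, 450, 500),
                             window = c(0.3, 0.4)) {
  vals <- as.matrix(expr_values(x))
  labels <- cluster_labels(clusters, nrow(vals))
  stopifnot(length(size_grid) >= 1, length(window) == 2,
            window[1] <= window[2])
  G <- ncol(vals)
  size_grid <- sort(unique(pmin(as.integer(size_grid), G)))
  stats_list <- deg_statistics(vals, labels)
  unions <- lapply(size_grid, function(s)
    unique(unlist(lapply(stats_list, function(df) df$gene[seq_len(s)]),
                  use.names = FALSE)))
  rates <- vapply(unions, function(genes)
    nonzero_rate(vals[, genes, drop = FALSE]), numeric(1))
  inside <- rates >= window[1] & rates <= window[2]
  if (!any(inside)) {
    dist <- pmax(window[1] - rates, rates - window[2], 0)
    inside <- seq_along(rates) == which.min(dist)
    message("no DEG list size reaches a non-zero rate in [", window[1],
            ", ", window[2], "]; falling back to size ",
            size_grid[inside], " (rate ", signif(rates[inside], 3), ")")
  }
  stopifnot(any(inside))
  cand <- data.frame(size = size_grid,
                     n_union = lengths(unions),
                     nonzero_rate = rates, selected = inside)
  sel <- unions[inside]
  names(sel) <- paste0("size_", size_grid[inside])
  structure(list(candidates = cand, lists = sel,
                 per_cluster_rankings = stats_list, window = window),
            class = "deg_selection")
}

#' @export
print.deg_selection <- function(x, ...) {
  cat("deg_selection: ", sum(x$candidates$selected), " list(s) in window [",
      x$window[1], ", ", x$window[2], "]\n", sep = "")
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Export DEG rankings as TSV
#'
#' @param selection a [select_deg_lists] result.
#' @param file output path (columns: cluster, rank, gene, U, p).
#' @export
write_deg_lists <- function(selection, file) {
  rows <- do.call(rbind, lapply(names(selection$per_cluster_rankings),
    function(cl) {
      df <- selection$per_cluster_rankings[[cl]]
      data.frame(cluster = cl, rank = seq_len(nrow(df)), gene = df$gene,
                 U = df$U, p = df$p)
    }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
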