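#' Build the spatial k-nearest-neighbour graph
#'
#' Each spot is connected to its `k` nearest Euclidean neighbours, plus a
#' self-loop: the neighbourhood N_u used by the attention layers always
#' contains u itself. Distance ties are broken by smaller spot index, so
#' the graph is deterministic for a fixed input. With
#' `symmetrize = TRUE` (default) the union with all reversed edges is
#' returned, so attention aggregation sees mutual neighbourhoods.
#'
#' @param coords spots-by-2 coordinate matrix (or an [st_dataset]).
#' @param k number of nearest neighbours, default 6.
#' @param symmetrize add reversed edges, default `TRUE`.
#' @return An object of class `spatial_graph`: list with `n_nodes`,
#'   `edges` (two-column integer matrix of ordered pairs `(u, v)` meaning
#'   v is in N_u), `k`, and `neighbors` (per-node integer list, self
#'   included).
#' @export
build_knn_graph <- function(coords, k = 6L, symmetrize = TRUE) {
  if (inherits(coords, "st_dataset")) coords <- coords$coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (",
                   n, ")")
  sq <- rowSums(coords^2)
  nbr <- vector("list", n)
  block <- 1024L
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) -
      2 * coords[rows, , drop = FALSE] %*% t(coords)
    for (i in seq_along(rows)) {
      u <- rows[i]
      d <- d2[i, ]
      d[u] <- -Inf                       # self first, then by distance
      ord <- order(d, seq_len(n))        # ties broken by smaller index
      nbr[[u]] <- ord[seq_len(k + 1L)]
    }
  }
  edges <- cbind(u = rep(seq_len(n), each = k + 1L),
                 v = unlist(nbr, use.names = FALSE))
  if (symmetrize) {
    edges <- unique(rbind(edges, edges[, 2:1, drop = FALSE]))
    colnames(edges) <- c("u", "v")
  }
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  nb <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n)))
  structure(list(n_nodes = n, edges = edges, k = as.integer(k),
                 neighbors = unname(lapply(nb, as.integer))),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph: ", x$n_nodes, " nodes, ", nrow(x$edges),
      " directed edges (k = ", x$k, ", self-loops included)\n", sep = "")
  invisible(x)
}

#' Export the edge list as a two-column TSV
#'
#' @param graph a [build_knn_graph] result.
#' @param file output path.
#' @export
write_graph <- function(graph, file) {
  utils::write.table(graph$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
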