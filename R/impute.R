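#' Impute dropout entries by within-cluster non-zero gene means
#'
#' Every zero entry (treated as a dropout event) of gene i in spot j is
#' replaced by the mean of the non-zero values of gene i over the spots
#' sharing spot j's cluster. Non-zero entries are never touched. If a
#' gene has no non-zero value anywhere in a cluster, its zero entries in
#' that cluster stay zero.
#'
#' @param x spots-by-genes matrix (typically normalized expression
#'   restricted to a DEG list) or `normalized_matrix`.
#' @param clusters a [gmm_cluster] result or label vector covering all
#'   spots.
#' @return The imputed matrix (same dimensions and dimnames).
#' @export
impute_with_clusters <- function(x, clusters) {
  vals <- as.matrix(expr_values(x))
  labels <- cluster_labels(clusters, nrow(vals))
  out <- vals
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    sub <- vals[idx, , drop = FALSE]
    nz <- sub != 0
    cnt <- colSums(nz)
    mean_nz <- ifelse(cnt > 0, colSums(sub) / cnt, 0)
    fill <- matrix(mean_nz, nrow = length(idx), ncol = ncol(sub),
                   byrow = TRUE)
    sub[!nz] <- fill[!nz]
    out[idx, ] <- sub
  }
  out
}

#' Average imputed matrices across DEG lists
#'
#' Combines the K per-list imputed matrices into the final denoised
#' matrix over the union of their gene sets: the entry for gene i, spot
#' j is the mean of the per-list estimates over the lists that contain
#' gene i. Observed (originally non-zero) entries are identical in every
#' list that carries the gene, so they pass through unchanged.
#'
#' @param per_list list of K imputed spots-by-genes matrices (possibly
#'   different gene columns; columns must be named).
#' @param observed optional original (pre-imputation) matrix used to
#'   record which entries were observed; if `NULL` the mask is derived
#'   from the per-list matrices (an entry is observed if non-zero and
#'   identical across carrying lists' inputs cannot be distinguished, so
#'   supplying `observed` is preferred in pipelines).
#' @return A list of class `imputation_result`: `final` (spots x union
#'   genes), `per_list`, `gene_union`, `n_lists` (per-gene count of
#'   carrying lists) and `observed_mask` (or `NULL`).
#' @export
merge_imputations <- function(per_list, observed = NULL) {
  stopifnot(is.list(per_list), length(per_list) >= 1)
  per_list <- lapply(per_list, as.matrix)
  gene_union <- unique(unlist(lapply(per_list, colnames),
                              use.names = FALSE))
  if (length(gene_union) == 0) stop("empty gene union across DEG lists")
  n <- nrow(per_list[[1L]])
  acc <- matrix(0, n, length(gene_union),
                dimnames = list(rownames(per_list[[1L]]), gene_union))
  cnt <- matrix(0L, n, length(gene_union))
  for (m in per_list) {
    j <- match(colnames(m), gene_union)
    acc[, j] <- acc[, j] + m
    cnt[, j] <- cnt[, j] + 1L
  }
  final <- acc / pmax(cnt, 1L)
  mask <- NULL
  if (!is.null(observed)) {
    observed <- as.matrix(expr_values(observed))
    miss <- setdiff(gene_union, colnames(observed))
    if (length(miss) > 0)
      stop("observed matrix lacks genes: ",
           paste(utils::head(miss, 5), collapse = ", "))
    obs <- observed[, gene_union, drop = FALSE]
    mask <- obs != 0
    final[mask] <- obs[mask]            # bit-identical pass-through
  }
  structure(list(final = final, per_list = per_list,
                 gene_union = gene_union, n_lists = cnt[1L, ],
                 observed_mask = mask),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("imputation_result: ", nrow(x$final), " spots x ",
      length(x$gene_union), " genes (union of ", length(x$per_list),
      " DEG list(s))\n", sep = "")
  if (!is.null(x$observed_mask))
    cat("  imputed entries: ",
        signif(mean(!x$observed_mask) * 100, 3), "%\n", sep = "")
  invisible(x)
}

#' Per-gene imputation report
#'
#' @param x an [merge_imputations] result with an observed mask.
#' @return data.frame with `gene` and `frac_imputed` (fraction of spots
#'   whose entry was filled in).
#' @export
imputation_report <- function(x) {
  stopifnot(inherits(x, "imputation_result"),
            !is.null(x$observed_mask))
  data.frame(gene = x$gene_union,
             frac_imputed = colMeans(!x$observed_mask),
             row.names = NULL)
}
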