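#' Fraction of non-zero entries of an expression matrix
#'
#' The non-zero rate is the data-quality statistic driving both the
#' minimum-count gene filter (target rate 0.14 at preprocessing) and the
#' DEG-list selection window (0.3--0.4).
#'
#' @param m a count or normalized matrix (dense or sparse), an
#'   [st_dataset], or a [normalize_counts] result.
#' @return The fraction of entries that are non-zero, in `[0, 1]`.
#' @export
nonzero_rate <- function(m) {
  m <- expr_values(m)
  if (length(m) == 0 || prod(dim(m)) == 0)
    stop("cannot compute a non-zero rate on an empty matrix")
  if (inherits(m, "sparseMatrix"))
    return(sum(m@x != 0) / prod(dim(m)))
  sum(m != 0) / length(m)
}

expr_values <- function(m) {
  if (inherits(m, "st_dataset")) return(m$counts)
  if (inherits(m, "normalized_matrix")) return(m$values)
  m
}

#' Gene-level minimum-count filter
#'
#' Removes genes whose total count across all spots is below `min_count`,
#' preserving gene order.
#'
#' @param d an [st_dataset].
#' @param min_count non-negative integer threshold.
#' @return The filtered `st_dataset`.
#' @export
filter_genes <- function(d, min_count) {
  stopifnot(inherits(d, "st_dataset"), min_count >= 0)
  keep <- which(Matrix::colSums(d$counts) >= min_count)
  if (length(keep) == 0)
    stop("min_count = ", min_count, " removes every gene")
  subset_dataset(d, genes = keep)
}

#' Estimate the minimum-count threshold from the non-zero rate
#'
#' Scans integer thresholds t = 0, 1, 2, ... and, for each, computes the
#' non-zero rate of the matrix after removing genes with total count
#' below t. The estimate is the smallest t whose filtered matrix reaches
#' `target_rate` (removing as few genes as possible). High-quality data
#' whose unfiltered rate already meets the target fall back to the floor
#' threshold (`floor_count`, default 5): only near-empty genes are
#' dropped. Image-based (STARmap) datasets skip this step entirely
#' because their gene panels are already small and curated.
#'
#' @param d an [st_dataset] (`platform` must not be `"starmap"`).
#' @param target_rate target non-zero rate, default 0.14.
#' @param floor_count threshold returned when the raw matrix already
#'   meets `target_rate`, default 5.
#' @param ceiling largest threshold scanned, default 1000.
#' @return A list with `threshold` (integer) and `curve`, a data.frame of
#'   class `quality_curve` with columns `threshold`, `nonzero_rate`,
#'   `genes_removed` recording the scan.
#' @export
estimate_min_count <- function(d, target_rate = 0.14, floor_count = 5L,
                               ceiling = 1000L) {
  stopifnot(inherits(d, "st_dataset"))
  if (d$platform == "starmap")
    stop("minimum-count estimation is skipped for image-based (starmap) data")
  sums <- Matrix::colSums(d$counts)
  nnz <- Matrix::colSums(d$counts != 0)
  n_spots <- nrow(d$counts)
  t_max <- min(ceiling, max(sums) )     # beyond max(sums) everything is gone
  thresholds <- 0:t_max
  ord <- order(sums)
  cs_nnz <- cumsum(nnz[ord])            # nnz removed if genes 1..i dropped
  n_removed <- findInterval(thresholds - 0.5, sums[ord])
  total_nnz <- sum(nnz)
  genes_left <- length(sums) - n_removed
  rate <- (total_nnz - c(0, cs_nnz)[n_removed + 1L]) /
    (n_spots * pmax(genes_left, 1L))
  rate[genes_left == 0] <- NA_real_
  curve <- data.frame(threshold = thresholds, nonzero_rate = rate,
                      genes_removed = n_removed)
  curve <- curve[!is.na(curve$nonzero_rate), , drop = FALSE]
  class(curve) <- c("quality_curve", "data.frame")
  if (curve$nonzero_rate[1L] >= target_rate)
    return(list(threshold = as.integer(floor_count), curve = curve))
  ok <- which(curve$nonzero_rate >= target_rate)
  if (length(ok) == 0)
    stop("no threshold up to ", t_max, " reaches a non-zero rate of ",
         target_rate, " (maximum achievable: ",
         signif(max(curve$nonzero_rate), 4), ")")
  list(threshold = as.integer(curve$threshold[ok[1L]]), curve = curve)
}

#' @export
plot.quality_curve <- function(x, target_rate = 0.14, ...) {
  graphics::plot(x$threshold, x$nonzero_rate, type = "l",
                 xlab = "minimum count threshold",
                 ylab = "non-zero rate", ...)
  graphics::abline(h = target_rate, lty = 2)
  invisible(x)
}

#' Library-size normalization and log transform
#'
#' Scales each spot's counts so that every library size equals
#' `target_size` (default: the median raw library size), then applies
#' `log(1 + x)`. Zeros map exactly to zeros, so the dropout pattern of
#' the raw matrix is preserved.
#'
#' @param d an [st_dataset].
#' @param target_size target library size; `NULL` uses the median.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (dense spots-by-genes matrix), `spot_ids`, `gene_ids` and
#'   `provenance` (target size plus any filters recorded upstream).
#' @export
normalize_counts <- function(d, target_size = NULL) {
  stopifnot(inherits(d, "st_dataset"))
  lib <- Matrix::rowSums(d$counts)
  if (any(lib == 0))
    stop("spot(s) with zero total count: ",
         paste(utils::head(d$spot_ids[lib == 0], 5), collapse = ", "))
  if (is.null(target_size)) target_size <- stats::median(lib)
  vals <- as.matrix(d$counts * (target_size / lib))
  vals <- log1p(vals)
  dimnames(vals) <- list(d$spot_ids, d$gene_ids)
  structure(list(values = vals, spot_ids = d$spot_ids,
                 gene_ids = d$gene_ids,
                 provenance = list(target_size = target_size)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix: ", nrow(x$values), " spots x ", ncol(x$values),
      " genes (library target ", signif(x$provenance$target_size, 5),
      ", log1p)\n", sep = "")
  invisible(x)
}
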