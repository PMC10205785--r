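#' Spatial transcriptomics dataset container
#'
#' An `st_dataset` bundles a spots-by-genes count matrix with 2-D spot
#' coordinates and optional per-spot annotation labels. Sequencing-based
#' platforms (10x Visium) use array row/column coordinates for graph
#' construction; image-based platforms (STARmap) use cell centroids.
#'
#' Counts are stored spots-by-genes. Readers for on-disk formats that use
#' the genes-by-spots convention (MatrixMarket triplets) transpose on load.
#'
#' @param counts non-negative count matrix, spots in rows, genes in columns
#'   (dense or `Matrix` sparse).
#' @param coords numeric matrix/data.frame with one row per spot and two
#'   columns of spatial coordinates.
#' @param spot_ids character vector of unique spot barcodes / cell ids.
#' @param gene_ids character vector of gene identifiers; duplicates are
#'   made unique by suffixing a counter.
#' @param labels optional character vector of per-spot annotation labels
#'   (`NA` marks unannotated spots).
#' @param platform one of `"visium"`, `"starmap"`, `"generic"`.
#' @param in_tissue optional logical/0-1 vector flagging spots inside the
#'   main tissue area (Visium `in_tissue` column).
#' @param pixel_coords optional full-resolution pixel coordinates, kept for
#'   plotting only.
#' @return An object of class `st_dataset`.
#' @export
st_dataset <- function(counts, coords, spot_ids = rownames(counts),
                       gene_ids = colnames(counts), labels = NULL,
                       platform = c("generic", "visium", "starmap"),
                       in_tissue = NULL, pixel_coords = NULL) {
  platform <- match.arg(platform)
  counts <- as_count_matrix(counts)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(counts) != length(spot_ids))
    stop("counts has ", nrow(counts), " rows but ", length(spot_ids),
         " spot ids were given")
  if (ncol(counts) != length(gene_ids))
    stop("counts has ", ncol(counts), " columns but ", length(gene_ids),
         " gene ids were given")
  if (nrow(coords) != nrow(counts) || ncol(coords) != 2L)
    stop("coords must be a ", nrow(counts), " x 2 matrix")
  if (anyDuplicated(spot_ids))
    stop("duplicated spot ids: ",
         paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids)) gene_ids <- make.unique(gene_ids, sep = "_")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(!is.finite(counts@x))) stop("counts must be finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(counts))
      stop("labels must have one entry per spot")
  }
  if (!is.null(in_tissue)) {
    in_tissue <- as.logical(as.integer(in_tissue))
    if (length(in_tissue) != nrow(counts))
      stop("in_tissue must have one entry per spot")
  }
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  rownames(coords) <- spot_ids
  structure(list(counts = counts, spot_ids = spot_ids, gene_ids = gene_ids,
                 coords = coords, labels = labels, platform = platform,
                 in_tissue = in_tissue, pixel_coords = pixel_coords),
            class = "st_dataset")
}

as_count_matrix <- function(m) {
  if (inherits(m, "sparseMatrix")) return(methods::as(m, "CsparseMatrix"))
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat("st_dataset (", x$platform, "): ", nrow(x$counts), " spots x ",
      ncol(x$counts), " genes\n", sep = "")
  cat("  non-zero rate: ", signif(nonzero_rate(x$counts), 4), "\n", sep = "")
  if (!is.null(x$labels))
    cat("  labels: ", length(unique(stats::na.omit(x$labels))),
        " classes (", sum(is.na(x$labels)), " unannotated)\n", sep = "")
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$counts)

#' Subset an st_dataset by spots and/or genes
#'
#' @param x an [st_dataset].
#' @param spots,genes index vectors (integer, logical, or id character).
#' @return The subsetted `st_dataset`.
#' @export
subset_dataset <- function(x, spots = NULL, genes = NULL) {
  if (is.null(spots)) spots <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  if (is.character(spots)) spots <- match(spots, x$spot_ids)
  if (is.character(genes)) genes <- match(genes, x$gene_ids)
  st_dataset(x$counts[spots, genes, drop = FALSE],
             coords = x$coords[spots, , drop = FALSE],
             spot_ids = x$spot_ids[spots], gene_ids = x$gene_ids[genes],
             labels = if (!is.null(x$labels)) x$labels[spots],
             platform = x$platform,
             in_tissue = if (!is.null(x$in_tissue)) x$in_tissue[spots],
             pixel_coords = if (!is.null(x$pixel_coords))
               x$pixel_coords[spots, , drop = FALSE])
}

#' Remove unusable spots
#'
#' Drops spots flagged as outside the main tissue area (Visium
#' `in_tissue = 0`) and, when annotation labels are attached, spots without
#' an annotation (`NA` or empty label). These outlier spots have very low
#' sequencing quality and typically no adjacent neighbours on the array.
#' The operation is idempotent.
#'
#' @param d an [st_dataset].
#' @return The filtered `st_dataset`.
#' @export
remove_outlier_spots <- function(d) {
  stopifnot(inherits(d, "st_dataset"))
  keep <- rep(TRUE, nrow(d$counts))
  if (!is.null(d$in_tissue)) keep <- keep & d$in_tissue
  if (!is.null(d$labels))
    keep <- keep & !is.na(d$labels) & nzchar(trimws(d$labels))
  if (!any(keep)) stop("all spots were removed as outliers")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("removed ", n_drop, " outlier spot(s) (out-of-tissue or unannotated)")
  subset_dataset(d, spots = which(keep))
}

#' Attach ground-truth labels to a dataset
#'
#' @param d an [st_dataset].
#' @param labels either a character vector aligned with `d$spot_ids`, or a
#'   named vector / two-column data.frame mapping spot id to label. Spots
#'   absent from the mapping get `NA`.
#' @return `d` with `labels` set.
#' @export
set_labels <- function(d, labels) {
  stopifnot(inherits(d, "st_dataset"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  }
  if (!is.null(names(labels))) {
    labels <- unname(labels[match(d$spot_ids, names(labels))])
  }
  d$labels <- as.character(labels)
  if (length(d$labels) != length(d$spot_ids))
    stop("labels must map every spot")
  d
}
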