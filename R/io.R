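#' Load a spatial transcriptomics dataset from disk
#'
#' Two on-disk layouts are recognised:
#' \describe{
#'   \item{`visium`}{a directory holding a MatrixMarket triplet
#'     (`matrix.mtx[.gz]`, `barcodes.tsv[.gz]`, `features.tsv[.gz]`,
#'     possibly under a `spatial/` or nested subdirectory) plus a spot
#'     position table (`tissue_positions_list.csv` legacy 6-column format
#'     or headered `tissue_positions.csv`). The matrix is stored
#'     genes-by-barcodes on disk and transposed to spots-by-genes on load.
#'     Barcodes missing from the position table are dropped with a
#'     message.}
#'   \item{`starmap` / `generic`}{a directory holding one cells-by-genes
#'     delimited count table (file name containing `count`, `expr` or
#'     `matrix`) and one coordinate table (name containing `coord`,
#'     `position` or `centroid`) with cell id plus two coordinate
#'     columns.}
#' }
#' If a two-column `truth`/`label` table is present it is attached as
#' ground-truth labels.
#'
#' @param path directory containing the dataset.
#' @param platform `"visium"`, `"starmap"` or `"generic"`.
#' @return An [st_dataset].
#' @export
load_dataset <- function(path, platform = c("visium", "starmap", "generic")) {
  platform <- match.arg(platform)
  if (!dir.exists(path)) stop("dataset directory not found: ", path)
  d <- if (platform == "visium") load_visium(path) else
    load_table_dataset(path, platform)
  lab <- find_file(path, "truth|label", required = FALSE)
  if (!is.null(lab)) d <- set_labels(d, read_labels(lab))
  d
}

find_file <- function(path, pattern, required = TRUE, what = pattern) {
  hits <- list.files(path, pattern = pattern, recursive = TRUE,
                     full.names = TRUE, ignore.case = TRUE)
  hits <- hits[!grepl("\\.(png|jpg|json)$", hits)]
  if (length(hits) == 0) {
    if (required) stop("no file matching '", what, "' found under ", path)
    return(NULL)
  }
  hits[[1L]]
}

load_visium <- function(path) {
  mtx <- find_file(path, "matrix\\.mtx(\\.gz)?$", what = "matrix.mtx")
  bc <- find_file(path, "barcodes\\.tsv(\\.gz)?$", what = "barcodes.tsv")
  ft <- find_file(path, "features\\.tsv(\\.gz)?$|genes\\.tsv(\\.gz)?$",
                  what = "features.tsv")
  pos <- find_file(path, "tissue_positions.*\\.csv(\\.gz)?$",
                   what = "tissue_positions")
  m <- Matrix::readMM(mtx)                      # genes x barcodes on disk
  barcodes <- readLines(bc)
  features <- utils::read.delim(ft, header = FALSE,
                                stringsAsFactors = FALSE)
  gene_ids <- as.character(features[[min(2L, ncol(features))]])
  if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match features/barcodes files")
  ptab <- read_positions(pos)
  idx <- match(barcodes, ptab$barcode)
  if (all(is.na(idx)))
    stop("no barcode in the count matrix matches the position table; ",
         "first offenders: ",
         paste(utils::head(barcodes, 3), collapse = ", "))
  if (anyNA(idx))
    message("dropped ", sum(is.na(idx)),
            " spot(s) absent from the position table")
  keep <- which(!is.na(idx))
  ptab <- ptab[idx[keep], , drop = FALSE]
  st_dataset(Matrix::t(m[, keep, drop = FALSE]),
             coords = cbind(ptab$array_row, ptab$array_col),
             spot_ids = barcodes[keep], gene_ids = gene_ids,
             platform = "visium", in_tissue = ptab$in_tissue,
             pixel_coords = cbind(ptab$pxl_row, ptab$pxl_col))
}

read_positions <- function(file) {
  first <- readLines(file, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  tab <- utils::read.csv(file, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 6L)
    stop("position table ", file, " must have 6 columns")
  names(tab) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row", "pxl_col")
  tab
}

load_table_dataset <- function(path, platform) {
  cf <- find_file(path, "count|expr|matrix", what = "count table")
  xf <- find_file(path, "coord|position|centroid", what = "coordinate table")
  counts <- read_delimited(cf, rownames = TRUE)
  coords <- read_delimited(xf, rownames = TRUE)
  idx <- match(rownames(counts), rownames(coords))
  if (all(is.na(idx)))
    stop("cell ids in ", cf, " do not match ", xf, "; first offenders: ",
         paste(utils::head(rownames(counts), 3), collapse = ", "))
  if (anyNA(idx))
    message("dropped ", sum(is.na(idx)),
            " cell(s) absent from the coordinate table")
  keep <- which(!is.na(idx))
  st_dataset(as.matrix(counts[keep, , drop = FALSE]),
             coords = as.matrix(coords[idx[keep], 1:2, drop = FALSE]),
             spot_ids = rownames(counts)[keep],
             gene_ids = colnames(counts), platform = platform)
}

read_delimited <- function(file, rownames = FALSE) {
  sep <- if (grepl("\\.csv(\\.gz)?$", file)) "," else "\t"
  utils::read.table(file, header = TRUE, sep = sep, row.names =
                      if (rownames) 1L else NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a two-column spot-label table
#'
#' @param file TSV/CSV with spot id in column 1 and label in column 2.
#' @return Named character vector of labels.
#' @export
read_labels <- function(file) {
  if (!file.exists(file)) stop("label file not found: ", file)
  tab <- read_delimited(file)
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels labels (vector or [gmm_cluster] result).
#' @param spot_ids spot identifiers.
#' @param file output path.
#' @export
write_labels <- function(labels, spot_ids, file) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  utils::write.table(data.frame(spot_id = spot_ids, label = labels),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an expression matrix to disk
#'
#' @param m spots-by-genes matrix (dense or sparse).
#' @param file output path; `.mtx` writes MatrixMarket (genes-by-spots,
#'   the on-disk convention), anything else a dense CSV with gene columns.
#' @export
write_matrix <- function(m, file) {
  if (grepl("\\.mtx$", file)) {
    Matrix::writeMM(methods::as(methods::as(Matrix::t(Matrix::Matrix(m)),
                                            "generalMatrix"),
                    "CsparseMatrix"), file)
  } else {
    utils::write.csv(as.matrix(m), file, row.names = TRUE)
  }
  invisible(file)
}
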