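#' Configuration for the layered-tissue simulator
#'
#' The generator emulates a cortical-layer-like tissue: spots on a
#' regular 2-D lattice, horizontal bands of equal height forming the
#' spatial domains, negative-binomial counts with per-spot library-size
#' variation, domain-specific marker genes with elevated means in their
#' layer, and independent zero-masking (dropout) on top of the intrinsic
#' negative-binomial zeros.
#'
#' @param grid lattice size `c(rows, cols)`, default 16 x 16.
#' @param n_layers number of horizontal domains, default 4.
#' @param genes total gene count, default 200.
#' @param markers_per_layer marker genes per layer, default 10.
#' @param marker_log_fold natural-log fold elevation of a marker's mean
#'   inside its layer, default 2.
#' @param baseline_mean baseline negative-binomial mean per gene and
#'   spot, default 0.55.
#' @param library_size_cv coefficient of variation of the lognormal
#'   per-spot library size factor, default 0.2.
#' @param dropout_rate independent zero-masking probability, default 0.3.
#' @param dispersion negative-binomial size parameter, default 2.
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid = c(16L, 16L), n_layers = 4L, genes = 200L,
                       markers_per_layer = 10L, marker_log_fold = 2,
                       baseline_mean = 0.55, library_size_cv = 0.2,
                       dropout_rate = 0.3, dispersion = 2, seed = 1L) {
  cfg <- list(grid = as.integer(grid), n_layers = as.integer(n_layers),
              genes = as.integer(genes),
              markers_per_layer = as.integer(markers_per_layer),
              marker_log_fold = marker_log_fold,
              baseline_mean = baseline_mean,
              library_size_cv = library_size_cv,
              dropout_rate = dropout_rate, dispersion = dispersion,
              seed = as.integer(seed))
  stopifnot(length(cfg$grid) == 2, all(cfg$grid >= 1),
            cfg$n_layers >= 1, cfg$n_layers <= cfg$grid[1L],
            cfg$markers_per_layer * cfg$n_layers <= cfg$genes,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$baseline_mean > 0, cfg$dispersion > 0,
            cfg$library_size_cv >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a layered spatial transcriptomics dataset
#'
#' @param cfg a [sim_config].
#' @return A list of class `sim_dataset` with `dataset` (an [st_dataset]
#'   whose `labels` carry the true layer of each spot), `truth` (a
#'   `cluster_assignment` of the generating layers), and `markers`
#'   (named list of marker gene ids per layer).
#' @export
simulate_layered_tissue <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  rows <- cfg$grid[1L]; cols <- cfg$grid[2L]
  n <- rows * cols
  coords <- cbind(row = rep(seq_len(rows), each = cols),
                  col = rep(seq_len(cols), times = rows))
  layer <- ceiling(coords[, "row"] / (rows / cfg$n_layers))
  layer <- pmin(layer, cfg$n_layers)

  gene_ids <- sprintf("gene%03d", seq_len(cfg$genes))
  marker_of <- rep(NA_integer_, cfg$genes)
  marker_of[seq_len(cfg$n_layers * cfg$markers_per_layer)] <-
    rep(seq_len(cfg$n_layers), each = cfg$markers_per_layer)

  # lognormal library size factors with mean 1 and the requested CV
  sdlog <- sqrt(log1p(cfg$library_size_cv^2))
  sf <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))

  mu <- matrix(cfg$baseline_mean, n, cfg$genes)
  for (g in which(!is.na(marker_of)))
    mu[layer == marker_of[g], g] <-
      cfg$baseline_mean * exp(cfg$marker_log_fold)
  mu <- mu * sf

  counts <- matrix(stats::rnbinom(n * cfg$genes, mu = mu,
                                  size = cfg$dispersion), n, cfg$genes)
  if (cfg$dropout_rate > 0) {
    mask <- stats::runif(n * cfg$genes) < cfg$dropout_rate
    counts[mask] <- 0L
  }
  spot_ids <- sprintf("spot_%03d_%03d", coords[, "row"], coords[, "col"])
  d <- st_dataset(counts, coords = coords, spot_ids = spot_ids,
                  gene_ids = gene_ids,
                  labels = paste0("layer", layer), platform = "generic")
  truth <- structure(list(labels = as.integer(layer),
                          n_clusters = cfg$n_layers,
                          seed = cfg$seed),
                     class = "cluster_assignment")
  markers <- split(gene_ids[!is.na(marker_of)],
                   paste0("layer", marker_of[!is.na(marker_of)]))
  structure(list(dataset = d, truth = truth, markers = markers,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", x$config$grid[1L], "x", x$config$grid[2L],
      " lattice, ", x$config$n_layers, " layers, ", x$config$genes,
      " genes (", x$config$markers_per_layer, " markers/layer)\n",
      sep = "")
  print(x$dataset)
  invisible(x)
}

#' Write a simulated dataset as a Visium-style fixture directory
#'
#' Produces `matrix.mtx` (genes x barcodes), `barcodes.tsv`,
#' `features.tsv`, `tissue_positions_list.csv` (legacy 6-column format)
#' and `truth_labels.tsv`, so that [load_dataset] round-trips it.
#'
#' @param sim a [simulate_layered_tissue] result (or an [st_dataset]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_visium_fixture <- function(sim, dir) {
  d <- if (inherits(sim, "sim_dataset")) sim$dataset else sim
  stopifnot(inherits(d, "st_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(d$counts), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(d$spot_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = d$gene_ids, name = d$gene_ids,
               type = "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(barcode = d$spot_ids,
               in_tissue = if (is.null(d$in_tissue)) 1L
                           else as.integer(d$in_tissue),
               array_row = d$coords[, 1L], array_col = d$coords[, 2L],
               pxl_row = round(d$coords[, 1L] * 100),
               pxl_col = round(d$coords[, 2L] * 100)),
    file.path(dir, "tissue_positions_list.csv"), sep = ",",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(d$labels))
    utils::write.table(
      data.frame(spot_id = d$spot_ids, label = d$labels),
      file.path(dir, "truth_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(dir)
}
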