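# Shared fixture builders (everything is generated in code).

# Hand-written 4-spot x 5-gene Visium triplet, independent of the
# package's own writers. Returns the directory.
write_tiny_visium <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              n_positions = 4L) {
  counts <- tiny_counts()
  mm <- c("%%MatrixMarket matrix coordinate integer general",
          paste(nrow(counts), ncol(counts), sum(counts != 0)))
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      if (counts[i, j] != 0)
        mm <- c(mm, paste(i, j, counts[i, j]))
  writeLines(mm, file.path(dir, "matrix.mtx"))        # genes x barcodes
  writeLines(paste0("BC", 1:4), file.path(dir, "barcodes.tsv"))
  writeLines(paste0("ENSG", 1:5, "\tGENE", 1:5, "\tGene Expression"),
             file.path(dir, "features.tsv"))
  pos <- data.frame(barcode = paste0("BC", 4:1), in_tissue = 1L,
                    row = c(2L, 2L, 1L, 1L), col = c(2L, 1L, 2L, 1L),
                    pr = 40:37, pc = 50:47)[seq_len(n_positions), ]
  utils::write.table(pos, file.path(dir, "tissue_positions_list.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  dir
}

# genes x barcodes count matrix for the tiny fixture
tiny_counts <- function() {
  matrix(c(1, 0, 2, 0,
           0, 3, 0, 0,
           4, 5, 6, 7,
           0, 0, 0, 8,
           9, 1, 0, 2), nrow = 5, byrow = TRUE,
         dimnames = list(paste0("ENSG", 1:5), paste0("BC", 1:4)))
}

# st_dataset straight from matrices (grid coords)
make_dataset <- function(counts, labels = NULL, platform = "generic",
                         in_tissue = NULL) {
  n <- nrow(counts)
  coords <- cbind(seq_len(n), rep(1, n))
  st_dataset(counts, coords = coords, labels = labels,
             platform = platform, in_tissue = in_tissue)
}

# small, quick pipeline configuration for tests that exercise the flow
# rather than the full-size study conditions
small_config <- function(...) {
  adept_config(gae = gae_config(hidden_dim = 64, latent_dim = 16,
                                iterations = 200), ...)
}

small_sim <- function(seed = 1, n_layers = 2) {
  simulate_layered_tissue(sim_config(grid = c(8, 8), genes = 60,
                                     n_layers = n_layers,
                                     markers_per_layer = 8, seed = seed))
}

# hand-constructed spatial_graph from an explicit neighbour list
graph_from_neighbors <- function(neighbors) {
  edges <- cbind(u = rep(seq_along(neighbors), lengths(neighbors)),
                 v = unlist(neighbors, use.names = FALSE))
  structure(list(n_nodes = length(neighbors), edges = edges, k = NA_integer_,
                 neighbors = lapply(neighbors, as.integer)),
            class = "spatial_graph")
}

# enumerate all set partitions of n elements as label vectors
# (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxl) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxl + 1L))
      rec(c(prefix, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# pair-counting oracle: n11, n10, n01 over all item pairs by explicit loop
pair_counts <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- 0L
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1L
      else if (sa) n10 <- n10 + 1L
      else if (sb) n01 <- n01 + 1L
    }
  c(n11 = n11, n10 = n10, n01 = n01)
}

# brute-force Mann-Whitney U by pair counting: #{x_i > y_j} + 0.5 ties
brute_force_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}
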