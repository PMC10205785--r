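#' Pipeline configuration
#'
#' Collects the tunable parameters of the whole clustering pipeline:
#' preprocessing (`target_nonzero_rate` for the minimum-count gene
#' filter), spatial graph (`knn_k`, `symmetrize`), autoencoder
#' (`gae`, a [gae_config]; its seed is overridden per stage), DEG
#' selection (`size_grid`, `deg_window`, optional `max_deg_lists` cap),
#' and replicate runs (`n_runs`, `base_seed`).
#'
#' @param target_nonzero_rate non-zero-rate target of the minimum-count
#'   filter, default 0.14.
#' @param knn_k spatial graph neighbours, default 6.
#' @param symmetrize mutualize the kNN graph, default `TRUE`.
#' @param gae a [gae_config].
#' @param size_grid candidate DEG list sizes.
#' @param deg_window non-zero-rate window for DEG list selection.
#' @param max_deg_lists cap on the number of selected DEG lists
#'   (`Inf` = keep all selected).
#' @param target_library_size library-size normalization target
#'   (`NULL` = median).
#' @param n_runs replicate runs for [adept_replicates], default 20.
#' @param base_seed first seed of a replicate series.
#' @return A list of class `adept_config`.
#' @export
adept_config <- function(target_nonzero_rate = 0.14, knn_k = 6L,
                         symmetrize = TRUE, gae = gae_config(),
                         size_grid = c(25, 50, 100, 150, 200, 250, 300,
                                       350, 400, 450, 500),
                         deg_window = c(0.3, 0.4), max_deg_lists = Inf,
                         target_library_size = NULL, n_runs = 20L,
                         base_seed = 1L) {
  stopifnot(inherits(gae, "gae_config"), knn_k >= 1, n_runs >= 1,
            target_nonzero_rate > 0, target_nonzero_rate < 1,
            max_deg_lists >= 1)
  structure(list(target_nonzero_rate = target_nonzero_rate,
                 knn_k = as.integer(knn_k), symmetrize = symmetrize,
                 gae = gae, size_grid = size_grid,
                 deg_window = deg_window, max_deg_lists = max_deg_lists,
                 target_library_size = target_library_size,
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed)),
            class = "adept_config")
}

# derived per-stage seeds, kept well below 2^31
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) %% 1e5) + offset * 100003 + 7)
}

#' Multi-stage spatial-domain clustering
#'
#' Fits the full pipeline to a spatial transcriptomics dataset:
#' \enumerate{
#'   \item preprocessing: outlier-spot removal, non-zero-rate driven
#'     minimum-count gene filtering (skipped for image-based `starmap`
#'     data), library-size normalization with log transform;
#'   \item spatial kNN graph over the spot coordinates;
#'   \item graph attention autoencoder embedding and an initial Gaussian
#'     mixture clustering;
#'   \item one-vs-rest Mann-Whitney DEG ranking per initial cluster,
#'     selection of the K list sizes whose union sub-matrix has a
#'     non-zero rate inside the window; for each list the sub-matrix is
#'     re-embedded, re-clustered, and its dropouts imputed by
#'     within-cluster non-zero gene means; the K imputed matrices are
#'     averaged over the gene union;
#'   \item a final embedding and Gaussian mixture clustering on the
#'     merged imputed matrix.
#' }
#' All randomness is funnelled through per-stage seeds derived from
#' `seed`, so a run is fully reproducible.
#'
#' @param x an [st_dataset] (e.g. from [load_dataset] or
#'   [simulate_layered_tissue]).
#' @param n_clusters number of spatial domains to recover (in benchmark
#'   use, the annotated domain count).
#' @param config an [adept_config].
#' @param seed integer seed for this run.
#' @param verbose emit per-stage progress messages.
#' @return An object of class `adept`, with `print`, `summary`,
#'   `labels`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' sim <- simulate_layered_tissue(sim_config(grid = c(8, 8), genes = 60,
#'                                           n_layers = 2,
#'                                           markers_per_layer = 5))
#' cfg <- adept_config(gae = gae_config(hidden_dim = 32, latent_dim = 8,
#'                                      iterations = 50))
#' fit <- adept(sim$dataset, n_clusters = 2, config = cfg)
#' table(fitted_labels = labels(fit), truth = sim$truth$labels)
#' @export
adept <- function(x, n_clusters, config = adept_config(),
                  seed = config$base_seed, verbose = FALSE) {
  stopifnot(inherits(x, "st_dataset"), inherits(config, "adept_config"),
            n_clusters >= 2)
  say <- function(...) if (verbose) message(...)
  log <- list()
  stage <- function(name, expr) {
    say("[adept] stage: ", name)
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[name]] <<- list(stage = name,
                         seconds = as.numeric(Sys.time() - t0))
    out
  }

  # 1. preprocessing + quality control
  d <- stage("preprocess", remove_outlier_spots(x))
  qc <- NULL
  if (d$platform != "starmap") {
    qc <- stage("quality_control",
                estimate_min_count(d, config$target_nonzero_rate))
    d <- filter_genes(d, qc$threshold)
  } else say("[adept] starmap platform: minimum-count estimation skipped")
  norm <- stage("normalize",
                normalize_counts(d, config$target_library_size))

  # 2. spatial graph
  graph <- stage("graph",
                 build_knn_graph(d$coords, k = config$knn_k,
                                 symmetrize = config$symmetrize))

  # 3. initial embedding + clustering
  gcfg <- config$gae
  gcfg$seed <- derive_seed(seed, 1L)
  fit0 <- stage("gae_initial", train_gae(norm$values, graph, gcfg))
  cl0 <- stage("gmm_initial",
               gmm_cluster(fit0, n_clusters,
                           seed = derive_seed(seed, 2L)))

  # 4. DEG list selection, per-list clustering and imputation
  sel <- stage("deg_selection",
               select_deg_lists(norm, cl0, config$size_grid,
                                config$deg_window))
  lists <- sel$lists
  if (length(lists) > config$max_deg_lists)
    lists <- lists[seq_len(config$max_deg_lists)]
  say("[adept] ", length(lists), " DEG list(s) used for imputation")
  per_list <- vector("list", length(lists))
  list_clusters <- vector("list", length(lists))
  for (k in seq_along(lists)) {
    sub <- norm$values[, lists[[k]], drop = FALSE]
    gk <- config$gae
    gk$seed <- derive_seed(seed, 10L + k)
    fk <- stage(paste0("gae_list_", k), train_gae(sub, graph, gk))
    ck <- stage(paste0("gmm_list_", k),
                gmm_cluster(fk, n_clusters,
                            seed = derive_seed(seed, 40L + k)))
    per_list[[k]] <- impute_with_clusters(sub, ck)
    list_clusters[[k]] <- ck$labels
  }
  gene_union <- unique(unlist(lapply(per_list, colnames),
                              use.names = FALSE))
  imp <- stage("merge_imputations",
               merge_imputations(per_list,
                                 observed = norm$values[, gene_union,
                                                        drop = FALSE]))

  # 5. final embedding + clustering on the imputed matrix
  gf <- config$gae
  gf$seed <- derive_seed(seed, 3L)
  fitF <- stage("gae_final", train_gae(imp$final, graph, gf))
  clF <- stage("gmm_final",
               gmm_cluster(fitF, n_clusters,
                           seed = derive_seed(seed, 4L)))

  metrics <- NULL
  if (!is.null(d$labels)) {
    metrics <- list(
      initial = c(ari = ari(d$labels, cl0$labels),
                  fms = fms(d$labels, cl0$labels),
                  purity = purity(d$labels, cl0$labels)),
      final = c(ari = ari(d$labels, clF$labels),
                fms = fms(d$labels, clF$labels),
                purity = purity(d$labels, clF$labels)))
  }

  structure(list(call = match.call(), config = config,
                 n_clusters = as.integer(n_clusters),
                 seed = as.integer(seed),
                 dataset = list(platform = d$platform,
                                n_spots = nrow(d$counts),
                                n_genes_input = ncol(x$counts),
                                n_genes_kept = ncol(d$counts),
                                spot_ids = d$spot_ids,
                                coords = d$coords, labels = d$labels),
                 qc = qc, graph = graph,
                 initial = list(labels = cl0$labels,
                                loss_history = fit0$loss_history,
                                final_loss = fit0$final_loss),
                 deg = sel,
                 imputation = imp,
                 final = list(labels = clF$labels,
                              embedding = fitF$embedding,
                              reconstruction = fitF$reconstruction,
                              loss_history = fitF$loss_history,
                              final_loss = fitF$final_loss),
                 metrics = metrics, log = log),
            class = "adept")
}

#' Replicate runs of the pipeline
#'
#' Runs [adept] `n_runs` times with seeds `base_seed`,
#' `base_seed + 1`, ... and scores each run against the ground-truth
#' labels attached to the dataset, summarizing the mean and standard
#' deviation of each metric at the initial and final stage. The spread
#' across seeds is the pipeline's robustness statistic: the imputation
#' stage is designed to shrink it.
#'
#' @param x an [st_dataset] with ground-truth `labels`.
#' @param n_clusters number of spatial domains.
#' @param config an [adept_config]; `n_runs` and `base_seed` are taken
#'   from it unless overridden.
#' @param n_runs,base_seed optional overrides.
#' @param verbose print progress.
#' @return A list of class `adept_replicates`: `runs` (data.frame with
#'   per-seed initial/final ARI, FMS, purity), `summary` (mean and sd
#'   per metric), and `best_run` (seed of the max final ARI).
#' @export
adept_replicates <- function(x, n_clusters, config = adept_config(),
                             n_runs = config$n_runs,
                             base_seed = config$base_seed,
                             verbose = FALSE) {
  if (is.null(x$labels))
    stop("replicate evaluation requires ground-truth labels")
  seeds <- base_seed + seq_len(n_runs) - 1L
  rows <- vector("list", n_runs)
  fits <- vector("list", n_runs)
  for (i in seq_along(seeds)) {
    if (verbose) message("[adept] replicate ", i, "/", n_runs,
                         " (seed ", seeds[i], ")")
    fit <- adept(x, n_clusters, config, seed = seeds[i])
    fits[[i]] <- fit$final$labels
    rows[[i]] <- data.frame(seed = seeds[i],
                            ari_initial = fit$metrics$initial[["ari"]],
                            ari_final = fit$metrics$final[["ari"]],
                            fms_final = fit$metrics$final[["fms"]],
                            purity_final = fit$metrics$final[["purity"]])
  }
  runs <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("ari_initial", "ari_final", "fms_final", "purity_final"),
    mean = vapply(runs[, -1L], mean, numeric(1)),
    sd = vapply(runs[, -1L], stats::sd, numeric(1)), row.names = NULL)
  structure(list(runs = runs, summary = summ,
                 best_run = runs$seed[which.max(runs$ari_final)],
                 labels = fits),
            class = "adept_replicates")
}

#' @export
print.adept_replicates <- function(x, ...) {
  cat("adept_replicates: ", nrow(x$runs), " runs\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("best run (max final ARI): seed ", x$best_run, "\n", sep = "")
  invisible(x)
}
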