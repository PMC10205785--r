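#' @export
print.adept <- function(x, ...) {
  cat("adept fit: ", x$dataset$n_spots, " spots, ",
      x$dataset$n_genes_kept, "/", x$dataset$n_genes_input,
      " genes kept, ", x$n_clusters, " domains (seed ", x$seed, ")\n",
      sep = "")
  if (!is.null(x$qc))
    cat("  min-count threshold: ", x$qc$threshold, "\n", sep = "")
  cat("  DEG lists used: ", length(x$imputation$per_list),
      " (union of ", length(x$imputation$gene_union), " genes)\n",
      sep = "")
  if (!is.null(x$metrics)) {
    cat("  initial ARI: ", signif(x$metrics$initial[["ari"]], 4),
        "  final ARI: ", signif(x$metrics$final[["ari"]], 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Summarize a fitted pipeline
#'
#' @param object an [adept] fit.
#' @param ... unused.
#' @export
summary.adept <- function(object, ...) {
  x <- object
  print(x)
  cat("\nDomain sizes:\n")
  print(table(domain = x$final$labels))
  cat("\nDEG list candidates:\n")
  print(x$deg$candidates, row.names = FALSE)
  if (!is.null(x$metrics)) {
    cat("\nAgreement with ground truth:\n")
    print(rbind(initial = x$metrics$initial, final = x$metrics$final))
  }
  cat("\nStage timing (s):\n")
  t <- vapply(x$log, function(l) l$seconds, numeric(1))
  print(round(t, 2))
  invisible(x)
}

#' Final spatial-domain labels
#'
#' @param object an [adept] fit.
#' @param ... unused.
#' @return Integer vector of final domain labels (1..n_clusters), named
#'   by spot id.
#' @export
labels.adept <- function(object, ...) {
  stats::setNames(object$final$labels, object$dataset$spot_ids)
}

#' Final imputed expression matrix
#'
#' @param object an [adept] fit.
#' @param ... unused.
#' @return The merged imputed matrix (spots x DEG-union genes); observed
#'   entries equal the normalized input exactly.
#' @export
fitted.adept <- function(object, ...) {
  object$imputation$final
}

#' Reconstruction residuals of the final autoencoder
#'
#' @param object an [adept] fit.
#' @param ... unused.
#' @return Matrix of (imputed input - reconstruction) at the final
#'   stage.
#' @export
residuals.adept <- function(object, ...) {
  object$imputation$final - object$final$reconstruction
}

#' Plot spatial domains
#'
#' Scatter of spot coordinates coloured by final domain label (or, with
#' `stage = "initial"`, by the pre-imputation clustering).
#'
#' @param x an [adept] fit.
#' @param stage `"final"` or `"initial"`.
#' @param ... passed to [graphics::plot].
#' @export
plot.adept <- function(x, stage = c("final", "initial"), ...) {
  stage <- match.arg(stage)
  lab <- if (stage == "final") x$final$labels else x$initial$labels
  co <- x$dataset$coords
  pal <- grDevices::hcl.colors(max(lab), "Dark 3")
  graphics::plot(co[, 2L], -co[, 1L], col = pal[lab], pch = 15,
                 xlab = "array col", ylab = "array row",
                 main = paste0("spatial domains (", stage, ")"), ...)
  invisible(x)
}
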