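#' External clustering agreement metrics
#'
#' Pair-counting and contingency-table measures of agreement between two
#' partitions of the same spots:
#' \describe{
#'   \item{`ari`}{adjusted Rand index: the Rand index corrected for
#'     chance agreement; 1 for identical partitions, around 0 for
#'     independent ones, can be negative.}
#'   \item{`fms`}{Fowlkes--Mallows score `TP / sqrt((TP+FP) (TP+FN))`
#'     over spot pairs, in `[0, 1]`.}
#'   \item{`purity`}{mean over predicted clusters of the largest class
#'     overlap fraction, `(1/n) * sum_k max_j n_kj`, in `(0, 1]`.}
#' }
#' All three are invariant to label permutations.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number.
#' @export
ari <- function(a, b) {
  tab <- pair_table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  maxi <- (sa + sb) / 2
  if (abs(maxi - expected) < .Machine$double.eps * max(1, maxi))
    return(1)                                   # both partitions identical
  (sij - expected) / (maxi - expected)
}

#' @rdname ari
#' @export
fms <- function(a, b) {
  tab <- pair_table(a, b)
  tp <- sum(choose(tab, 2))
  pa <- sum(choose(rowSums(tab), 2))
  pb <- sum(choose(colSums(tab), 2))
  if (pa == 0 || pb == 0) return(0)
  tp / sqrt(pa * pb)
}

#' @rdname ari
#' @param truth,pred reference and predicted labels (purity is asymmetric:
#'   clusters of `pred` are scored against classes of `truth`).
#' @export
purity <- function(truth, pred) {
  tab <- pair_table(pred, truth)
  sum(apply(tab, 1L, max)) / sum(tab)
}

pair_table <- function(a, b) {
  if (inherits(a, "cluster_assignment")) a <- a$labels
  if (inherits(b, "cluster_assignment")) b <- b$labels
  if (length(a) != length(b))
    stop("label vectors differ in length (", length(a), " vs ",
         length(b), ")")
  if (length(a) == 0) stop("empty label vectors")
  unclass(table(a, b))
}

#' Rank competing methods across datasets
#'
#' Within each dataset (column), methods are ranked by score with rank 1
#' for the highest score; ties share the minimum rank. The sum and
#' average of ranks across datasets summarize overall standing, the
#' robustness statistic used to compare clustering tools across
#' heterogeneous benchmarks.
#'
#' @param scores methods-by-datasets numeric matrix (or data.frame) of
#'   scores where larger is better; row names identify methods.
#' @return A list of class `method_ranking`: `ranks` (integer matrix),
#'   `sum_rank` and `avg_rank` (named per-method vectors), and
#'   `best_count` (datasets in which each method attains the top score).
#' @export
rank_methods <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least two methods to rank")
  if (any(!is.finite(scores))) stop("scores contain missing values")
  ranks <- apply(scores, 2L, function(s)
    rank(-s, ties.method = "min"))
  ranks <- matrix(as.integer(ranks), nrow(scores),
                  dimnames = dimnames(scores))
  sum_rank <- rowSums(ranks)
  best <- rowSums(ranks == 1L)
  structure(list(ranks = ranks, sum_rank = sum_rank,
                 avg_rank = sum_rank / ncol(scores), best_count = best),
            class = "method_ranking")
}

#' @export
print.method_ranking <- function(x, ...) {
  tab <- data.frame(sum_rank = x$sum_rank, avg_rank = x$avg_rank,
                    best = x$best_count)
  print(tab[order(x$avg_rank), ])
  invisible(x)
}

#' Published benchmark score tables
#'
#' Loads the methods-by-datasets score matrices bundled with the package
#' (average ARI, purity and FMS of six spatial clustering tools on ten
#' annotated benchmark sections: eight DLPFC sections, one breast-cancer
#' section, one STARmap section).
#'
#' @param metric one of `"ari"`, `"purity"`, `"fms"`.
#' @return A 6 x 10 numeric matrix with method row names.
#' @export
benchmark_scores <- function(metric = c("ari", "purity", "fms")) {
  metric <- match.arg(metric)
  f <- system.file("extdata", paste0("benchmark_", metric, ".csv"),
                   package = "adept", mustWork = TRUE)
  as.matrix(utils::read.csv(f, row.names = 1L, check.names = FALSE))
}
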