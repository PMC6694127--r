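#' Pairwise Spearman correlation of fold-change vectors
#'
#' For every pair of datasets, the Spearman rank correlation of their log2
#' fold-change vectors over the genes the pair has in common (fold changes
#' for the full gene universe of each dataset, not only the DE genes).
#' Genes without a valid fold change are dropped before intersecting.
#'
#' @param results List of `de_result` objects carrying fold changes for
#'   their full gene universes.
#' @param min_common_genes Minimum common-gene count per pair; a pair below
#'   it is a hard error naming the pair.
#' @return List with `corr` (symmetric Spearman matrix, unit diagonal) and
#'   `n_common` (symmetric matrix of pairwise common-gene counts).
#' @export
fc_correlation <- function(results, min_common_genes = 100L) {
  ids <- vapply(results, function(r) r$dataset_id, "")
  if (anyDuplicated(ids)) fail("duplicate dataset ids")
  n <- length(ids)
  if (n < 2L) fail("need at least 2 datasets")
  vecs <- lapply(results, function(r) {
    t <- r$table[is.finite(r$table$log2fc), ]
    stats::setNames(t$log2fc, t$gene)
  })
  corr <- diag(1, n)
  n_common <- matrix(0L, n, n, dimnames = list(ids, ids))
  dimnames(corr) <- list(ids, ids)
  diag(n_common) <- vapply(vecs, length, 0L)
  pairs <- pair_index(n)
  for (pr in seq_len(nrow(pairs))) {
    i <- pairs[pr, 1]; j <- pairs[pr, 2]
    common <- intersect(names(vecs[[i]]), names(vecs[[j]]))
    if (length(common) < min_common_genes)
      fail("datasets '", ids[i], "' and '", ids[j], "' share only ",
           length(common), " genes (< ", min_common_genes, ")")
    rho <- stats::cor(vecs[[i]][common], vecs[[j]][common],
                      method = "spearman")
    corr[i, j] <- corr[j, i] <- rho
    n_common[i, j] <- n_common[j, i] <- length(common)
  }
  list(corr = corr, n_common = n_common)
}

#' Convert a correlation matrix to a distance matrix
#'
#' Two dialects of "Euclidean distance according to correlation
#' coefficients": `"corr_rows"` (default) treats each dataset's row of the
#' correlation matrix as its profile and takes Euclidean distances between
#' rows -- the common practice when a distance matrix is derived from a
#' correlation matrix in R; `"direct"` maps each coefficient through
#' `sqrt(2 * (1 - rho))`, the chordal distance of standardised variables.
#' Both yield a symmetric matrix with an exactly zero diagonal.
#'
#' @param corr Symmetric correlation matrix.
#' @param dialect `"corr_rows"` or `"direct"`.
#' @return Symmetric non-negative distance matrix, zero diagonal.
#' @export
correlation_to_distance <- function(corr,
                                    dialect = c("corr_rows", "direct")) {
  dialect <- match.arg(dialect)
  if (!isSymmetric(unname(corr))) fail("`corr` must be symmetric")
  d <- switch(dialect,
    corr_rows = as.matrix(stats::dist(corr)),
    direct = sqrt(pmax(2 * (1 - corr), 0))
  )
  diag(d) <- 0
  dimnames(d) <- dimnames(corr)
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, takes the top `k`
#' eigenpairs, and scales eigenvectors by the square root of their
#' eigenvalues. When fewer than `k` eigenvalues are positive the remaining
#' axes are zero-filled with a warning. The sign of each axis is fixed
#' deterministically (the largest-magnitude coordinate on each axis is made
#' positive) so repeated runs are bit-identical.
#'
#' @param dist Symmetric non-negative distance matrix with zero diagonal.
#' @param k Embedding dimension (default 2).
#' @return List with `embedding` (n x k coordinates, rows named as `dist`)
#'   and `eigenvalues` (all n, descending).
#' @export
classical_mds <- function(dist, k = 2L) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < k + 1L) fail("need at least k + 1 = ", k + 1L, " points")
  if (!isSymmetric(unname(dist)) || any(dist < 0) ||
      any(abs(diag(dist)) > 1e-12))
    fail("`dist` must be symmetric, non-negative, with zero diagonal")
  fit <- suppressWarnings(stats::cmdscale(dist, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = n)
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " of ", k,
            " requested axes have positive eigenvalues; zero-filling")
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  # deterministic sign convention per axis
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(dist)
  colnames(pts) <- paste0("dim", seq_len(k))
  list(embedding = pts, eigenvalues = sort(fit$eig, decreasing = TRUE))
}

#' Build the full cross-dataset distance model
#'
#' Convenience wrapper chaining [fc_correlation()],
#' [correlation_to_distance()] and [classical_mds()] and attaching tissue
#' labels, producing the object consumed by [tissue_distance_test()].
#'
#' @param results List of `de_result` objects.
#' @param tissue Named character vector mapping dataset id to tissue label.
#' @param config A [run_config()].
#' @param k Embedding dimension (default 2).
#' @return Object of class `dataset_distance_model` with fields
#'   `dataset_ids`, `tissue`, `corr`, `n_common`, `dist`, `embedding`,
#'   `eigenvalues`.
#' @export
build_distance_model <- function(results, tissue, config = run_config(),
                                 k = 2L) {
  fc <- fc_correlation(results, config$min_common_genes)
  ids <- rownames(fc$corr)
  missing <- setdiff(ids, names(tissue))
  if (length(missing))
    fail("no tissue label for dataset(s): ", paste(missing, collapse = ", "))
  d <- correlation_to_distance(fc$corr, config$distance_dialect)
  mds <- classical_mds(d, k = k)
  structure(list(dataset_ids = ids,
                 tissue = tissue[ids],
                 corr = fc$corr,
                 n_common = fc$n_common,
                 dist = d,
                 embedding = mds$embedding,
                 eigenvalues = mds$eigenvalues),
            class = "dataset_distance_model")
}

#' @export
print.dataset_distance_model <- function(x, ...) {
  cat(sprintf("dataset_distance_model: %d datasets, tissues: %s\n",
              length(x$dataset_ids),
              paste(sort(unique(x$tissue)), collapse = ", ")))
  invisible(x)
}

#' Permutation test for tissue clustering of datasets
#'
#' Tests whether datasets from the same tissue lie closer together than
#' datasets from different tissues. The statistic is
#' `T = mean(between-tissue distances) - mean(within-tissue distances)`,
#' measured either in the 2-D MDS embedding (default) or on the input
#' distance matrix, per `config$mds_distance_space`. The null permutes
#' tissue labels across datasets uniformly; the empirical p-value uses the
#' add-one rule `(n_ge + 1) / (n_permutations + 1)`, so it is never zero.
#'
#' Tissues represented by a single dataset contribute no within-tissue
#' pairs and are excluded from the within-tissue means (with a warning);
#' if every tissue is a singleton, or all datasets share one tissue, the
#' test is undefined and errors.
#'
#' @param model A `dataset_distance_model`.
#' @param config A [run_config()] (`n_permutations`, `seed`,
#'   `mds_distance_space`).
#' @param n_permutations,seed Optional overrides of the config values.
#' @return Object of class `tissue_test_result`: `within_mean` (per-tissue
#'   mean within-tissue distance), `observed` (T), `n_permutations`,
#'   `n_ge`, `p`, `seed`, `space`.
#' @export
tissue_distance_test <- function(model, config = run_config(),
                                 n_permutations = NULL, seed = NULL) {
  stopifnot(inherits(model, "dataset_distance_model"))
  n_permutations <- n_permutations %||% config$n_permutations
  seed <- seed %||% config$seed
  labels <- as.character(model$tissue)
  n <- length(labels)
  D <- if (config$mds_distance_space == "embedding") {
    as.matrix(stats::dist(model$embedding))
  } else {
    model$dist
  }

  counts <- table(labels)
  if (length(counts) < 2L)
    fail("all datasets share one tissue; no between-tissue pairs")
  if (all(counts < 2L))
    fail("every tissue has a single dataset; no within-tissue pairs")
  if (any(counts < 2L))
    warning("tissue(s) with a single dataset excluded from within-tissue ",
            "means: ", paste(names(counts)[counts < 2L], collapse = ", "))

  pairs <- pair_index(n)
  pd <- D[pairs]  # distances for all i < j pairs
  stat <- function(lab) {
    same <- lab[pairs[, 1]] == lab[pairs[, 2]]
    mean(pd[!same]) - mean(pd[same])
  }
  observed <- stat(labels)

  within_mean <- vapply(names(counts)[counts >= 2L], function(tis) {
    same <- labels[pairs[, 1]] == tis & labels[pairs[, 2]] == tis
    mean(pd[same])
  }, 0)

  null <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) stat(sample(labels)), 0)
  })
  n_ge <- sum(null >= observed)
  structure(list(within_mean = within_mean,
                 observed = observed,
                 n_permutations = as.integer(n_permutations),
                 n_ge = as.integer(n_ge),
                 p = (n_ge + 1) / (n_permutations + 1),
                 seed = seed,
                 space = config$mds_distance_space),
            class = "tissue_test_result")
}

#' @export
print.tissue_test_result <- function(x, ...) {
  cat("Tissue-clustering permutation test\n")
  for (tis in names(x$within_mean))
    cat(sprintf("  mean within-tissue distance (%s): %.4g\n",
                tis, x$within_mean[[tis]]))
  cat(sprintf("  T = between - within = %.4g\n", x$observed))
  cat(sprintf("  permutation p = %.4g (%d permutations, space = %s)\n",
              x$p, x$n_permutations, x$space))
  invisible(x)
}
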