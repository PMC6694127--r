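#' Fold change between case and control groups
#'
#' On the linear scale the fold change is the ratio of group means,
#' `mean(case) / mean(control)`; on the log2 scale it is derived from the
#' difference of group means, `log2fc = mean(case) - mean(control)` and
#' `fc = 2^log2fc`. Genes whose linear-scale group mean is not positive
#' cannot yield a ratio and are flagged (they are excluded from DE calling
#' downstream rather than raising an error).
#'
#' @param case_values,control_values Non-empty numeric vectors.
#' @param scale `"linear"` or `"log2"`.
#' @return A list with `fc`, `log2fc` and logical `flagged`.
#' @examples
#' fold_change(c(3, 3), c(2, 2), "linear")    # fc 1.5
#' fold_change(c(5, 5), c(3, 3), "log2")      # log2fc 2, fc 4
#' @export
fold_change <- function(case_values, control_values,
                        scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!length(case_values) || !length(control_values))
    fail("both groups must be non-empty")
  mc <- mean(case_values)
  mk <- mean(control_values)
  if (scale == "linear") {
    if (mk <= 0 || mc <= 0) {
      return(list(fc = NA_real_, log2fc = NA_real_, flagged = TRUE))
    }
    fc <- mc / mk
    list(fc = fc, log2fc = log2(fc), flagged = FALSE)
  } else {
    l2 <- mc - mk
    list(fc = 2^l2, log2fc = l2, flagged = FALSE)
  }
}

#' Two-sided Wilcoxon rank-sum test p-value
#'
#' Mode `"auto"` uses exact enumeration when the pooled sample size is at
#' most 16 and the data are tie-free, otherwise the normal approximation
#' with midrank tie correction and continuity correction. Mode `"exact"`
#' refuses ties and falls back to the normal approximation with a warning.
#' When all values across both groups are identical the test is degenerate
#' and p = 1.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' ranksum_test(c(1, 2), c(3, 4))   # exact, 1/3
#' @export
ranksum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 2L || length(y) < 2L)
    fail("each group needs at least 2 observations")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)

  ties <- anyDuplicated(pooled) > 0L
  exact <- switch(mode,
    auto = length(pooled) <= 16L && !ties,
    exact = {
      if (ties) warning("ties present; falling back to normal approximation")
      !ties
    },
    normal = FALSE
  )
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  if (is.na(p)) return(1)  # zero-variance degenerate case
  min(max(p, 0), 1)
}

#' Differential-expression calls for a set of per-gene records
#'
#' Applies the joint fold-change and p-value rule with strict inequalities:
#' `up` when `fc > fc_threshold` and `p < p_threshold`; `down` when
#' `fc < 1/fc_threshold` and `p < p_threshold`; otherwise `ns`. Flagged
#' genes (no valid fold change) are always `ns`. When `config$fdr == "bh"`
#' the Benjamini-Hochberg adjusted p-value is thresholded instead of the
#' raw one (off by default).
#'
#' @param records Data frame with columns `gene`, `fc`, `log2fc`, `p` and
#'   optionally logical `flagged`.
#' @param config A [run_config()].
#' @param dataset_id Dataset identifier carried into the result.
#' @return An object of class `de_result`: list with `dataset_id` and a
#'   `table` data frame (`gene`, `fc`, `log2fc`, `p`, `direction`).
#' @export
call_de <- function(records, config = run_config(), dataset_id = "dataset") {
  need <- c("gene", "fc", "log2fc", "p")
  if (!all(need %in% names(records)))
    fail("records need columns: ", paste(need, collapse = ", "))
  flagged <- if ("flagged" %in% names(records)) records$flagged else
    !is.finite(records$fc)
  p_use <- records$p
  if (config$fdr == "bh") {
    p_use[!flagged] <- stats::p.adjust(records$p[!flagged], method = "BH")
  }
  up <- !flagged & records$fc > config$fc_threshold &
    p_use < config$p_threshold
  down <- !flagged & records$fc < 1 / config$fc_threshold &
    p_use < config$p_threshold
  direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  tab <- data.frame(gene = as.character(records$gene),
                    fc = records$fc, log2fc = records$log2fc,
                    p = records$p, direction = direction,
                    stringsAsFactors = FALSE)
  structure(list(dataset_id = dataset_id, table = tab), class = "de_result")
}

#' Per-dataset differential expression analysis
#'
#' Computes, for every gene of one cohort, the case/control fold change and
#' the two-sided Wilcoxon rank-sum p-value, then assigns direction calls via
#' [call_de()].
#'
#' @param dataset An [expression_dataset()].
#' @param config A [run_config()].
#' @param mode Rank-sum test mode, see [ranksum_test()].
#' @return A `de_result`.
#' @export
de_analysis <- function(dataset, config = run_config(),
                        mode = c("auto", "exact", "normal")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mode <- match.arg(mode)
  case_idx <- which(dataset$group == "case")
  ctrl_idx <- which(dataset$group == "control")
  genes <- dataset$genes
  n <- length(genes)
  fc <- log2fc <- p <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    cv <- dataset$values[i, case_idx]
    kv <- dataset$values[i, ctrl_idx]
    f <- fold_change(cv, kv, dataset$scale)
    fc[i] <- f$fc
    log2fc[i] <- f$log2fc
    flagged[i] <- f$flagged
    p[i] <- if (f$flagged) NA_real_ else ranksum_test(cv, kv, mode)
  }
  records <- data.frame(gene = genes, fc = fc, log2fc = log2fc, p = p,
                        flagged = flagged, stringsAsFactors = FALSE)
  call_de(records, config, dataset_id = dataset$dataset_id)
}

#' @export
print.de_result <- function(x, ...) {
  n <- table(factor(x$table$direction, levels = c("up", "down", "ns")))
  cat(sprintf("de_result '%s': %d genes (%d up, %d down, %d ns)\n",
              x$dataset_id, nrow(x$table), n[["up"]], n[["down"]], n[["ns"]]))
  invisible(x)
}

#' Extract the up- or down-regulated gene list from a DE result
#'
#' @param de A `de_result`.
#' @param direction `"up"` or `"down"`.
#' @param sorted Order genes by fold change (descending for `up`, ascending
#'   for `down`), ties broken by symbol. Default `TRUE`.
#' @return Character vector of gene symbols.
#' @export
de_genes <- function(de, direction = c("up", "down"), sorted = TRUE) {
  direction <- match.arg(direction)
  tab <- de$table[de$table$direction == direction, , drop = FALSE]
  if (!nrow(tab)) return(character(0))
  if (sorted) {
    ord <- if (direction == "up") order(-tab$fc, tab$gene)
           else order(tab$fc, tab$gene)
    tab <- tab[ord, , drop = FALSE]
  }
  tab$gene
}

#' Cross-dataset signed direction matrix
#'
#' Builds the gene x dataset matrix of signed log2 fold changes used to
#' compare direction of change across tissues: a cell carries the gene's
#' log2 fold change where the gene was called `up` or `down` in that
#' dataset, and is missing otherwise. Only genes called in at least
#' `min_datasets` datasets are retained (the concordance display rule);
#' rows are ordered by the number of datasets with a call, then by symbol.
#'
#' @param results List of `de_result` objects.
#' @param min_datasets Minimum number of datasets with a non-`ns` call.
#' @return Object of class `direction_matrix`: list with `genes`,
#'   `dataset_ids`, `n_datasets` (calls per retained gene) and the numeric
#'   `cells` matrix (NA = no call). An empty result is returned with a
#'   warning, not an error.
#' @export
direction_matrix <- function(results, min_datasets = 3L) {
  if (length(results) < min_datasets)
    fail("need at least `min_datasets` (", min_datasets, ") DE results")
  ids <- vapply(results, function(r) r$dataset_id, "")
  if (anyDuplicated(ids)) fail("duplicate dataset ids in results")

  called <- lapply(results, function(r) {
    t <- r$table[r$table$direction != "ns", c("gene", "log2fc")]
    stats::setNames(t$log2fc, t$gene)
  })
  genes <- sort(unique(unlist(lapply(called, names), use.names = FALSE)))
  if (!length(genes)) {
    warning("no gene called in any dataset; direction matrix is empty")
    cells <- matrix(NA_real_, 0, length(ids), dimnames = list(NULL, ids))
    return(structure(list(genes = character(0), dataset_ids = ids,
                          n_datasets = integer(0), cells = cells),
                     class = "direction_matrix"))
  }
  cells <- matrix(NA_real_, length(genes), length(ids),
                  dimnames = list(genes, ids))
  for (j in seq_along(called)) {
    v <- called[[j]]
    cells[names(v), j] <- v
  }
  n_ds <- rowSums(!is.na(cells))
  keep <- n_ds >= min_datasets
  if (!any(keep))
    warning("no gene reaches min_datasets = ", min_datasets,
            "; direction matrix is empty")
  cells <- cells[keep, , drop = FALSE]
  n_ds <- n_ds[keep]
  ord <- order(-n_ds, rownames(cells))
  cells <- cells[ord, , drop = FALSE]
  structure(list(genes = rownames(cells), dataset_ids = ids,
                 n_datasets = as.integer(n_ds[ord]), cells = cells),
            class = "direction_matrix")
}

#' @export
print.direction_matrix <- function(x, ...) {
  cat(sprintf("direction_matrix: %d genes x %d datasets\n",
              length(x$genes), length(x$dataset_ids)))
  invisible(x)
}
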