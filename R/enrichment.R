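#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability that a query list of size `n`
#' drawn from a universe of size `N` overlaps a set of size `K` (after
#' intersection with the universe) in at least the observed `k` elements.
#' The tail is evaluated in log space for numerical stability. This is the
#' standard ORA statistic; no EASE-style adjustment is applied.
#'
#' @param query Character vector, the interesting list (must be a subset of
#'   `universe`; duplicates removed).
#' @param term Character vector, the annotation set (intersected with the
#'   universe before testing).
#' @param universe Character vector, the measured gene (or drug) universe.
#' @return List with `k`, `n`, `K`, `N`, `p`, `neglog10p`.
#' @examples
#' hypergeom_ora(c("A", "B", "C", "D"), LETTERS[1:5], LETTERS[1:10])
#' @export
hypergeom_ora <- function(query, term, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) fail("empty universe")
  query <- unique(as.character(query))
  if (!length(query)) fail("no significant genes to test (empty query)")
  if (length(setdiff(query, universe)))
    fail("query contains elements outside the universe: ",
         paste(utils::head(setdiff(query, universe), 3), collapse = ", "))
  term <- intersect(unique(as.character(term)), universe)
  k <- length(intersect(query, term))
  n <- length(query)
  K <- length(term)
  N <- length(universe)
  logp <- stats::phyper(k - 1L, K, N - K, n,
                        lower.tail = FALSE, log.p = TRUE)
  p <- min(exp(logp), 1)
  list(k = k, n = n, K = K, N = N, p = p, neglog10p = -log10(p))
}

#' Separate up/down over-representation analysis of one dataset
#'
#' Tests the dataset's up-regulated and down-regulated gene lists
#' independently against every set of the database, using the dataset's own
#' measured gene universe as background (platforms differ between cohorts,
#' so a global universe would bias the test). Records with p below
#' `config$p_threshold` are retained. With `config$fdr = "bh"`, BH-adjusted
#' p-values (per direction) are thresholded instead.
#'
#' @param de A `de_result` (from [de_analysis()] or [call_de()]).
#' @param db A [gene_set_db()].
#' @param config A [run_config()].
#' @return Data frame of enrichment records: `dataset_id`, `direction`,
#'   `term_id`, `k`, `n`, `K`, `N`, `p`, `neglog10p`. An empty up or down
#'   list skips that direction with a warning.
#' @export
enrich_dataset <- function(de, db, config = run_config()) {
  stopifnot(inherits(de, "de_result"), inherits(db, "gene_set_db"))
  universe <- de$table$gene
  out <- list()
  for (direction in c("up", "down")) {
    query <- de$table$gene[de$table$direction == direction]
    if (!length(query)) {
      warning("dataset '", de$dataset_id, "': empty ", direction,
              " list; direction skipped")
      next
    }
    rows <- lapply(seq_along(db$term_id), function(i) {
      r <- hypergeom_ora(query, db$members[[i]], universe)
      data.frame(dataset_id = de$dataset_id, direction = direction,
                 term_id = db$term_id[i], k = r$k, n = r$n, K = r$K,
                 N = r$N, p = r$p, neglog10p = r$neglog10p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    p_use <- if (config$fdr == "bh") stats::p.adjust(tab$p, "BH") else tab$p
    out[[direction]] <- tab[p_use < config$p_threshold, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(dataset_id = character(0), direction = character(0),
                      term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      neglog10p = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Cross-dataset term-overlap matrix
#'
#' Summarises enrichment records across datasets into the heat-map-ready
#' matrix of signed `-log10(p)` values: positive for up-list enrichment,
#' negative for down-list, missing where the term was not significant.
#' A (term, direction) pair is retained only when significant in at least
#' `min_overlap` datasets; a term significant in both directions in one
#' dataset contributes two rows (the per-direction convention, recorded in
#' the object's `convention` field).
#'
#' @param records Enrichment records from [enrich_dataset()], row-bound
#'   across datasets (already filtered to significant records).
#' @param min_overlap Minimum datasets per retained (term, direction) row.
#' @return Object of class `term_overlap_matrix`: `term_id`, `direction`,
#'   `dataset_ids`, `cells` (signed -log10 p, NA missing), `convention`.
#'   Empty results are allowed (with a warning).
#' @export
term_overlap <- function(records, min_overlap = 2L) {
  ids <- sort(unique(records$dataset_id))
  key <- paste(records$term_id, records$direction, sep = "\r")
  counts <- vapply(split(records$dataset_id, key),
                   function(d) length(unique(d)), 0L)
  keep_keys <- names(counts)[counts >= min_overlap]
  if (!length(keep_keys))
    warning("no (term, direction) pair significant in >= ", min_overlap,
            " datasets; overlap matrix is empty")
  parts <- strsplit(keep_keys, "\r", fixed = TRUE)
  term_id <- vapply(parts, function(x) x[1] %||% NA_character_, "")
  direction <- vapply(parts, function(x) x[2] %||% NA_character_, "")
  ord <- order(-counts[keep_keys], term_id, direction)
  term_id <- term_id[ord]; direction <- direction[ord]
  keep_keys <- keep_keys[ord]

  cells <- matrix(NA_real_, length(keep_keys), length(ids),
                  dimnames = list(keep_keys, ids))
  rec_keep <- records[key %in% keep_keys, , drop = FALSE]
  rk <- paste(rec_keep$term_id, rec_keep$direction, sep = "\r")
  sign_ <- ifelse(rec_keep$direction == "up", 1, -1)
  for (i in seq_len(nrow(rec_keep))) {
    cells[rk[i], rec_keep$dataset_id[i]] <- sign_[i] * rec_keep$neglog10p[i]
  }
  rownames(cells) <- paste(term_id, direction, sep = ":")
  structure(list(term_id = term_id, direction = direction,
                 dataset_ids = ids, cells = cells,
                 convention = "per-direction"),
            class = "term_overlap_matrix")
}

#' @export
print.term_overlap_matrix <- function(x, ...) {
  cat(sprintf(
    "term_overlap_matrix: %d (term, direction) rows x %d datasets [%s]\n",
    length(x$term_id), length(x$dataset_ids), x$convention))
  invisible(x)
}

#' Drug-set enrichment of a candidate compound list
#'
#' The same hypergeometric machinery as gene-set ORA, applied to drugs:
#' tests whether a list of candidate compounds over-represents each drug
#' set (targets, pathways, indications, adverse reactions) relative to the
#' full catalogue of queryable compounds. Records with p below
#' `config$p_threshold` are retained.
#'
#' @param drugs Character vector of candidate drug names (non-empty).
#' @param db A `drug_set_db` from [read_drugset_db()].
#' @param universe All drug names in the reference catalogue.
#' @param config A [run_config()].
#' @return Data frame: `set_id`, `category`, `k`, `n`, `K`, `N`, `p`,
#'   `neglog10p`, ordered by p.
#' @export
drugset_enrichment <- function(drugs, db, universe, config = run_config()) {
  stopifnot(inherits(db, "drug_set_db"))
  if (!length(drugs)) fail("no significant genes to test (empty drug list)")
  rows <- lapply(seq_along(db$set_id), function(i) {
    r <- hypergeom_ora(drugs, db$members[[i]], universe)
    data.frame(set_id = db$set_id[i], category = db$category[i],
               k = r$k, n = r$n, K = r$K, N = r$N, p = r$p,
               neglog10p = r$neglog10p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  p_use <- if (config$fdr == "bh") stats::p.adjust(tab$p, "BH") else tab$p
  tab <- tab[p_use < config$p_threshold, , drop = FALSE]
  tab <- tab[order(tab$p, tab$set_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
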