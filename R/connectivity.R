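#' Trim a DE result into a connectivity query signature
#'
#' A connectivity query takes the dataset's up-regulated genes (essential)
#' and down-regulated genes (optional). Only genes present in the reference
#' catalogue's universe are "valid". Datasets with fewer than
#' `config$signature_min` (default 10) valid up-regulated genes are
#' rejected; lists longer than `config$signature_max` (default 150) are
#' truncated to the top genes by fold change (largest fold change for up,
#' smallest for down; ties broken by gene symbol so truncation is
#' deterministic).
#'
#' @param de A `de_result`.
#' @param catalogue_universe Character vector of catalogue genes.
#' @param config A [run_config()].
#' @return Object of class `signature`: `dataset_id`, `up` (descending fold
#'   change), `down` (ascending fold change, possibly empty),
#'   `valid_up_count`, `valid_down_count` (counts before truncation).
#'   Rejection raises a condition of class `signature_too_small`.
#' @export
trim_signature <- function(de, catalogue_universe, config = run_config()) {
  stopifnot(inherits(de, "de_result"))
  up_all <- de_genes(de, "up")
  down_all <- de_genes(de, "down")
  up <- up_all[up_all %in% catalogue_universe]
  down <- down_all[down_all %in% catalogue_universe]
  if (length(up) < config$signature_min) {
    cond <- structure(
      class = c("signature_too_small", "error", "condition"),
      list(message = paste0(
             "dataset '", de$dataset_id, "' excluded: ", length(up),
             " valid up-regulated genes (minimum ", config$signature_min,
             ")"),
           call = NULL))
    stop(cond)
  }
  if (length(up) > config$signature_max)
    up <- up[seq_len(config$signature_max)]
  n_down <- length(down)
  if (n_down > config$signature_max)
    down <- down[seq_len(config$signature_max)]
  structure(list(dataset_id = de$dataset_id, up = up, down = down,
                 valid_up_count = length(up_all[up_all %in% catalogue_universe]),
                 valid_down_count = n_down),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature '%s': %d up / %d down genes\n",
              x$dataset_id, length(x$up), length(x$down)))
  invisible(x)
}

#' KS enrichment score of a gene set in a ranked profile
#'
#' The bidirectional Kolmogorov-Smirnov statistic of the connectivity-map
#' family. With the set's ascending positions `r_1 < ... < r_t` in a
#' profile of `N` ranked genes:
#' `a = max_j (j/t - r_j/N)`, `b = max_j (r_j/N - (j-1)/t)`, and
#' `es = a` if `a > b`, else `-b`. A score near +1 means the set sits at
#' the top of the profile (genes the drug up-regulates most), near -1 at
#' the bottom.
#'
#' @param gene_set Character vector of genes (all must be in the profile).
#' @param profile Character vector: the ranked gene list, rank 1 first.
#' @return Enrichment score in \[-1, 1\].
#' @examples
#' prof <- LETTERS[1:10]
#' ks_enrichment_score(c("A", "J"), prof)  # -0.5
#' @export
ks_enrichment_score <- function(gene_set, profile) {
  t_n <- length(gene_set)
  if (t_n < 1L) fail("gene_set must contain at least one gene")
  r <- match(gene_set, profile)
  if (anyNA(r))
    fail("gene(s) not in profile universe: ",
         paste(utils::head(gene_set[is.na(r)], 3), collapse = ", "))
  r <- sort(r)
  N <- length(profile)
  j <- seq_len(t_n)
  a <- max(j / t_n - r / N)
  b <- max(r / N - (j - 1) / t_n)
  if (a > b) a else -b
}

#' Connectivity score of a signature against one drug profile
#'
#' Combines the KS enrichment scores of the signature's up and down lists
#' into a single score scaled to \[-100, 100\]. With only an up list the
#' score is `100 * es_up`. With both lists: if the two enrichment scores
#' share a sign the profile is not coherently related to the signature and
#' the score is 0; otherwise `score = 100 * (es_up - es_down) / 2`. A
#' strongly negative score marks a compound whose expression profile
#' reverses the signature.
#'
#' @param sig A `signature` from [trim_signature()].
#' @param profile Ranked gene character vector (rank 1 = most up-regulated
#'   by the drug).
#' @return List with `es_up`, `es_down` (NULL when the down list is empty)
#'   and `score`.
#' @export
connectivity_score <- function(sig, profile) {
  stopifnot(inherits(sig, "signature"))
  es_up <- ks_enrichment_score(sig$up, profile)
  if (!length(sig$down)) {
    return(list(es_up = es_up, es_down = NULL, score = 100 * es_up))
  }
  es_down <- ks_enrichment_score(sig$down, profile)
  score <- if (sign(es_up) == sign(es_down)) 0
           else 100 * (es_up - es_down) / 2
  list(es_up = es_up, es_down = es_down, score = score)
}

#' Score a signature against every drug in a catalogue
#'
#' @param sig A `signature`.
#' @param catalogue A [drug_catalogue()].
#' @return Data frame with one row per drug: `drug`, `es_up`, `es_down`
#'   (NA when the signature has no down list), `score`; catalogue order.
#' @export
connectivity_scan <- function(sig, catalogue) {
  stopifnot(inherits(catalogue, "drug_catalogue"))
  drugs <- names(catalogue$profiles)
  res <- lapply(drugs, function(d) {
    r <- connectivity_score(sig, catalogue$profiles[[d]])
    data.frame(drug = d, es_up = r$es_up,
               es_down = r$es_down %||% NA_real_,
               score = r$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select signature-reversing compounds by score window
#'
#' Returns the drugs whose connectivity score falls inside the closed
#' interval `config$score_window` (default \[-100, -80\]): compounds whose
#' profiles most strongly reverse the query signature.
#'
#' @param records Data frame from [connectivity_scan()].
#' @param config A [run_config()].
#' @return Character vector of drug names, sorted by ascending score.
#' @export
select_reversers <- function(records, config = run_config()) {
  lo <- config$score_window[1]; hi <- config$score_window[2]
  hits <- records[records$score >= lo & records$score <= hi, , drop = FALSE]
  hits <- hits[order(hits$score, hits$drug), , drop = FALSE]
  hits$drug
}

#' Cross-dataset candidate-compound overlap
#'
#' Aggregates per-dataset reversal-candidate lists into the recurrent
#' "interested drugs" list: compounds appearing in at least `min_datasets`
#' of the surviving datasets. Datasets whose candidate list holds fewer
#' than 2 compounds are dropped before counting (a single-compound list
#' carries no overlap information and the corresponding cohort is excluded
#' from the comparison).
#'
#' @param per_dataset_lists Named list: dataset id -> character vector of
#'   candidate drugs.
#' @param min_datasets Minimum number of dataset lists a drug must appear
#'   in (4 for human groups, "more than three"; 5 for animal groups,
#'   "more than four").
#' @return List with `interested_drugs` (sorted by count desc, then name),
#'   `counts` (named integer vector over all candidate drugs) and
#'   `used_datasets` (ids surviving the 2-compound rule).
#' @export
overlap_candidates <- function(per_dataset_lists, min_datasets = 4L) {
  keep <- vapply(per_dataset_lists, function(x) length(x) >= 2L, TRUE)
  dropped <- names(per_dataset_lists)[!keep]
  if (length(dropped))
    message("dataset(s) dropped (fewer than 2 candidate compounds): ",
            paste(dropped, collapse = ", "))
  lists <- per_dataset_lists[keep]
  if (!length(lists)) fail("no dataset with >= 2 candidate compounds")
  counts <- table(unlist(lapply(lists, unique), use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  hits <- counts[counts >= min_datasets]
  interested <- names(hits)[order(-hits, names(hits))]
  list(interested_drugs = interested, counts = counts,
       used_datasets = names(lists))
}
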