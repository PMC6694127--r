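#' Per-dataset profile of a DE result group
#'
#' Extracts what the shared-term permutation null needs from each dataset:
#' its measured gene universe and the sizes of its up and down lists.
#'
#' @param results List of `de_result` objects.
#' @return Named list (by dataset id) of lists with `universe`, `n_up`,
#'   `n_down`.
#' @export
group_profile <- function(results) {
  out <- lapply(results, function(r) {
    list(universe = r$table$gene,
         n_up = sum(r$table$direction == "up"),
         n_down = sum(r$table$direction == "down"))
  })
  names(out) <- vapply(results, function(r) r$dataset_id, "")
  out
}

# Group-level significant term ids: (term, direction) pairs significant in
# >= min_overlap datasets of the group, collapsed to the union of term ids.
group_term_set <- function(records, min_overlap) {
  if (!nrow(records)) return(character(0))
  key <- paste(records$term_id, records$direction, sep = "\r")
  counts <- vapply(split(records$dataset_id, key),
                   function(d) length(unique(d)), 0L)
  keys <- names(counts)[counts >= min_overlap]
  unique(vapply(strsplit(keys, "\r", fixed = TRUE), `[[`, "", 1L))
}

#' Observed number of shared significant terms between two dataset groups
#'
#' For each group, the (term, direction) pairs significant in at least
#' `min_overlap` datasets of that group define the group's term set (union
#' over directions); the statistic is the size of the intersection of the
#' two groups' term sets.
#'
#' @param records_a,records_b Enrichment records ([enrich_dataset()]
#'   output, row-bound) for the two groups.
#' @param min_overlap Per-group minimum dataset count.
#' @return Integer shared-term count.
#' @export
shared_term_count <- function(records_a, records_b, min_overlap = 2L) {
  length(intersect(group_term_set(records_a, min_overlap),
                   group_term_set(records_b, min_overlap)))
}

new_permutation_result <- function(statistic_name, observed, null_values,
                                   seed) {
  n <- length(null_values)
  n_ge <- sum(null_values >= observed)
  counts <- table(null_values)
  structure(list(statistic_name = statistic_name,
                 observed = as.integer(observed),
                 n_permutations = n,
                 null_counts = stats::setNames(as.integer(counts),
                                               names(counts)),
                 n_ge = as.integer(n_ge),
                 p = (n_ge + 1) / (n + 1),
                 seed = seed),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s): observed = %d, p = %.4g (%d replicates)\n",
    x$statistic_name, x$observed, x$p, x$n_permutations))
  invisible(x)
}

#' Permutation null for the shared significant-term count
#'
#' The gene-resampling random experiment: each replicate draws, for every
#' dataset of both groups, a uniform random gene list of the dataset's
#' observed up/down list sizes from that dataset's own universe, re-runs
#' the hypergeometric enrichment and the group-level term-overlap criteria
#' exactly as the real pipeline does, and records the number of significant
#' terms shared between the groups. The empirical p-value uses the add-one
#' rule and exceedance is `>= observed` (conservative).
#'
#' @param group_a,group_b Group profiles from [group_profile()] (or lists
#'   of `de_result` objects, converted automatically).
#' @param db A [gene_set_db()].
#' @param observed The observed shared-term count from the real pipeline
#'   (see [shared_term_count()]); required.
#' @param config A [run_config()] (`p_threshold`, `term_overlap_min`,
#'   `n_permutations`, `seed`).
#' @param n_permutations,seed Optional overrides.
#' @return A `permutation_test_result` (statistic `shared_terms`).
#' @export
permute_term_overlap <- function(group_a, group_b, db, observed,
                                 config = run_config(),
                                 n_permutations = NULL, seed = NULL) {
  if (missing(observed) || is.null(observed))
    fail("`observed` shared-term count must be supplied")
  stopifnot(inherits(db, "gene_set_db"))
  as_profile <- function(g) {
    if (length(g) && inherits(g[[1]], "de_result")) group_profile(g) else g
  }
  group_a <- as_profile(group_a); group_b <- as_profile(group_b)
  n_permutations <- n_permutations %||% config$n_permutations
  seed <- seed %||% config$seed
  min_overlap <- config$term_overlap_min

  # Precompute, per dataset, term membership as indices into its universe.
  prep <- function(profile) {
    lapply(profile, function(ds) {
      idx <- lapply(db$members, function(m) which(ds$universe %in% m))
      list(N = length(ds$universe), n_up = ds$n_up, n_down = ds$n_down,
           idx = idx, K = vapply(idx, length, 0L))
    })
  }
  prep_a <- prep(group_a); prep_b <- prep(group_b)
  n_terms <- length(db$term_id)

  # One replicate's significant-term set for one group.
  group_replicate <- function(prep_g) {
    hits_up <- matrix(FALSE, n_terms, length(prep_g))
    hits_down <- matrix(FALSE, n_terms, length(prep_g))
    for (d in seq_along(prep_g)) {
      ds <- prep_g[[d]]
      n_tot <- ds$n_up + ds$n_down
      if (n_tot == 0L || n_tot > ds$N) next
      pick <- sample.int(ds$N, n_tot)
      for (dir in c("up", "down")) {
        n_q <- if (dir == "up") ds$n_up else ds$n_down
        if (n_q == 0L) next
        q <- if (dir == "up") pick[seq_len(ds$n_up)]
             else pick[ds$n_up + seq_len(ds$n_down)]
        mask <- logical(ds$N); mask[q] <- TRUE
        k <- vapply(ds$idx, function(ix) sum(mask[ix]), 0L)
        p <- stats::phyper(k - 1L, ds$K, ds$N - ds$K, n_q,
                           lower.tail = FALSE)
        if (config$fdr == "bh") p <- stats::p.adjust(p, "BH")
        sig <- p < config$p_threshold
        if (dir == "up") hits_up[, d] <- sig else hits_down[, d] <- sig
      }
    }
    reached <- rowSums(hits_up) >= min_overlap |
      rowSums(hits_down) >= min_overlap
    which(reached)
  }

  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      length(intersect(group_replicate(prep_a), group_replicate(prep_b)))
    }, 0L)
  })
  new_permutation_result("shared_terms", observed, null, seed)
}

#' Permutation null for the shared interested-drug count
#'
#' The drug-resampling random experiment: each replicate samples, for every
#' dataset, a uniform random candidate list of the observed size (without
#' replacement) from the reference catalogue, applies the recurrence rule
#' ([overlap_candidates()]) per group with that group's minimum dataset
#' count, and records the size of the intersection of the two groups'
#' interested-drug lists. Datasets with candidate lists shorter than 2
#' compounds are dropped first, as in the real pipeline.
#'
#' @param sizes_a,sizes_b Named integer vectors: per-dataset candidate-list
#'   sizes for the two groups.
#' @param catalogue_size Total number of compounds in the reference
#'   catalogue.
#' @param observed Observed shared-drug count from the real pipeline.
#' @param config A [run_config()].
#' @param min_a,min_b Per-group recurrence minima (defaults:
#'   `config$human_overlap_min` and `config$animal_overlap_min`).
#' @param n_permutations,seed Optional overrides.
#' @return A `permutation_test_result` (statistic `shared_drugs`).
#' @export
permute_drug_overlap <- function(sizes_a, sizes_b, catalogue_size, observed,
                                 config = run_config(),
                                 min_a = config$human_overlap_min,
                                 min_b = config$animal_overlap_min,
                                 n_permutations = NULL, seed = NULL) {
  if (missing(observed) || is.null(observed))
    fail("`observed` shared-drug count must be supplied")
  if (any(c(sizes_a, sizes_b) > catalogue_size))
    fail("a candidate-list size exceeds the catalogue size")
  n_permutations <- n_permutations %||% config$n_permutations
  seed <- seed %||% config$seed
  sizes_a <- sizes_a[sizes_a >= 2L]
  sizes_b <- sizes_b[sizes_b >= 2L]

  group_replicate <- function(sizes, min_n) {
    if (!length(sizes)) return(integer(0))
    counts <- integer(catalogue_size)
    for (s in sizes) {
      pick <- sample.int(catalogue_size, s)
      counts[pick] <- counts[pick] + 1L
    }
    which(counts >= min_n)
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      length(intersect(group_replicate(sizes_a, min_a),
                       group_replicate(sizes_b, min_b)))
    }, 0L)
  })
  new_permutation_result("shared_drugs", observed, null, seed)
}
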