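#' Analysis run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' The defaults are the criteria used throughout the multi-cohort analysis:
#' a gene is differentially expressed when its case/control fold change is
#' above `fc_threshold` (or below its reciprocal) with a rank-sum p-value
#' under `p_threshold`; connectivity-map queries require 10--150 valid
#' up-regulated genes; reversal candidates are compounds scoring inside
#' `score_window`; candidate drugs must recur in at least
#' `human_overlap_min` human (respectively `animal_overlap_min` animal)
#' datasets; permutation nulls use `n_permutations` replicates.
#'
#' @param fc_threshold Fold-change cut-off (> 1). A gene is "up" when
#'   `fc > fc_threshold` and "down" when `fc < 1/fc_threshold` (strict
#'   inequalities). Default 1.5.
#' @param p_threshold Per-gene (and per-term) significance level in (0, 1).
#'   Default 0.05.
#' @param signature_min,signature_max Valid-gene bounds for a connectivity
#'   query signature. Datasets with fewer than `signature_min` valid
#'   up-regulated genes are excluded; lists longer than `signature_max` are
#'   truncated to the top genes by fold change. Defaults 10 and 150.
#' @param score_window Length-2 numeric, the closed connectivity-score
#'   interval defining reversal candidates. Default `c(-100, -80)`.
#' @param human_overlap_min,animal_overlap_min Minimum number of datasets a
#'   candidate compound must recur in to be retained, for human-type and
#'   animal-type dataset groups. Defaults 4 and 5 ("more than three",
#'   "more than four").
#' @param n_permutations Number of random replicates for permutation nulls.
#'   Default 10000.
#' @param seed Integer base seed for every stochastic stage.
#' @param distance_dialect How dataset correlations become distances:
#'   `"corr_rows"` (Euclidean distance between rows of the correlation
#'   matrix, the default) or `"direct"` (`sqrt(2 * (1 - rho))`).
#' @param fdr `"none"` (default) or `"bh"`. When `"bh"`, Benjamini-Hochberg
#'   adjusted p-values are used for DE and enrichment calls. Off by default:
#'   the headline criteria deliberately use raw p-values.
#' @param mds_distance_space Space in which the tissue-clustering test
#'   measures distances: `"embedding"` (2-D MDS map, default) or `"input"`
#'   (the distance matrix fed to MDS).
#' @param direction_min_datasets Minimum datasets a gene must be called in
#'   to enter the cross-dataset direction matrix. Default 3.
#' @param min_common_genes Minimum pairwise common-gene count required for a
#'   fold-change correlation. Default 100.
#' @param term_overlap_min Minimum datasets a term must be significant in to
#'   enter the term-overlap matrix and group-level shared-term sets.
#'   Default 2.
#'
#' @return An object of class `run_config` (a validated named list).
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$fc_threshold
#' @export
run_config <- function(fc_threshold = 1.5,
                       p_threshold = 0.05,
                       signature_min = 10L,
                       signature_max = 150L,
                       score_window = c(-100, -80),
                       human_overlap_min = 4L,
                       animal_overlap_min = 5L,
                       n_permutations = 10000L,
                       seed = 1L,
                       distance_dialect = c("corr_rows", "direct"),
                       fdr = c("none", "bh"),
                       mds_distance_space = c("embedding", "input"),
                       direction_min_datasets = 3L,
                       min_common_genes = 100L,
                       term_overlap_min = 2L) {
  distance_dialect <- match.arg(distance_dialect)
  fdr <- match.arg(fdr)
  mds_distance_space <- match.arg(mds_distance_space)

  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    fail("`fc_threshold` must be a number > 1")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    fail("`p_threshold` must lie in (0, 1)")
  if (!is_count(signature_min) || !is_count(signature_max) ||
      signature_min >= signature_max)
    fail("`signature_min` must be an integer < `signature_max`")
  if (length(score_window) != 2L || !is.numeric(score_window) ||
      score_window[1] >= score_window[2])
    fail("`score_window` must be (lo, hi) with lo < hi")
  if (!is_count(human_overlap_min) || human_overlap_min < 1 ||
      !is_count(animal_overlap_min) || animal_overlap_min < 1)
    fail("overlap minima must be positive integers")
  if (!is_count(n_permutations) || n_permutations < 1)
    fail("`n_permutations` must be a positive integer")
  if (!is_count(seed)) fail("`seed` must be an integer")

  cfg <- list(
    fc_threshold = as.numeric(fc_threshold),
    p_threshold = as.numeric(p_threshold),
    signature_min = as.integer(signature_min),
    signature_max = as.integer(signature_max),
    score_window = as.numeric(score_window),
    human_overlap_min = as.integer(human_overlap_min),
    animal_overlap_min = as.integer(animal_overlap_min),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    distance_dialect = distance_dialect,
    fdr = fdr,
    mds_distance_space = mds_distance_space,
    direction_min_datasets = as.integer(direction_min_datasets),
    min_common_genes = as.integer(min_common_genes),
    term_overlap_min = as.integer(term_overlap_min)
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat YAML key-value file
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#' Keys absent from the file keep their [run_config()] defaults. A `groups`
#' key (a named list of dataset-id vectors, e.g. `human:`/`animal:`) is
#' carried through for the pipeline's two-group comparison mode.
#'
#' @param path Path to a YAML file of `run_config` keys.
#' @return A `run_config` object; any `groups` entry is attached as the
#'   `"groups"` attribute.
#' @seealso [run_config()], [write_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  groups <- raw[["groups"]]
  raw[["groups"]] <- NULL
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    fail("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- do.call(run_config, raw)
  if (!is.null(groups)) {
    groups <- lapply(groups, as.character)
    if (is.null(names(groups)) || any(names(groups) == ""))
      fail("config `groups` must be a named list of dataset-id vectors")
    attr(cfg, "groups") <- groups
  }
  cfg
}

#' Write a resolved run configuration to YAML
#'
#' Every pipeline run writes its resolved configuration (including the seed)
#' beside its outputs so stochastic stages can be reproduced exactly.
#'
#' @param config A `run_config` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  groups <- attr(config, "groups")
  if (!is.null(groups)) out$groups <- groups
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) {
    cat(sprintf("  %-24s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  g <- attr(x, "groups")
  if (!is.null(g)) {
    cat("  groups:\n")
    for (k in names(g)) cat(sprintf("    %-8s %s\n", k, paste(g[[k]], collapse = ", ")))
  }
  invisible(x)
}
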