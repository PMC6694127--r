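#' Design for a synthetic multi-cohort expression study
#'
#' Describes a collection of case/control cohorts with planted, known
#' structure: several tissues, each contributing multiple small cohorts;
#' one or more disjoint planted gene sets whose log2 effect size may differ
#' in sign and magnitude per tissue (emulating gene programmes up-regulated
#' in one tissue and down-regulated in another); gene baseline means drawn
#' once and shared across cohorts so that fold-change vectors, not absolute
#' levels, carry the signal; and per-cohort gene dropout emulating
#' platform-specific gene universes.
#'
#' The defaults mirror a multi-cohort case/control study on microarray-like
#' log2 intensities: 4 brain and 4 blood human cohorts of 10--12 samples
#' per group; three disjoint 40-gene planted sets -- a tissue-discordant
#' set (+2 in brain, -2 in blood, the immune-like pattern), a concordant
#' up-regulated set (+2 in both) and a concordant down-regulated set
#' (-2 in both, the oxidative-phosphorylation-like pattern); baseline
#' means N(8, 2); noise sd 0.5; and 20% gene dropout per cohort.
#'
#' @param n_genes Number of genes in the global universe.
#' @param tissues Data frame with columns `tissue`, `n_datasets`, `n_case`,
#'   `n_control` and optionally `organism` (default `"human"`).
#' @param planted_sets List of planted sets, each a list with `name`,
#'   `genes` (integer indices into the universe) and `effects` (named
#'   numeric: tissue -> signed log2 effect).
#' @param baseline_mu_sd Length-2 numeric: mean and sd of the global gene
#'   baseline distribution (log2 scale).
#' @param noise_sd Sd of the per-measurement Gaussian noise (log2 scale).
#' @param dropout_frac Fraction of genes absent from each cohort, in
#'   \[0, 0.5\] so at least half the universe remains everywhere.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `synth_design`.
#' @export
synth_design <- function(n_genes = 2000L,
                         tissues = data.frame(
                           tissue = c("brain", "blood"),
                           n_datasets = c(4L, 4L),
                           n_case = c(10L, 12L),
                           n_control = c(12L, 10L)),
                         planted_sets = list(
                           list(name = "planted_discordant",
                                genes = 1:40,
                                effects = c(brain = 2, blood = -2)),
                           list(name = "planted_up",
                                genes = 41:80,
                                effects = c(brain = 2, blood = 2)),
                           list(name = "planted_down",
                                genes = 81:120,
                                effects = c(brain = -2, blood = -2))),
                         baseline_mu_sd = c(8, 2),
                         noise_sd = 0.5,
                         dropout_frac = 0.2,
                         seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) fail("`n_genes` must be positive")
  if (!is.data.frame(tissues) || !nrow(tissues) ||
      !all(c("tissue", "n_datasets", "n_case", "n_control") %in%
           names(tissues)))
    fail("`tissues` needs columns tissue, n_datasets, n_case, n_control")
  if (is.null(tissues$organism)) tissues$organism <- "human"
  if (sum(tissues$n_datasets) < 1) fail("design has 0 datasets")
  if (!is.numeric(dropout_frac) || dropout_frac < 0 || dropout_frac > 0.5)
    fail("`dropout_frac` must lie in [0, 0.5] (at least half the genes ",
         "must remain in every dataset)")
  all_planted <- unlist(lapply(planted_sets, `[[`, "genes"))
  if (anyDuplicated(all_planted))
    fail("planted gene sets must be disjoint")
  if (length(all_planted) && (max(all_planted) > n_genes ||
                              min(all_planted) < 1))
    fail("planted gene indices out of range")
  for (ps in planted_sets) {
    if (is.null(ps$name) || is.null(ps$effects))
      fail("each planted set needs `name`, `genes` and `effects`")
  }
  structure(list(n_genes = as.integer(n_genes),
                 tissues = tissues,
                 planted_sets = planted_sets,
                 baseline_mu_sd = as.numeric(baseline_mu_sd),
                 noise_sd = as.numeric(noise_sd),
                 dropout_frac = as.numeric(dropout_frac),
                 seed = as.integer(seed)),
            class = "synth_design")
}

synth_gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Generate the cohorts of a synthetic design
#'
#' Gene baselines are drawn once for the whole study; each cohort then
#' receives a dropout-reduced gene subset and log2-scale values
#' `baseline + case_indicator * delta(gene, tissue) + N(0, noise_sd)`.
#' Output is deterministic given the design seed.
#'
#' @param design A [synth_design()].
#' @return Named list of [expression_dataset()] objects (ids
#'   `<tissue>_<k>`).
#' @export
generate_datasets <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  genes <- synth_gene_names(design$n_genes)
  with_seed(design$seed, {
    baseline <- stats::rnorm(design$n_genes,
                             design$baseline_mu_sd[1],
                             design$baseline_mu_sd[2])
    delta <- function(tissue) {
      d <- numeric(design$n_genes)
      for (ps in design$planted_sets) {
        eff <- ps$effects[[tissue]] %||% 0
        d[ps$genes] <- d[ps$genes] + eff
      }
      d
    }
    out <- list()
    tissue_counter <- integer(0)
    for (r in seq_len(nrow(design$tissues))) {
      row <- design$tissues[r, ]
      d_tis <- delta(row$tissue)
      for (k in seq_len(row$n_datasets)) {
        n_seen <- tissue_counter[row$tissue]
        if (is.na(n_seen)) n_seen <- 0L
        tissue_counter[row$tissue] <- n_seen + 1L
        id <- sprintf("%s_%02d", row$tissue, n_seen + 1L)
        n_keep <- design$n_genes -
          floor(design$dropout_frac * design$n_genes)
        keep <- sort(sample.int(design$n_genes, n_keep))
        n_case <- row$n_case
        n_ctrl <- row$n_control
        n_s <- n_case + n_ctrl
        samples <- c(sprintf("%s_case_%02d", id, seq_len(n_case)),
                     sprintf("%s_ctrl_%02d", id, seq_len(n_ctrl)))
        grp <- stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                               samples)
        eff <- matrix(0, length(keep), n_s)
        eff[, seq_len(n_case)] <- d_tis[keep]
        vals <- baseline[keep] + eff +
          matrix(stats::rnorm(length(keep) * n_s, 0, design$noise_sd),
                 length(keep), n_s)
        dimnames(vals) <- list(genes[keep], samples)
        out[[id]] <- expression_dataset(
          dataset_id = id, values = vals, group = grp,
          tissue = row$tissue, organism = row$organism,
          platform_id = sprintf("SYNTH_%s", id), scale = "log2")
      }
    }
    out
  })
}

#' Generate a gene-set database with planted terms
#'
#' One term per planted set of the design (exact membership), plus
#' `n_random_terms` terms of uniformly drawn size and membership. The
#' planted terms give enrichment recovery a known answer; the random terms
#' provide the null background.
#'
#' @param design A [synth_design()].
#' @param n_random_terms Number of random terms.
#' @param term_size_range Length-2 integer: min and max random-term size.
#' @param seed Integer seed (defaults to the design seed).
#' @return A [gene_set_db()].
#' @export
generate_genesets <- function(design, n_random_terms = 100L,
                              term_size_range = c(20L, 50L),
                              seed = design$seed) {
  stopifnot(inherits(design, "synth_design"))
  if (max(term_size_range) > design$n_genes)
    fail("term sizes cannot exceed the gene universe")
  genes <- synth_gene_names(design$n_genes)
  with_seed(seed, {
    ids <- vapply(design$planted_sets, `[[`, "", "name")
    desc <- rep("planted", length(ids))
    members <- lapply(design$planted_sets, function(ps) genes[ps$genes])
    for (i in seq_len(n_random_terms)) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
      ids <- c(ids, sprintf("RAND_%04d", i))
      desc <- c(desc, "random")
      members <- c(members, list(genes[sample.int(design$n_genes, size)]))
    }
    gene_set_db(ids, desc, members)
  })
}

#' Generate a ranked drug-profile catalogue with planted compounds
#'
#' Random drugs are uniform permutations of the gene universe. A planted
#' `reverser` for a target signature places the signature's up-genes in the
#' bottom ranks and its down-genes in the top ranks (strongly negative
#' connectivity score by construction); a `mimicker` does the opposite.
#'
#' @param gene_universe Character vector of catalogue genes.
#' @param n_random_drugs Number of random compounds (`DRUG_0001`, ...).
#' @param planted List of planted compounds, each a list with `name`,
#'   `role` (`"reverser"` or `"mimicker"`) and `signature` (list with `up`
#'   and `down` gene vectors, subsets of the universe).
#' @param seed Integer seed.
#' @return A [drug_catalogue()].
#' @export
generate_drug_catalogue <- function(gene_universe, n_random_drugs = 500L,
                                    planted = list(), seed = 1L) {
  gene_universe <- as.character(gene_universe)
  N <- length(gene_universe)
  random_names <- if (n_random_drugs > 0)
    sprintf("DRUG_%04d", seq_len(n_random_drugs)) else character(0)
  planted_names <- vapply(planted, `[[`, "", "name")
  if (length(intersect(planted_names, random_names)))
    fail("planted drug name collides with a random drug name")
  if (anyDuplicated(planted_names)) fail("duplicate planted drug names")
  with_seed(seed, {
    profiles <- list()
    for (nm in random_names)
      profiles[[nm]] <- gene_universe[sample.int(N)]
    for (pl in planted) {
      role <- match.arg(pl$role, c("reverser", "mimicker"))
      up <- as.character(pl$signature$up)
      down <- as.character(pl$signature$down %||% character(0))
      if (length(setdiff(c(up, down), gene_universe)))
        fail("planted signature genes outside the universe for '",
             pl$name, "'")
      mid <- setdiff(gene_universe, c(up, down))
      mid <- mid[sample.int(length(mid))]
      profiles[[pl$name]] <- if (role == "reverser") c(down, mid, up)
                             else c(up, mid, down)
    }
    drug_catalogue(profiles)
  })
}

#' Generate a drug-set database around a catalogue
#'
#' Companion generator for drug-set enrichment: one `target` set per
#' planted-compound group (exact membership) plus random sets drawn from
#' the whole catalogue. Not part of the planted-structure contract; it
#' simply gives the drug-set enrichment stage a database to run against.
#'
#' @param catalogue_drugs All drug names of the catalogue.
#' @param planted_groups Named list: set id -> character vector of member
#'   drugs (e.g. the planted reversers).
#' @param n_random_sets Number of random sets.
#' @param set_size_range Length-2 integer: random set sizes.
#' @param seed Integer seed.
#' @return A `drug_set_db`.
#' @export
generate_drugsets <- function(catalogue_drugs, planted_groups = list(),
                              n_random_sets = 50L,
                              set_size_range = c(5L, 25L), seed = 1L) {
  with_seed(seed, {
    ids <- names(planted_groups) %||% character(0)
    category <- rep("target", length(ids))
    members <- unname(planted_groups)
    for (i in seq_len(n_random_sets)) {
      size <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
      ids <- c(ids, sprintf("DSET_%04d", i))
      category <- c(category, "other")
      members <- c(members,
                   list(sample(catalogue_drugs, min(size,
                                                    length(catalogue_drugs)))))
    }
    if (anyDuplicated(ids)) fail("duplicate drug-set ids")
    structure(list(set_id = ids, category = category,
                   members = lapply(members, as.character)),
              class = "drug_set_db")
  })
}
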