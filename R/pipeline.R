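# Orchestration: study simulation to disk, staged pipeline runs, manifests.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  write_tsv(df, path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate a complete study directory
#'
#' Writes the full on-disk layout consumed by [run_all()]: per-dataset
#' matrix and phenotype TSVs, a `datasets.tsv` metadata table, a gene-set
#' GMT with planted terms, a ranked drug-profile catalogue with planted
#' reversers, a drug-set database, and a resolved `config.yaml` (declaring
#' `human`/`animal` groups when the design spans both).
#'
#' The planted reversers target the signature of `reverser_tissue`: the
#' planted genes with positive effect there form the signature's up list
#' and those with negative effect its down list.
#'
#' @param out_dir Output directory (created if needed).
#' @param design A [synth_design()].
#' @param config A [run_config()]; written beside the data.
#' @param n_random_terms,term_size_range Passed to [generate_genesets()].
#' @param n_random_drugs Number of random catalogue compounds.
#' @param n_planted_reversers Number of planted reverser compounds
#'   (`REVERSER_1`, ...).
#' @param reverser_tissue Tissue whose planted signature the reversers
#'   target (default: first tissue of the design).
#' @return The output directory, invisibly.
#' @export
simulate_study <- function(out_dir, design = synth_design(),
                           config = run_config(seed = design$seed),
                           n_random_terms = 100L,
                           term_size_range = c(20L, 50L),
                           n_random_drugs = 500L,
                           n_planted_reversers = 5L,
                           reverser_tissue = design$tissues$tissue[1]) {
  dir.create(file.path(out_dir, "datasets"), recursive = TRUE,
             showWarnings = FALSE)
  datasets <- generate_datasets(design)

  meta <- do.call(rbind, lapply(datasets, function(ds) {
    data.frame(dataset_id = ds$dataset_id, tissue = ds$tissue,
               organism = ds$organism, platform_id = ds$platform_id,
               scale = ds$scale,
               matrix = file.path("datasets",
                                  paste0(ds$dataset_id, ".matrix.tsv")),
               phenotype = file.path("datasets",
                                     paste0(ds$dataset_id,
                                            ".phenotype.tsv")),
               stringsAsFactors = FALSE)
  }))
  for (ds in datasets) {
    write_expression_dataset(ds,
      file.path(out_dir, "datasets", paste0(ds$dataset_id, ".matrix.tsv")),
      file.path(out_dir, "datasets",
                paste0(ds$dataset_id, ".phenotype.tsv")))
  }
  write_tsv(meta, file.path(out_dir, "datasets.tsv"))

  db <- generate_genesets(design, n_random_terms, term_size_range,
                          seed = derive_seed(design$seed, 1L))
  write_gmt(db, file.path(out_dir, "genesets.gmt"))

  genes <- synth_gene_names(design$n_genes)
  sig_up <- character(0); sig_down <- character(0)
  for (ps in design$planted_sets) {
    eff <- ps$effects[[reverser_tissue]] %||% 0
    if (eff > 0) sig_up <- c(sig_up, genes[ps$genes])
    if (eff < 0) sig_down <- c(sig_down, genes[ps$genes])
  }
  planted <- lapply(seq_len(n_planted_reversers), function(i) {
    list(name = sprintf("REVERSER_%d", i), role = "reverser",
         signature = list(up = sig_up, down = sig_down))
  })
  catalogue <- generate_drug_catalogue(genes, n_random_drugs, planted,
                                       seed = derive_seed(design$seed, 2L))
  write_drug_catalogue(catalogue, file.path(out_dir, "catalogue.tsv"))

  drugsets <- generate_drugsets(
    names(catalogue$profiles),
    planted_groups = if (n_planted_reversers > 0)
      list(PLANTED_TARGET = vapply(planted, `[[`, "", "name")) else list(),
    seed = derive_seed(design$seed, 3L))
  write_gmt(drugsets, file.path(out_dir, "drugsets.gmt"))

  organisms <- unique(meta$organism)
  human <- tolower(meta$organism) %in% c("human", "homo sapiens")
  if (any(human) && any(!human)) {
    attr(config, "groups") <- list(human = meta$dataset_id[human],
                                   animal = meta$dataset_id[!human])
  }
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

read_study_datasets <- function(data_dir) {
  meta_path <- file.path(data_dir, "datasets.tsv")
  if (!file.exists(meta_path))
    fail("missing dataset table: ", meta_path)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (nrow(meta) < 2L) fail("need at least 2 datasets")
  datasets <- lapply(seq_len(nrow(meta)), function(i) {
    r <- meta[i, ]
    read_expression_dataset(
      file.path(data_dir, r$matrix), file.path(data_dir, r$phenotype),
      metadata = list(dataset_id = r$dataset_id, tissue = r$tissue,
                      organism = r$organism, platform_id = r$platform_id,
                      scale = r$scale))
  })
  names(datasets) <- meta$dataset_id
  datasets
}

#' Run the full pipeline on a study directory
#'
#' Executes the stages in order -- differential expression, cross-dataset
#' similarity, enrichment, connectivity/drug prediction, and (when the
#' configuration declares two dataset groups) the permutation validation of
#' cross-group overlaps -- writing TSV tables and JSON summaries per stage
#' under `outdir`, plus the resolved configuration and a run manifest with
#' file hashes, seeds and timings. A failing stage stops the run with the
#' stage named. With identical inputs, configuration and seed, all stage
#' outputs are byte-identical across reruns.
#'
#' Expected `data_dir` layout (as written by [simulate_study()]):
#' `datasets.tsv`, `datasets/`, `genesets.gmt`, `catalogue.tsv`, and
#' optionally `drugsets.gmt`.
#'
#' The tissue-clustering test needs at least two tissues with two datasets
#' each; on degenerate tissue layouts it is skipped with a warning recorded
#' in the manifest rather than failing the run.
#'
#' @param data_dir Input study directory.
#' @param config A [run_config()]; a `groups` attribute (named list of
#'   dataset ids, e.g. from [read_config()]) enables the two-group mode.
#' @param outdir Output directory (created if needed).
#' @param stages Which stages to write outputs for (prerequisite stages
#'   are still computed in memory). Default: all.
#' @return A `run_manifest` (invisibly written to `manifest.json`).
#' @export
run_all <- function(data_dir, config = run_config(), outdir,
                    stages = c("de", "similarity", "enrich", "connect",
                               "permtest")) {
  stages <- match.arg(stages, several.ok = TRUE)
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  timings <- list()
  outputs <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  run_stage <- function(name, expr) {
    ts <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        fail("stage '", name, "' failed: ", conditionMessage(e))
      }),
      warning = function(w) { note(w); invokeRestart("muffleWarning") }
    )
    timings[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 3)
    res
  }

  emit <- function(path) outputs <<- c(outputs, path)

  groups <- attr(config, "groups")
  datasets <- run_stage("load", read_study_datasets(data_dir))
  if (!is.null(groups)) {
    unknown <- setdiff(unlist(groups), names(datasets))
    if (length(unknown))
      fail("config `groups` references unknown dataset(s): ",
           paste(unknown, collapse = ", "))
  }
  genesets_path <- file.path(data_dir, "genesets.gmt")
  catalogue_path <- file.path(data_dir, "catalogue.tsv")
  if (!file.exists(genesets_path))
    fail("missing gene-set file (config key genesets_file): ",
         genesets_path)
  if (!file.exists(catalogue_path))
    fail("missing drug catalogue (config key catalogue_file): ",
         catalogue_path)
  drugsets_path <- file.path(data_dir, "drugsets.gmt")

  write_config(config, file.path(outdir, "config_resolved.yaml"))
  emit(file.path(outdir, "config_resolved.yaml"))

  ## ---- stage: differential expression (always computed) ----
  de_dir <- file.path(outdir, "de")
  if ("de" %in% stages) dir.create(de_dir, showWarnings = FALSE)
  de_results <- run_stage("de", {
    res <- lapply(datasets, function(ds) de_analysis(ds, config))
    if ("de" %in% stages) for (r in res) {
      write_tsv(r$table, file.path(de_dir, paste0(r$dataset_id, ".de.tsv")))
      emit(file.path(de_dir, paste0(r$dataset_id, ".de.tsv")))
      writeLines(de_genes(r, "up"),
                 file.path(de_dir, paste0(r$dataset_id, ".up.txt")))
      writeLines(de_genes(r, "down"),
                 file.path(de_dir, paste0(r$dataset_id, ".down.txt")))
      emit(file.path(de_dir, paste0(r$dataset_id, ".up.txt")))
      emit(file.path(de_dir, paste0(r$dataset_id, ".down.txt")))
    }
    if ("de" %in% stages) {
      dm <- direction_matrix(res, config$direction_min_datasets)
      write_matrix_tsv(dm$cells,
                       file.path(de_dir, "direction_matrix.tsv"),
                       id_col = "gene")
      emit(file.path(de_dir, "direction_matrix.tsv"))
      write_json(list(stage = "de", seed = config$seed,
                      n_datasets = length(res),
                      n_up = vapply(res, function(r)
                        sum(r$table$direction == "up"), 0L),
                      n_down = vapply(res, function(r)
                        sum(r$table$direction == "down"), 0L)),
                 file.path(de_dir, "summary.json"))
      emit(file.path(de_dir, "summary.json"))
    }
    res
  })

  ## ---- stage: similarity ----
  tissue_test <- NULL
  if ("similarity" %in% stages) {
  sim_dir <- file.path(outdir, "similarity")
  dir.create(sim_dir, showWarnings = FALSE)
  tissue_map <- vapply(datasets, function(d) d$tissue, "")
  tissue_test <- run_stage("similarity", {
    model <- build_distance_model(de_results, tissue_map, config)
    write_matrix_tsv(model$corr, file.path(sim_dir, "corr.tsv"),
                     "dataset_id")
    write_matrix_tsv(model$dist, file.path(sim_dir, "dist.tsv"),
                     "dataset_id")
    emb <- data.frame(dataset_id = model$dataset_ids,
                      tissue = unname(model$tissue),
                      x = model$embedding[, 1], y = model$embedding[, 2],
                      stringsAsFactors = FALSE)
    write_tsv(emb, file.path(sim_dir, "embedding.tsv"))
    write_tsv(data.frame(eigenvalue = model$eigenvalues),
              file.path(sim_dir, "eigenvalues.tsv"))
    for (f in c("corr.tsv", "dist.tsv", "embedding.tsv",
                "eigenvalues.tsv"))
      emit(file.path(sim_dir, f))
    tt <- tryCatch(
      tissue_distance_test(model, config,
                           seed = derive_seed(config$seed, 11L)),
      error = function(e) {
        warning("tissue test skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(tt)) {
      write_json(list(statistic = "between_minus_within_mean_distance",
                      method = "tissue label permutation",
                      space = tt$space,
                      within_mean = as.list(tt$within_mean),
                      observed = tt$observed,
                      n_permutations = tt$n_permutations,
                      n_ge = tt$n_ge, p = tt$p, seed = tt$seed),
                 file.path(sim_dir, "tissue_test.json"))
      emit(file.path(sim_dir, "tissue_test.json"))
    }
    tt
  })
  }

  ## ---- stage: enrichment ----
  enr_records <- NULL
  if (any(c("enrich", "permtest") %in% stages)) {
  enr_dir <- file.path(outdir, "enrichment")
  if ("enrich" %in% stages) dir.create(enr_dir, showWarnings = FALSE)
  geneset_db <- read_gmt(genesets_path)
  enr_records <- run_stage("enrich", {
    recs <- lapply(de_results, function(r)
      enrich_dataset(r, geneset_db, config))
    all_rec <- do.call(rbind, recs)
    if ("enrich" %in% stages) {
      for (i in seq_along(recs)) {
        id <- de_results[[i]]$dataset_id
        write_tsv(recs[[i]], file.path(enr_dir,
                                       paste0(id, ".enrichment.tsv")))
        emit(file.path(enr_dir, paste0(id, ".enrichment.tsv")))
      }
      tom <- term_overlap(all_rec, config$term_overlap_min)
      write_matrix_tsv(tom$cells, file.path(enr_dir, "term_overlap.tsv"),
                       "term_direction")
      emit(file.path(enr_dir, "term_overlap.tsv"))
      write_json(list(stage = "enrich", convention = tom$convention,
                      min_overlap = config$term_overlap_min,
                      n_significant_records = nrow(all_rec),
                      n_overlap_rows = length(tom$term_id)),
                 file.path(enr_dir, "summary.json"))
      emit(file.path(enr_dir, "summary.json"))
    }
    all_rec
  })
  }

  ## ---- stage: connectivity ----
  connect <- NULL
  catalogue <- NULL
  if (any(c("connect", "permtest") %in% stages)) {
  con_dir <- file.path(outdir, "connectivity")
  write_conn <- "connect" %in% stages
  if (write_conn) dir.create(con_dir, showWarnings = FALSE)
  catalogue <- read_drug_catalogue(catalogue_path)
  connect <- run_stage("connect", {
    candidate_lists <- list()
    excluded <- character(0)
    for (r in de_results) {
      sig <- tryCatch(
        trim_signature(r, catalogue$gene_universe, config),
        signature_too_small = function(e) {
          excluded <<- c(excluded, conditionMessage(e))
          NULL
        })
      if (is.null(sig)) next
      scan <- connectivity_scan(sig, catalogue)
      cand <- select_reversers(scan, config)
      if (write_conn) {
        write_tsv(scan,
                  file.path(con_dir,
                            paste0(r$dataset_id, ".connectivity.tsv")))
        emit(file.path(con_dir, paste0(r$dataset_id, ".connectivity.tsv")))
        writeLines(cand, file.path(con_dir,
                                   paste0(r$dataset_id,
                                          ".candidates.txt")))
        emit(file.path(con_dir, paste0(r$dataset_id, ".candidates.txt")))
      }
      candidate_lists[[r$dataset_id]] <- cand
    }
    if (length(excluded)) warning(paste(excluded, collapse = "; "))

    group_ids <- groups %||% list(all = names(candidate_lists))
    interested <- list()
    for (g in names(group_ids)) {
      lists_g <- candidate_lists[intersect(group_ids[[g]],
                                           names(candidate_lists))]
      min_g <- if (g == "animal") config$animal_overlap_min
               else config$human_overlap_min
      ov <- tryCatch(overlap_candidates(lists_g, min_g),
                     error = function(e) {
                       warning("group '", g, "': ", conditionMessage(e))
                       NULL
                     })
      if (is.null(ov)) next
      interested[[g]] <- ov
      if (write_conn) {
        write_tsv(data.frame(drug = names(ov$counts),
                             n_datasets = unname(ov$counts),
                             interested = names(ov$counts) %in%
                               ov$interested_drugs),
                  file.path(con_dir, paste0("interested_", g, ".tsv")))
        emit(file.path(con_dir, paste0("interested_", g, ".tsv")))
      }
    }

    if (write_conn && file.exists(drugsets_path)) {
      drugset_db <- read_drugset_db(drugsets_path)
      for (g in names(interested)) {
        drugs_g <- interested[[g]]$interested_drugs
        if (!length(drugs_g)) next
        dse <- drugset_enrichment(drugs_g, drugset_db,
                                  names(catalogue$profiles), config)
        write_tsv(dse, file.path(con_dir,
                                 paste0("drugset_enrichment_", g, ".tsv")))
        emit(file.path(con_dir, paste0("drugset_enrichment_", g, ".tsv")))
      }
    }
    list(candidate_lists = candidate_lists, interested = interested,
         excluded = excluded)
  })
  }

  ## ---- stage: permutation validation (two-group mode) ----
  perm <- NULL
  if ("permtest" %in% stages && !is.null(groups) && length(groups) == 2L) {
    perm_dir <- file.path(outdir, "permutation")
    dir.create(perm_dir, showWarnings = FALSE)
    perm <- run_stage("permtest", {
      ga <- names(groups)[1]; gb <- names(groups)[2]
      rec_a <- enr_records[enr_records$dataset_id %in% groups[[ga]], ]
      rec_b <- enr_records[enr_records$dataset_id %in% groups[[gb]], ]
      obs_terms <- shared_term_count(rec_a, rec_b, config$term_overlap_min)
      prof <- group_profile(de_results)
      pt <- permute_term_overlap(prof[groups[[ga]]], prof[groups[[gb]]],
                                 geneset_db, obs_terms, config,
                                 seed = derive_seed(config$seed, 21L))

      cl <- connect$candidate_lists
      ia <- connect$interested[[ga]]
      ib <- connect$interested[[gb]]
      obs_drugs <- length(intersect(ia$interested_drugs %||% character(0),
                                    ib$interested_drugs %||% character(0)))
      sizes <- function(g) {
        ids <- intersect(groups[[g]], names(cl))
        vapply(cl[ids], length, 0L)
      }
      min_of <- function(g) if (g == "animal") config$animal_overlap_min
                            else config$human_overlap_min
      pd <- permute_drug_overlap(sizes(ga), sizes(gb),
                                 length(catalogue$profiles), obs_drugs,
                                 config, min_a = min_of(ga),
                                 min_b = min_of(gb),
                                 seed = derive_seed(config$seed, 22L))
      for (res in list(pt, pd)) {
        path <- file.path(perm_dir, paste0(res$statistic_name, ".json"))
        write_json(list(statistic = res$statistic_name,
                        observed = res$observed,
                        n_permutations = res$n_permutations,
                        null_counts = as.list(res$null_counts),
                        n_ge = res$n_ge, p = res$p, seed = res$seed),
                   path)
        emit(path)
      }
      list(shared_terms = pt, shared_drugs = pd)
    })
  }

  manifest <- structure(list(
    config = unclass(config),
    groups = groups,
    seed = config$seed,
    data_dir = normalizePath(data_dir),
    timings = timings,
    warnings = warnings_log,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(outputs))), basename(outputs)),
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  ), class = "run_manifest")
  write_json(unclass(manifest), file.path(outdir, "manifest.json"))

  invisible(structure(list(manifest = manifest, de = de_results,
                           tissue_test = tissue_test,
                           enrichment = enr_records,
                           connectivity = connect,
                           permutation = perm),
                      class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("  datasets:", length(x$de), "\n")
  if (!is.null(x$tissue_test))
    cat(sprintf("  tissue test p = %.4g\n", x$tissue_test$p))
  if (!is.null(x$permutation)) {
    cat(sprintf("  shared terms: observed %d, p = %.4g\n",
                x$permutation$shared_terms$observed,
                x$permutation$shared_terms$p))
    cat(sprintf("  shared drugs: observed %d, p = %.4g\n",
                x$permutation$shared_drugs$observed,
                x$permutation$shared_drugs$p))
  }
  invisible(x)
}
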