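#' Construct and validate an expression dataset
#'
#' One cohort: a gene x sample expression matrix with case/control labels
#' and tissue/organism/scale metadata. Validation enforces the invariants
#' every downstream stage relies on: finite values (non-negative on linear
#' scale), unique gene symbols, a group label for every sample, and minimum
#' group sizes -- at least 2 per group for human cohorts and at least 5 per
#' group for animal-model cohorts (the screening rule that both groups must
#' be greater than four).
#'
#' @param dataset_id Unique dataset identifier.
#' @param values Numeric gene x sample matrix with row and column names.
#' @param group Named character vector (or factor) mapping every sample id
#'   to `"case"` or `"control"`.
#' @param tissue Tissue label, e.g. `"brain"`, `"blood"`.
#' @param organism Organism, e.g. `"human"`, `"mouse"`. Anything other than
#'   `"human"` / `"homo sapiens"` is treated as an animal model.
#' @param platform_id Platform / gene-universe identifier.
#' @param scale `"linear"` or `"log2"`, the scale of `values`. Fold changes
#'   are ratios of group means on the linear scale and differences of group
#'   means on the log2 scale, so this field must be set correctly.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, values, group,
                               tissue = "unknown", organism = "human",
                               platform_id = "unknown",
                               scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    fail("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    fail("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    fail("duplicate gene symbols in dataset '", dataset_id, "'")
  if (anyDuplicated(colnames(values)))
    fail("duplicate sample ids in dataset '", dataset_id, "'")
  if (any(!is.finite(values)))
    fail("non-finite expression values in dataset '", dataset_id, "'")
  if (scale == "linear" && any(values < 0))
    fail("negative values are not allowed on the linear scale (dataset '",
         dataset_id, "')")

  group <- stats::setNames(as.character(group), names(group))
  samples <- colnames(values)
  missing <- setdiff(samples, names(group))
  if (length(missing))
    fail("no phenotype for sample(s): ", paste(missing, collapse = ", "))
  group <- group[samples]
  if (!all(group %in% c("case", "control")))
    fail("group labels must be 'case' or 'control' (dataset '",
         dataset_id, "')")

  n_case <- sum(group == "case")
  n_control <- sum(group == "control")
  animal <- !tolower(organism) %in% c("human", "homo sapiens")
  min_n <- if (animal) 5L else 2L
  if (n_case < min_n || n_control < min_n) {
    if (animal) {
      fail("group size must exceed 4 for animal datasets (dataset '",
           dataset_id, "': ", n_case, " case / ", n_control, " control)")
    }
    fail("each group needs at least 2 samples (dataset '", dataset_id,
         "': ", n_case, " case / ", n_control, " control)")
  }

  structure(
    list(dataset_id = as.character(dataset_id),
         tissue = as.character(tissue),
         organism = as.character(organism),
         platform_id = as.character(platform_id),
         scale = scale,
         genes = rownames(values),
         samples = samples,
         values = values,
         group = group),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset '%s': %d genes x %d samples (%d case / %d control)\n",
    x$dataset_id, length(x$genes), length(x$samples),
    sum(x$group == "case"), sum(x$group == "control")))
  cat(sprintf("  tissue=%s organism=%s platform=%s scale=%s\n",
              x$tissue, x$organism, x$platform_id, x$scale))
  invisible(x)
}

#' Read an expression dataset from TSV files
#'
#' The matrix file is tab-separated with gene symbols in the first column
#' (header `gene`) and sample ids in the header row; the phenotype file has
#' columns `sample_id` and `group` (`case`/`control`). Duplicated gene
#' symbols are collapsed by keeping the row with the highest mean value --
#' a deterministic rule for gene-level inputs that arrive with accidental
#' duplicates. Sample order of the matrix is preserved. Parsing is
#' locale-independent (decimal point only) and accepts LF or CRLF endings.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param phenotype_path Path to the phenotype TSV.
#' @param metadata Named list with `dataset_id`, `tissue`, `organism`,
#'   `platform_id`, `scale`. Missing entries fall back to
#'   [expression_dataset()] defaults.
#' @return An `expression_dataset`.
#' @export
read_expression_dataset <- function(matrix_path, phenotype_path,
                                    metadata = list()) {
  if (!file.exists(matrix_path)) fail("matrix file not found: ", matrix_path)
  if (!file.exists(phenotype_path))
    fail("phenotype file not found: ", phenotype_path)

  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) fail("matrix must have a gene column plus samples")
  genes <- tab[[1L]]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !(cells %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    fail(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                 bad[1, 1], genes[bad[1, 1]], colnames(cells)[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    fail(sprintf("missing value at row %d (gene '%s'), column '%s'",
                 bad[1, 1], genes[bad[1, 1]], colnames(cells)[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, colnames(cells))

  if (anyDuplicated(genes)) {
    means <- rowMeans(num)
    # keep, per symbol, the row with the highest mean value
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)  # preserve original row order
    num <- num[keep, , drop = FALSE]
  }

  ph <- utils::read.delim(phenotype_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ph)))
    fail("phenotype file needs columns 'sample_id' and 'group'")
  grp <- stats::setNames(as.character(ph$group), as.character(ph$sample_id))

  expression_dataset(
    dataset_id = metadata$dataset_id %||% basename(matrix_path),
    values = num,
    group = grp,
    tissue = metadata$tissue %||% "unknown",
    organism = metadata$organism %||% "human",
    platform_id = metadata$platform_id %||% "unknown",
    scale = metadata$scale %||% "log2"
  )
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression_dataset()]: round-trips genes, samples,
#' groups and values at full precision.
#'
#' @param dataset An `expression_dataset`.
#' @param matrix_path,phenotype_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_dataset <- function(dataset, matrix_path, phenotype_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- data.frame(gene = dataset$genes,
                    format(dataset$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene", dataset$samples)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- data.frame(sample_id = dataset$samples,
                   group = unname(dataset$group[dataset$samples]))
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Construct a gene-set database
#'
#' @param term_id Character vector of unique term ids.
#' @param description Character vector of term descriptions.
#' @param members List of non-empty character vectors of gene symbols.
#'   Symbol comparison throughout the package is case-sensitive.
#' @return An object of class `gene_set_db`.
#' @export
gene_set_db <- function(term_id, description, members) {
  term_id <- as.character(term_id)
  if (anyDuplicated(term_id))
    fail("duplicate term_id: ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  if (length(description) != length(term_id) ||
      length(members) != length(term_id))
    fail("term_id, description and members must have equal length")
  if (length(members) && any(!vapply(members, length, 0L)))
    fail("every member set must be non-empty")
  members <- lapply(members, function(m) unique(as.character(m)))
  structure(list(term_id = term_id,
                 description = as.character(description),
                 members = members),
            class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  sizes <- vapply(x$members, length, 0L)
  cat(sprintf("gene_set_db: %d sets (sizes %s)\n", length(x$term_id),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `term<TAB>description<TAB>member...`.
#' Member case is preserved; comparisons are case-sensitive.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_db`. An empty file yields an empty database with a
#'   warning; a line with fewer than 3 fields or a duplicated term id is an
#'   error naming the line.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) fail("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_db(character(0), character(0), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short))
    fail("GMT line ", short[1], " has fewer than 3 fields: ", path)
  gene_set_db(
    term_id = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    members = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write a gene-set database as GMT
#' @param db A `gene_set_db` (or `drug_set_db`; the category field is
#'   written in the description slot).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  if (inherits(db, "drug_set_db")) {
    lines <- mapply(function(id, cat, m) paste(c(id, cat, m), collapse = "\t"),
                    db$set_id, db$category, db$members)
  } else {
    lines <- mapply(function(id, d, m) paste(c(id, d, m), collapse = "\t"),
                    db$term_id, db$description, db$members)
  }
  writeLines(unlist(lines, use.names = FALSE), path)
  invisible(path)
}

DRUGSET_CATEGORIES <- c("target", "pathway", "indication",
                        "adverse_reaction", "other")

#' Read a drug-set database (GMT-like)
#'
#' Same layout as GMT with the description field holding the set category
#' (`target`, `pathway`, `indication`, `adverse_reaction`; anything else is
#' mapped to `other`). Used for drug-set enrichment of reversal candidates.
#'
#' @param path Path to the file.
#' @return An object of class `drug_set_db`.
#' @export
read_drugset_db <- function(path) {
  db <- read_gmt(path)
  category <- db$description
  category[!category %in% DRUGSET_CATEGORIES] <- "other"
  structure(list(set_id = db$term_id,
                 category = category,
                 members = db$members),
            class = "drug_set_db")
}

#' Construct a ranked drug-profile catalogue
#'
#' The reference catalogue for connectivity queries: for every compound, the
#' full list of genes ordered from most up-regulated by the compound
#' (rank 1) to most down-regulated (rank N). Every profile must be a
#' permutation of the same gene universe.
#'
#' @param profiles Named list of character vectors; each a permutation of
#'   the catalogue gene universe.
#' @return An object of class `drug_catalogue` with fields `gene_universe`
#'   (sorted symbols) and `profiles`.
#' @export
drug_catalogue <- function(profiles) {
  if (!length(profiles) || is.null(names(profiles)) ||
      any(names(profiles) == ""))
    fail("`profiles` must be a non-empty named list")
  if (anyDuplicated(names(profiles)))
    fail("duplicate drug names in catalogue")
  universe <- sort(profiles[[1L]])
  for (d in names(profiles)) {
    p <- as.character(profiles[[d]])
    if (length(p) != length(universe) || !identical(sort(p), universe))
      fail("profile for drug '", d,
           "' is not a permutation of the catalogue gene universe")
    profiles[[d]] <- p
  }
  structure(list(gene_universe = universe, profiles = profiles),
            class = "drug_catalogue")
}

#' @export
print.drug_catalogue <- function(x, ...) {
  cat(sprintf("drug_catalogue: %d drugs x %d genes\n",
              length(x$profiles), length(x$gene_universe)))
  invisible(x)
}

#' Read a drug-profile catalogue from TSV
#'
#' One row per drug: the drug name followed by the full ordered gene list
#' (rank 1 = most up-regulated by the drug). No header.
#'
#' @param path Path to the catalogue TSV.
#' @return A `drug_catalogue`.
#' @export
read_drug_catalogue <- function(path) {
  if (!file.exists(path)) fail("catalogue file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) fail("empty drug catalogue: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  drugs <- vapply(fields, `[[`, "", 1L)
  profiles <- stats::setNames(lapply(fields, `[`, -1L), drugs)
  drug_catalogue(profiles)
}

#' Write a drug-profile catalogue as TSV
#' @param catalogue A `drug_catalogue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "drug_catalogue"))
  lines <- vapply(names(catalogue$profiles), function(d) {
    paste(c(d, catalogue$profiles[[d]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
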