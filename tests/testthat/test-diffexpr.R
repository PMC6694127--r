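test_that("fold change follows the group-mean definition on both scales", {
  r <- fold_change(c(3, 3), c(2, 2), "linear")
  expect_equal(r$fc, 1.5)
  expect_equal(r$log2fc, log2(1.5))

  same <- fold_change(c(2, 4), c(2, 4), "linear")
  expect_equal(same$fc, 1)
  expect_equal(same$log2fc, 0)

  r2 <- fold_change(c(5, 5), c(3, 3), "log2")
  expect_equal(r2$log2fc, 2)
  expect_equal(r2$fc, 4)

  # log2fc and fc stay consistent
  set.seed(1)
  for (i in 1:20) {
    a <- rexp(5); b <- rexp(5)
    r <- fold_change(a, b, "linear")
    expect_equal(r$log2fc, log2(r$fc), tolerance = 1e-12)
  }

  # non-positive linear means cannot give a ratio: flagged, not an error
  flag <- fold_change(c(1, 1), c(0, 0), "linear")
  expect_true(flag$flagged)
  expect_true(is.na(flag$fc))
})

test_that("exact rank-sum p matches full enumeration for tie-free samples", {
  expect_equal(ranksum_test(c(1, 2), c(3, 4), "exact"), 1/3)
  expect_equal(ranksum_test(1:8, 9:16, "exact"), 2 / choose(16, 8))

  set.seed(7)
  for (nx in 2:5) {
    for (ny in 2:5) {
      if (nx + ny > 12) next
      for (rep in 1:3) {
        x <- rnorm(nx)
        y <- rnorm(ny)
        expect_equal(ranksum_test(x, y, "exact"),
                     ranksum_enum_oracle(x, y), tolerance = 1e-12,
                     info = sprintf("nx=%d ny=%d rep=%d", nx, ny, rep))
      }
    }
  }
})

test_that("rank-sum handles degenerate and tied inputs", {
  expect_equal(ranksum_test(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(ranksum_test(c(1, 1, 2), c(1, 1, 2)), 1)
  expect_warning(p <- ranksum_test(c(1, 1, 2), c(2, 3, 4), "exact"),
                 "ties")
  expect_true(p > 0 && p <= 1)
})

test_that("exact and normal p-values agree on tie-free grids", {
  # Full grid over every configuration with 8 <= n_total <= 16: the
  # continuity-corrected normal approximation never deviates from the
  # exact p by more than its analytic worst case (0.0424, reached at the
  # most unbalanced n_total = 8 split).
  worst <- 0
  for (n_tot in 8:16) {
    for (nx in 2:(n_tot - 2)) {
      ny <- n_tot - nx
      if (ny < 2) next
      base <- seq_len(n_tot)  # any tie-free values reduce to ranks
      for (u_x in list(seq_len(nx), seq(1, n_tot, length.out = nx))) {
        idx <- unique(round(u_x))
        x <- base[idx]
        y <- base[-idx]
        d <- abs(ranksum_test(x, y, "exact") -
                 ranksum_test(x, y, "normal"))
        worst <- max(worst, d)
      }
    }
  }
  expect_lte(worst, 0.043)
})

test_that("DE calls use strict threshold inequalities", {
  cfg <- run_config()
  rec <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    fc = c(1.6, 1.5, 0.5, 1.6, 2/3),
                    log2fc = log2(c(1.6, 1.5, 0.5, 1.6, 2/3)),
                    p = c(0.01, 0.001, 0.04, 0.05, 0.04))
  de <- call_de(rec, cfg, "t")
  expect_equal(de$table$direction,
               c("up",   # fc > 1.5, p < 0.05
                 "ns",   # fc exactly 1.5 fails the strict > rule
                 "down", # 0.5 < 1/1.5
                 "ns",   # p exactly 0.05 fails the strict < rule
                 "ns"))  # 2/3 is exactly 1/1.5: strict < fails
})

test_that("BH adjustment is applied only when requested", {
  genes <- sprintf("g%02d", 1:10)
  rec <- data.frame(gene = genes, fc = rep(2, 10), log2fc = 1,
                    p = c(0.001, 0.03, 0.04, rep(0.6, 7)))
  raw <- call_de(rec, run_config(), "t")
  bh <- call_de(rec, run_config(fdr = "bh"), "t")
  expect_equal(sum(raw$table$direction == "up"), 3L)
  # BH-adjusted: 0.03 -> min(p * n/rank) from the right >= 0.05
  expect_equal(sum(bh$table$direction == "up"), 1L)
  expect_equal(bh$table$p, raw$table$p)  # reported p stays raw
})

test_that("DE analysis is invariant to sample and gene order", {
  design <- planted_two_tissue_design(3, n_genes = 60,
                                      n_per_tissue = c(1L, 1L),
                                      dropout = 0)
  ds <- generate_datasets(design)[[1]]
  de1 <- de_analysis(ds)

  perm_s <- sample(seq_along(ds$samples))
  perm_g <- sample(seq_along(ds$genes))
  ds2 <- expression_dataset(ds$dataset_id,
                            ds$values[perm_g, perm_s],
                            ds$group[perm_s],
                            tissue = ds$tissue, organism = ds$organism,
                            platform_id = ds$platform_id, scale = ds$scale)
  de2 <- de_analysis(ds2)
  tab2 <- de2$table[match(de1$table$gene, de2$table$gene), ]
  expect_equal(de1$table$fc, tab2$fc, tolerance = 1e-12)
  expect_equal(de1$table$direction, tab2$direction)
})

test_that("null synthetic data yields symmetric, rare DE calls", {
  up <- 0; down <- 0; total <- 0
  for (seed in 1:3) {
    datasets <- generate_datasets(null_design(seed))
    for (ds in datasets) {
      de <- de_analysis(ds)
      up <- up + sum(de$table$direction == "up")
      down <- down + sum(de$table$direction == "down")
      total <- total + nrow(de$table)
    }
  }
  # joint FC + p rule is stricter than the p threshold alone
  expect_lt((up + down) / total, 0.05)
  # direction symmetry under the null
  expect_gt(binom.test(up, up + down, 0.5)$p.value, 0.01)
})

test_that("direction matrix applies the dataset-count retention rule", {
  genes <- synth_genes(6)
  cfg <- run_config()
  # gene G00001: up in 3 datasets; G00002: up in 2; G00003: up 3 + down 2
  mk <- function(id, up = character(0), down = character(0)) {
    l2 <- ifelse(genes %in% up, 1.5, ifelse(genes %in% down, -1.5, 0.1))
    p <- ifelse(genes %in% c(up, down), 0.001, 0.9)
    make_de(id, genes, l2, p, cfg)
  }
  res <- list(
    mk("b1", up = genes[c(1, 3)]), mk("b2", up = genes[c(1, 3)]),
    mk("b3", up = genes[c(1, 2, 3)]), mk("l1", down = genes[3]),
    mk("l2", up = genes[2], down = genes[3]))

  dm <- direction_matrix(res, min_datasets = 3)
  expect_true(all(c("G00001", "G00003") %in% dm$genes))
  expect_false("G00002" %in% dm$genes)  # only 2 datasets
  # G00003: up in 3, down in 2 -> 5 signed cells with both signs
  row3 <- dm$cells["G00003", ]
  expect_equal(sum(!is.na(row3)), 5L)
  expect_equal(sum(row3 > 0, na.rm = TRUE), 3L)
  expect_equal(sum(row3 < 0, na.rm = TRUE), 2L)
  # rows ordered by dataset count, descending
  expect_equal(dm$genes[1], "G00003")

  # boundary: min_datasets = 1 keeps every called gene
  dm1 <- direction_matrix(res, min_datasets = 1)
  expect_true(all(c("G00001", "G00002", "G00003") %in% dm1$genes))

  # empty retained set warns instead of failing
  null_res <- lapply(1:3, function(i)
    make_de(paste0("n", i), genes, rep(0.01, 6), rep(0.9, 6), cfg))
  expect_warning(dm0 <- direction_matrix(null_res, 3), "empty")
  expect_equal(nrow(dm0$cells), 0L)
})
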