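test_that("signature trimming follows the valid-gene and size rules", {
  cfg <- run_config()
  genes <- sprintf("g%04d", 1:400)
  # 200 valid up genes with distinct fold changes
  l2 <- c(seq(2, 1, length.out = 200), rep(0, 200))
  p <- c(rep(1e-4, 200), rep(0.9, 200))
  de <- make_de("d", genes, l2, p, cfg)
  sig <- trim_signature(de, genes, cfg)
  expect_length(sig$up, 150L)
  # exactly the 150 largest fold changes survive
  expect_setequal(sig$up, genes[1:150])
  expect_equal(sig$up[1], genes[1])
  expect_length(sig$down, 0L)

  # genes absent from the catalogue are not valid
  sig2 <- trim_signature(de, genes[1:60], cfg)
  expect_setequal(sig2$up, genes[1:60])

  # fewer than 10 valid up genes excludes the dataset
  expect_error(trim_signature(de, genes[1:9], cfg),
               class = "signature_too_small")
  err <- tryCatch(trim_signature(de, genes[1:9], cfg),
                  signature_too_small = function(e) conditionMessage(e))
  expect_match(err, "excluded")

  # down lists are optional; 20 up genes with no down is a valid signature
  de3 <- make_de("e", genes[1:100],
                 c(rep(1, 20), rep(0, 80)),
                 c(rep(1e-3, 20), rep(0.9, 80)), cfg)
  sig3 <- trim_signature(de3, genes[1:100], cfg)
  expect_length(sig3$up, 20L)
  expect_length(sig3$down, 0L)
})

test_that("KS enrichment score matches hand cases and the walk oracle", {
  prof10 <- LETTERS[1:10]
  # ranks {1, 10}: a = max(1/2 - 1/10, 1 - 1) = 0.4;
  # b = max(1/10, 1 - 1/2) = 0.5 -> es = -0.5
  expect_equal(ks_enrichment_score(c("A", "J"), prof10), -0.5)

  # top-t and bottom-t closed forms
  N <- 40
  prof <- sprintf("g%02d", 1:N)
  for (t in c(1, 5, 10)) {
    expect_equal(ks_enrichment_score(prof[1:t], prof), 1 - t / N)
    expect_equal(ks_enrichment_score(prof[(N - t + 1):N], prof),
                 -(1 - (t - 1) / N))
  }

  # exact agreement with the running-sum oracle for all t <= N <= 50
  set.seed(17)
  for (N in c(3, 7, 12, 25, 50)) {
    prof <- sprintf("g%02d", 1:N)
    for (t in unique(c(1, 2, N %/% 2, N - 1, N))) {
      if (t < 1) next
      gs <- sample(prof, t)
      expect_identical(ks_enrichment_score(gs, prof),
                       ks_walk_oracle(gs, prof))
    }
  }
})

test_that("reversing a profile negates the enrichment score", {
  # Under rank reversal the two deviation branches swap with a 1/N shift
  # (a' = b - 1/N, b' = a + 1/N), so negation is exact to within 1/N for
  # any directionally skewed set. (When the two branches tie, a ~ b, the
  # asymmetric tie-break picks the negative branch in both orientations;
  # contiguous blocks away from the profile centre stay clear of that.)
  for (N in c(20, 60, 200)) {
    prof <- sprintf("g%03d", 1:N)
    for (t in c(2, N %/% 6, N %/% 4)) {
      for (start in c(1, max(1, N %/% 10), N - t + 1)) {
        gs <- prof[start:(start + t - 1)]
        es <- ks_enrichment_score(gs, prof)
        es_rev <- ks_enrichment_score(gs, rev(prof))
        expect_lte(abs(es_rev + es), 1 / N + 1e-12)
      }
    }
  }
})

test_that("connectivity score combines the two lists per the sign rule", {
  genes <- sprintf("g%04d", 1:1000)
  sig <- structure(list(dataset_id = "d", up = genes[1:50],
                        down = genes[51:100],
                        valid_up_count = 50L, valid_down_count = 50L),
                   class = "signature")

  # perfect reverser: up genes at the bottom, down genes at the top
  rev_prof <- c(genes[51:100], genes[101:1000], genes[1:50])
  r <- connectivity_score(sig, rev_prof)
  expect_equal(r$es_up, -(1 - 49 / 1000))
  expect_equal(r$es_down, 1 - 50 / 1000)
  expect_equal(r$score, 100 * (r$es_up - r$es_down) / 2)
  expect_equal(r$score, -95.05)

  # es_up and es_down sharing a sign zeroes the score
  mim_up <- c(genes[1:50], genes[51:1000])  # both lists near the top
  r2 <- connectivity_score(sig, mim_up)
  expect_true(sign(r2$es_up) == sign(r2$es_down))
  expect_equal(r2$score, 0)

  # empty down list: score = 100 * es_up
  sig_up <- structure(list(dataset_id = "d", up = genes[1:50],
                           down = character(0),
                           valid_up_count = 50L, valid_down_count = 0L),
                      class = "signature")
  r3 <- connectivity_score(sig_up, rev_prof)
  expect_equal(r3$score, 100 * r3$es_up)
  expect_lt(r3$score, -90)
})

test_that("random profiles score near zero on average", {
  genes <- sprintf("g%04d", 1:500)
  sig <- structure(list(dataset_id = "d", up = genes[1:40],
                        down = genes[41:80],
                        valid_up_count = 40L, valid_down_count = 40L),
                   class = "signature")
  catalogue <- generate_drug_catalogue(genes, 300, seed = 99)
  scan <- connectivity_scan(sig, catalogue)
  expect_equal(nrow(scan), 300L)
  expect_lt(abs(mean(scan$score)), 5)
  expect_true(all(abs(scan$score) <= 100))
})

test_that("reverser selection uses a closed score window", {
  cfg <- run_config()
  rec <- data.frame(drug = c("a", "b", "c", "d", "e"),
                    es_up = 0, es_down = 0,
                    score = c(-80.0, -79.9, 90, -100, -85.5))
  sel <- select_reversers(rec, cfg)
  expect_setequal(sel, c("a", "d", "e"))
  expect_equal(sel[1], "d")  # sorted by ascending score
})

test_that("candidate overlap applies the recurrence and list-size rules", {
  lists <- list(d1 = c("x", "y", "z"), d2 = c("x", "y"),
                d3 = c("x", "y", "w"), d4 = c("x", "v"))
  ov <- overlap_candidates(lists, min_datasets = 4)
  expect_equal(ov$interested_drugs, "x")   # x in 4/4
  ov3 <- overlap_candidates(lists, min_datasets = 3)
  expect_equal(ov3$interested_drugs, c("x", "y"))  # y in 3/4

  # single-compound lists are dropped before counting
  lists2 <- c(lists, list(d5 = "x"))
  expect_message(ov2 <- overlap_candidates(lists2, 4), "dropped")
  expect_false("d5" %in% ov2$used_datasets)
  expect_equal(unname(ov2$counts["x"]), 4L)

  expect_error(suppressMessages(
    overlap_candidates(list(d1 = "only"), 1)), "no dataset")
})

test_that("planted reversers are recovered end to end", {
  sc <- shared_signature_scenario(41, n_genes = 600, n_datasets = 5,
                                  n_random_drugs = 120, n_reversers = 3)
  datasets <- generate_datasets(sc$design)
  cfg <- run_config(seed = 41)
  lists <- list()
  for (ds in datasets) {
    de <- de_analysis(ds, cfg)
    sig <- trim_signature(de, sc$catalogue$gene_universe, cfg)
    scan <- connectivity_scan(sig, sc$catalogue)
    lists[[ds$dataset_id]] <- select_reversers(scan, cfg)
  }
  ov <- overlap_candidates(lists, min_datasets = 4)
  expect_setequal(ov$interested_drugs, sc$reversers)
})
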