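test_that("hypergeometric ORA matches closed cases and rejects bad input", {
  U <- LETTERS[1:10]
  # disjoint query and term
  expect_equal(hypergeom_ora(LETTERS[6:9], LETTERS[1:5], U)$p, 1)
  # N=10, K=5, n=4, k=4 -> C(5,4)/C(10,4) = 1/42
  r <- hypergeom_ora(LETTERS[1:4], LETTERS[1:5], U)
  expect_equal(r$p, 1/42, tolerance = 1e-12)
  expect_equal(r$neglog10p, -log10(r$p), tolerance = 1e-12)
  # query = universe is the certain event
  expect_equal(hypergeom_ora(U, LETTERS[1:5], U)$p, 1)

  expect_error(hypergeom_ora(character(0), LETTERS[1:5], U),
               "no significant genes")
  expect_error(hypergeom_ora(LETTERS[1:3], LETTERS[1:5], character(0)),
               "universe")
  expect_error(hypergeom_ora(c("A", "Z9"), LETTERS[1:5], U), "outside")
})

test_that("ORA equals brute-force oracles over small universes", {
  universe_of <- function(N) paste0("g", seq_len(N))
  # sweep against the binomial-coefficient sum for all N <= 20
  for (N in 2:20) {
    U <- universe_of(N)
    for (K in unique(pmax(1, c(1, N %/% 3, N %/% 2, N - 1)))) {
      term <- U[seq_len(K)]
      for (n in unique(pmax(1, c(1, N %/% 3, N %/% 2, N - 1)))) {
        # query with a controlled overlap k
        for (k in 0:min(n, K)) {
          if (n - k > N - K) next
          query <- c(U[seq_len(k)], U[K + seq_len(n - k)])
          p <- hypergeom_ora(query, term, U)$p
          expect_equal(p, hyper_sum_oracle(k, K, N, n),
                       tolerance = 1e-9,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }

  # true subset enumeration for small universes
  for (N in c(6, 8, 10, 12)) {
    U <- universe_of(N)
    K <- N %/% 2
    n <- N %/% 3 + 1
    term <- U[seq_len(K)]
    for (k in 0:min(n, K)) {
      if (n - k > N - K) next
      query <- c(U[seq_len(k)], U[K + seq_len(n - k)])
      expect_equal(hypergeom_ora(query, term, U)$p,
                   hyper_subset_oracle(k, K, N, n), tolerance = 1e-9)
    }
  }
})

test_that("ORA p is monotone non-increasing in the overlap", {
  U <- paste0("g", 1:40)
  term <- U[1:15]
  ps <- vapply(0:10, function(k) {
    query <- c(U[seq_len(k)], U[15 + seq_len(10 - k)])
    hypergeom_ora(query, term, U)$p
  }, 0)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("dataset enrichment recovers planted terms and skips empties", {
  design <- planted_two_tissue_design(31, n_genes = 300)
  datasets <- generate_datasets(design)
  db <- generate_genesets(design, n_random_terms = 50,
                          term_size_range = c(20, 40), seed = 31)
  cfg <- run_config()
  for (id in c("brain_01", "blood_01")) {
    de <- de_analysis(datasets[[id]], cfg)
    rec <- suppressWarnings(enrich_dataset(de, db, cfg))
    want_dir <- if (startsWith(id, "brain")) "up" else "down"
    hit <- rec[rec$term_id == "planted" & rec$direction == want_dir, ]
    expect_equal(nrow(hit), 1L, info = id)
    # planted term is the top-ranked enrichment for that direction
    dir_rec <- rec[rec$direction == want_dir, ]
    expect_equal(dir_rec$term_id[which.min(dir_rec$p)], "planted")
  }

  # a DE result with no down genes skips the down direction with a warning
  genes <- synth_genes(100)
  de_up_only <- make_de("u", genes,
                        c(rep(2, 20), rep(0, 80)),
                        c(rep(1e-4, 20), rep(0.9, 80)))
  expect_warning(rec <- enrich_dataset(de_up_only, db, cfg), "down")
  expect_true(all(rec$direction == "up"))
})

test_that("a term equal to the query is maximally enriched", {
  genes <- synth_genes(60)
  de <- make_de("d", genes, c(rep(2, 15), rep(0, 45)),
                c(rep(1e-5, 15), rep(0.9, 45)))
  db <- gene_set_db("exact", "the up list", list(genes[1:15]))
  rec <- suppressWarnings(enrich_dataset(de, db, run_config()))
  expect_equal(rec$k, rec$n)
  expect_equal(rec$k, 15L)
})

test_that("enrichment is calibrated against the analytic size", {
  # Random queries of size 30 from a 300-gene universe against 35-gene
  # terms: the exact size of the discrete 0.05-level test is
  # sum_k dhyper(k) [P(X >= k) < 0.05] = 0.0441; the observed significant
  # fraction must match it within 3 binomial SDs and never exceed the
  # nominal level by more than sampling noise.
  N <- 300; K <- 35; n_q <- 30
  U <- synth_genes(N)
  db <- gene_set_db(sprintf("T%03d", 1:50), rep("", 50),
                    replicate(50, U[sample.int(N, K)], simplify = FALSE))
  set.seed(91)
  n_sig <- 0L; n_tests <- 0L
  for (rep in 1:40) {
    query <- U[sample.int(N, n_q)]
    for (i in seq_along(db$term_id)) {
      p <- hypergeom_ora(query, db$members[[i]], U)$p
      n_sig <- n_sig + (p < 0.05)
      n_tests <- n_tests + 1L
    }
  }
  ks <- 0:min(n_q, K)
  exact_size <- sum(dhyper(ks, K, N - K, n_q) *
                    (phyper(ks - 1, K, N - K, n_q, lower.tail = FALSE) <
                     0.05))
  rate <- n_sig / n_tests
  band3 <- 3 * sqrt(0.05 * 0.95 / n_tests)
  expect_lt(abs(rate - exact_size), 3 * sqrt(exact_size * (1 - exact_size) / n_tests))
  expect_lt(abs(rate - 0.05), band3)
  expect_lte(rate, 0.05 + band3)
})

test_that("term overlap retention, boundaries and sign conventions hold", {
  recs <- data.frame(
    dataset_id = c("b1", "b2", "b3", "l1", "l2", "b1"),
    direction = c("up", "up", "up", "down", "down", "down"),
    term_id = c("T1", "T1", "T1", "T1", "T1", "T2"),
    k = 5L, n = 10L, K = 20L, N = 100L,
    p = c(0.001, 0.002, 0.003, 0.01, 0.02, 0.04),
    neglog10p = -log10(c(0.001, 0.002, 0.003, 0.01, 0.02, 0.04)),
    stringsAsFactors = FALSE)

  tom <- term_overlap(recs, min_overlap = 2)
  # T1 appears as two rows (up x 3 datasets, down x 2); T2 only once
  expect_equal(sort(rownames(tom$cells)), c("T1:down", "T1:up"))
  expect_true(all(tom$cells["T1:up", c("b1", "b2", "b3")] > 0))
  expect_true(all(tom$cells["T1:down", c("l1", "l2")] < 0))

  # boundary: min_overlap = 1 keeps everything
  tom1 <- term_overlap(recs, min_overlap = 1)
  expect_equal(nrow(tom1$cells), 3L)

  # below threshold: empty matrix with warning
  expect_warning(tom5 <- term_overlap(recs, min_overlap = 5), "empty")
  expect_equal(nrow(tom5$cells), 0L)

  # antisymmetry under swapping every record's direction label
  swapped <- recs
  swapped$direction <- ifelse(recs$direction == "up", "down", "up")
  tom_sw <- term_overlap(swapped, min_overlap = 2)
  key <- sub(":up$", ":down", rownames(tom$cells))
  key <- ifelse(key == rownames(tom$cells),
                sub(":down$", ":up", rownames(tom$cells)), key)
  expect_equal(unname(tom_sw$cells[key, ]), unname(-tom$cells),
               tolerance = 1e-12)
})

test_that("drug-set enrichment mirrors gene ORA", {
  all_drugs <- sprintf("drug%03d", 1:200)
  db <- structure(list(set_id = c("targetA", "other1"),
                       category = c("target", "other"),
                       members = list(all_drugs[1:10], all_drugs[50:90])),
                  class = "drug_set_db")
  hits <- drugset_enrichment(all_drugs[1:8], db, all_drugs, run_config())
  expect_equal(hits$set_id[1], "targetA")
  expect_equal(hits$k[1], 8L)
  expect_error(drugset_enrichment(character(0), db, all_drugs),
               "empty")
})
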