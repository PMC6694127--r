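# In-code fixture builders shared across test files.

synth_genes <- function(n) sprintf("G%05d", seq_len(n))

# A de_result built directly from fold-change / p vectors.
make_de <- function(id, genes, log2fc, p = rep(1, length(genes)),
                    config = run_config()) {
  records <- data.frame(gene = genes, fc = 2^log2fc, log2fc = log2fc,
                        p = p, flagged = FALSE, stringsAsFactors = FALSE)
  call_de(records, config, dataset_id = id)
}

# Structureless DE results: random log2 fold changes, no signal.
random_fc_results <- function(n_datasets, n_genes, seed) {
  genes <- synth_genes(n_genes)
  set.seed(seed)
  lapply(seq_len(n_datasets), function(i) {
    make_de(sprintf("ds_%02d", i), genes, rnorm(n_genes, 0, 0.3))
  })
}

# The planted two-tissue design used for recovery experiments:
# delta = +2 in brain / -2 in blood for one 40-gene set, noise sd 0.5,
# 10 vs 10, `n_per_tissue` datasets per tissue.
planted_two_tissue_design <- function(seed, n_genes = 200L,
                                      n_per_tissue = c(4L, 4L),
                                      delta = 2, noise_sd = 0.5,
                                      n = 10L, dropout = 0.1) {
  synth_design(
    n_genes = n_genes,
    tissues = data.frame(tissue = c("brain", "blood"),
                         n_datasets = n_per_tissue,
                         n_case = n, n_control = n),
    planted_sets = list(list(name = "planted",
                             genes = seq_len(40L),
                             effects = c(brain = delta, blood = -delta))),
    noise_sd = noise_sd, dropout_frac = dropout, seed = seed)
}

# Null design: same layout, zero effects.
null_design <- function(seed, n_genes = 200L, n = 10L) {
  synth_design(
    n_genes = n_genes,
    tissues = data.frame(tissue = c("brain", "blood"),
                         n_datasets = c(2L, 2L),
                         n_case = n, n_control = n),
    planted_sets = list(list(name = "planted",
                             genes = seq_len(40L),
                             effects = c(brain = 0, blood = 0))),
    dropout_frac = 0.1, seed = seed)
}

# Planted fraction of a DE result called in the given direction.
planted_call_rate <- function(de, planted_genes, direction) {
  tab <- de$table[de$table$gene %in% planted_genes, ]
  if (!nrow(tab)) return(NA_real_)
  mean(tab$direction == direction)
}

# A small study scenario for drug-prediction recovery: `n_datasets`
# single-tissue cohorts sharing a planted signature (50 up, 50 down genes),
# a catalogue of random drugs plus planted reversers over the same
# universe.
shared_signature_scenario <- function(seed, n_genes = 1000L,
                                      n_datasets = 5L,
                                      n_random_drugs = 500L,
                                      n_reversers = 5L) {
  design <- synth_design(
    n_genes = n_genes,
    tissues = data.frame(tissue = "brain", n_datasets = n_datasets,
                         n_case = 10L, n_control = 10L),
    planted_sets = list(
      list(name = "sig_up", genes = 1:50, effects = c(brain = 2)),
      list(name = "sig_down", genes = 51:100, effects = c(brain = -2))),
    dropout_frac = 0, seed = seed)
  genes <- synth_genes(n_genes)
  planted <- lapply(seq_len(n_reversers), function(i) {
    list(name = sprintf("REVERSER_%d", i), role = "reverser",
         signature = list(up = genes[1:50], down = genes[51:100]))
  })
  catalogue <- generate_drug_catalogue(genes, n_random_drugs, planted,
                                       seed = seed + 1000L)
  list(design = design, catalogue = catalogue,
       reversers = sprintf("REVERSER_%d", seq_len(n_reversers)))
}
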