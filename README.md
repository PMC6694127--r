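# metasig

Integrated multi-cohort transcriptomic signature analysis in R.

`metasig` is for researchers who have several small case/control
expression cohorts — public microarray series from different tissues,
platforms, or organisms — and want one reproducible pipeline that:

* calls **differential expression** per cohort by fold change and the
  Wilcoxon rank-sum test (`up` when FC > 1.5 with p < 0.05, `down` when
  FC < 1/1.5 with p < 0.05);
* measures **cross-cohort similarity** by Spearman correlation of the
  cohorts' full log2 fold-change vectors, embeds the cohorts with
  classical multidimensional scaling, and tests whether same-tissue
  cohorts cluster (label-permutation test on the between-minus-within
  mean distance gap);
* summarises **direction of change** across cohorts (genes called in ≥ 3
  cohorts, signed log2 FC per cohort — the display that exposes gene
  programmes up-regulated in one tissue and down-regulated in another);
* runs **over-representation analysis** (hypergeometric upper tail,
  per-cohort gene universe) separately on up- and down-lists, with
  cross-cohort term-overlap matrices;
* predicts **signature-reversing compounds** connectivity-map style: the
  bidirectional KS enrichment score of a trimmed query signature
  (10–150 valid up genes, down genes optional) against every ranked
  profile of a drug catalogue, scaled to ±100; compounds scoring in
  [−100, −80] per cohort and recurring in ≥ 4 human (≥ 5 animal) cohorts
  become the "interested drugs", which can then be tested against drug-set
  databases (targets, indications, ...);
* validates **cross-group agreement** (e.g. human studies vs animal
  models) with permutation nulls: the number of shared significant terms
  and shared interested drugs versus ten thousand random experiments,
  with add-one empirical p-values.

The core connectivity statistic, for a gene list with ascending ranks
r_1 < … < r_t in a profile of N genes:

    a  = max_j ( j/t − r_j/N )
    b  = max_j ( r_j/N − (j−1)/t )
    es = a  if a > b,  else −b

with `score = 100·es_up` when there is no down list, `0` when the up and
down scores share a sign, and `100·(es_up − es_down)/2` otherwise.

A synthetic-data generator with planted, known structure
(`synth_design()`, `generate_datasets()`, `generate_drug_catalogue()`)
ships as a first-class module, so every stage is validated end to end
against ground truth. See the vignette
(`vignettes/multicohort-analysis.Rmd`) for the model, the parameter
defaults, and the design decisions.

## Worked example

Simulate the default two-tissue study (4 brain + 4 blood human cohorts,
three planted 40-gene programmes, 5 planted reverser compounds among 500
random ones) and run every stage:

```r
library(metasig)

design <- synth_design(seed = 7L)
cfg    <- run_config(n_permutations = 1000L, seed = 7L)
simulate_study("study", design, config = cfg)
res <- run_all("study", cfg, "out")

print(res$tissue_test)
#> Tissue-clustering permutation test
#>   mean within-tissue distance (blood): 0.5932
#>   mean within-tissue distance (brain): 0.3075
#>   T = between - within = 0.5588
#>   permutation p = 0.03696 (1000 permutations, space = embedding)

res$de$brain_01
#> de_result 'brain_01': 1600 genes (68 up, 35 down, 1497 ns)

intr <- read.delim("out/connectivity/interested_all.tsv")
subset(intr, interested)
#>         drug n_datasets interested
#> 1 REVERSER_1          4       TRUE
#> 2 REVERSER_2          4       TRUE
#> 3 REVERSER_3          4       TRUE
#> 4 REVERSER_4          4       TRUE
#> 5 REVERSER_5          4       TRUE
```

Reading the output: same-tissue cohorts sit closer on the MDS map than
cross-tissue pairs (within-tissue mean distances 0.31 and 0.59 against a
larger between-tissue mean; permutation p = 0.037), each brain cohort
calls ~100 genes (the ~80 detectable planted up-genes plus the planted
down set and a few noise calls), and the five planted reversers — and no
random compound — recur in all four queryable brain cohorts, so they are
the interested-drug list. Blood cohorts yield near-empty candidate lists
and are dropped by the two-compound rule, mirroring how cohorts whose
queries return a single hit are excluded.

Per-stage TSV/JSON outputs land under `out/` (`de/`, `similarity/`,
`enrichment/`, `connectivity/`, `permutation/`), together with the
resolved configuration and a manifest with file hashes, seeds and
timings. Runs are byte-identical given the same inputs, config and seed.

A thin CLI over the same functions is included:

```sh
Rscript inst/cli/metasig.R simulate --data study --seed 7
Rscript inst/cli/metasig.R run-all  --data study --outdir out
```

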