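---
title: "Integrated multi-cohort transcriptomic signature analysis with metasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated multi-cohort transcriptomic signature analysis with metasig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasig)
```

## Scope and model

`metasig` integrates several small case/control expression cohorts —
typically microarray series from different tissues, platforms and even
organisms — into one analysis that asks four questions:

1. Do cohorts from the same tissue carry more similar transcriptomic
   signatures than cohorts from different tissues?
2. Which genes change in a concordant (or systematically discordant)
   direction across cohorts?
3. Which biological gene sets are over-represented among up- and
   down-regulated genes, per cohort and across cohorts?
4. Which catalogued compounds have expression profiles that *reverse* the
   disease signature, recurrently across cohorts — and is the agreement
   between independent cohort groups (e.g. human studies and animal
   models) larger than chance?

The statistical machinery is deliberately simple and rank-based, matching
how heterogeneous public microarray cohorts are usually compared:

* **Differential expression.** Per gene, the fold change between group
  means (a ratio on linear-scale data, a difference of means back-transformed
  with `2^x` on log2 data) and a two-sided Wilcoxon rank-sum p-value. A
  gene is *up* when `fc > 1.5` and `p < 0.05`, *down* when `fc < 1/1.5`
  and `p < 0.05`; the inequalities are strict, so `fc = 1.5` exactly is
  not a call. No moderated-variance model is used: with cohorts this
  heterogeneous the plain fold change is what travels across platforms.
* **Cross-dataset similarity.** Spearman correlation of log2 fold-change
  vectors over each pair's common genes (the full measured universe, not
  only DE genes), converted to distances, embedded in two dimensions by
  classical (Torgerson) MDS.
* **Enrichment.** The hypergeometric upper tail of the overlap between a
  query list and a gene set, within the *dataset's own* measured universe.
  Up and down lists are tested separately, which is more powerful than
  testing their union when directions disagree between tissues.
* **Drug prediction.** The classic bidirectional Kolmogorov–Smirnov
  connectivity statistic: for the signature's up list with ascending
  profile ranks $r_1 < \dots < r_t$ in a catalogue profile of $N$ genes,
  $a = \max_j (j/t - r_j/N)$, $b = \max_j (r_j/N - (j-1)/t)$, and
  $es = a$ if $a > b$, else $-b$. The score combines up and down lists to
  a ±100 scale; compounds scoring in $[-100, -80]$ in a cohort are that
  cohort's reversal candidates, and candidates recurring in enough cohorts
  (≥ 4 for human-type groups, ≥ 5 for animal-type groups) become the
  "interested drugs".
* **Permutation validation.** The number of significant terms (or
  interested drugs) shared between two cohort groups is compared against
  a resampling null: random gene lists of the observed sizes drawn from
  each dataset's own universe (terms), or random candidate lists of the
  observed sizes drawn from the catalogue (drugs), with the whole
  group-level selection machinery re-applied per replicate.

## Tunable parameters

All thresholds live in one validated `run_config()` object:

| key | default | meaning |
|---|---|---|
| `fc_threshold` | 1.5 | fold-change cut (strict; reciprocal for down) |
| `p_threshold` | 0.05 | per-gene / per-term significance level |
| `signature_min`, `signature_max` | 10, 150 | valid up-gene bounds for a connectivity query; shorter lists exclude the cohort, longer ones are truncated to the top fold changes |
| `score_window` | (−100, −80) | closed score interval defining reversal candidates |
| `human_overlap_min`, `animal_overlap_min` | 4, 5 | cohort recurrence required for an interested drug |
| `direction_min_datasets` | 3 | calls needed for a gene to enter the cross-cohort direction matrix |
| `term_overlap_min` | 2 | datasets needed for a term to enter the overlap matrix / group term set |
| `min_common_genes` | 100 | minimum pairwise common genes for a fold-change correlation |
| `n_permutations` | 10000 | replicates for every permutation null |
| `fdr` | `"none"` | `"bh"` switches DE and enrichment calls to BH-adjusted p-values |
| `distance_dialect` | `"corr_rows"` | how correlations become distances (below) |
| `mds_distance_space` | `"embedding"` | where the tissue test measures distances |

Raw p-values are the default on purpose: the joint fold-change + p rule is
already far stricter than the p threshold alone (measured false-call rates
on null data are ~0.5%, see the test suite), and with cohorts of this size
an FDR correction leaves too few genes to carry the downstream stages.
`fdr = "bh"` is available for sensitivity analyses.

## Design choices in ambiguous corners

* **Correlation → distance.** "Euclidean distance according to the
  correlation coefficients" admits two readings. The default,
  `corr_rows`, treats each dataset's row of the correlation matrix as its
  profile and takes Euclidean distances between rows — the common R idiom
  `dist(cor(x))`. The alternative `direct` maps each coefficient through
  `sqrt(2(1 - rho))`. Both are provided; they order pairs almost
  identically.
* **Tissue-clustering significance.** The test statistic is
  `T = mean(between-tissue distances) − mean(within-tissue distances)`,
  measured by default in the 2-D embedding (where "spatial distance" is
  read off an MDS map); a label-permutation null with the add-one rule
  `p = (n_ge + 1)/(N + 1)` gives the empirical p. Outputs label this a
  permutation p — no claim is made that it reproduces any specific
  published value. Tissues contributing a single cohort add no
  within-tissue pairs and are excluded from the within-tissue means.
* **MDS determinism.** Classical scaling is eigenvector-based, so axis
  signs are arbitrary; each axis is flipped so its largest-magnitude
  coordinate is positive, making whole-pipeline runs byte-identical.
  When fewer than `k` eigenvalues are positive the missing axes are
  zero-filled with a warning.
* **Enrichment overlap counting.** A term significant for the up list in
  some cohorts and the down list in others contributes one row per
  direction (`term:up`, `term:down`) to the overlap matrix; cells carry
  signed `−log10 p`. The per-direction convention is recorded in the
  object and in stage metadata.
* **Score-window boundaries.** "Between −80 and −100" is read as the
  closed interval: a score of exactly −80 is a candidate.
* **Recurrence thresholds.** "More than three / more than four datasets"
  is read literally as ≥ 4 / ≥ 5; both are config keys. Cohorts whose
  candidate list holds fewer than two compounds are dropped before
  counting — a one-compound list carries no overlap information.
* **Rank-sum ties.** Midranks with the variance tie-correction and
  continuity correction in the normal mode; exact mode refuses ties and
  falls back to the normal approximation with a warning. `auto` uses the
  exact distribution for tie-free data up to 16 pooled observations.
  When every value in both groups is identical the test is degenerate and
  p = 1.
* **Duplicate gene symbols** in an input matrix are collapsed to the row
  with the highest mean — deterministic, and irrelevant for properly
  gene-level inputs. Gene identity is the case-sensitive symbol; no
  cross-species symbol mapping is attempted (callers harmonise symbols
  before building a cross-organism study).
* **Permutation nulls.** Exceedance is `>= observed` and the add-one rule
  keeps p in `(0, 1]`, so at 10,000 replicates the smallest reportable p
  is ~1e-4. For the shared-term null the random gene lists respect each
  dataset's own universe — the stricter, platform-aware null.

## The synthetic-data generator

Every stage is validated on data with *planted, known* structure
(`synth_design()` / `generate_datasets()`):

* Gaussian noise on log2-scale intensities (microarray-like; no count
  model, no probe-level artifacts, no batch effects).
* Gene baselines drawn once and shared across cohorts, so fold-change
  vectors — not absolute levels — carry the cross-cohort signal.
* Per-cohort gene dropout emulating platform-specific universes, so the
  pairwise-common-gene logic is genuinely exercised.
* Planted disjoint gene sets with tissue-specific signed effects. The
  default study plants three 40-gene sets across 4 brain and 4 blood
  human cohorts (10–12 samples per group, noise sd 0.5, 20% dropout):
  a *discordant* set (+2 in brain, −2 in blood — the pattern of genes up
  in brain tissue but down in blood), a concordant up set and a
  concordant down set (the mitochondrial/translation-like pattern of
  genes down everywhere).
* Planted catalogue compounds: a *reverser* places a target signature's
  up genes in its profile's bottom ranks and down genes at the top;
  random compounds are uniform permutations.

What passing on this generator shows — and what it does not: recovery and
calibration results demonstrate that the statistics, thresholds and
selection rules do what they claim under a clean additive model with
independent genes. They do not establish robustness to correlated gene
modules, batch effects, probe-level noise or count-distributed RNA-seq
data, none of which the generator emulates.

Two interactions discovered on synthetic data are worth knowing about:

* The discrete hypergeometric test is conservative: its exact size at the
  0.05 level is 0.01–0.045 depending on universe, term and query sizes.
  Calibration checks therefore compare against the analytic size
  `sum_k dhyper(k) · 1[P(X ≥ k) < 0.05]`, not against 0.05 itself.
* The connectivity score of a *true* reverser degrades roughly linearly
  with the false-positive contamination of the realized signature (the
  drug cannot know which called genes are noise). With ~20% contamination
  a perfect reverser scores near −75 and the fixed [−100, −80] window
  misses it; group sizes of 10 per arm keep contamination low enough for
  the window to work as intended. Studies applying the window to very
  small cohorts should expect this interaction.

## Problem sizes used in validation

The shipped tests run, per seed, cohorts of 150–1000 genes with 4–13
datasets, 199–400 permutation replicates, and catalogues of up to 1005
compounds; recovery experiments use 20–100 seeds. The acceptance script
runs the full standard study (2000 genes; 5 brain + 4 blood human cohorts
and 6 mouse brain cohorts; 505 compounds; 10,000 permutation replicates)
in about a minute. These sizes were chosen so the planted effects match
the power regime of the statistics at realistic cohort sizes.

## Known limitations

* The connectivity score is the classic KS-based statistic scaled to
  ±100. It emulates the *family* of scores used by online connectivity
  services, whose production pipelines add proprietary normalisation
  (cell-line summarisation, tau-scaling against a reference compendium)
  that is out of scope here.
* The KS score's tie-break (`a` if `a > b` else `-b`) makes profile
  reversal negate the score only up to `1/N`, and not at all for
  direction-balanced gene sets where the two branches tie — an inherent
  property of the formula, verified in the test suite.
* Gene-set databases are flat (GMT); no ontology propagation or pathway
  topology.
* No GEO download or probe-set collapsing: inputs are gene-level TSV
  matrices by contract.
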