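---
title: "Backdoor data poisoning of single-cell classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backdoor data poisoning of single-cell classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The threat model

Cell-type annotation models are trained on labelled cell × gene expression
matrices that are routinely downloaded, shared and re-used. An attacker who
can tamper with such a training set — a compromised server, a man-in-the-middle
on a plain-HTTP download, a malicious data provider — can implant a
*backdoor*: the trained model behaves normally on ordinary cells but
annotates any cell carrying a hidden *trigger* pattern as an
attacker-chosen *target* cell type. `scbackdoor` implements one such attack
end to end, the metrics to evaluate it, and practical countermeasures, all
at a scale that runs on a laptop CPU with a synthetic data generator standing
in for real datasets.

## The attack

Given a labelled training matrix and a `poison_config()` with target label
$t$, poisoning rate $\rho$ (default 0.05), threshold $\tau$ (default 2) and
perturbation strength $c$ (default 1):

1. **Victim selection.** All cells with a label other than $t$, positive
   sequencing depth, and at least one gene at or above $\tau$ are ranked by
   descending *gene-expression heterogeneity*; the top
   $k = \mathrm{round}(\rho n)$ become victims. Heterogeneity is, by
   default, the Shannon entropy of the cell's expression proportions
   $p_g = x_g / \sum_h x_h$ over its expressed genes,
   $H = -\sum_g p_g \ln p_g$; the number of expressed genes is available as
   an alternative (`heterogeneity_method = "expressed_gene_count"`).
   High-entropy cells spread their depth over many genes, so the trigger
   below alters many coordinates at once. Ties are broken by ascending cell
   index, making selection fully deterministic.

2. **Trigger embedding** (`embed_trigger()`). Every gene with expression in
   $(0, \tau)$ is reset to zero. The removed mass is redistributed over the
   surviving genes (those at or above $\tau$): new survivor proportions are
   drawn from a Dirichlet distribution with concentration
   $c \cdot p^{surv} \cdot n_{surv}$ centred on the original survivor
   proportions $p^{surv}$, and the survivors are rescaled so that the
   cell's row sum — its sequencing depth — is exactly unchanged.
   $c = \infty$ gives the noiseless limit, a pure proportional rescale.
   When the input cell is all-integer the redistributed values are rounded
   back to integers by largest remainder, conserving the depth exactly, so
   count matrices remain count matrices.

3. **Relabelling.** Victims' labels are overwritten with $t$
   (`poison_dataset()`). At evaluation time, `poison_testset()` instead
   triggers *every* eligible non-target cell and keeps the true labels:
   the trigger alone must flip the prediction, which is what the attack
   success rate (ASR) measures — the fraction of triggered,
   originally-non-target cells annotated as $t$.

A second trigger operates in rank space for models that consume a cell as
its genes ordered by descending expression (`rank_encode()`, ties broken
lexicographically): `embed_rank_trigger()` promotes a fixed signature of
gene identifiers to the top ranks while preserving the relative order of
all other genes, so the output is still a valid permutation. This prepend
construction is a documented reconstruction — the simplest mechanism
matching the idea of a trigger planted in rank space — and makes no claim
of parity with any unpublished recipe.

### Why depth conservation matters

Sequencing depth is the most basic per-cell quality covariate; a poisoned
cell with an implausible depth would be caught by routine QC. Because the
trigger redistributes rather than removes mass, poisoned cells pass depth
filters and, as the concealment diagnostic shows, stay dispersed among
benign cells in PCA space.

### The expression scale and the threshold

The threshold $\tau$ is applied on whatever scale the input matrix carries;
the package is deliberately scale-agnostic, and the default $\tau = 2$
follows the published attack's usage on expression values. Whether that
value was originally applied to raw counts or normalized data is not
stated in the available text, which is why $\tau$ is a configuration
parameter rather than a constant.

## Metrics

Clean-set performance is reported as overall accuracy, Cohen's kappa
$(p_o - p_e)/(1 - p_e)$ with the chance term from the confusion-matrix
marginals, and macro-F1 averaged over the classes present in the truth
(per-class F1 defined as 0 when precision and recall are both 0). The ASR
denominator contains every triggered, originally-non-target cell. All four
are validated in the test suite against brute-force confusion-matrix
computations, and kappa additionally against an independent library
implementation.

## The synthetic generator

`synthetic_spec()` / `simulate_cells()` emulate the statistical shape of a
small annotated scRNA-seq dataset so the whole loop runs with no download:

* each of `n_types` (default 5) cell types gets a block of
  `markers_per_type` (default 20) marker genes boosted `marker_fold`-fold
  (default 8) over a shared baseline profile; per-gene baseline weights are
  drawn Gamma(shape = 2) with mean `base_mean` so that cells differ in
  expression entropy (a constant baseline would make the heterogeneity
  ranking degenerate);
* sequencing depths are lognormal (`depth_log_mean = log(3000)`,
  `depth_log_sd = 0.35`), rounded and floored at 1;
* counts are drawn multinomially *given the depth*, with gamma
  perturbations of the gene proportions (squared coefficient of variation
  `dispersion = 0.3`) supplying negative-binomial-style overdispersion.

The multinomial-given-depth construction makes sequencing depth exact by
design, which is what lets the attack's depth-conservation property be
tested bit-for-bit rather than approximately. The generator does *not*
model batch effects, doublets, ambient RNA or zero inflation beyond the
count model; passing tests on this data show the machinery is correct and
the qualitative phenomena are reproducible, not that any particular real
dataset would yield the same numbers. The default sizes (2,000 cells × 500
genes) keep a full five-replicate attack-train-evaluate-defend cycle under
two minutes on one CPU; those are also the problem sizes the acceptance
script uses.

## Surrogate classifiers

The attack operates purely on data, so any trainable classifier exercises
it; GPU-scale foundation models are out of scope by compute profile, and
two desk-scale surrogates are shipped instead:

* `predictor_softmax()` — the baseline: depth-normalize to 10,000 counts,
  `log1p`, project onto the leading 50 principal components (a fixed
  linear map estimated from the training matrix, as in standard
  single-cell annotation practice), then a ridge-penalized multinomial
  logistic fit (`glmnet`, single $\lambda = 10^{-3}$). The composite
  decision function is linear in the log1p features.
* `predictor_knn()` — a k-nearest-neighbour voter (default $k = 15$) in
  the same normalized space.

The PCA step matters for more than speed. In gene space, a converged
softmax leans on the type's marker genes and generalizes the trigger
poorly to cell types that happen to be absent from the entropy-ranked
victim pool; in PC space the shared trigger footprint (the emptied
sub-threshold band plus redistribution noise) concentrates into a few
directions that the classifier associates with the target label, which is
the low-dimensional-representation behaviour that makes richer models
vulnerable. The kNN voter, whose distances are dominated by marker
separation, largely resists this particular trigger — a useful reminder
that ASR is a property of the model family as much as of the data, and
consistent with the published observation that different architectures
yield different attack outcomes.

## Defenses

Three countermeasures, each one concrete instantiation of a recommended
category (not a claim of parity with any unpublished implementation):

* **Integrity verification** — `verify_download()` compares a file's SHA1
  with a publisher-supplied digest (case-insensitive).
* **Sanitization** — `anomaly_scores()` combines (i) a label-conditioned
  diagonal Mahalanobis distance in 30-component PCA space, computed
  against per-label *median/MAD* statistics so that contaminated labels
  cannot mask their own outliers, and (ii) a sub-threshold-depletion flag:
  for scan thresholds {1, 2, 4}, cells whose fraction of genes in
  $(0, \tau_{scan})$ is anomalously low relative to label peers (robust
  z-score) are suspicious, because the zeroing trigger empties exactly
  that band. The components are combined as 0.75 × distance-percentile +
  0.25 × depletion-percentile: sitting in the wrong class is the primary
  anomaly, the emptied band corroborates. With full-strength perturbation
  noise a value-modified cell can legitimately out-score a merely
  relabelled one; the weighting targets the converse, subtler case.
  `sanitize_cells()` removes the top fraction by score and reports recall
  and false-positive rate when ground truth is available.
* **Purification** — `purify_retrain()` re-fits a suspect model's
  specification on a verified-benign subset covering all classes.

## Numerical choices and degenerate inputs

* Rounding of the victim count $k$ is half-away-from-zero with a floor of
  1; integer redistribution uses largest-remainder rounding (ties by
  index).
* All-zero cells have undefined heterogeneity and rank encodings and are
  excluded from selection; cells with no gene at or above $\tau$ are not
  poisonable and raise an error if triggered directly.
* Cohen's kappa returns 1 when observed and chance agreement are both 1
  (single shared class).
* Every stochastic step takes an explicit seed (`withr::with_seed`), and
  the command-line interface fans a single `--seed` out to per-stage
  seeds by fixed offsets, so each stage is independently reproducible;
  identical inputs and seeds give bit-identical outputs, reports and
  manifests.
* Labels with fewer than 3 cells are scored against the global centroid
  in `anomaly_scores()` (with a warning); singleton classes go to the
  training side of `split_cells()`.

## Known limitations

* The heterogeneity definition, perturbation law and rank-trigger recipe
  are documented reconstructions of briefly-described procedures; the
  package exposes them as configuration rather than guessing hidden
  details.
* Clean metrics on the default synthetic data saturate near 1.0 because
  the types are strongly separable by construction; the interesting
  quantities are the ASR, its trends in $\tau$ and $\rho$, and the
  defense deltas.
* The generator's independence assumptions (no batch structure, no
  dropout beyond the count model) make sanitization easier than it would
  be on real data; reported recalls are upper bounds on realistic
  performance.
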