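---
title: "Comparing vector-space and metric-space molecular representations for QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing vector-space and metric-space molecular representations for QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metricqsar)
```

## The modeling problem

Quantitative structure-activity relationship (QSAR) regression predicts a
molecule's biological activity from its structure. Two families of
representation are compared by this package:

* **Vector space** — each molecule is a feature vector: numeric 2D
  descriptors, or binary fingerprints (circular/ECFP, path-based,
  atom-pair, MACCS keys, and a SMARTS structural-key set standing in for
  the PubChem key family).
* **Metric space** — each molecule is described *only* by its relation to
  the other molecules of the dataset: its row of a pairwise similarity
  matrix. For fingerprints the similarity is the Tanimoto coefficient
  Tc(A, B) = c / (a + b − c); similarity matrices from external methods
  (e.g. graph-alignment scores) are consumed through a file adapter.
  Similarities are used directly, without conversion to distances: every
  comparison method already produces a similarity matrix, and an extra
  transformation step would add nothing to a PCA-based pipeline.

Three modeling approaches cross these representations:

1. `vector_fs` — random-forest permutation-importance ranking of the
   vector-space dimensions, followed by feedforward selection (the
   "selected features" model);
2. `vector_pca` — PCA of the vector space, adding principal components in
   variance order (the "optimized principal components" model);
3. `metric_pca` — PCA of the square similarity matrix, with held-out
   molecules projected through their cross-similarities to the training
   molecules.

The default grid is 18 representations (6 + 6 + 6); over five datasets
that is 90 model tasks (`enumerate_representations()`).

## Activity curation

Input tables carry Ki values in nM. Curation drops records with missing
activity or unparseable structures, reduces salts/mixtures to their
largest connected fragment, and, among records with the same canonical
structure, keeps the most recent measurement (greatest publication year;
an undated record loses the tie; equal years resolve to the later input
row, which keeps the rule auditable from the input order). Ki is then
mapped to a clamped, scaled pKi:

$$\mathrm{spKi} = \begin{cases} 0 & K_i \ge 10^4\ \mathrm{nM} \\
(4 - \log_{10} K_i)/4 & 1 < K_i < 10^4 \\ 1 & K_i \le 1\ \mathrm{nM}
\end{cases}$$

Compounds at or beyond 10 µM are treated as uniformly weak; sub-nanomolar
potencies are saturated. The transform is monotone and continuous at both
boundaries.

Each dataset is split once into a training set and an independent
validation set (IVS). The held-out proportion is a free choice here; the
package defaults to `ivs_fraction = 0.2` (seed 17), an
unstratified random draw over identifiers sorted by `mol_id` so the
partition is invariant to input row order. IVS molecules are excluded
from every ranking, reduction, selection and fitting step and scored
exactly once.

## Dimension selection and model fitting

All models are radial-kernel ε-SVRs with the conventional defaults
(cost 1, γ = 1/k, ε = 0.1); SVR has no stochastic component, so refits
are bit-identical. The number of dimensions k is chosen by feedforward
five-fold cross-validation: dimensions are added in rank order (RF
importance for `vector_fs`, variance order for the PCA approaches), each
candidate k is scored on the held-out folds, and the k minimizing the
mean CV RMSE wins (ties to the smallest k; the mean CV PVE is recorded
alongside). The schedule is unit-stride up to 30 dimensions and stride-5
beyond, capped at `k_max = min(100, n − 1, p)` — a compute concession
that is configurable back to pure unit stride.

Two numerically consequential choices:

* **Fold-wise refitting.** In the PCA approaches the reduction (and, for
  descriptors, the standardization) is refit inside each CV fold on the
  fold's training rows only; in the metric approach the similarity
  sub-matrix and its PCA are rebuilt per fold and held-out molecules
  enter as cross-similarity rows. Reducing once on the full training set
  would leak held-out structure into the fold scores; the package
  exposes `refit_per_fold = FALSE` for that laxer variant, but the strict
  version is the default and is what the pure-noise guard test certifies
  (chance-level CV PVE for every k on a random response).
* **Centering and scaling.** Descriptor columns are standardized with
  training-set statistics (heterogeneous units); fingerprint bits and
  similarity columns are mean-centered only, since they already share a
  scale. PCA loadings follow a deterministic sign convention
  (largest-magnitude element positive) so runs are comparable.

Performance is reported as PVE = 1 − SS~res~/SS~tot~ and RMSE on the IVS.
A constant evaluation response leaves PVE undefined (`NA`); RMSE remains
valid.

## Comparing representations

Per-dataset IVS PVEs form a datasets × treatments table; each dataset
ranks the treatments (rank 1 = highest PVE, ties averaged). The Friedman
statistic with the standard tie correction is referred to the chi-square
distribution on k − 1 degrees of freedom. Post hoc grouping uses
Conover's all-pairs least-significant-difference on rank sums with a
t reference on (n − 1)(k − 1) degrees of freedom at α = 0.05; treatments
whose rank sums do not differ significantly share a letter, and a
treatment can belong to several groups. Because the decision rule is an
interval on rank sums, the letters are exactly the maximal runs of
mutually indistinct treatments in rank-sum order.

## Nearest-neighbor pruning

The robustness experiment removes molecules until no retained pair has
similarity at or above a threshold, then reruns the pipeline. The removal
rule is greedy max-degree elimination (ties: larger maximum similarity,
then lexicographically smaller identifier) — deterministic and
near-maximal in retention; an exact maximum independent set would be
intractable and is not what an iterative curation procedure does.
Thresholds are calibrated per similarity method by bisection so that all
methods retain a comparable number of molecules; pruning precedes the
train/IVS split.

## The synthetic generator

`generate_synthetic()` emulates the statistical structure of a curated
bioactivity extraction so the whole pipeline is testable offline:

* **Clustered chemical series.** Cluster centroids are Bernoulli(p~on~)
  bit vectors (default p~on~ = 0.3, 256 bits, 8 clusters of 50); members
  copy their centroid with per-bit flip probability ε = 0.05. Within- vs
  between-cluster Tanimoto separation is a tested property.
* **Similarity-correlated activity.** The latent activity is
  y\* = Σ β~j~·bit~j~ + u~cluster~ + ε with u ~ N(0, 0.05²) and noise
  N(0, 0.05²). Five informative bits carry a mildly decaying effect
  profile (1.5:1) with total budget 1.1. The budget exceeding 1 makes
  both clamp clauses of the Ki mapping reachable; the flat-ish decay
  keeps every informative effect (weakest β ≈ 0.18, i.e. ≈3.5 noise SDs)
  identifiable — a steeply decaying profile would plant "informative"
  bits that are statistically indistinguishable from centroid-correlated
  proxy bits, making recovery ill-posed rather than hard. Informative-bit
  centroid patterns are required to vary between series for the same
  reason.
* **Clamp-spanning Ki.** Ki = 10^{4(1 − y\*)} nM, so y\* < 0 and y\* > 1
  exercise the 10 µM and 1 nM clamps.
* **Dirty-data features.** 5% activity cliffs (y\* reflected around the
  observed midrange — highly similar molecules, very different
  activity), 5% duplicate records re-emitted with later years and
  log-normally perturbed Ki, 5% salt-like records with a disconnected
  `[Na+]` fragment. Fingerprints are emitted directly (one row per
  record) together with simple valid ether SMILES, so curation and
  toolkit smoke tests run without any download.

What the generator does *not* emulate: real medicinal-chemistry
scaffolds, descriptor distributions of any particular target, assay
heterogeneity beyond year-tagged duplicates, or locally nonlinear
structure-activity landscapes beyond the planted cliffs. Passing tests
certify the pipeline's statistical machinery on data whose ground truth
is known — not predictive performance on any real target.

## Study sizes and replication used by the test suite

The certification experiments run at n = 400 molecules (320 train / 80
IVS), the generator's default. The pruning experiment targets one third
of the original size; its validation sets then hold only ~27 molecules,
so single-replicate PVE differences are noisy and the expected
degradation is asserted on the median over 15 replicate datasets
(generator seeds 1–15) rather than a handful.

## Known limitations

* Descriptor coverage follows the installed toolkit (a compact set of 2D
  properties), far narrower than commercial descriptor suites.
* Fingerprint bit widths are fixed by the toolkit (e.g. 1024-bit path
  fingerprints, 4096-bit ECFP); exact bit-compatibility with other
  software versions is out of scope.
* Graph-based similarity is consumed only as a precomputed matrix.
* The Conover letter display may differ from other post hoc families
  (e.g. Nemenyi) on borderline pairs; α defaults to 0.05.
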