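---
title: "Models and design choices in bascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in bascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

bascreen predicts compound–target binding affinities for a panel of protein
targets assembled from protein–protein interaction neighborhoods, and ranks
screening candidates across that panel. This vignette explains the models,
their assumptions, the tunable parameters, and the choices made where the
design was genuinely open. It states no empirical result that the package's
tests or acceptance script do not themselves compute.

## 1. From IC50 to binding affinity

Potency measurements enter as IC50 values with explicit units
(M, mM, uM, nM, pM; micro-sign spellings are alias-mapped). After
conversion to molar, the label is

$$\mathrm{BA} = 1.3633 \times \log_{10}(\mathrm{IC50\ [M]})
\quad \text{(kcal/mol)},$$

the standard free-energy scaling at 298 K ($RT\ln 10 \approx 1.3633$
kcal/mol). More negative means stronger binding; a 1 µM compound maps to
−8.18 kcal/mol. Two conventions had to be fixed:

* **Units.** Molar input is adopted because it places typical micromolar
  actives in the −6 to −8 kcal/mol range where screening literature reports
  strong binders. The conversion refuses non-positive input rather than
  clamping.
* **Replicates.** Repeated measurements of one compound against one target
  are collapsed by the geometric mean of IC50 (equivalently, the arithmetic
  mean of BA): potency errors are log-normal, so averaging belongs in log
  space.

`ic50_from_ba()` is the exact inverse and round-trips to 1e-9; the test
suite checks strict monotonicity and the log-linearity increment of 1.3633
per decade.

## 2. Panel assembly

Per-target datasets are kept only when they hold at least
`min_dataset_size` compounds after aggregation (default 100, inclusive: a
dataset of exactly 100 passes). The threshold exists because the
per-target learner is cross-validated five-fold; below roughly a hundred
points the fold metrics are too unstable to compare across targets.

The target panel derives from a PPI network (STRING-style edge list,
treated as undirected; duplicate and reversed pairs collapse, self-loops
drop, confidence scores are stored but not filtered on by default). Each
seed protein contributes its *core subnetwork* — itself plus its direct
interactors, never second-shell nodes — and the global panel is the union
of core subnetworks intersected with the targets that own a passing
dataset. Orderings are lexicographic throughout so panel assembly is
deterministic.

## 3. Transformer fingerprints

Molecules are embedded by a sequence-to-sequence transformer autoencoder
trained on unlabeled SMILES:

* **Tokenizer**: atom-level greedy longest match. Two-character elements
  (`Cl`, `Br`) and whole bracket atoms (`[nH]`) are single tokens; all
  other characters tokenize singly. Detokenization is exact concatenation,
  and the round-trip identity is property-tested on generated corpora.
  Special tokens `<pad>`, `<sos>`, `<eos>`, `<unk>` are reserved in the
  vocabulary.
* **Encoder**: token embedding (scaled by $\sqrt{d}$) plus sinusoidal
  positional encoding, followed by `n_blocks` post-norm transformer blocks
  (multi-head self-attention → residual + layer norm → position-wise
  feed-forward of width $4d$ → residual + layer norm). Defaults: 4 blocks,
  4 heads, $d = 256$.
* **Reconstruction head**: the architecture's "2 linear layers" are read as
  a position-wise two-layer head (ReLU between) mapping final encoder
  states to vocabulary logits; training minimises token cross-entropy
  against the input sequence. This is a non-autoregressive reading of the
  sequence-to-sequence autoencoder; it keeps the encoder — the only part
  the fingerprint uses — identical to the conventional architecture while
  making desk-scale training tractable.
* **Fingerprint**: the concatenation over blocks of the per-coordinate
  maximum over sequence positions of each block's output. With defaults
  that is 4 × 256 = 1024 dimensions. Among the readings of "max pooling
  yielding 1024 dims from a 256-dim model", block-wise max pooling with
  concatenation is the one consistent with both numbers; the alternative
  (concatenating mean- and max-pools of fewer blocks) is noted as an open
  interpretation but not implemented.

Training is plain gradient descent with Adam, implemented in R with
hand-derived backpropagation; a test verifies every layer's analytic
gradient against central differences at 1e-4. Optimizer settings
(`learning_rate` 1e-3, `batch_size` 16) are conventional defaults; none
are stated by the reference architecture. With identical seeds and
single-threaded BLAS, pretraining is bit-reproducible, which the suite
asserts.

**Scale.** The full-scale corpus default (861 000 unlabeled SMILES)
is configuration metadata documenting the intended production regime;
desk-scale runs — everything in the tests and examples — use corpora of a
few hundred generated SMILES and widths of 8–48. The fingerprint-dimension
contract (4 × `embed_dim`) is tested at the full default width through a
real forward pass.

## 4. Per-target boosted-tree models

Each target's model maps fingerprints to BA with gradient-boosted CART
regression trees under squared-error loss. Stagewise residual fitting with
shrinkage (`learning_rate`, default 0.05 at `n_trees` = 200; depth 3,
`min_leaf` 5), optional row subsampling and per-tree feature subsampling.
The description of "bootstrap resampling" in gradient boosting is
interpreted as optional stochastic-gradient-boosting row subsampling
(`subsample`), off by default. Tree growth is deterministic: features are
scanned in index order and a split must strictly improve the incumbent.

Cross-validation follows the seed-averaging protocol: for each of five
distinct seeds (default 0–4), a fresh five-fold partition is drawn,
out-of-fold predictions are pooled across folds, and per-seed Pearson R
and RMSE are computed on the pooled vector; the reported metrics are means
over seeds, and the five full-data refits form the prediction ensemble
(predictions average the five members). Pooled-out-of-fold R was chosen
over the mean of per-fold R because per-fold correlations are unstable at
fold sizes near 20–30; folds are re-drawn per seed rather than fixed, so
seed averaging integrates over partition noise as well as fitting noise.
Both choices are documented here because the protocol's prose supports
either reading.

## 5. Cross-target matrix and screening

The matrix mixes two unit systems deliberately, mirroring the panel
heatmap it reproduces: diagonal cells (model and dataset share a target)
hold that model's self-CV Pearson R; off-diagonal cells hold the strongest
BA the row model predicts over the column dataset's compounds. "Strongest"
means most negative kcal/mol — the sign convention under which the
literature calls −7.8 "strong affinity" — so the aggregation is a minimum
over signed values. `cell_kind` tags (`self_cv_r` / `cross_max_ba`) keep
downstream numeric use safe, and the TSV export is lossless to full double
precision.

Screening predicts a full compounds × targets BA table, assigns each
compound its most negative target, and ranks by best BA with
lexicographic tie-breaks on compound id. No automatic hit threshold is
imposed; a positive control, when supplied, is only flagged for manual
inspection.

## 6. The synthetic world

The generator replaces ChEMBL/STRING inputs for all testing:

* **SMILES** are built constructively — linear/branched chains over
  C, N, O, S with terminal halogens, optional single rings from
  valence-safe templates (benzene, pyridine, furan, cyclopentane/hexane) —
  never by rejection-sampling an external validator. Every string
  tokenizes and round-trips by construction.
* **Affinity oracle**: per-target linear weights (SD `weight_scale`,
  default 0.5 kcal/mol per feature unit) over substructure counts (atom
  counts, ring closures, halogens, token-length bins) plus an intercept of
  −7.5 kcal/mol, putting typical actives at a few micromolar. The feature
  set deliberately overlaps what a sequence model can encode, so
  fingerprint→BA learnability is guaranteed by design — a green recovery
  test certifies the pipeline's plumbing and learner, not chemistry.
* **Noise** is applied in BA (log) space with SD `noise_sd` (default 0.5
  kcal/mol, a realistic inter-assay spread of ~0.37 log units) before
  exact inversion to IC50; rows are written in µM or nM.
* **Dataset sizes** default to 150/120/99, straddling the inclusion
  threshold so filter composition is exercised.
* **PPI**: one hub per target with `n_neighbors` direct interactors
  (default 3) and `n_periphery` second-shell nodes per interactor
  (default 2) — the star-plus-periphery topology of seed-centered STRING
  neighborhoods.

What the synthetic world does **not** emulate: realistic
medicinal-chemistry distributions, stereochemistry, charged species,
assay-specific censoring, or inter-target correlation structure. Green
tests therefore establish algorithmic correctness and reproducibility,
not predictive performance on real chemistry.

**Recovery experiments.** The acceptance suite trains on noiseless panels
of 200 compounds per target — the same sample size as the noisy recovery
property (noise 0.5 kcal/mol, n = 200, CV R > 0.6) — using the desk-scale
encoder at width 48 and 600 depth-3 trees, and requires per-target CV
R ≥ 0.9; pure-noise labels must stay below |R| < 0.3. Width 48 rather
than 256 is purely a runtime choice; the oracle signal lives in
substructure counts, which max-pooled fingerprints encode only through
many random projections, so narrower encoders lose recovery headroom
before wider ones.

## 7. Numerical and degenerate-input choices

* Zero-variance vectors make Pearson R an error, never a silent 0; constant
  labels abort training with the same reasoning.
* Five-fold splits require n ≥ 5 and balance fold sizes to within 1.
* Attention softmax is row-max-stabilised; layer norm uses eps 1e-5.
* Tree splits place thresholds at midpoints between adjacent distinct
  values; equal-gain ties resolve to the earliest feature and lowest
  threshold, making fits reproducible across platforms up to BLAS
  reduction order.
* Empty prediction inputs return empty vectors; empty record sets build
  size-0 datasets rather than erroring, but an empty assembled panel is an
  error that names the threshold.
* The pipeline is single-threaded and deterministic by default; the run
  manifest (config echo, per-stage checksums, CV summaries) suffices to
  re-run bit-identically, which both the unit and acceptance suites check.

## 8. Known limitations

* The transformer trains in interpreted R: production-scale corpora
  (10⁵–10⁶ SMILES) need hours, not the seconds of desk scale. The
  architecture was kept faithful rather than fast.
* Fingerprints from max pooling discard token counts beyond what random
  projections retain; signals proportional to large homopolymer counts are
  systematically harder to recover than presence/absence signals.
* The GBDT implementation covers squared-error regression only — the only
  loss the pipeline needs — with no quantile or Huber variants.
* Panel assembly resolves targets by exact name equality between activity
  tables and PPI nodes; cross-database identifier resolution is out of
  scope.
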