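---
title: "Modeling 5'UTR-driven protein expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 5'UTR-driven protein expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The 5' untranslated region (5'UTR) of an mRNA controls ribosome recruitment
and translation initiation; engineered 5'UTRs are a standard lever for
raising protein output in mRNA therapeutics. `utr5xpress` provides a
complete, testable toolkit for the computational side of that problem:
predicting a translation-efficiency (TE) label from 5'UTR sequence,
compressing redundant sequence libraries by clustering, and normalizing the
reporter-assay measurements (firefly-luciferase bioluminescence) that ground
such models in actual protein output. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## Data model and filtering

A `utr_dataset` holds one record per 5'UTR: an id, an A/C/G/T sequence
(U is mapped to T at ingest so every downstream module sees a single
alphabet), a TE value on a log scale (negative values are expected for part
of the range), an RPKM abundance, and a cell-line tag. TE and RPKM are taken
as given, never recomputed from reads.

`filter_dataset()` keeps records that (i) carry a TE label and (ii) have
RPKM strictly greater than the cutoff (default 10). Low-abundance
transcripts are removed because TE, a Ribo-seq/RNA-seq count ratio, is
dominated by Poisson noise at shallow depth; "exceeding 10" is implemented
as a strict inequality. The filter is idempotent and records its removal
counts in the dataset provenance.

## Feature space

`extract_features()` assembles three feature groups:

* **SEQUENCE** — k-mer frequencies for k = 1..6 (each k-mer's count divided
  by the number of windows `L - k + 1`, so each k's frequencies sum to 1),
  GC metrics (`gc_content`, `at_ratio`, `cg_ratio` = #C/#G), and the number
  of ATG triplets anywhere in the UTR (each can seed an upstream ORF that
  represses the main ORF).
* **CODON** — frequencies of the 64 triplets read non-overlapping from the
  5' end in frame 0. A UTR has no reading frame, so a fixed deterministic
  convention is used; the trailing incomplete triplet is ignored.
* **STRUCTURE** — thermodynamic descriptors computed with ViennaRNA's
  `RNAfold` at 37 °C (mammalian context; configurable): the minimum free
  energy (`MFE`, kcal/mol), the G-quadruplex contribution `Gquad_energy` =
  (MFE with G-quadruplex scoring) − (plain MFE), which is ≤ 0 because
  admitting an extra stabilizing motif class can only stabilize, and
  `mean_distance`, the ensemble mean base-pair distance (RNAfold's "ensemble
  diversity"), a structural-flexibility proxy in nucleotides.

Numerical edge cases are resolved in favor of a dense finite matrix:
`cg_ratio` of a G-free sequence is 0 with a warning, and k-mers longer than
the sequence get frequency 0. Features are not standardized by default
(tree ensembles are scale-invariant); a `standardize` switch exists for
other consumers.

## Tree-ensemble regressor

`train_rf()` fits extremely randomized regression trees: at each node a
random subset of `max_features` x p features is considered and each gets one
random split threshold; trees see the full training set (no bootstrap by
default, switchable), and the prediction is the unweighted mean of the tree
outputs. Defaults are 100 trees, `max_features = 0.8`,
`min_samples_leaf = 1`, unlimited depth, `min_samples_split = 2`. The
ensemble is fitted by `ranger` with `splitrule = "extratrees"`; the package
surface pins all semantics (naming, importances normalized to sum to one,
strict column matching at prediction).

`rf_grid_search()` evaluates the candidate grid
`n_estimators` in {50, 100, 150} x `min_samples_leaf` in {1, 2, 4} x
`max_features` in {0.5, 0.8} (18 combinations) by k-fold cross-validated
mean squared error with folds shared across combinations (a paired
comparison). Ties break toward fewer trees, then larger leaves — prefer the
simpler model.

## Soft-classification expression codec

Instead of regressing the expression value directly, the network predicts a
probability distribution over 29 ordered expression categories. Encoding
assumes a latent normal around the observed value `e` (already mapped to
bin space 0..28): `rho ~ N(e + 0.5, 0.5)`; category i receives the mass of
`rho` in `[i, i+1)`, with the first and last categories absorbing the tails.
Decoding is the distribution's expectation over bin indices,
`sum_i p_i * i`. Why a latent-normal soft label rather than hard binning:
the spread over neighboring categories encodes measurement uncertainty and
makes the Kullback-Leibler training loss well-behaved.

Two details were underdetermined and are fixed explicitly:

* **Edge convention.** The interval rule `[i, i+1)` conflicts at a single
  boundary point with describing category 0 as `(-inf, 1]`; the half-open
  convention (bin 0 = `(-inf, 1)`) is used everywhere. The disagreement has
  zero probability mass under the continuous latent model.
* **Label map.** How log-scale TE values (negative for part of their range)
  map onto categories 0..28 must be chosen; the package fits an affine map
  anchoring the observed minimum to bin 0 and maximum to bin 28
  (`fit_bin_spec()`), stores it with every trained model, and inverts it
  exactly at prediction time. The codec round-trips interior values to
  within 0.05 bins (verified against a direct numerical evaluation of
  `E[clamp(floor(rho), 0, 28)]`).

KL divergence uses `0 log 0 = 0` and floors predicted probabilities at
1e-12 before the logarithm.

## The convolutional soft classifier

The network is fully convolutional over the one-hot sequence (channels
A, C, G, T), with dynamic padding: each batch is right-padded with all-zero
columns to its own longest sequence (never truncated; sequences above 200 nt
are rejected). The architecture is a stem (standard convolution, kernel 7,
batch normalization, SiLU) followed by six convolutional blocks
(defaults 256 stem channels and block widths [128, 128, 64, 64, 64, 64]).
Each block applies a grouped convolution (kernel 3), batch normalization and
SiLU, a squeeze-and-excitation gate, a pointwise convolution and batch
normalization, and a channel-wise residual connection back to the block
input. Where the channel count changes between blocks, a resizing block
shaped like the stem converts the width; all convolutions are "same"-padded,
stride 1 (no positional downsampling — the blocks act on channels only). The
head is a pointwise convolution to 29 channels, global average pooling over
positions, and a softmax, so every output row is a valid bin distribution.

Design points the architecture description leaves open, and the choices
made:

* **Masked statistics.** Global average pooling (in the head and in the
  excitation gates) and the batch-normalization statistics run over real
  positions only, and activations at padded positions are re-zeroed after
  every layer. This makes outputs invariant to the declared padded length —
  otherwise predictions would depend on which sequences happen to share a
  batch, which is the defensible reading of "padding rather than
  truncation". The invariance is asserted in the test suite at 1e-5.
* **Group count** defaults to 4; **excitation rank** defaults to
  channels/4. The excitation stage is a low-rank bilinear factorization
  (pool → C x r → SiLU → r x C → sigmoid), the compressed form of the usual
  two-layer gate.
* **Optimizer.** Training minimizes the mean KL divergence between encoded
  targets and outputs with the Lion optimizer (sign-based updates with
  decoupled weight decay; defaults lr 1e-4, betas 0.9/0.99, weight decay
  1e-2, following the optimizer's published recommendation). Weight decay
  applies to convolution and excitation weights only.

The forward and backward passes are implemented explicitly in vectorized R
(convolutions as shifted matrix products), which keeps the package
dependency-free on this path; every layer's gradient is verified against
central finite differences in the test suite (relative error < 1e-4).
Training is deterministic for fixed seeds on one CPU.

## Greedy incremental clustering and dataset compression

Library construction is expensive, so redundant sequences should not all be
measured or trained on. `greedy_cluster()` implements single-pass
incremental clustering: sequences sorted longest-first (ties broken
lexicographically by id for determinism); each sequence joins the first
existing cluster (in creation order) whose representative it matches at or
above the identity threshold (default 0.5), else founds a new cluster. The
representative is therefore always the longest member. A best-match variant
is available behind a flag; the reference path compares against every
representative with no prefilter, and the test suite checks it against a
literal sequential transcription of the procedure on hundreds of random
instances.

**Identity metric.** Pairwise identity is computed from an optimal global
(Needleman-Wunsch) alignment with match +1, mismatch −2, and effectively
prohibitive interior gap costs (opening 100, extension 10), normalized by
the alignment length. The stringent scoring is deliberate: redundancy
detection asks whether two sequences are near-copies, and permissive gap
placement inflates the apparent identity of unrelated nucleotide sequences
(with typical homology-search scoring, two random 5'UTRs score 0.4-0.6,
which would make a 50% threshold meaningless — this is also why standard
nucleotide clustering tools do not operate at 50%). Under the package
default, unrelated sequences score ~0.25 and 10%-divergent mutant pairs
score ≥ 0.7, so the 0.5 threshold separates the two populations cleanly.
The CD-HIT-style shorter-sequence denominator is selectable in
`similarity_params()` for users who want that convention.

From a clustering, `build_test_set()` takes the representatives of all
multi-member clusters as a maximally diverse held-out set (singletons are
excluded — no similar training sequence would remain for them), and two
training-subset rules are provided: `select_percentage()` (a seeded uniform
sample of `ceiling(fraction x remaining)` per cluster, so no non-empty
cluster contributes zero) and `select_count()` (up to k per cluster, default
6; smaller clusters contribute everything). `compression_metrics()` reports
`1 - subset/full` and the ratio of subset-trained to full-trained
correlation. `run_compression_experiment()` wires the whole comparison
together, including a size-matched random-selection control drawn from the
same non-test pool (equal n per replicate, so the comparison isolates the
selection rule), with a run-time assertion that held-out representatives
never enter any training subset.

## Evaluation

`pearson_r()` is the Pearson correlation with zero-variance inputs treated
as errors rather than silent NAs. `run_cv()` implements both
cross-validation schemes: *standard* (one seeded shuffle, fixed contiguous
folds — deterministic) and *randomized* (independent re-shuffle per
repetition). The headline metric is the unweighted mean of per-fold
correlations; the pooled-prediction correlation is reported alongside.
`binned_abs_error()` profiles the mean absolute error across label
intervals (empty intervals are reported as missing, not zero), and
`bias_slopes()` quantifies regression toward the mean: the OLS slope of
predicted~actual (< 1 for any CV-fitted smoother on noisy labels: the model
overestimates low and underestimates high values) and of error~actual,
which satisfies `slope_error = slope_pred - 1` exactly.
`ablation_study()` re-runs the cross-validation on feature-group subsets
with shared fold assignments so the comparison is paired.

## Plate normalization (ABI)

Reporter bioluminescence is measured on replicate 96-well plates, each
carrying a reference well. `compute_abi()` averages technical replicates
(duplicates by default), divides each sample's per-plate signal by the
same plate's reference signal, and averages the ratio across plates
(3 by default): `ABI = (1/n) sum_i experimental_i / reference_i`. The
per-plate ratio cancels plate-wide multiplicative effects (cell density,
reagent batches), so the ABI is invariant to rescaling any single plate and
the reference sample's own ABI is exactly 1. Technical replicates are
averaged *before* the ratio. Plates missing a sample lower that sample's
`n` with a warning instead of failing the run, since real plate data has
dropouts; there is no background subtraction by default.

## Synthetic data: what it emulates and what it does not

The generators make the whole pipeline testable without downloads:

* `generate_utrs()` — i.i.d. sequences with controllable GC bias, uniform
  lengths (defaults 60-100 nt, capped at 200).
* `plant_clusters()` — mutually dissimilar seed sequences (pairwise
  identity < 0.3, rejection-sampled) expanded into families by per-base
  substitution (substitutions always change the base, so expected
  mutant-seed identity is exactly 1 − rate). Family sizes may be uniform or
  skewed. Planted-structure experiments use 120-200 nt sequences — the
  typical scale of the longer human 5'UTRs — because identity estimates
  concentrate as 1/sqrt(L) and shorter sequences cannot satisfy the seed
  dissimilarity requirement reliably.
* `simulate_te()` — labels on the log-TE scale as a linear function of
  z-scored named features plus Gaussian noise. `target_r2` calibrates the
  noise so the generating model's population R-squared is known (the best
  achievable prediction correlation is then sqrt(R2)); RPKM values are drawn
  above the filter cutoff so filtering is a no-op unless a test plants
  violations. An optional per-family random intercept (`family_effect_sd`)
  adds label structure shared within sequence families but invisible to the
  extracted features. This emulates the empirical observation motivating
  clustering-based compression: closely similar 5'UTRs share expression
  determinants beyond any fixed feature set. It matters for the
  selection-rule comparison: without it, a feature-only model extrapolates
  to families it has never seen and cluster-aware selection has nothing to
  win; with it, covering every family becomes genuinely informative, which
  is the regime the compression strategy targets. The comparison also uses
  skewed family sizes (a few dominant families plus many small ones, as in
  real redundancy-heavy libraries) — under exactly uniform family sizes a
  random subset covers clusters as evenly as count-based selection does and
  the two rules are equivalent by construction.
* `simulate_plates()` — replicate plates with a reference well, log-normal
  well noise, and duplicate technical reps; at zero noise `compute_abi()`
  recovers the planted ratios exactly.

All generators are pure functions of their spec and seed. What the
synthetic data does *not* emulate: real 5'UTR composition beyond GC bias,
uORF/IRES grammar, cell-line effects, or the empirical TE distribution —
passing tests demonstrate correctness of the machinery and recoverability
of planted structure, not biological accuracy on real libraries.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study-scale experiments at
sizes chosen to exercise the claims while staying desk-sized: n = 1000 for
feature-recovery cross-validation (population R-squared 0.8; ceiling
r ≈ 0.894), 20 planted families x 50 mutants for cluster recovery, a
~1060-sequence skewed redundant library for the selection comparison, and
500 sequences with a reduced network (stem 64, blocks [32, 32, 16, 16, 16,
16]) for learnability. Full-width training on thousands of sequences is
supported but not part of the tests. Other numerical conventions: bin
distributions are validated to sum to 1 within 1e-6; KL uses a 1e-12 floor;
grid-search and ablation comparisons share fold assignments; and all
randomness flows through explicit integer seeds (no wall-clock seeding
anywhere).

## Known limitations

* The identity metric is a package convention (documented above), not a
  reconstruction of any particular clustering tool's internals; at
  thresholds far above 0.8 a banded-alignment tool will differ.
* Codon usage on a UTR is a composition summary under a fixed frame
  convention, not a claim that UTRs are translated.
* The network trains on CPU in R; it is intended for the reduced
  configurations used in testing and for moderate libraries, not for
  large-scale sweeps.
* TE labels are treated as an opaque log-scale quantity; the logarithm base
  is never needed because the label map is fitted to the data.
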