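---
title: "Predicting drug-target interactions from PSSMs and fingerprints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from PSSMs and fingerprints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtiforge)
```

## The prediction problem

Given a set of drugs, a set of target proteins and a list of known
interacting pairs (the layout of the Yamanishi gold-standard benchmarks:
enzymes, ion channels, GPCRs, nuclear receptors), the task is to score an
arbitrary (drug, protein) pair for how likely the two are to interact.
Known pairs are the positives; because non-interactions are never curated,
an equally sized negative set is sampled uniformly from the remaining
drug × target cross-product.  This balanced construction is standard for
these benchmarks, and its main caveat is worth stating up front: some
sampled "negatives" may be undiscovered positives, so measured error rates
are upper bounds.

## Input representations

**Proteins.**  A PSI-BLAST position-specific scoring matrix (PSSM) is an
H × 20 integer matrix Θ for a protein of length H: row i holds the
log-odds of residue i being substituted by each amino acid across the
iterated profile search, a compact encoding of evolutionary conservation.
The package parses the `-out_ascii_pssm` dialect (three header lines, then
index, residue, 20 log-odds integers, 20 weighted percentages, two floats
per row) and keeps only the log-odds block — the percentages carry no
additional scoring information.  Running PSI-BLAST itself is out of scope;
its output files are consumed.

Downstream layers need a fixed-size input, but proteins vary in length.
The package reduces Θ to the 20 × 20 normalised cross-product ΘᵀΘ/H:
entry (j, k) is the per-residue average of the product of the scores for
amino acids j and k.  This transform is length-invariant, symmetric,
permutation-invariant over residues, and is the natural single-channel
image for a small convolutional network.  It deliberately discards
sequence order — an explicit design decision in favour of a fixed, simple,
well-conditioned input; a pad/crop alternative could preserve order at the
cost of an arbitrary length cutoff.

**Drugs.**  The 881-bit PubChem substructure fingerprint, decoded from
Base64 transport text.  The byte layout is fixed here as: a 4-byte
big-endian bit count (must equal 881, anything else is rejected as a
different fingerprint type), then the bits packed most-significant-bit
first with zero padding.  Bit-exactness matters, so the dialect is
round-trip tested on a thousand random vectors.  Computing fingerprints
from structures (SMILES) is out of scope.

## The convolutional feature extractor

The network is the smallest stack that exercises every layer type on a
20 × 20 input:

| layer | output | parameters |
|---|---|---|
| conv 3×3, 8 channels | 18×18×8 | 80 |
| mean-pool 2×2 | 9×9×8 | — |
| conv 3×3, 16 channels | 7×7×16 | 1,168 |
| mean-pool 2×2 | 3×3×16 | — |
| dense 128 (feature layer Γ) | 128 | 18,560 |
| dense 2 (class scores) | 2 | 258 |

Convolution is valid cross-correlation plus bias and activation; pooling
is non-overlapping mean pooling (a trailing row/column that does not fill
a window is dropped, hence 7 → 3), chosen over max pooling for smooth
gradients — max pooling is available by configuration.  Hidden activation
is ReLU by default (tanh, sigmoid and identity are selectable; the
gradient tests use tanh to avoid the ReLU kink).  The loss is mean softmax
cross-entropy plus an L2 penalty (θ/2)·ΣW² over weights only — biases are
never penalised.  Training is plain full-batch gradient descent with
learning rate ε, matching the update rule the model family is defined
with; no momentum, mini-batching or adaptive optimisers.  Initialisation
is seeded uniform(−0.1, 0.1); everything is deterministic given the seed.

Defaults — θ = 1e-4, ε = 0.05, 10 epochs — were fixed once as the smallest
training budget at which the planted-signal benchmark (below) plateaus;
the extractor does not need to be a strong classifier on its own, because
classification is delegated to the ELM.  The extracted representation Γ is
the penultimate dense layer's activations (128 values).

Two readings of the fusion order are possible: fuse fingerprint and
protein features before the network, or extract protein features first and
fuse after.  A 2-D convolution over a concatenated heterogeneous vector is
ill-defined, so this package extracts first and fuses after:
[Γ ‖ 881 fingerprint bits], 1,009 features per pair.  A 2D-PCA descriptor
(below) can replace the CNN for ablation, with everything else unchanged.

## The extreme learning machine

The classifier is a single-hidden-layer network whose hidden layer is
random and *frozen*: input weights and offsets are drawn once from
uniform(−1, 1) under a seed.  With S[j, i] = g(Wᵢ·Xⱼ + bᵢ) (sigmoid g by
default), training reduces to the linear system SV = P with one-hot
targets (1,0)/(0,1), solved as V = S⁺P — the minimum-norm least-squares
solution, computed by SVD with singular values below 1e-12 of the largest
treated as zero.  This is the unique Moore–Penrose solution: among all
minimisers of ‖SV − P‖ it has the smallest norm, and when S is square and
generic the fit interpolates (residual at machine precision), which the
tests assert.  The continuous decision score is the positive-column minus
negative-column output; ties at exactly zero are called negative.

The hidden-layer width defaults to min(1000, 10·L) for L training
samples.  One practical regime matters: when N ≥ L the least-squares fit
interpolates the training labels, which is harmless for cross-validation
(held-out pairs are never in S) but memorises sampled negatives when
ranking candidates — the ranking workflow therefore accepts a smaller
`n_hidden` and an `n_models` score ensemble (mean over independently
seeded fits), the standard remedy for random-hidden-layer variance.

## Evaluation

Five-fold cross-validation splits the labeled *pairs* (not drugs or
proteins — cold-start evaluation is a non-goal) after a seeded shuffle
into disjoint folds of size ⌊n/5⌋, the remainder spread one per fold over
the first folds.  Per fold, the feature extractor and the ELM are fitted
on the four training folds only, together with all normalisation
statistics (a scalar mean/sd for the protein matrices, per-column z-scores
for the fused features) — nothing fitted ever sees held-out labels, which
the test suite enforces structurally.  Folds are unstratified by default
(a stratification flag exists), since nothing in the benchmark protocol
requires stratification.

Metrics are the standard confusion suite — accuracy, sensitivity,
specificity, precision, MCC — with a zero denominator reported as `NA` for
that metric only, plus the ROC AUC computed by a grouped-threshold sweep
with trapezoidal integration, which equals the Mann–Whitney statistic with
half credit for ties (asserted against a pairwise-counting oracle).  Folds
aggregate as arithmetic mean and *sample* (n−1) standard deviation: that
convention, and not the population form, reproduces the published
`mean ± sd` rows of the gold-standard benchmark tables from their per-fold
cells, which `benchmark_consistency()` checks cell by cell.  Three
published sd cells disagree with their own fold rows by one unit in the
last printed digit; they are listed, not hidden.

## The 2D-PCA ablation descriptor

Two-dimensional PCA forms the 20 × 20 image covariance
G = (1/n)Σ(Aᵢ−Ā)ᵀ(Aᵢ−Ā) over the protein matrices, takes the k leading
eigenvectors U, and represents each protein by the row-major flattening of
AᵢU (20·k values; k = 6 by default, giving 120 features, close to the CNN
feature width).  Eigenvectors are sign-ambiguous, so all invariance tests
compare projections up to per-axis sign.  Swapping the CNN for 2D-PCA while
keeping everything else fixed is the package's built-in ablation.

## Synthetic data with a planted signal

Because the real benchmarks require external downloads and a SwissProt
PSI-BLAST run, the package ships generators that emulate all three input
families and plant a recoverable signal:

* every drug and target carries a latent class bit; the latent-1 block is
  sized to hold approximately `n_positives` pairs;
* positives are drawn without replacement with weight 1 inside the block
  and 1 − `signal_strength` outside — at strength 1 the block is exactly
  the positive set, at 0 labels are independent of the latent classes;
* the latent bit shifts the observable features: latent-1 drugs get a
  fingerprint bit density of 0.15 + 0.25·s (baseline 0.15), latent-1
  targets a +4·s shift of their PSSM scores (clamped to the PSI-BLAST
  range [−10, 12]); protein lengths are uniform in [80, 200].

Defaults (60 drugs × 50 targets, 500 positives) give a balanced 1,000-pair
problem at which the full pipeline reaches a mean five-fold AUC above 0.99
at strength 1 and ~0.5 at strength 0, with AUC non-decreasing in between.
The generator emulates the formats and the learnability structure of the
real data, not its marginals: real fingerprints are correlated across
bits, real PSSMs are sequence-structured, and real interaction networks
have hub drugs and promiscuous targets.  Passing the planted benchmark
therefore demonstrates that the machinery works end to end and recovers a
known signal — not that the published benchmark numbers are reproduced,
which would require the deposited data, SwissProt-backed PSSMs and
hyperparameters that were never reported.

## Numerical choices and limitations

* Negative sampling enumerates candidates in drug-major order and takes a
  seeded uniform sample without replacement, so results reproduce across
  platforms; identifiers are opaque case-sensitive strings.
* The ELM pseudoinverse cutoff (1e-12 relative) and the CNN divergence
  check (error naming the epoch on non-finite loss) are the only numeric
  guards; no silent clipping anywhere.
* Candidate ranking scores all non-positive pairs, including those used as
  sampled negatives during training — consistent with treating every
  unknown pair as a candidate.
* Problem sizes in the test-suite and the acceptance script (1,000-pair
  planted datasets, five seeds; 50-instance oracle sweeps) were chosen as
  the smallest at which the assertions are statistically comfortable.
* Out of scope by design: PSI-BLAST invocation, SMILES processing, kernel
  or ridge ELM variants, GPU/minibatch training, cold-start splits, and
  any comparison baselines (an SVM can be plugged in through the trainer
  interface but none ships).
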