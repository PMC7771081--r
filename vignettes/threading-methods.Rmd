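---
title: "Threading by learned residue-pair scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threading by learned residue-pair scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threadr)
```

## The problem

Template-based modelling predicts the structure of a *query* protein by
aligning its sequence onto a *template* of known structure and copying the
template's backbone through the alignment. Its accuracy is dominated by two
decisions: which residue of the template each query residue aligns to, and
which template to use. Both get hard when only remote homologs — proteins
conserved in structure but diverged in sequence — are available.

`threadr` treats the first decision as a dense prediction problem on the
`L_T x L_Q` grid of all template-query residue pairs: a fully-convolutional
residual network maps a 77-channel pairwise feature tensor to a matrix of
*aligning probabilities* `p_ij`, and a Maximum Accuracy (MAC) dynamic
program decodes that matrix into a local alignment. The optimal MAC score
doubles as the ranking key for the second decision, template selection.

## Pairwise features

Every cell `(i, j)` of the input tensor concatenates:

* **Sequence profiles (20 + 20).** Positional amino-acid frequencies from
  each protein's MSA, with an additive pseudocount (default `1e-3`) and
  renormalization; columns with no informative symbol become uniform. We use
  plain frequencies rather than a profile HMM's mixed emission
  probabilities: profile construction upstream of the engine is out of its
  scope, and frequencies keep the generator and the engine self-contained.
* **Observed template structure (13).** 8-state secondary structure
  (one-hot), relative solvent accessibility in `[0, 1]`, backbone dihedrals
  encoded as `angle/180` (two channels; a sin/cos encoding would need four
  and break the 13-column inventory), and contact numbers: the count of
  residues at sequence separation `>= 2` within 8 Å, computed once with
  C-alpha and once with C-beta distances and scaled by 0.1 so the channel
  stays O(1). Glycine substitutes its C-alpha wherever a C-beta is needed.
* **Predicted structure, both sides (8 + 8).** 3-state secondary structure,
  solvent accessibility, dihedrals, interface probability, disorder
  probability — the tracks a sequence-based predictor provides.
* **Contact eigen-features (8).** With `M` a residue-residue contact
  matrix (binary from template coordinates at the strict `< 8 Å` C-beta
  threshold; predicted probabilities, used as-is without binarization, for
  the query), residue `i` is embedded as
  `(sqrt(lambda_1) v_1i, ..., sqrt(lambda_8) v_8i)` from the eight
  eigenpairs of largest magnitude, and the pair feature is
  `sqrt(|lambda_k^T lambda_k^Q|) |v_ki^T| |v_kj^Q|`. The absolute values
  make the feature invariant to the arbitrary sign of eigenvectors, and the
  absolute value under the root keeps the radicand defined when eigenvalues
  of mixed sign pair up — contact matrices are not positive semidefinite,
  so negative eigenvalues do occur. Selection is by `|lambda|` descending
  with ties broken toward the algebraically larger value; proteins shorter
  than 8 residues pad with zero eigenpairs.

The channel order (template profile, query profile, template observed,
template predicted, query predicted, eigen) is fixed so that serialized
model checkpoints remain valid; nothing in the method depends on the order
beyond this reproducibility concern.

## The scorer

The network is deliberately simple: a 1x1 convolution projects the 77
channels to `n_filters` (the projection is needed so identity skip
connections type-check), then `n_blocks` post-activation residual blocks
(3x3 convolution, ELU, 3x3 convolution, add the identity skip, ELU), then a
1x1 convolution to one channel and a sigmoid. The default configuration is
16 blocks of 16 filters. No normalization layers are used; at the filter
counts involved, training is stable without them. Because there are no
dense layers, the parameter count is independent of both protein lengths
and one network scores any template-query pair.

Weights initialize with variance-scaling (fan-in) draws from a seeded RNG,
so a configuration plus a seed reproduces a model exactly. Convolutions are
implemented as im2col gathers followed by BLAS matrix products, with the
hot loops in C++; gradients are hand-derived and verified against finite
differences to `1e-5` in the test suite.

## Labels and loss

Reference alignments come from structural superposition. Each aligned pair
carries a local TM-score conservation weight

```
w_ij = 1 / (1 + (d_ij / d0)^2)
```

where `d_ij` is the pair's C-alpha distance after a Kabsch superposition of
the aligned sets, and `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` (floored at
0.5 Å) is evaluated at the mean of the two protein lengths — the same
length that normalizes the loss, chosen because no single protein owns the
reference alignment. Gap positions carry weight 0.

Training minimizes, per sample,

```
(1 / (L_T L_Q)) * sum_ij [ -L w_ij log p_ij - (1 - w_ij) log(1 - p_ij) ]
```

with `L = (L_T + L_Q)/2`. The `L` factor is the entire class-imbalance
treatment: there are at most `min(L_T, L_Q)` positive cells against
`L_T x L_Q` negatives, and weighting positives by the average length
restores their gradient contribution without any resampling. Probabilities
are clamped to `[1e-7, 1 - 1e-7]` before the logarithms.

Minibatches (size 2) zero-pad every sample to the batch's largest
dimensions; padded cells are excluded from the loss and from `L_T`/`L_Q`,
which always denote true lengths — so padding changes nothing but compute,
and the suite asserts the loss is bit-for-bit identical under appended
padding. Samples are bucketed by area before batching to limit padding
waste, under a seeded shuffle.

Optimization is AdamW (decoupled weight decay `1e-4`, applied to weights
but not biases) with a learning rate warmed up linearly from 0 to 0.01
over the first two epochs and decayed polynomially (power 1) to `1e-4`
over the following sixteen; the schedule is continuous at the boundary.
Early stopping monitors mean validation loss — cheaper than alignment
accuracy and monotone with the objective at this scale — and the
best-validation parameters are returned.

## Maximum Accuracy decoding

Given `p`, the DP fills

```
S[i, j] = max( S[i-1, j-1] + p_ij - alpha,
               S[i-1, j] - alpha/2,
               S[i, j-1] - alpha/2,
               0 )
```

with zero boundaries; traceback starts at the global argmax (ties: smallest
`i`, then `j`) and follows recorded choices (ties: diagonal, up, left,
stop) until a zero cell, emitting matched cells. `alpha` (default 0.3)
is the greediness control: each match must beat `alpha`, each interior gap
step costs `alpha/2`, and terminal gaps are free, giving a local alignment.
The optimal score is non-increasing in `alpha` and zero exactly when the
alignment is empty.

A design note on the recursion: a "maximum accuracy" recursion whose match
branch does not accumulate `S[i-1, j-1]` cannot maximize a *sum* of match
probabilities — its score matrix is history-free. We therefore implement
the accumulating recursion standard in posterior-decoding alignment; the
history-free variant remains available (`recursion = "printed"`) for
comparison. An exhaustive enumeration oracle over all monotone local match
sets (feasible to `L_T x L_Q <= 30`) pins the DP down: scores agree to
`1e-12` over hundreds of random instances in the tests, and recovered
paths agree whenever the optimum is unique.

## Structure metrics

TM-score and GDT quantify alignment-implied model quality. Both maximize
over superpositions; exhaustive search is not attempted. Instead a bounded
fragment-seeded search superposes on sliding fragments of length 4, L/4,
L/2 and L, then iterates re-superposition on the pairs within a distance
cutoff until the selected set is stable — an approximation to the reference
implementations that is exact for self- and rigid-copy comparisons and
never falls below the single all-pair Kabsch superposition (asserted in the
suite). GDT averages superposable fractions at 1, 2, 4 and 8 Å and is
reported on the 0-1 scale. Where a full 3D model would require external
comparative-modelling software, evaluation copies template C-alpha
coordinates through the alignment as the implied model — a documented
proxy: it measures alignment quality, not side-chain or loop quality.

## The synthetic generator

Real training corpora for threading are built from structure-classification
databases and external predictors; none of that is reproducible at desk
scale. The generator instead manufactures template-query pairs with exactly
known ground truth:

* **Backbones** are chains of ideal secondary-structure segments (lengths
  4-15): helix (2.3 Å radius, 100 degree turn, 1.5 Å rise), strand
  (3.3 Å rise, alternating 1.6 Å zigzag), coil (3.8 Å random-walk steps
  with excluded-volume rejection below 3.0 Å), joined by 3.8 Å steps under
  random rotations. Consecutive C-alpha distances stay within
  [3.2, 4.2] Å; C-betas sit 1.5 Å off the local axis (glycine: C-alpha).
* **Queries** derive from templates by residue deletion/insertion (rate
  0.1, split evenly), isotropic coordinate noise (sd 0.3 Å), and sequence
  substitution (rate 0.1); the surviving correspondence *is* the reference
  alignment, weighted by local TM-scores of the noisy superposition.
* **Profiles** plant the learnable signal: aligned columns of the two
  profiles share one draw from a distribution concentrated (parameter 100,
  i.e. near one-hot) on the residue identity, with small independent
  jitter; unaligned columns draw independently. The suite verifies the
  signal suffices *before* any training: MAC decoding of the raw
  profile-similarity matrix already recovers most reference pairs.
* **Query contact maps** emulate a contact predictor by passing true
  C-beta distances through a logistic centered at 8 Å.

These defaults are the package's standard study conditions, chosen once as
a plausible remote-homolog regime (≈10% indels and mutations, sub-Å
coordinate noise) and not tuned thereafter. What passing tests show, and do
not show: recovery under these conditions demonstrates that the feature
path, loss, optimizer and decoder are implemented correctly and that the
architecture can learn residue-pair correspondence from profile and contact
signal; it says nothing about accuracy on real remote homologs, where
profiles are noisier, indels are longer and structurally clustered, and
contact predictions have correlated errors.

## Problem sizes and numerical choices

The bundled experiments run on one CPU in minutes: the recovery experiment
trains the reduced scorer (4 blocks, 8 filters) on 200 pairs of length
~60 for up to 10 epochs (warmup 1, decay 9 — the published 2 + 16 schedule
assumes a far longer run) and evaluates on 20 held-out pairs; threading
trials use 5-template libraries over 20 seeded replicates. Numerical
guards: probability clamping at `1e-7`; eigen tie-breaks toward the larger
eigenvalue; traceback tie-breaks diagonal-first; degenerate Kabsch inputs
(fewer than 3 points, rank-deficient covariance) raise errors rather than
returning garbage; empty alignments serialize as 0-row TSVs and PIR output
for them is refused.

## Limitations

* The scorer ships untrained; users train on their own pairs or the
  synthetic generator. The original large-scale weights are not
  reproducible here.
* TM-score/GDT use a bounded superposition search; values are lower bounds
  that are tight in practice but not certified optima.
* mmCIF, multi-chain assemblies, and the external tool chain (MSA search,
  secondary-structure and contact predictors, comparative model building)
  are out of scope; their outputs are inputs here.
* Ranking uses the raw MAC score without length normalization, so in
  libraries of wildly varying template lengths long templates enjoy a
  mild advantage.
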