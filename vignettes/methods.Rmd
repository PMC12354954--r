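---
title: "Spectral dinucleotide features and a compact CNN for pseudouridine site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral dinucleotide features and a compact CNN for pseudouridine site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Pseudouridine (Ψ) is the 5-position isomer of uridine and the most
abundant RNA modification. The prediction task handled here is fully
supervised and window-based: inputs are fixed-length RNA windows,
center-aligned on a uridine, labeled by whether that uridine is a Ψ
site. The package assumes the windows arrive pre-extracted (the public
benchmark sets in this field are distributed this way, at 21 nt for the
human and mouse sets and 31 nt for yeast); it does not slice windows out
of transcripts, and it does not de-duplicate sequences (redundancy
removal is an upstream dataset-construction step).

The classifier pipeline has three stages.

**1. Dinucleotide physicochemical encoding.** Each of the N−1
overlapping dinucleotides of a length-N window is replaced by a
tabulated constant, once for stacking free energy (kcal/mol; range
−3.42 for GC to −0.93 for AA/UU) and once for hydrophilicity
(dimensionless; 0.04 for AA to 0.52 for CU). The shipped table is the
standard published set of 16 values per property
(`dinucleotide_properties()`). The two encodings are deliberately
complementary: free energy mostly separates G/C-rich from A/U-rich
contexts, while hydrophilicity also separates U from A (UU = 0.44
vs AA = 0.04), which matters because Ψ-site flanks tend to be U-rich
and non-site flanks A-rich.

**2. DFT amplitude spectrum.** Each numeric profile h of length
L = N−1 is transformed as H(k) = Σₙ h(n)·e^{−i(2π/L)kn} and reduced to
amplitudes Z_k = |H(k)|. All L amplitudes are kept per property — the DC
term (|profile sum|, a composition summary) and both halves of the
conjugate-symmetric spectrum — because the method's published feature
count, 2(N−1), implies no truncation. Redundant symmetric columns cost
nothing at these sizes and keep the feature indices interpretable
(`FreeEnergy_Amp_k`, `Hydrophilicity_Amp_k`, k from 1). In mixed-length
sets, shorter profiles are right-padded with zeros to the longest
profile length *before* the transform; padding acts on the numeric
profile, not on the nucleotide string, since no "zero nucleotide"
exists. No standardization is applied by default (the features are used
raw); `extract_features(..., standardize = TRUE)` provides an optional
per-column z-score for experimentation.

**3. The network.** A compact CNN:

- an input-mapping stage that takes the 2(N−1)-vector onto an m×m
  grid, m ∈ {6, 7, 8}. The default mode is a *learnable linear
  projection* (`dense_projection`); `zero_pad` instead appends
  m² − 2(N−1) zeros and reshapes row-major (for 60 features on an 8×8
  grid, exactly 4 zeros). Both modes are first-class because both
  arrangements are plausible readings of the architecture; the
  projection is the default as the more expressive of the two, and the
  choice is recorded in the model spec. The projection is linear — any
  nonlinearity can be absorbed by the convolution activation that
  follows.
- one valid 2-D convolution layer, square kernel k ∈ {3, 4, 5}, stride
  s ∈ {1, 2, 3}, 16 filters. The filter count is not a tuned
  hyperparameter; 16 is the default (configurable) as the smallest
  power of two that leaves a non-trivial flattened representation even
  when pooling reduces the map to 1×1. Output side is
  ⌊(m − k)/s⌋ + 1.
- 2×2 max pooling with stride 2 and no padding. When the conv map is
  1×1 pooling is undefined, so it is skipped (and flagged in the spec)
  rather than treated as an error — this keeps the 8×8-grid / 5×5-kernel
  / stride-3 configuration trainable.
- a dense head of depth d ∈ {1, 2, 3} and width u ∈ {4, 8, 16, 32},
  activation ReLU or SeLU (shared with the conv layer), each dense
  layer followed by 30% dropout (inverted scaling, disabled at
  prediction time).
- a 2-unit softmax trained with cross-entropy.

Unstated engineering details are fixed at conventional values and
logged in the model object: Adam at its usual defaults (learning rate
10⁻³, β₁ = 0.9, β₂ = 0.999), batch size 32, Glorot-uniform
initialization, row-major grid reshape. One integer seed drives weight
initialization, epoch shuffling, and dropout masks, so training is
deterministic given the seed on a given platform. The whole network is
implemented in base R matrix algebra (im2col convolution, manual
backpropagation, verified against finite-difference gradients in the
test suite); at ≤8×8 grids and ≤32-unit layers this trains a 10-fold CV
on 200 windows in a few seconds on one CPU, so a deep-learning
framework would add dependency weight without benefit.

## Hyperparameter search and evaluation

Random search samples uniformly and independently from the six
candidate lists (3·3·3·3·4·2 = 648 combinations). The draw count is not
part of the published protocol; the default is 30 (~5% of the space),
in keeping with random search's point of being much cheaper than
exhaustion. Each draw is a deterministic function of (space seed, draw
index); combinations that cannot form a network for the given input
(kernel larger than grid, or zero-pad grid smaller than the feature
vector) are rejected and redrawn, with rejection counts logged.

The two-phase protocol: screening by stratified 5-fold cross-validation
at 15 epochs, scored by the dual metrics ACC and MCC; final evaluation
of the winner by stratified 10-fold cross-validation at 30 epochs. The
selection rule among screened configurations is ACC first, MCC as the
tie-break, earliest draw as the final tie-break — ACC is the field's
headline metric, and MCC is the natural second key since it is the
other metric the screening phase computes. All configurations are
screened on identical folds (fold assignment depends only on labels, k,
and seed), so comparisons are paired.

Cross-validation is stratified even though the benchmark convention
only requires non-overlapping folds: the benchmarks are balanced, and
stratification is the faithful reading that also stabilizes per-fold
metrics at these sample sizes. Per-fold ACC/Sn/Sp/MCC use hard labels
at a 0.5 probability threshold (configurable); AUC is the Mann–Whitney
rank statistic (ties contribute ½) computed within each validation fold
and averaged, matching the per-fold reporting of the other four
metrics; a pooled-predictions AUC is available behind
`pooled_auc = TRUE`. Metrics with zero denominators (e.g. a fold where
every prediction is negative) are reported as 0 and flagged degenerate
instead of erroring, so a bad configuration cannot crash a search.

## The synthetic benchmark generator

`generate_dataset()` emulates the compositional structure that makes
the published benchmarks learnable, so the whole pipeline is testable
without downloads. Both classes have uridine at the window center
(negatives are genuine uridine sites too). Flank residues are drawn
independently per position from a background that is uniform over
{A, C, G, U}, shifted by the signal: at signal strength s, positives
move s·δ of probability mass toward U in the 5 positions on each side
of the center, and negatives move s·δ toward A across all flank
positions — the U-rich-near-center vs A-rich contrast reported for the
real datasets. δ = 0.4 (so the enriched base reaches probability 0.65
at s = 1) and the 5-position window are fixture constants chosen to
give a strong but not degenerate signal; both are configurable, and
neither is a claim about biology.

What the generator does *not* emulate: species-specific motifs,
dinucleotide correlations, secondary structure, or the exact
per-position enrichment statistics of the real data. Passing the
end-to-end tests therefore shows that the pipeline can recover a strong
positional composition signal and stays at chance on an exchangeable
null — not that it attains any particular accuracy on the real
benchmarks, which must be supplied by the user (they load unchanged via
`load_dataset()`).

## Numerical choices and degenerate inputs

- The DFT uses the fast transform; tests pin it to a naive O(L²)
  double-sum oracle at 10⁻⁹ absolute tolerance and check Parseval and
  conjugate symmetry on random profiles of lengths 1–64.
- Sequences must have N ≥ 2 (one dinucleotide); empty profiles are
  errors, as is padding to a shorter target.
- T is silently normalized to U on input (benchmark files are often
  DNA-alphabet), with a one-line note per file; any other non-ACGU
  residue is an error naming the record and position.
- Even-length windows have no center; the center check reports them as
  unverifiable rather than rejecting them, since the pipeline itself is
  defined for any N ≥ 2.
- Labels come from which file a record is in, never from header
  parsing — no header dialect exists for these benchmarks.
- Cross-entropy probabilities are clamped at 10⁻¹² inside the log;
  non-finite loss aborts training with a diagnostic rather than
  propagating NaNs into the search.
- Per-fold and per-draw seeds are derived from the master seed by fixed
  integer arithmetic kept inside 32-bit range.

## Problem sizes

The shipped tests and the acceptance script run on simulated sets of
100–200 windows (the size of the smaller published benchmarks), with
10-fold/30-epoch final cross-validation and small search budgets
(n_iter ≤ 4 in tests); these sizes exercise every code path and keep
the full suite under a minute. The defaults users see
(`n_iter = 30`, k = 10, 30 epochs) match the published protocol and
remain cheap: a 30-draw search on a 200-window set completes in about a
minute on one CPU.

## Known limitations

- Zero-padding mixed-length sets is implemented as specified but is
  untested against any published number beyond dimension counts, since
  the public benchmarks are fixed-length.
- Only the two dinucleotide properties are shipped; higher-order
  (e.g. trinucleotide) encodings are out of scope.
- Exact bit-level reproducibility is guaranteed for a given platform
  and BLAS; across platforms, tiny floating-point differences in
  training can change individual predictions near the 0.5 threshold.
- The model reports probabilities from a softmax trained on balanced
  data; on strongly imbalanced inputs the 0.5 threshold is not
  calibrated and should be tuned by the user.
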