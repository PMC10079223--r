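---
title: "Predicting G4-seq mismatch scores: model, simulation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting G4-seq mismatch scores: model, simulation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4scan)
```

## The problem and the model

G4-seq reports, for nearly every non-overlapping 15 nt bin of a genome and
for both strands, a *mismatch score* in 0–100%: the fraction of base calls
that differ between sequencing under a G4-stabilizing condition (K+, or K+
with the ligand PDS) and a control read. Polymerase stalling at folded
G-quadruplexes causes these mismatches, so the score is a quantitative proxy
for G4 propensity. `g4scan` regresses that score on sequence.

The input to the regressor is the 15 nt bin plus `flank_len` (L) nt of
genomic context on each side, one-hot encoded in channel order A, C, G, T;
an N becomes the uniform row (0.25, 0.25, 0.25, 0.25), i.e. "no information,
equal probability". Minus-strand bins are reverse-complemented at window
extraction, so the model always sees the measured strand 5'→3' — G4s form
on the G-rich strand, and both strands are measured independently. Windows
hanging over a chromosome end are filled with N, which the encoding maps to
the same neutral rows.

The network is a single valid (un-padded) 1D convolution of `n_kernels`
kernels of width `kernel_size` with ReLU activation, global max-pooling over
positions, a ReLU dense layer of `dense_units`, and one linear output
neuron. Defaults are 256 kernels × 95 nt and 32 dense units with L = 100
(input 215 nt); the parameter count is `4kF + F + FD + D + D + 1`
(`parameter_count()`), 105,793 in that configuration. Two choices deserve
comment:

* **Valid convolution.** With k = 95 on a 215 nt input, a padded convolution
  would evaluate the kernel mostly off-sequence at the boundaries; valid
  mode keeps every kernel placement fully informed (121 positions).
* **Linear, unclipped output.** A sigmoid squashed to the score range costs
  accuracy, and the score is only *correlated* with G4 stability — ranking
  fidelity matters more than hitting the absolute value, and Pearson-based
  evaluation is affine-invariant. Reports may clip to [0, 100] for display,
  but metrics always use the raw output.

Both one-sided variants ("upstream" / "downstream" flank only, input
15 + L nt) are supported, mirroring the flank-asymmetry analysis the
architecture was originally selected with, and `architecture_grid()` spans
the published sweep protocol (L from 0 to 140 by 20; k from 5 to 2L + 15 by
10).

## Training

Training minimizes mean squared error with Adam (learning rate 0.001, batch
size 256, one epoch by default — genome-scale tracks are redundant enough
that a single pass converges). Batches are extracted *on demand*: the stream
holds only coordinates and scores, cuts windows from the genome and encodes
them per batch, so memory is the genome plus one batch regardless of track
size. Shuffling is a pure function of `seed` and epoch, so training is
bit-reproducible; bins with missing scores are skipped and counted.

Three numerical choices stabilize small-budget training and are defaults
everywhere:

* **Target standardization.** The stream's scores are centered and scaled to
  unit variance for the loss; the calibration constants are stored in the
  model and predictions are mapped back to percent. Adam's per-parameter
  step is bounded by roughly the learning rate, so on a 0–100 target scale a
  short run cannot even reach the target mean; standardization makes
  convergence independent of the score scale and leaves Pearson evaluation
  untouched.
* **Near-zero output-layer initialization.** Hidden layers use seeded
  Glorot-uniform weights, but the output layer starts at 1% of that scale,
  so initial predictions sit at the (standardized) target mean. Without
  this, the first violent correction can drive every dense-layer rectifier
  negative at once — a dead network whose gradients vanish and whose output
  collapses to a constant.
* **Gradient-norm clipping** (global norm 5 by default). Score distributions
  are heavy-tailed (rare, very high-scoring G4 bins), and an occasional
  extreme batch otherwise produces destabilizing steps.

The loss aborts with the batch index if it turns non-finite. A
leave-chromosome-out split helper (`split_by_chromosome()`) implements the
evaluation scheme: named chromosomes are held out for testing/validation and
never streamed during training.

## From scores to G4 calls

`call_peaks()` reproduces the G4-seq peak-production rule: keep bins
scoring **strictly above** 14.4, merge book-ended runs (gap ≤ `max_gap`,
default 0, matching bedtools-merge semantics), assign each region its
maximum member score, and keep regions scoring **at least** the
condition threshold (25 for K+, 35 for K+ +PDS). The boundary semantics
follow the wording that regions *greater than* 14.4 merge and those
*smaller than* 25/35 are filtered out, so a region at exactly 25 survives.
Input must be position-sorted; unsorted input errors rather than being
silently reordered, to keep streaming semantics honest. The 14.4 value was
originally derived by calibrating against published peak lists;
`calibrate_merge_threshold()` exposes that calibration as a grid search
maximizing nucleotide-level Jaccard agreement.

Detection quality is measured at nucleotide resolution
(`nucleotide_labels()`, `detection_metrics()`): precision TP/(TP+FP), recall
TP/(TP+FN), Jaccard TP/(TP+FP+FN), with zero-denominator ratios reported as
missing rather than 0.

PQ motif matching (`find_pq()`) uses the canonical regular expression
`G{3,}([ACGT]{1,7}G{3,}){3}` or the extended form with loops to 12 nt,
reporting leftmost, greedy-maximal, non-overlapping matches — the counts are
what published PQ tallies use, and enumerating overlapping alternatives
would inflate them. Both strands of a genome are scanned with minus-strand
coordinates mapped back. For PQ-only evaluation (`pq_only_selection()`),
a PQ is kept only if no other PQ (either strand) intersects its 100 nt
flanks and at least one same-strand measured bin overlaps it; it is paired
with the **maximum** overlapping bin score — the mapping from a multi-bin PQ
to one score is not specified by the assay, and the maximum matches how
merged peaks are scored.

## Scanning

`score_probe()` implements the microarray protocol: pad the probe with
`flank_len` N positions per side, slide the model across every window at
stride 1, return the maximum and its offset (ties to the smallest offset,
for determinism). Padding with N rather than any concrete sequence is the
only choice that adds no sequence information. `scan_genome()` emits a
prediction for every 15 nt bin on both strands (stride 1 available for dense
scans); `max_scoring_subsequence()` does the same within a single sequence,
N-padding context beyond its ends.

## Interpretation

All interpretation procedures exploit the probability encoding: a position
can hold a *distribution* over bases, not just a letter. Builders:
`pattern_fixed()` (one-hot), `pattern_uniform()` (0.25 everywhere) and
`pattern_biased(base, p)` (p on one base, (1−p)/3 on the rest;
`p = 0.25` reproduces the uniform row exactly, which anchors the
flank-composition scan).

* **Loop-length scan** — the four-tract pattern GGG·loop·GGG·loop·GGG·loop·GGG
  with uniform loops, varying one loop from 1 to 12 nt. Non-varied loops
  default to length 1 (the canonical wild type GGGNGGGNGGGNGGG); the
  original description leaves this open, and length 1 makes the baseline
  the canonical motif itself.
* **G-tract mutation scan** — each of the 12 guanines substituted by A, C, T;
  `delta = wild-type − mutant`, so destabilizing mutations are positive.
* **Flank-composition scan** — one 20 nt flank bin set to `biased(base, p)`
  for a grid of p, all else uniform; bins are indexed from the central bin
  outwards (a 100 nt flank has 5 per side).
* **Mutation map** — every position of a sequence substituted to every base,
  same sign convention; wild-type cells are exactly 0. The table has one
  column per base (not 3 per position) so the wild-type column is explicit
  and all-N inputs still have well-defined entries.
* **Integrated gradients** — attributions
  `(x − baseline) ⊙ mean_path_gradient` along the straight path from the
  all-0.25 baseline, discretized with a midpoint Riemann sum (default 128
  steps). Per-position letter heights are the channel sums. The
  completeness residual `|Σ attribution − (f(x) − f(baseline))|` is carried
  in the metadata; because the network is piecewise linear the midpoint rule
  converges quickly, and on trained fixture models the residual is well
  below 1% of the output gap at 512 steps. The exact step count used in the
  original analyses is unreported; 128 keeps the residual below plotting
  resolution. Motifs are centered in the input window, shifted one position
  left when exact centering is impossible (a deterministic tie-break).

`kras_attribution()` chains these for the 35 nt KRAS promoter G4: find the
maximum-scoring 15 nt sub-sequence (with N-padded flanks, absent genomic
context) and attribute the winning window.

## Cross-dataset statistics

`cross_species_matrix()` trains one model per dataset under identical
spec/config (exactly k trainings for k datasets) and fills the full train ×
evaluate Pearson matrix; a failed training flags its row and the run
continues. Whether diagonals use held-out chromosomes or full self-prediction
is controlled by `eval_chroms` and recorded in the `self_evaluation`
attribute, since either convention is defensible. `genome_properties()`
computes the descriptors used to explain transfer performance (genome size,
GC content excluding N, extended-PQ count on both strands, PQ density per
genome nucleotide, fraction of bins under 5%); per-property significance
combines Spearman p-values across evaluation datasets with the unweighted
harmonic mean p-value `n / Σ(1/p)` (the simple form; weighted variants
exist but only the plain HMP is called for). Asymptotic Spearman p-values
can underflow to exactly 0 at tiny n with perfect rank agreement; the report
floors them at the smallest positive double before combining.

## The synthetic generator

`simulate_genome()` draws an i.i.d. background at a configurable GC
fraction and plants PQ motifs (tracts 3–5 nt, loops 1–7 nt over A/C/T) at a
configurable rate on random strands, non-overlapping with 30 nt separation;
every insertion is logged. `simulate_track()` scores every 15 nt bin on both
strands with a transparent surrogate: each position takes +min(run, 4) in a
G-run and −min(run, 4) in a C-run; the raw score is the central-bin mean
plus α times the flank mean, squashed through
`100 / (1 + exp(−1.5 (raw − 1)))`, plus N(0, σ) noise clipped to [0, 100].
The surrogate is *deliberately not* the learned model — it is a documented
ground truth that makes parameter-recovery claims falsifiable, and its
constants are frozen so documented values (all-A window → 18.24; canonical
central motif → 89.09) stay stable.

Defaults are the package's study conditions, chosen once: 200 kb over 4
chromosomes (large enough for ~26,600 training bins and a fully held-out
chromosome, small enough for desk-scale runs), GC 0.4 (vertebrate-like),
2 planted motifs/kb (dense enough for ~100 plants per chromosome),
α = 0.5 (flanks matter, but less than the central bin, as in the real
assay), σ = 5 (≈ a third of the background score SD), surrogate flank
20 nt. With α > 0 a flank-blind predictor is strictly worse than the
flank-aware truth, which grounds the package's central qualitative claim —
models with flanks beat flankless models — in a testable property.

What the simulator does **not** emulate: polymerase-stalling chemistry and
its strand asymmetries, sequencing-error profiles, score missingness,
repeat structure, and non-canonical G4s (bulged or mismatched tracts).
Passing recovery tests therefore demonstrates that the pipeline learns and
detects the planted signal class under noise — not that it reproduces
assay-specific artifacts of real G4-seq data.

## Desk-scale experiment sizes

The bundled recovery experiment (also run by `scripts/acceptance.R`) uses
the default 200 kb conditions: an L = 20, k = 25 model against an L = 0,
k = 15 model, trained 3 epochs at learning rate 0.01 with batch 256 and
chromosome 1 held out. The elevated learning rate and epoch count are the
desk-scale counterpart of the reference schedule (0.001, one epoch over
hundreds of millions of samples): with ~80 batches per epoch instead of
~1.5 million, the update budget shrinks by four orders of magnitude, and
Adam's bounded step size would otherwise leave the model far from
convergence. Typical results: held-out r ≈ 0.96 with flanks, ≈ 0.93
without, detection Jaccard ≈ 0.75 against noiseless-truth peaks, and
complete recovery of planted motifs. The balanced evaluation in the
acceptance script samples 100 per score stratum (not 1,000) because a 6,666
bin chromosome cannot fill the published stratum size; the procedure is
otherwise identical.

## Known limitations

* The network is trained from scratch at desk scale in tests; reproducing
  published genome-scale accuracies requires the corresponding full tracks
  and compute, which the framework supports but does not ship.
* Checkpoints are single-file RDS archives with a versioned header; they are
  not portable to other frameworks.
* Training is single-threaded deterministic; no GPU or multi-worker path.
* `find_pq()` reports non-overlapping matches only; overlapping alternative
  foldings are intentionally not enumerated.
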