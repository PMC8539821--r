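---
title: "Multi-label subcellular localization from sequence and evolution profiles"
author: "sublocr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label subcellular localization from sequence and evolution profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A protein can reside in more than one cellular compartment at once, so
predicting its subcellular localization from sequence is a *multi-label*
problem: for L candidate locations the target is a binary vector with at
least one positive entry, and the model emits L independent probabilities.
In the human benchmarks this package is designed around, the label matrix
is very sparse — on the 14-location set of 3106 proteins, the 3681 positive
assignments fill only 8.47% of the 3106 x 14 cells, and the per-location
counts span 1021 (Nucleus) down to 22 (Synapse) — so both the loss and the
evaluation metrics must respect sparsity and ranking rather than plain
accuracy.

## Inputs and encodings

Two fixed-size encodings are computed per protein:

* **One-hot matrix** (`one_hot_encode()`): `l_max` x 23 binary; row i
  carries a single 1 at the alphabet index of residue i. The 23 columns
  are the 20 standard residues in one-letter alphabetical order followed
  by B, Z and X; U folds onto C, O onto K, and J or any unknown letter
  onto X. Rows beyond the sequence are zero (padding); sequences longer
  than `l_max` lose their C-terminal residues.
* **PSSM** (`parse_psiblast_pssm()` + `normalize_pssm()`): the PSI-BLAST
  ASCII profile has 42 numeric columns per residue (20 log-odds scores,
  20 weighted observation percentages, information content, relative
  weight). A constant zero 43rd column pads the matrix to the network's
  l_max x 43 input; zero is inert, so users holding 43-column precomputed
  matrices can load them verbatim via `read_matrix_tsv()` instead. Whether
  that extra column was a position index or a bias in the original
  pipeline is not recoverable from the architecture description; the
  inert-padding reading is the only one that cannot inject signal. By
  default PSSM values are fed to the network unscaled; an elementwise
  sigmoid squashing is available (`pssm_scaling = "sigmoid"`) for users
  who prefer bounded inputs.

`l_max` defaults to 1000 with C-terminal truncation and zero padding; the
dense head requires a fixed input size and these are the conventional
choices when nothing else is specified. Padding rows are fed to the BLSTM
as zero inputs rather than masked; masking would change the reachable
states of the backward pass, and the fixed-length contract keeps the two
convolution branches shape-compatible.

## Model

Four architecture variants share one vocabulary of parts
(`model_config()`):

* `blstm` — a 2-layer bidirectional LSTM over the one-hot rows; the
  concatenated final hidden states of the two directions feed the dense
  head. Gates follow the standard form: forget and input coefficients
  and the candidate state are affine maps of `[h_(t-1), x_t]` through a
  sigmoid (or tanh for the candidate), `C_t = f_t C_(t-1) + i_t C~_t`,
  and `h_t = o_t tanh(C_t)`, which bounds every state in (-1, 1).
* `blstm_conv1` — the per-position BLSTM states form an `l_max` x 2h
  image ("encoded to 256 values" per position at full scale) that a
  4-convolution / 3-max-pool stack (ConvNet1) reduces to features.
* `conv2` — an identically shaped stack (ConvNet2) reads the PSSM image
  alone.
* `full` — ConvNet1 and ConvNet2 outputs are concatenated, flattened and
  passed through the dense head.

Convolution is valid cross-correlation (`C_ij = sum_mn w_mn X_(i+m)(j+n)`,
no kernel flip), ReLU after every convolution, one fully connected layer
to L logits and an elementwise sigmoid. Scores are independent per-label
probabilities; they are deliberately not softmax-normalized, and the test
suite asserts that their sum is unconstrained. The full-scale defaults are
the published architecture: kernels 256/128/64/32 of sizes 4x3 then 3x3,
2x2 pooling after the first three convolutions, 128 LSTM units per
direction. The 43-wide PSSM survives this geometry exactly (43 -> 41 ->
20 -> 18 -> 9 -> 7 -> 3 -> 1), which is a good hint that 43 columns and
3-wide kernels were designed together.

The loss is mean binary cross-entropy over the label terms plus an L2
penalty `lambda * ||w||^2` restricted to convolution kernels — not LSTM or
dense weights. Scores are clipped to `[1e-7, 1 - 1e-7]` inside the loss so
the logarithms stay finite.

## Training

`training_config()` defaults: Adam (learning rate 1e-3, beta 0.9/0.999),
60 epochs, batch 32, lambda 1e-4, global gradient-norm clip 5, score
binarization threshold 0.5 for F1/MCC. These are the package's choices
where the method description gives only "the optimization algorithms
minimize the loss"; every one of them is exposed.

Two numerical choices deserve explanation because they decide whether the
recurrent variants train at all:

* **LSTM input-weight initialization at unit variance.** The first LSTM
  layer sees one-hot rows, so exactly one input is active per step and
  the effective fan-in is 1; fan-in-scaled schemes (Glorot/He with
  fan-in 23) leave the state images two orders of magnitude too small to
  drive the convolution stack. Input-to-hidden matrices are therefore
  drawn uniform(-sqrt(3), sqrt(3)) (variance 1), recurrent matrices stay
  Glorot, and the forget-gate bias starts at 1.
* **Adam epsilon 1e-4.** With the conventional 1e-8, parameters whose
  gradients are tiny-but-noisy — the recurrent weights behind a deep,
  still-random convolution stack — take essentially full-size steps in
  random directions (`m/sqrt(v)` is scale-free), and the recurrent
  dynamics random-walk into saturation before any signal reaches them;
  the encoder's state images then collapse to near-constants and
  training flatlines at the label base rate. A larger epsilon makes the
  step proportional to the gradient below the 1e-4 scale, which we found
  to be the difference between training reliably and not training at
  all.

`train_staged()` adds a second safeguard for the BLSTM-fed variants:
stage one freezes the randomly initialized BLSTM (a reservoir-style fixed
encoder whose images are computed once and cached, so these epochs are
cheap) and trains only the convolution stack and head; stage two
fine-tunes everything jointly, optionally at a larger learning rate —
once the readout is aligned, gradients into the encoder carry signal and
tolerate bigger steps. Aligning the readout before touching the encoder
removes the race between signal discovery and encoder drift. Both stages
run in short warm-restart chunks (fresh Adam state and shuffle stream
every few epochs), which acts as a mild annealing schedule and measurably
improves held-out ranking at a fixed epoch budget.

Training is bitwise deterministic for a fixed seed: initialization comes
from `build_model()`'s seed, per-epoch shuffles from the training seed,
and the engine is single-threaded. The output bias starts at the logit of
each label's training base rate so early updates go into per-location
signal rather than re-deriving the prior. Divergence (non-finite loss)
raises an error naming the epoch.

## Evaluation

The metrics module implements the exact printed forms, with ties resolved
the way the non-strict inequalities dictate: in ranking loss a
true/false-label tie counts as a violation, and coverage and
label-ranking average precision use inclusive (>=) ranks. One notational
wrinkle: the ranking-loss denominator is printed as
`||y_i||_0 (n - ||y_i||_0)` with n elsewhere the number of samples; the
only reading that makes the quantity a fraction of discordant label pairs
is n = L (the number of labels), and that is what is implemented.
Coverage is reported 1-based exactly as the formula computes it (some
libraries report rank - 1). Per-label F1/MCC/AUC use a 0.5 threshold for
binarization (AUC is rank-based with half-credit for ties); labels with a
single class in the evaluated fold are undefined and are excluded from
macro-averages rather than imputed, with the affected labels listed in
the report. Every metric is checked against exhaustive brute-force
enumeration on hundreds of small random instances in the test suite.

## The synthetic benchmark

`generate_dataset()` builds datasets with a decodable ground truth and no
external downloads: each location owns a distinct random 6-residue motif
(pairwise Hamming distance >= 2); each protein draws its number of
locations from (0.83, 0.15, 0.017, 0.003) — mirroring the 2580/480/43/3
multiplicity split of the 14-location benchmark — and carries two planted
copies of each positive location's motif at non-overlapping uniform
positions in an otherwise uniform-random sequence of length ~N(300, 60),
truncated at 50. Pseudo-PSSMs (`generate_pseudo_pssm()`) emulate the
*shape* of an evolutionary profile: background log-odds N(-1, 1) with the
residue's own column raised by 5, softmax-derived percentages, an
information-content column, and a constant relative weight. Both network
branches can therefore decode the truth — the sequence branch from the
motifs, the profile branch from the conserved columns at motif sites.

What the generator does *not* emulate: homology structure between
proteins, real substitution matrices, compositional biases, signal
peptides, or label correlations beyond independent sampling. Passing the
learning checks on this benchmark demonstrates that the pipeline can
extract planted sequence signal end-to-end; it says nothing about
accuracy on real proteomes.

## Desk-scale study configuration

The learning checks run on one CPU core, so they use the compact
configuration (`compact_model_config()`, `compact_training_config()`):
2000 training / 500 held-out proteins, 14 locations, `l_max` 400 (the
generator's length distribution fits under it), 20 LSTM units per
direction, 8 kernels per convolution layer, batch 32, staged training
(learning rate 3e-3 frozen stage, 5e-3 joint stage, warm restarts every
3 epochs; 10 + 18 epochs for the headline `blstm_conv1` run, 3 + 5 for
the three-seed `full`-vs-`conv2` comparison). Two further compact-scale
choices matter:

* **Pooling is 4x1** — positions only, and coarser than full scale. At an
  image width of 40 (vs. 256 at full scale) a 2-wide feature-axis pool
  would discard a quarter of the encoder per layer; and pooling positions
  down to 3 cells per channel leaves the dense head little room to
  memorize position-specific quirks, which empirically is the difference
  between motif-generalizing solutions and pure position memorization.
  The full-scale defaults keep 2x2 pooling.
* **PSSMs are sigmoid-squashed** in the compact study
  (`pssm_scaling = "sigmoid"`). Raw profiles carry percentage columns up
  to 100; through four convolutions these produce activations orders of
  magnitude above the BLSTM image's, so the global gradient-norm clip is
  consumed by the PSSM branch and the sequence branch of the `full`
  variant is starved of updates. Squashing puts both branch inputs on
  the same bounded scale. The full-scale default remains unscaled.

At this scale the ablation reproduces the published ordering
qualitatively: the sequence-driven variants clearly beat the PSSM-only
ConvNet2, and attaching both branches does not fall below ConvNet2
alone. `run_synthetic_ablation()` packages the whole experiment.

## Cross-validation protocol

`run_cross_validation()` partitions proteins (not residues) into k folds
by a seeded uniform shuffle of the sorted ids — sorting first makes the
folds a function of the id set, not of input order — trains on k-1 folds
and evaluates the held-out fold with the full metric report. Stratified
assignment by each protein's rarest label is available (`stratify =
TRUE`) but off by default, since plain "k-fold over proteins" is the
protocol as described. Aggregates are the mean and standard deviation
across folds; the mean is asserted (to 1e-12) to equal the mean of the
per-fold values.

## Limitations

* The published benchmark scores (e.g. average precision 0.7901, ranking
  loss 0.0758, coverage 1.2848 on the 3106-protein set) were obtained on
  the deposited external datasets with GPU-scale training and
  hyperparameters that were not published; they are not reproducible at
  desk scale and this package does not claim them. A full-scale run is a
  matter of pointing `load_dataset()` at the deposited FASTA/labels,
  `cli_encode()`-ing with `l_max = 1000`, and training the default
  `model_config()` variants with fivefold `run_cross_validation()` — the
  code path is identical to the compact one, only slower.
* PSI-BLAST itself is out of scope: PSSMs are consumed, never computed.
* Sequences beyond `l_max` lose C-terminal residues, including any
  localization signal there.
* The engine is plain single-threaded C++; it is sized for the compact
  study and for full-scale *inference*, not for full-scale training.
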