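---
title: "Capsule-critic WGAN for protein function prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsule-critic WGAN for protein function prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the two-stage model, the assumptions behind each component, every tunable
parameter that matters, the numerical choices, and the limits of what the
desk-scale tests demonstrate.

## The two-stage model

**Stage 1** trains a Wasserstein GAN on one-hot encoded protein
sequences. The critic `D` approximates the Earth-Mover's distance between
the real-sequence distribution and the generator's via the
Kantorovich–Rubinstein dual

$$\min_G \max_{D \in \text{1-Lip}} \; \mathbb{E}_{x \sim p_r}[D(x)] - \mathbb{E}_{z}[D(G(z))].$$

The classical saturating GAN objective (cross-entropy between
discriminator outputs and real/fake labels) is implemented nowhere and
documented here only for contrast: Wasserstein training is the form the
method uses, because its critic gives usable gradients even when the two
distributions have disjoint support — the typical regime for discrete
sequences.

**Stage 2** treats the trained critic, minus its final linear layer, as a
feature extractor for real proteins (transfer learning), and trains a
single-layer sigmoid classifier on those features with binary
cross-entropy,

$$J(\theta) = -\tfrac{1}{m}\sum_i \big[y^{(i)} \log h_\theta(x^{(i)}) + (1-y^{(i)})\log(1-h_\theta(x^{(i)}))\big],$$

one independent output per GO class (no GO-hierarchy propagation: each
function is predicted separately, mirroring the method's design).

## Sequence representation

* Alphabet: the 20 canonical amino acids plus one padding symbol, V = 21.
  The padding symbol has index 0. Non-canonical residue codes
  (B, J, O, U, X, Z) map to padding by default; a strict mode errors
  instead, naming residue and 1-based position.
* Encoding: each sequence is truncated to `seq_len` (default 160, the
  length reported to work best for this model family) or right-padded;
  each position is a one-hot row, so every position sums to exactly 1.
  The 2,000-residue cap is a separate *dataset-level* filter applied
  before encoding, matching the method's two distinct rules.
* Decoding takes the per-position argmax (ties to the lowest vocabulary
  index) and terminates at the first padding symbol. On one-hot encodings
  of real sequences this is identical to stripping trailing padding; on
  generator outputs it additionally guarantees decoded strings never
  contain the padding character internally.

## Capsule stage

Votes, coupling, squash and routing follow the standard
routing-by-agreement scheme:

* Votes: $\hat{x}_{k|j} = W_{jk} x_j + B_{jk}$. The bias is per
  $(j,k)$ pair by default (`bias_mode = "per_pair"`); `"per_output"` ties
  it across input capsules, recovering the narrower reading of a per-$k$
  bias.
* Routing: logits $b_{jk}$ start at zero on every forward pass (routing
  is stateless across batches); each of the 3 rounds computes
  $c_{j\cdot} = \mathrm{softmax}(b_{j\cdot})$ over the *output* axis
  (so $\sum_k c_{jk} = 1$), $s_k = \sum_j c_{jk}\hat{x}_{k|j}$,
  $v_k = \mathrm{squash}(s_k)$, and, except after the last round, the
  agreement update $b_{jk} \mathrel{+}= \hat{x}_{k|j}\cdot v_k$. The
  update rule is the standard one; the source text names but does not
  write it, so it is documented here as an assumption.
* Squash: $(\|s\|^2/(1+\|s\|^2))\,s/\|s\|$. The zero vector maps to the
  zero vector exactly; an epsilon (1e-8) guards only the internal
  division. Output norms lie in $[0,1)$ and increase monotonically with
  the input norm.

Inside the critic, the capsule stage is vectorized over the batch; a
dedicated test checks it against the scalar-loop reference
implementation element by element.

## Network architectures

Both networks use six residual blocks of two same-padded 1-D
convolutions (kernel 5) with LeakyReLU (slope 0.2) and an additive skip
scaled by 0.3; kernel size, slope and skip scale are not stated by the
source and are configuration values with these defaults.

* Generator: latent vector (128) → linear to `L × d` position features →
  residual stack → per-position projection to V channels →
  Gumbel-softmax (temperature τ = 1, no annealing). By default the
  straight-through estimator is used: the emitted batch is a hard one-hot
  sample (the argmax of the Gumbel-softmax is an exact categorical
  sample) while gradients flow through the underlying softmax. This is a
  deliberate deviation from a soft-output default: with soft fake inputs
  a desk-scale critic separates real from generated batches purely by
  simplex "softness" and its transfer features carry no sequence content.
  `straight_through = FALSE` restores the soft path.
* Critic: 1-D conv (V → d) → residual stack → capsule conv sub-layer
  (stride 4, `primary_dim` channels; each retained position is one
  primary capsule) → squash → routing (3 rounds) → length layer → linear
  scalar. The reshape into primary capsules must tile the conv output
  exactly; an impossible factorization is a construction error.
* Parameter counts are reported by `count_params()` and tested against
  analytic layer-by-layer sums for small configurations. The trainable
  parameter totals printed for the original full-scale networks
  (18,447,894 and 4,029,697) are not derivable from the published
  topology description — channel widths are never stated — so they are
  reported but never asserted.

## Training

* Critic objective per update: `mean(D(fake)) − mean(D(real))` plus the
  gradient penalty `λ·mean((‖∇_x̃ D(x̃)‖₂ − 1)²)` at per-sample uniform
  interpolates, λ = 10. The penalty form is the standard soft-constraint
  variant — a λ hyperparameter only exists for that form — with weight
  clipping (`lipschitz = "clip"`) available as the alternative.
* The penalty's parameter gradient is computed by true double
  backpropagation: the autodiff engine's backward pass emits
  differentiable graph nodes, so differentiating through an
  input-gradient is exact (verified against finite differences and a
  closed-form second-order example).
* Schedule: per cycle, `n_critic = 5` critic updates share the cycle's
  real minibatch (fresh generator noise each update), then one generator
  update on `−mean(D(G(z)))`. One epoch is `⌊N/Ψ⌋` full minibatches
  (drop-last), Ψ = 32. Histories therefore hold exactly
  `epochs·⌊N/Ψ⌋·n_critic` critic entries and `epochs·⌊N/Ψ⌋` generator
  entries.
* Optimizer: RMSprop, learning rate 1e-4, alpha 0.99, eps 1e-8 — the
  published full-scale settings, kept as `gan_config()` defaults. The
  desk-scale pipeline default (`run_config()`) raises the learning rate
  to 1e-3 because its schedule has roughly 200× fewer updates than the
  full-scale one.
* Determinism: all randomness flows from `config$seed` through R's RNG;
  two runs with the same seed produce bit-identical loss histories and
  parameters (single-threaded BLAS assumed). A non-finite loss aborts
  with a reference to the last per-epoch checkpoint.

## Classifier and evaluation

* Features: the capsule length-layer outputs of real sequences — the
  literal input to the deleted final layer. `tap = "residual"` offers the
  pre-capsule pooled features for ablation.
* Classifier: one dense layer + sigmoid, binary cross-entropy (probabilities
  clamped to `[1e-7, 1-1e-7]`), Adam with lr 0.001, β₁ 0.9, β₂ 0.999
  (named but unconfigured in the source; standard defaults adopted),
  40 epochs, minibatch 32. Features are z-scored with training-fold
  statistics. Decision threshold 0.5 with ties counted positive.
* Class selection: eligibility requires ≥ 16 annotated proteins; the 25
  most frequent eligible classes are kept, ties broken lexicographically
  by GO id (the source states only "frequent"; the deterministic
  tie-break makes selection reproducible).
* Metrics: micro-averaged by default — pooled tp/fp/fn match the pooled
  notation of the defining formulas — with macro available by flag. Zero
  denominators yield 0, flagged per class. "Accuracy", where needed, is
  interpreted as label-slot accuracy, 1 − Hamming loss; the source never
  defines it, and one of its printed summary rows is internally
  inconsistent with its own printed precision/recall at 1 d.p., so
  only the comparison-table rows are used for formula consistency checks.
* Cross validation: plain shuffled repeated k-fold (k = 3, 5 repeats), no
  multi-label stratification (none is specified); fold sizes differ by at
  most one; each (repeat, fold) classifier derives its seed from the base
  seed, making whole reports deterministic.

## Synthetic corpus

The generator emulates what the pipeline needs from a real annotated
proteome and nothing more:

* background sequences drawn i.i.d. from uniform residue frequencies
  (a realistic "uniprot-like" composition preset exists; uniform is the
  default so planted motifs are the *only* learnable signal);
* one distinct k-mer motif (length 6 by default, all equal length so none
  nests in another) per class, inserted at uniform-random non-overlapping
  positions of each annotated protein — class membership is therefore
  statistically detectable from sequence content by construction;
* default design: 8 classes, 320 proteins, lengths 80–160, 1–3 labels per
  protein, balanced class weights (≈ 80 proteins per class on average).
  Balanced weights reconcile the design's per-class and total counts;
  long-tailed class structure, needed to exercise the ≥ 16 eligibility
  filter and top-25 selection, is available through `class_weights` or
  exact designed `class_counts` and is what the selection tests use;
* a JSON manifest records every planted label and motif position — the
  ground truth the tests compare against;
* `permute_labels()` breaks sequence–function association for negative
  controls while preserving per-class counts exactly (a full permutation
  followed by pair swaps that repair duplicate pairs).

It does not imitate real protein domain grammar, homology families or
secondary structure; passing tests show the pipeline recovers *planted
compositional/motif* signal, not that it predicts real GO annotation.

## Problem sizes and what the desk scale shows

The default pipeline configuration (width-16 networks, 2 epochs, 320
proteins, sequence length 160) runs in minutes on one CPU; the module
tests use far smaller instances (sequence lengths 12–48, widths 6–8).
These sizes are the package's chosen study conditions for a tested,
reproducible artifact.

One consequence is documented openly: after two desk-scale epochs the
critic remains close to its random initialization, and its capsule-length
features summarize little beyond pooled residue composition. On the
default design the end-to-end micro-F1 exceeds the label-permuted
control only modestly — far short of what motif-specific features would
give (a probe with oracle motif-indicator features reaches micro-F1 1.0
through the same classifier and CV machinery, and even oracle
*composition* features reach only ≈ 0.40). Closing that gap requires
adversarial training on the order of the original full-scale schedule
(thousands of updates on tens of thousands of proteins), which is
precisely the regime this package does not attempt to reproduce. The
acceptance suite therefore contains one deliberately strict end-to-end
recovery check that fails at desk scale and is kept failing rather than
weakened; every component-level property it depends on (gradient
exactness, routing equivalence to the scalar reference, metric
identities, determinism, better-than-chance feature probes) passes.

## Known limitations

* No mixed-precision, no parallelism; the autodiff engine favors
  correctness and testability over speed.
* Checkpoints are R serializations plus JSON manifests; they are
  runtime artifacts, not an interchange format.
* The capsule module implements vector capsules with dynamic routing
  only — no EM routing, matrix capsules, or margin loss.
* GO identifiers are opaque labels; no ontology graph, no true-path
  propagation, no protein-centric (CAFA-style) metrics.
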