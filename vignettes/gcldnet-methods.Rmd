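---
title: "Lesion segmentation with level feature aggregation and attention feature fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion segmentation with level feature aggregation and attention feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Histopathological examination of H&E-stained tissue is the gold standard for
diagnosing gastric cancer, and delineating the lesion region pixel-by-pixel is
the task that most directly supports a pathologist's reading. Lesions vary
enormously in size and shape, and the surrounding tissue contains structures
that mimic lesion texture, so a plain encoder–decoder (U-Net-style) network
often under-uses the information in its deeper feature maps. `gcldnet`
implements a segmentation architecture built around two ideas: a decoder that
**aggregates features across every level and position** of the decoding
lattice, and a fusion head that applies **channel attention per scale** before
merging multiscale features. Training uses the **focal Tversky loss**, which
weights false negatives and false positives asymmetrically and focuses the
loss on hard, low-overlap images.

Because the network, its initialisation, its optimiser, and its gradients are
implemented in this package (reverse-mode autodiff over im2col/col2im
convolution kernels; no external deep-learning framework), every quantity the
package reports is reproducible to the bit given a seed.

## Architecture

### Encoder

Six feature maps $X^{i,1}$, $i = 1..6$, at spatial sizes $\mathrm{input}/2^{i-1}$.
Level 1 is computed at full resolution by a stride-1 double-conv block —
the decoder's level-1 aggregation needs a full-resolution $X^{1,1}$ — and each
deeper level halves the grid once with a stride-2 convolution followed by a
stride-1 convolution. Every convolution is followed by ReLU and batch
normalisation. The bundled backbone (`"smallconv"`) is deliberately small and
pretrained-free so that training is feasible on one CPU; per-level widths
$C_1..C_6$ are configurable. Large pretrained backbones are out of scope for
this package: no weights are bundled, and `encoder_spec()` says so explicitly
when one is requested.

### Level feature aggregation (LFA)

The decoder is a lattice $X^{i,j}$ ($i$ = level, $j$ = position), filled
bottom-to-top and left-to-right:

1. From the deepest map $X^{6,1}$, a chain of five transposed convolutions
   (kernel 4, stride 2 — exact doubling) produces $X^{5,2}, X^{4,2}, \dots, X^{1,2}$.
2. At level 5 everything present is concatenated channel-wise:
   $X^{5,3} = X^{5,1} \oplus X^{5,2}$.
3. A new chain rises from $X^{5,3}$ (nodes $X^{i,3}$), then level 4 is
   aggregated: $X^{4,4} = X^{4,1} \oplus X^{4,2} \oplus X^{4,3}$; and so on,
   ending with $X^{1,6} = X^{1,1} \oplus X^{1,2} \oplus \cdots \oplus X^{1,5} \oplus X_U^{1,6}$.

The five aggregated maps $X^{1,6}, X^{2,6}, X^{3,5}, X^{4,4}, X^{5,3}$ are the
decoder's output. Aggregation is concatenation only — no post-concatenation
fusion convolution — so channel counts follow
$C^{agg}_i = C_i + (6 - i)\,d_i$, where $d_i$ is the width every chain node
landing on level $i$ is projected to.

Design points the architecture description leaves open, and the choices made
here:

* **Chain widths $d_i$** are not published. Default: $\lceil C_i / 2 \rceil$,
  configurable (including a single shared width). This bounds the channel
  growth of pure concatenation.
* **One shared chain with labelled intermediates** — the chain equations name
  the same intermediate maps in several compositions, which we read as one
  chain per aggregation round, not independent chains; weights are independent
  across steps and rounds.
* Each transposed convolution is followed by ReLU and batch normalisation,
  matching the conv–activation–BN pattern used elsewhere in the network.
* The activation $f$ is ReLU throughout (the architecture description writes
  $f(\cdot)$ without naming it).
* Concatenation order is the $k$-index order of the aggregation formula
  (encoder map first, then chain arrivals oldest-first), fixed for
  reproducibility.

### Attention feature fusion (AFFM)

Per aggregated scale $i$:

1. $X^{i,U}$: bilinear upsampling to input resolution (half-pixel centres).
2. $X_C = f(X^{i,U} * W + b)$: a 3×3 convolution with ReLU, then
   $X_B = \gamma (X_C - E) / \sqrt{\mathrm{Var} + \varepsilon} + \beta$: batch
   normalisation (batch statistics during training, running statistics at
   inference, $\varepsilon = 10^{-5}$).
3. Channel descriptors by global average and global max pooling of $X_B$,
   pushed through a **shared** bottleneck MLP (hidden width
   $\lceil C/r \rceil$, ReLU — the hidden activation is unstated in the
   architecture description; ReLU is the standard choice in channel
   attention); the two outputs are summed and squashed:
   $W_A = \sigma(\mathrm{MLP}(P_{Avg}) + \mathrm{MLP}(P_{Max})) \in (0,1)^C$.
4. $X^{i,A} = W_A \otimes X^{i,U}$ — the attention weights multiply the
   **upsampled** map, not the conv output they were computed from. This
   asymmetric wiring is kept exactly as specified. It forces a shape
   constraint: $W_A$ has the width of $X_B$, so the 3×3 convolution must
   preserve its channel count; the per-scale conv width therefore defaults to
   the scale's aggregated width rather than being freely configurable.

The fused feature is the concatenation $X^F = \oplus_i X^{i,A}$, and a 1×1
convolution + sigmoid head turns it into a per-pixel lesion probability.
With attention disabled the module reduces exactly to plain multiscale
upsample-and-concatenate, which is what the ablation configuration uses.

### Variants

`build_model()` assembles three variants with identical input/output
contracts, mirroring the ablation ladder: `baseline` (encoder + U-Net-style
decoder), `baseline+lfa`, and `baseline+lfa+affm`.

## The focal Tversky loss

With per-pixel foreground probabilities $p_{1i}$ ($p_{0i} = 1 - p_{1i}$) and
one-hot ground truth $g_{1i}, g_{0i}$:

$$TI = \frac{\sum_i p_{1i} g_{1i} + s}{\sum_i p_{1i} g_{1i} + \alpha \sum_i p_{1i} g_{0i} + \beta \sum_i p_{0i} g_{1i} + s},
\qquad L = (1 - TI)^{1/\lambda}.$$

In this pixel form $\alpha$ weights the false-positive mass $p_1 g_0$ and
$\beta$ the false-negative mass $p_0 g_1$. At $\alpha = \beta = 0.5,
\lambda = 1$ the loss is *exactly* the soft Dice loss (the package's Dice loss
uses the same smoothing constant $s$, so the identity is exact, not
approximate). $\lambda > 1$ flattens the loss near $TI = 1$, which keeps
nearly-solved images contributing — "hard example mining". The recommended
range is $\lambda \in [1, 3]$; defaults are $\alpha = 0.7$, $\beta = 0.3$,
$\lambda = 4/3$ (the convention of the focal-Tversky literature; the values
used in the original experiments are unpublished), and $s = 10^{-6}$, which
defines the doubly-empty case as $TI = 1$.

Closed-form gradients treat $p_1$ and $p_0$ as independent inputs:

$$\frac{\partial L}{\partial p_{1i}} = -\frac{1}{\lambda}(1 - TI)^{1/\lambda - 1}
  \frac{g_{1i}\,\mathrm{den} - (g_{1i} + \alpha g_{0i})\,\mathrm{num}}{\mathrm{den}^2},
\qquad
\frac{\partial L}{\partial p_{0i}} = \frac{1}{\lambda}(1 - TI)^{1/\lambda - 1}
  \frac{\beta\, g_{1i}\,\mathrm{num}}{\mathrm{den}^2}.$$

The signs follow from differentiating $L$ directly: the first is $\le 0$
(raising a foreground probability on a true-foreground pixel lowers the loss)
and the second $\ge 0$. The factor $(1 - TI)^{1/\lambda - 1}$ is singular at
$TI = 1$ for $\lambda > 1$; `ftl_gradients()` reports that case as a typed
condition (`gcld_ftl_singular`), and the trainer substitutes the zero
gradient, which is the correct descent direction at the loss minimum. The
test-suite verifies these formulas against reverse-mode autodiff and central
finite differences on random inputs.

Training uses the analytic gradient at the probability layer and
backpropagates through the network on the tape; the same mechanism serves
Dice, BCE and Dice+BCE losses for the loss-comparison interface.

## Training protocol

* SGD with momentum 0.9 (momentum and weight decay are unstated in the
  protocol this follows; 0.9 and 0 are the customary defaults), batch size 6.
* Reduce-on-plateau schedule monitoring the test-split Dice: after 5
  consecutive epochs without strict improvement the rate is halved, floor
  $10^{-6}$. The schedule is a pure state machine (`plateau_scheduler()`/
  `plateau_step()`) so the halving rule is unit-testable in isolation.
* **Deep supervision** ("joint collaborative training"): each aggregated map
  gets an auxiliary 1×1-conv + sigmoid head, upsampled bilinearly to full
  resolution. The reference protocol gives no loss weights; each auxiliary
  head gets relative weight `aux_weight` (default 0.25) against 1 for the
  main head, normalised to sum to 1. The default keeps the main head
  dominant — with equal weights the main head receives only $1/(k+1)$ of the
  gradient signal, which measurably slows its convergence in short runs;
  `aux_weight = 1` restores the equal scheme. Auxiliary heads exist only in
  the training graph — inference always uses the main head alone.
* Augmentation: random horizontal/vertical flips (applied jointly to image
  and mask) and per-channel sample centering.
* The protocol monitors the test split, as the original training protocol
  implies (8:2 split only, no third partition); a held-out validation list
  can be supplied instead.
* Full-scale defaults (`train_config()`): 150 epochs, initial rate $10^{-2}$.
  These reproduce the reference protocol for large-scale runs.

### Scaled-down study conditions

All shipped experiments run on one CPU, so the package's test-suite and
`scripts/acceptance.R` use a reduced configuration chosen once: encoder
widths (3, 4, 6, 8, 10, 12), shared chain width 2, attention reduction
$r = 4$, 128×128 images, 100 samples split 80/20. The absolute-performance
run on the easy preset trains 7 epochs at rate 0.1; the ablation runs on
the hard preset train 6 epochs per seed at rate 0.05 (the harder task
benefits from the gentler rate — at 0.1 its epoch-to-epoch Dice trajectory
is visibly noisy). These rates are higher than the full-scale default
because the scaled-down networks are orders of magnitude smaller and train
for a handful of epochs; $10^{-2}$ barely moves such a network from its
initialisation in that budget. None of the loss/architecture parameters
change between the two regimes.

## The synthetic generator

`generate_dataset()` emulates the gross structure of gastric-cancer
histopathology fields so that every module is exercisable without external
data: a pink stroma background with coarse and fine random texture; lesions
as unions of 1–4 overlapping ellipses with sinusoidal boundary perturbation,
colour-shifted toward dense-nuclei purple and carrying a fine speckle
texture (dense nuclei); and distractor structures that take the *lesion*
hue while keeping the smooth background texture. Colour thresholding
therefore produces false positives on distractors and the task needs
texture and spatial context — the regime in which multiscale aggregation
and attention have something to contribute. Masks are the exact lesion
support. Two presets define the study conditions: `"easy"` (colour shift
0.35, 0–2 distractors at half the lesion hue shift, noise sd 0.04) for
absolute-performance checks, and `"hard"` (colour shift 0.16, 2–5
distractors at 0.8 of the lesion shift, noise sd 0.08, lesion radii 6–30%
of the image side) for the ablation-ordering experiment.

What the generator does **not** emulate: nuclear morphology, staining
variability between laboratories, scanner artefacts, tissue folds, or the
annotation noise of real datasets. Passing the shipped experiments
demonstrates that the architecture, gradients and training loop work as
specified — it does not certify clinical performance; the reported
full-scale numbers of the reference experiments require the original
datasets and GPU-scale training, both outside this package's scope.

## Numerical choices

* **Smoothing** $s = 10^{-6}$ in Tversky numerator and denominator; the same
  constant in the Dice loss preserves the FTL–Dice identity exactly.
* **Batch norm**: population variance, $\varepsilon = 10^{-5}$, running-stat
  momentum 0.1; batch statistics in training, running statistics at
  inference.
* **Bilinear resize** uses half-pixel centres with clamped edges; nearest
  neighbour for masks so they stay strictly binary.
* **Binarisation** threshold 0.5 with ties to foreground (`>=`).
* **Attention weights** are clamped to $[10^{-12}, 1 - 10^{-12}]$ after the
  sigmoid: in double precision a saturated sigmoid rounds to exactly 0 or 1,
  which would break the documented open-interval invariant; the true
  derivative in that regime is below $10^{-17}$, so the clamp is
  training-neutral.
* **Degenerate metrics**: empty ground truth met by an empty prediction
  scores 1 on every metric; an empty prediction against a non-empty ground
  truth scores DSC = JI = PRE = 0. Documented and tested.
* **Initialisation**: He-normal fan-in for conv/dense weights, zero biases,
  BN $\gamma = 1$, $\beta = 0$; all draws come from seeded RNG streams, and
  generation, splitting, initialisation and training each take explicit
  seeds, so runs are bit-reproducible.
* **Transposed convolutions** are implemented as the exact adjoint of the
  stride-2 convolution (kernel 4, stride 2, padding 1), so upsampling doubles
  the grid exactly and the adjoint identity
  $\langle \mathrm{conv}(y), x\rangle = \langle y, \mathrm{conv}^T(x)\rangle$
  holds to machine precision.

## Known limitations

* The bundled encoder is not a pretrained large-scale backbone; absolute
  performance on real histopathology data is not comparable to GPU-scale
  results, and no claim of that kind is made.
* Dataset-level metrics default to the mean of per-image metrics (pooled
  aggregation is available behind a flag); which convention the reference
  experiments used is unstated.
* Double-precision CPU tensors throughout: correct and reproducible, but not
  fast. The intended problem sizes are the scaled-down conditions above.
* BN statistics are shared across deep-supervision and main paths; with very
  small batches the running statistics are noisy, which is the usual
  small-batch BN caveat.
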