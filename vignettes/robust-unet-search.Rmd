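---
title: "Searching robust U-Net architectures for MR-to-CT synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching robust U-Net architectures for MR-to-CT synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robunet)
```

## The problem

Encoder-decoder networks that synthesize CT images from MR slices are
accurate on clean inputs but can be brittle: a single-step adversarial
perturbation of the input - invisible to a reader - can badly corrupt the
synthesized Hounsfield values, especially in thin, high-contrast structures
such as bone.  The usual remedy, adversarial training, buys robustness at
some cost in clean accuracy and at roughly twice the training cost.

`robunet` takes the alternative route: treat robustness as a property of the
*architecture* and search for it.  The package defines a categorical space
of U-Net-style genotypes, estimates each candidate's robustness cheaply on a
small "subdataset", and drives the search either by uniform sampling
(best-of-N) or by a Tree-structured Parzen Estimator (TPE) that learns which
regions of the space produce robust networks.

## The architecture space

Each network is described by a *genotype*: a depth $d \in \{1,\dots,5\}$ and
one block configuration per encoder and decoder position.  A block has

* a **connection pattern**: a 4-bit mask over the branches $A_1,\dots,A_4$
  of an Inception-style multi-branch module (at least one branch active,
  hence 15 patterns, written `"0001"` to `"1111"` with $A_1$ the most
  significant bit);
* a **filter count** from $\{8, 16, 32, 64, 128, 256\}$;
* an optional **squeeze-and-excitation (SE)** gate with reduction ratio in
  $\{2, 4, 8, 16\}$.

That gives $15 \times 6 \times (1 + 4) = 450$ block configurations and

$$|\mathcal{X}| = \sum_{d \in \{2,3,4,5\}} 450^{2d}
  = 450^4 + 450^6 + 450^8 + 450^{10} \approx 3.4\times10^{26}$$

architectures in the canonical search configuration.  The exact count
exceeds the integer range of doubles, so the package carries a minimal
arbitrary-precision integer type and computes it exactly:

```{r}
sp <- unet_space()
count_block_configs(sp)
count_search_space(sp)
```

Depth 1 is supported by the type but the canonical configuration searches
depths 2-5, matching the closed form above; including depth 1 adds only
$450^2$ and does not move the headline count.

### From genotype to network

A block runs: multi-branch module $\rightarrow$ point-wise $1\times1$
fusing convolution $\rightarrow$ resolution stage $\rightarrow$ $3\times3$
convolution $\rightarrow$ optional SE gate, with ReLU after every
convolution and "same" padding throughout.  The resolution stage is a
kernel-4 stride-2 convolution in encoders (halving H and W) and nearest
$2\times$ upsampling in decoders.  Decoder $j$ consumes the concatenation
of the previous stage's output with the skip tensor from its mirror
encoder $d-j+1$; decoder 1 is the deepest, first-applied decoder.  A final
linear $1\times1$ convolution produces the output in normalized CT units.

Several elements of the block are only constrained loosely by the
literature this design descends from, so the package fixes them as its own
design choices:

* branch operators: $A_1 = 1\times1$ conv, $A_2 = 3\times3$ conv,
  $A_3 = 5\times5$ conv factorized as two $3\times3$s, $A_4 = 3\times3$
  max-pool followed by a $1\times1$ conv - an Inception-V3-flavoured
  palette; each active branch emits the block's full filter count and the
  fusing convolution maps the concatenation back down;
* no batch normalization and no dropout (smallest assumption set; the
  attack and its gradient stay exact in inference mode);
* upsampling is nearest-neighbour (cheap, artifact-free for regression);
* the SE bottleneck width is clamped to $\max(1, C/r)$, so every ratio in
  the candidate set is admissible for every filter count.

The networks are built on the package's own convolution engine
(im2col + BLAS with hand-written reverse-mode backward passes), which
provides exact gradients with respect to **both** the weights (training)
and the input pixels (attack generation).  Gradient correctness is pinned
by finite-difference tests at $10^{-3}$ relative tolerance.

## The attack and the two training regimes

The fast gradient sign method perturbs an input slice $S$ with target $T$
as

$$S_{adv} = S + \varepsilon\,\mathrm{sign}(\nabla_S\, l(S, T)),$$

with $l$ the training loss (MSE).  No clipping is applied: the MR inputs
are z-scored and unbounded, and the formula carries no projection.
`sign(0) = 0`, so zero-gradient pixels are untouched, and $\varepsilon = 0$
is the identity.

Training always uses Adam with the AMSgrad correction, learning rate
$10^{-4}$, batch size 6 and MSE loss.  Two regimes exist:

* **regular**: up to 150 epochs with early stopping (patience 5) on the
  validation loss; the returned weights are the arg-min-validation
  checkpoint;
* **adversarial**: the per-sample loss is replaced by
  $\tilde l(S,T) = \beta\, l(S,T) + (1-\beta)\, l(S_{adv},T)$ with
  $\beta \sim \mathrm{Bernoulli}(p_r)$ drawn independently per sample
  ($p_r = 0.5$, $\varepsilon = 0.2$ by default).  Gradients are not
  propagated through attack generation, and the same early-stopping rule
  applies.  Checkpoint selection uses the clean validation MSE in both
  regimes, so the two fits are selected by the same criterion.

## Robustness estimation and the search

Each candidate is scored by the *subdataset protocol*: six training
subjects split 4:1:1 into train/val/test; ten inner training epochs with a
weight snapshot after every epoch; the snapshot with minimal validation
loss is evaluated on the subdataset test slices perturbed by FGSM at
$\varepsilon = 0.2$.  The default metric is the Dice coefficient of the
bone region (the region most damaged by attacks and the one used to select
models for reporting); MAE-based objectives are negated so that the search
always maximizes.  A diverging inner training scores $-\infty$ with a flag
and the search continues.

Two strategies consume this objective:

* `random_search()` - N independent uniform genotypes, best-of-N;
* `tpe_search()` - after `n_startup` uniform trials, the history is split
  at the $\gamma$-quantile of the objective into good and bad sets;
  smoothed categorical densities $l$ (good) and $g$ (bad) are fit for
  every variable along the tree (depth at the root, per-position block
  fields conditional on the depth reaching that position, SE ratio
  conditional on the SE flag); `n_candidates` draws from $l$ are ranked by
  $\prod l/g$ over their active variables and the best is proposed.

The TPE's free parameters are design choices, exposed in `tpe_config()`:
$\gamma = 0.25$, 20 startup trials, 24 candidate draws, and add-one-style
smoothing with total prior weight 1 spread uniformly over each categorical
domain.  The smoothing keeps both densities proper when the good/bad split
is degenerate (all-equal objectives), in which case the suggestion
distribution collapses toward uniform sampling.  Inactive variables
(blocks beyond the sampled depth, ratios with SE off) contribute neither
density terms nor score terms.

The full protocol repeats each search several times (15 at study scale),
retrains every repeat's best genotype on the full training data with the
regular regime, and selects the arg-max of test-set robustness - by
default at the milder reporting magnitude $\varepsilon = 0.06$ on the bone
region.

## Synthetic cohort

The institutional MR/CT pairs behind the original study are not
redistributable, so the package generates paired head phantoms that
reproduce exactly the features the pipeline depends on:

* three HU regimes by construction - air background at $-1000$, a skull
  ring in $[900, 1500]$, soft-tissue interior in $[0, 80]$ - so the region
  masks (air $< -500$, bone $> 500$, soft $(-500, 300)$, whole head
  $\ge -500$) are well separated;
* per-subject elliptical geometry with smooth radius drift across the 182
  axial slices of each volume;
* an MR appearance that is a *non-monotone* function of tissue class
  (air and bone dark, soft tissue bright), corrupted by a multiplicative
  bias field and additive Gaussian noise - so the MR-to-CT map is
  learnable but not a pixel-wise intensity transform;
* the study's preprocessing: volume-wise z-scoring of MR, and CT shifted
  by $+1000$ then standardized with fixed mean 1250 and deviation 2500
  (air maps to $-0.5$; the shift direction is chosen so the fixed mean
  lies inside the data range, and the inverse used by the metrics is the
  exact inverse of whatever is configured).

The cohort defaults mirror the study: 63/9/7 train/val/test subjects of
182 slices, giving 11466/1638/1274 images, with the 6-subject 4:1:1
subdataset drawn from the training split.  Resolution is configurable
(default 256); no package quantity depends on it, so tests run at 8-64
pixels.  What the phantoms do **not** emulate: real anatomy, registration
error, scanner-specific noise spectra, or partial-volume effects at tissue
boundaries.  Passing tests therefore demonstrate that the machinery -
attack, training, metrics, search - behaves correctly and that the
qualitative robustness phenomena reproduce on a learnable synthesis task;
they say nothing quantitative about clinical data.

One liberty is taken with the generator's preconditions: slices may be as
small as $8\times8$ (the cohort-counting checks run at that size), while
running a depth-$d$ network requires the side length to be divisible by
$2^d$, enforced with a clear error at forward time.

## Metrics and reporting

All metrics pool the full 3D volume per subject.  Dice for a region
compares the mask thresholded from the *prediction* against the mask
thresholded from the *ground truth*; MAE averages over the ground-truth
mask only, so it cannot be improved by mis-predicting the mask.  Two
conventions: both-empty Dice is 1 (correct absence is rewarded), and an
empty ground-truth region yields a missing MAE rather than 0.  The
published region definition for air ("HU < 500") overlaps soft tissue and
bone verbatim; it is treated as a typo for $< -500$ and the threshold is
configurable.  Paired model comparisons use the Wilcoxon signed-rank test
(exact null for small untied samples) with Bonferroni correction, n = 3 by
default.

## Problem sizes in the tests and the acceptance script

The package's own checks run at desk scale, chosen once as part of the
test design: cohort counting at $8\times8$; gradient and attack oracles at
$8\times8$-$32\times32$; the TPE-vs-random benchmark on a training-free
surrogate objective (negative Hamming distance to a hidden genotype,
depth 3, budget 60, 15 paired repeats); the adversarial-training contrast
with a tiny two-block genotype at $32\times32$, 25 epochs, 5 seeds, with
robustness read on the whole-head region (bone Dice at this scale is too
noisy to order reliably); and an end-to-end smoke experiment with 8
subjects of 16 slices at $32\times32$, search budget 5 with 2 repeats over
a reduced space (filters 8/16, depths 1-2), learning rate $3\times10^{-3}$
to converge within a handful of epochs.  The smoke experiment is run twice
to confirm bit-identical summaries under a fixed seed.

## Known limitations

* The engine is plain R + BLAS: fine for the desk-scale protocol,
  impractical for 256-filter depth-5 networks at $256\times256$ - the
  full-scale study conditions are expressible in `experiment_config()` but
  assume serious compute.
* Only FGSM and Gaussian corruption are implemented; iterative attacks
  (PGD and relatives) are out of scope, as are 3D architectures,
  transformer blocks, weight-sharing supernets and differentiable search.
* The handcrafted "Baseline" genotype is a documented stand-in (all four
  branches active, no SE), not a reproduction of any published network.
* The Bernoulli mixing draws $\beta$ per sample, checkpoint selection uses
  clean validation MSE, and attacks are generated per slice with the model
  in inference mode - all stated choices where the protocol admits
  alternatives.
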