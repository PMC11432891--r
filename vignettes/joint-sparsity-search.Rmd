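---
title: "Joint sparsity search and direction-field refinement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint sparsity search and direction-field refinement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transformer-based segmentation models for cardiac cine-MR carry far more
parameters than the task needs, and the surplus is not uniformly
distributed: individual feature dimensions inside attention heads, hidden
units of the MLP blocks, and many patch tokens contribute little to the
final Dice score. `vitslim` implements a single-round, differentiable
architecture search that scores all three kinds of sites at once and then
physically slices a compact subnet out of the trained "supernet", plus a
directional-field (DF) module that repairs the boundary-pixel errors that
compression tends to amplify.

## The search model

Every searchable linear layer is stored once at its maximal width (the
super-weight matrix); a candidate narrower layer is a slice of it. A
learnable mask multiplies *activations*, not weights:

* `z_a[l,h] ∈ R^d` multiplies the biased projections `q_i`, `k_i`, `v_i`
  of head `h` in layer `l` (the same vector multiplies all three), so
  `A_i = softmax((q_i z)(k_i z)^T / sqrt(d))` and `O_i = A_i (v_i z)`.
  The softmax temperature keeps the full `sqrt(d)` with no
  mask-dependent correction.
* `z_m[l] ∈ R^M` multiplies the post-ReLU hidden activation of the MLP:
  `t_e = relu(f1(t)) · z_m`, `t_out = f2(t_e)`.
* a patch score per (layer, token) scales the token row at the entry of
  each encoder block through `tanh`, which bounds the multiplier in
  (−1, 1) and keeps patch masks from exploding.

Masks start at 1 and are co-trained with the weights by AdamW under

    L = CE(f(x), y) + w_mhsa Σ|z_a| + w_mlp Σ|z_m| + w_patch Σ|tanh(z_p)|

The penalty is added once per optimization step, not per pixel. After
training, every site is ranked by `|z|` (`|tanh z|` for patches) and the
bottom of each ranking is dropped to meet a per-kind budget; kept counts
are `ceiling(fraction × total)` so a stated budget is never undershot, and
the ranking is global across layers and heads, which is what allows
different heads to end up with different widths. Ties are broken by
(layer, head, index) so extraction is deterministic.

Scoring by magnitude rather than signed value is deliberate: the penalty
drives magnitudes toward zero, and a negative mask of large magnitude
still transmits signal, so elimination should target low influence, not
low signed value.

### Why magnitudes separate used from unused sites

Under AdamW the penalty's contribution to a mask update is normalized by
the running RMS of that mask's gradient. Two consequences shape the
defaults:

* the search must start from *converged* ("pretrained") weights — the
  three-step workflow is search on a pretrained model, budget selection,
  retraining. On a converged model the cross-entropy gradient of an
  unused dimension's mask is near zero, so the penalty moves it at the
  full learning rate, while used dimensions are held in place by the
  restoring cross-entropy gradient;
* many small steps beat few large ones: the penalty drift accumulates
  linearly in the step count while the gradient-noise random walk grows
  only with its square root. The planted-importance harness therefore
  uses minibatches of 4 sequences.

## Subnet extraction

Extraction slices the kept columns of the q/k/v projections (with their
bias entries), the matching projection rows, and the kept MLP hidden
units; heads whose whole dimension set is dropped disappear entirely.
Eliminated patches leave the token sequence at the first layer where they
die; because the search is global, a patch can occasionally die in a
shallow layer yet survive a deeper ranking, so a monotonicity pass
replaces each layer's kept set with its running intersection before
slicing (removals only). The decoder needs a full spatial grid, so dead
positions contribute zero vectors when tokens are re-assembled — exactly
the zero-mask limit of the search phase. In the binarized masked
reference forward, a dead patch is excluded from the attention softmax
(logit −∞) and its row zeroed; with that convention, slicing and
binarized masking agree to float round-off, which the test suite asserts
at 1e-4.

Parameter accounting is closed-form — each kept MHSA dimension costs
`3(D+1) + D` parameters, each MLP hidden unit `(D+1) + D` — and is tested
against exhaustive tensor enumeration. FLOPs are reported as
multiply–accumulate operations (1 MAC = 1 FLOP, stated in every report):
token-wise linear terms scale with the per-layer live patch count `N_l`,
attention score/apply terms with `N_l²`. Absolute FLOP or parameter
figures of full-scale cardiac models are not comparable to this
desk-scale encoder and are not reproduced here.

## The direction-field module

The ground-truth field assigns every tissue pixel the unit vector from
its nearest same-class boundary pixel toward the pixel (inward); boundary
and background pixels get (0, 0), so field magnitudes are exactly 0 or 1.
A boundary pixel is a tissue pixel with a 4-connected neighbor of a
different class; pixels on the image edge count as boundary. The nearest
boundary site is found by exact Euclidean search per class region, with
ties broken by the first minimizer in column-major order (the test oracle
compares distances, not indices). Orientation is chosen inward because
the correction walks information from the confident interior outward;
the defining equation is ambiguous about the arrow's direction but the
narrated behavior is not.

The learned head is a 1×1 convolution from the 64-channel pre-classifier
feature map to 2 field channels, with no activation, trained by
mean-squared error against the ground-truth field *restricted to tissue
pixels* (background targets are zero vectors and would otherwise dominate
the loss); the field loss is added to the segmentation cross-entropy with
weight 1.0. Correction iterates

    F_i(p) = F_{i-1}(p_x + D(p)_x, p_y + D(p)_y),  i = 1..N,  N = 5

with bilinear interpolation at the displaced location, border clamping,
and the field held fixed across iterations; pixel centers sit at integer
(x = column, y = row) coordinates, 0-based. Because the displacement is
fixed, each iteration is the same sparse linear operator, which is also
how the gradient is propagated (its transpose). The rectified map `FN'`
is concatenated with `FN` and a final 1×1 convolution produces the class
scores.

Two further choices matter:

* the cross-entropy gradient is not propagated through the predicted
  displacement; the field head learns only from the field regression
  loss. This keeps the rectification a geometric operation rather than a
  free-form attention-like mixer, and it decouples the two losses.
* when the DF module is attached to an already-trained model
  (`add_df_module()`), the existing classifier becomes the `FN` head and
  the fusion is initialized as a pass-through of `FN` (identity on the
  first C channels, zeros on the rectified block). The augmented model
  therefore starts out computing exactly what the plain model computed,
  and training mixes in the rectified path only where it helps. Without
  this identity initialization the DF variant starts from a random
  classifier and, at desk scale, needs more epochs than the comparison
  grants it.

A prose description of an alternative correction procedure (thresholding
vector lengths and walking through 8-neighborhoods until the central
region is reached) accompanies the defining equation in the source
material but never states its threshold and does not match the fixed-N
bilinear iteration; only the equation is implemented.

## The encoder around the search

The full segmentation model is: linear patch embedding (8×8 patches), `L`
pre-activation-free residual encoder blocks (MHSA + MLP, as above), a
1×1-conv decoder from final tokens to a 64-channel map bilinearly
upsampled to the input grid, plus a learnable per-channel skip of the raw
image for full-resolution detail, ReLU, and the classifier or DF triple.
Two deliberate simplifications relative to full-scale hybrid
encoder–decoders:

* no LayerNorm: the masked forward equations contain no normalization,
  and omitting it makes the slicing–masking equivalence exact rather
  than approximate. At 2 layers with sd-0.02 initialization, training is
  stable without it.
* the convolutional stem and multi-stage skip decoder of full-scale
  models are replaced by the linear embedding and the single image skip;
  only the search and DF mechanisms are the scientific surface here, and
  every mechanism (super-weights, masks, slicing, rectification) is
  exercised unchanged.

## Synthetic data

`generate_phantom()` emulates short-axis cardiac anatomy: a bright LV
blood pool inside a mid-grey myocardial ring (the ring lies strictly
between the LV interior and background by construction), with a darker
crescent-shaped RV pool adjacent to the ring, randomized centers, radii,
aspect ratios and intensities, Gaussian boundary blur (σ 1 px) and
additive Gaussian noise (σ 0.05), clamped to [0, 1]; labels are the
pre-blur geometry. This reproduces the statistical features the method
assumes — blurred boundaries, similar grey values between classes, noise
— but not MR physics (no bias fields, no coil profiles, no pathology
subgroups, no through-plane anisotropy), so passing benchmarks here show
the machinery works as specified, not that the method reaches any
particular accuracy on real cine-MR.

`generate_planted_task()` builds the search-validation task: a frozen
weight construction routes `k` designated MHSA head dimensions (split
across layers, since without residual bypass the signal must traverse
every layer) so that exactly those dimensions carry the label: value
projections read per-sequence signal components from the first token
coordinates, zero q/k weights make attention uniform so mean pooling
preserves the per-sequence signal, the MLP is initialized to the exact
ReLU identity `f2([I;−I] relu) ∘ f1 = id`, and the classifier is the
informed (pretrained) readout of the pooled signal coordinates. Non-signal
dimensions carry independent noise coordinates. Defaults: 256 sequences
of 8 tokens, effect size 1.0, token noise 0.5 — strong enough that a
linear probe on the signal coordinates reaches ≥95% accuracy while one
on noise coordinates stays near chance, which the tests verify.

## Problem sizes and optimizer defaults

All training is plain R matrix algebra with a hand-derived backward pass
(verified against central finite differences in the suite), so problem
sizes are chosen for minutes-scale CPU runs:

* benchmark phantoms: 200 images at 32×32, patch 8 (16 tokens), split
  7:1:2; encoder `L = 2`, `H = 2`, `d = 10` (`D = 20`), `M = 40`,
  64-channel decoder features, 4 classes. `d` and `M` are chosen so that
  70% budgets are exact integers: extraction at 70/70/60 removes exactly
  30% of searchable parameters.
* workflow: 50 search epochs, budget selection, 50 retraining epochs,
  AdamW throughout; learning rate 3e-3 and batch 32 for the phantom
  benchmark (1e-3 converges visibly slower at this scale), weight decay
  1e-2 applied decoupled to weight matrices only — never to masks (the
  L1 penalty is the only shrinkage applied to them) and never to biases.
* sparsity weights default to `w_mhsa = 2e-4`, `w_mlp = 4e-4`,
  `w_patch = 1e-4` (the best-performing row of the weight exploration;
  the accompanying prose cites `4e-5` for the MLP weight once, which
  contradicts that table and is taken to be a typo — both values are
  accepted via configuration).
* planted-importance harness: 30 search epochs, batch 4 (see above),
  learning rate 1e-3.
* the benchmark runs one search to define the subnet (mirroring the
  published workflow, where one search produces the architecture that is
  then studied) and repeats only the seeded retraining comparison of the
  DF-enabled versus DF-disabled compact model.

## Numerical choices and degenerate inputs

* Softmax rows are stabilized by subtracting the row maximum; excluded
  (dead) keys carry −∞ logits and exactly zero attention.
* `ceiling` budgets guarantee at least one site per kind survives any
  valid budget; budget fractions must lie in (0, 1].
* Empty label masks yield an all-zero ground-truth field; regions whose
  pixels are all boundary have no interior and contribute zero vectors.
* Two empty sets define DSC = 1 (predicting absence correctly is not an
  error); mean DSC is the unweighted mean over tissue classes, background
  excluded, and per-image and per-class aggregations are both reported
  because averaging order is a reporting choice, not a model property.
* Non-finite activations or losses abort with the epoch and term named;
  nothing is clipped silently.
* All randomness is seeded through scoped RNG (`withr`), so every
  generator, search and benchmark is bit-reproducible from its seed.

## Known limitations

* The encoder is a small stand-in, not a hybrid ResNet–ViT at ImageNet
  scale; absolute DSC values on phantoms say nothing about ACDC-scale
  accuracy.
* Rectification moves features at most `N` pixels; gross misplacements
  are out of its reach, and a badly wrong learned field can distort
  rather than repair (mitigated, not removed, by the identity-initialized
  fusion).
* The L1 search inherits AdamW's scale-invariance caveat: weights can in
  principle re-inflate what masks shrink. Weight decay and the
  pretrained starting point keep this in check at the scales used here,
  but the ranking is only meaningful on a converged model.
* 2-D only; volumes are handled by slicing along the last axis.
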