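---
title: "From atom-sphere sketches to photorealistic-style renders: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From atom-sphere sketches to photorealistic-style renders: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(protrender)
```

## The problem

Photorealistic molecular renders (path tracing, soft lighting, ambient
occlusion, fog) are expensive to set up and compute in 3D graphics
packages. The approach implemented here sidesteps that cost: a protein is
first drawn as a *sketch* — a trivially cheap 2D image of depth-sorted
circles, one per atom — and a conditional image-to-image translation
network then maps the sketch to an image that imitates a photorealistic
style. Because all information the network sees travels through the
sketch, the sketch encoding is the heart of the design:

* **Red/green channels encode the element.** Carbon is (100%, 100%),
  nitrogen (100%, 0%), oxygen (0%, 100%), hydrogen (0%, 50%), phosphorus
  (50%, 50%). Any other element is encoded as carbon — the encoding is a
  classification hint, not a chemical registry.
* **The blue channel encodes depth.** 100% for atoms nearest the camera,
  0% for the most distant, linear in camera-space z between the per-image
  extremes (the endpoints are the specification; linearity is the
  package's choice of interpolant).
* Circles are sized by the Bondi van der Waals radius divided by
  camera-space depth (perspective projection), outlined in a gray that
  darkens with proximity, and filled with a subtle three-step radial
  gradient (multipliers 1.0/0.85/0.7 at radius fractions 0.5/0.8/1.0,
  highlight offset 20% toward the upper left) to suggest sphericity.

Two encoding details are genuinely open and are therefore exposed in
`sketch_config()`: the direction of the outline depth shading
(`outline_near_black`, default nearest = black) and the gradient geometry.
The background is black because no element encoding reaches (0, 0) on
R/G, which makes the colorizer's protein mask unambiguous; a white
background would collide with a near carbon at (100%, 100%, ~100%).
One consequence is accepted deliberately: the outline of the very nearest
atom is pure black and therefore indistinguishable from background in the
binary mask; the fill region is unaffected, and the outline stroke is
centred on the circle edge so the mask area stays within a few percent of
the analytic disc area.

## The camera model

The camera is perspective (`project()`): pixel offsets are proportional
to `x/z`, and circle radii shrink as `1/z` — two atoms at depths `d` and
`2d` differ in drawn radius by exactly a factor of two. Depth is
renormalized per image over the in-frustum atoms. For animations this
per-image normalization would make the blue channel flicker as the depth
extremes move, so `project()` and the animation driver accept a fixed
`[z_near, z_far]` window that pins the encoding across frames. Poses are
unit quaternions plus a focus point, a distance and a focal scale, and
serialize to a one-line `key=value` viewport record that round-trips to
1e-6.

## The style oracle

Training the translator requires paired targets. Rather than depending on
an external 3D renderer, the package ships a deterministic analytic
renderer (`render_target()`) that produces the *described effects* of
three styles — `simple_surface` (element colours), `chalky` (uniform
white, fully diffuse), `chalky_shadow` (chalky plus a shadow cast on a
white floor below the molecule):

* nearest ray-sphere intersection per pixel;
* Lambertian shading `max(0, n·l)` plus a 0.3 ambient floor;
* an ambient-occlusion proxy: the fraction of 12 fixed hemisphere
  directions (a golden-spiral set, rotated into the surface frame) blocked
  by neighbouring spheres within 5 Å, darkening by `ao_strength`;
* fade-to-white fog, `fog_strength * (1 - depth_norm)` lerp toward white;
* for `chalky_shadow`, soft shadows from five fixed jittered light
  directions onto the floor plane at the molecule's lower edge.

This is explicitly a stand-in with the same *qualitative* features as a
path-traced scene; depth-of-field, subsurface scattering and HDRI
lighting are omitted as irrelevant to exercising the learning pipeline.
Passing tests therefore demonstrate that the pipeline learns *this*
family of shading effects from sketches — not that it reproduces any
specific third-party renderer pixel-for-pixel. `level_background()`
mirrors the usual post-step of leveling the background to exact white
(flood-connected region from the corners, affine rescale, clamp).

## Training pairs

`build_corpus()` renders each variant at a full internal resolution
(default 1024²) and area-downsamples to the requested output side, so the
256/512/1024 corpora are resamplings of one render, not re-renders.
Structure-level augmentation (`augment_structure()`) randomly removes
waters (p = 0.5) and hydrogens (p = 0.5), substitutes retained hydrogens
with rarer elements (p = 0.02 per H; S, P, Fe, Cl, Br) — substitution is
skipped entirely when hydrogens were dropped — and draws a uniform random
rotation and a camera-distance factor in [0.85, 1.25]. The probabilities
are package defaults for "sometimes/occasionally"-style augmentation and
are exposed in `augment_config()`. Image-level augmentation is a ~112%
upscale (default 1.117, chosen so 256 scales to exactly 286) followed by
a random crop at the original size, with sketch and target sharing one
crop window. Images are never flipped or rotated: the targets have a
consistent light direction, and flips would make it unlearnable.

The synthetic fixture generator (`make_fixture()`) supplies the
structures: a self-avoiding pseudo-backbone with 3.8 Å Cα spacing
decorated with N/C/O (optionally H) at bond-like distances, optional
waters, and smooth sinusoidal per-frame perturbations for trajectories.
It emulates the *geometry statistics* that matter to the renderer (atom
packing, element mix, size); it does not emulate secondary structure,
side-chain chemistry or realistic dynamics, so tests passing on fixtures
say nothing about biological plausibility — only about the rendering and
learning machinery.

## The translator

The translator is a conditional adversarial pair:

* **Generator** — a U-Net: stride-2 4×4 convolutions down (instance
  normalization from the second block, leaky ReLU 0.2), and a
  resize-convolution decoder (nearest-neighbour 2× upsample + 3×3
  convolution, instance norm, ReLU) with skip concatenation after each
  step, finishing in tanh. Instance rather than batch normalization is
  deliberate: statistics are per-image, so inference is batch-independent.
  The resize-convolution decoder replaces transposed convolution — the
  same role in the architecture, with no checkerboard artifacts and a
  simpler exact backward pass. The reference depth is 7 downsampling
  stages at 128 px; the network is fully convolutional, so any input side
  divisible by `2^depth` works, and toy tests run depth 6 at 64 px.
* **Discriminator** — a patch classifier over the concatenated
  (sketch, image) pair: three stride-2 and two stride-1 4×4 convolution
  blocks ending in per-patch logits (~70 px receptive field).

The generator loss is binary cross-entropy against the discriminator plus
`l1_weight = 100` times the mean absolute error to the target; the
discriminator trains on real/fake cross-entropy. Optimization is Adam
(β₁ = 0.5) at `initial_lr = 2e-4`, constant for `epochs_const` epochs and
then decaying linearly to exactly zero over `epochs_decay` — the
conventional two-phase 1000 + 1000 schedule at full scale. Everything is
implemented in R on top of BLAS: convolutions are cached im2col gathers
and matrix products, and the backward pass is checked against finite
differences in the test suite. Full-scale training (≈1000 pairs, 1024²,
2000 epochs) is supported by the code path but is far outside a desk-CPU
budget; the shipped tests train at 64² — 8 pairs for 40 epochs (loss
halves well below the untrained generator) and a 2-pair, 200-epoch
overfit (training L1 < 0.05) — sizes chosen to demonstrate the
optimization is wired correctly, which is what toy-scale GAN training can
demonstrate.

Per-epoch scale-and-crop augmentation during training is available
(`train_config(augment = TRUE)`) but off by default: the toy corpora are
small enough that the moving crop window dominates the loss signal.

## Colorization

Recoloring happens after inference, entirely in image space. The
colour-intensity matrix is the element-wise product of four matrices —
the sketch's binary protein mask, the render's grayscale (unweighted
channel mean), the sketch's blue (depth) channel, and the scalar user
strength — so shadowed regions take less colour than lit ones and distant
fog keeps its fade. `apply_color()` is then a per-pixel weighted average
`(1 - w)·render + w·colour`. An optional blur of `w` softens edges; the
kernel is Gaussian with σ = blend_radius/3 truncated at 3σ, so its
support is exactly the user's radius and background farther away is
provably untouched. Blur is applied after the four-factor product.

## Animation

`plan_poses()` generates camera paths: `still` (pose count follows the
trajectory length for multi-frame structures), `turntable` (frame *i* of
*n* rotated by `i·360/n` degrees — the full turn is partitioned, the last
frame stopping one step short of 360), `rock` (one full sinusoidal
oscillation across the sequence, `A·sin(2πi/(n-1))`, which starts at rest
and touches ±A exactly when `n-1` is divisible by 4 — defaults ±15°), and
`zoom` (geometric distance interpolation, default factors 1.0 → 0.6).
`render_sequence()` renders sketch → translator-or-oracle → optional
colorization per frame, writes `frame_%04d.png` plus a JSON manifest with
per-frame viewports, checksums and a ready-to-run ffmpeg line. Temporal
flicker from per-frame depth normalization is mitigated with the fixed
depth window; smoothing *between* frames (optical-flow interpolation) is
an external post-processing step by design — the manifest's PNG sequence
is exactly what such tools consume.

## Numerical choices and degenerate inputs

* Rasterization is 2× supersampled and box-downsampled; all rendering is
  pure arithmetic, so identical inputs give bit-identical images.
* Draw order ties (equal depth) break by atom serial, ascending.
* A lone atom gets depth 1 ("nearest"); atoms behind the camera are
  dropped, and an all-behind scene is an explicit error.
* Instance normalization is skipped on 1×1 feature maps (the bottleneck),
  where per-image statistics are degenerate.
* `auto_frame()` places the bounding sphere's near face at 80% of the
  image side, which guarantees every atom projects inside the frame under
  perspective magnification.
* Fixture coordinates are rounded to 3 decimals at creation so structures
  round-trip exactly through fixed-column PDB text.

## Known limitations

* The style oracle is qualitative; nothing is calibrated against a
  path-traced reference.
* Only protein-surface sphere sketches are supported; backbone/cartoon
  sketch modes are deliberately absent (the encoding carries no
  connectivity, so a translator cannot reliably reconstruct secondary
  structure from it).
* Single global colorization colour; no per-chain colouring.
* CPU-only: full-scale (1024², thousands of epochs) training is
  impractical here; the architecture supports it, the wall-clock does not.
* No mmCIF reading, no hydrogen placement, no bond perception.
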