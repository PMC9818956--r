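---
title: "Methods: two-camera deformable registration of pen video frames"
author: "penreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-camera deformable registration of pen video frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two fixed cameras observe the same livestock pen from different wall
positions with overlapping fields of view. Many downstream tasks
(cross-view tracking, behaviour analysis) need pixel-level
correspondence between the two co-temporal frames. A single projective
transform (homography) captures the dominant geometry between the two
views of the (planar) pen floor, but the residual misalignment — animals
standing above the floor plane, lens imperfections, scene depth — is
non-linear and varies from frame to frame. `penreg` implements the full
pipeline: radial-distortion correction, pen masking and grayscale
conversion, landmark-fitted projective pre-registration, and a learned
dense deformable refinement evaluated by target registration error
(TRE).

## Preprocessing model

Lens distortion is modelled as radial-only: in normalized coordinates
$(x, y) = (p - c)/s$ with principal point $c$ and scale $s$, a point
maps to $x_d = x\,(1 + k_1 r^2 + k_2 r^4 + k_3 r^6)$, $r^2 = x^2 + y^2$
(and likewise for $y$). In practice only $k_1, k_2$ are calibrated;
$k_3$ defaults to 0. The coefficients enter as configuration — corner
detection and coefficient estimation from checkerboards is upstream of
this package. Because the original source does not state the
normalization behind its "normalized image coordinates", the `scale` /
`center` fields of `DistortionModel` parameterize that choice
explicitly. Undistortion inverts the radial factor by fixed-point
iteration ($q \leftarrow p / (1 + k_1 r^2(q) + \dots)$, at most 20
iterations, tolerance $10^{-9}$ in normalized units), which converges
whenever the radial polynomial is monotone over the observed radii; a
grossly non-invertible setting raises an error that reports the worst
residual. Grayscale conversion uses ITU-R BT.601 luma weights
(0.299, 0.587, 0.114). Image resampling is bilinear with out-of-frame
samples filled with 0, matching the black borders that masking produces.

Throughout the package the coordinate convention is: `x` = column,
`y` = row, 0-based, pixel centers at integer coordinates.

## Linear pre-registration

The projective baseline is fitted from manually placed landmark pairs
(the field protocol uses 35 per pen) by the normalized direct linear
transform: both point sets are centered and scaled to mean distance
$\sqrt{2}$, the $2n \times 9$ design system is solved by SVD, and the
normalizations are undone. Landmarks are manual and assumed
outlier-free, so plain least squares is used (no RANSAC). The fitted
homography maps moving-view points into the fixed view; *image* warping
uses its inverse (backward sampling), so that image content moves the
way points do. Pre-registration landmarks must be disjoint from the
landmarks used later for fine-tuning and evaluation; the command-line
interface enforces separate files.

## Deformable registration model

The residual alignment is a dense displacement field
$\Phi : \Omega \to \mathbb{R}^2$ predicted by a U-Net style
encoder–decoder $T_\theta(I_m, I_f) = \Phi$ from the stacked
(fixed, moving) 2-channel input. Registration solves

$$\arg\min_\Phi\; M(I_f, I_m(\Phi)) + \lambda\, R(\Phi),$$

where $I_m(\Phi)$ is the moving image warped by $\Phi$ through a
differentiable bilinear (spatial-transformer) sampler, $M$ is an
intensity similarity (MSE by default; NCC and SSD are available), and
$R$ is the diffusion regularizer — the squared norm of the spatial
gradients of $\Phi$ by forward finite differences.

**Field semantics.** $\Phi$ drives a *backward* warp: the registered
image at pixel $p$ samples the moving image at $p + \Phi(p)$. This is
the standard spatial-transformer convention; the direction is stated
explicitly because it determines how landmarks must be mapped. A
moving-image landmark $p$ lands in the fixed frame at the point $p'$
solving $p' + \Phi(p') = p$. At evaluation time this inverse is solved
by an under-relaxed fixed-point iteration (damping 0.7, at most 30
iterations, tolerance $10^{-3}$ px — the damping keeps the iteration
contractive for fields whose local gradients approach 1), with a
2×2-Jacobian Newton fallback for landmarks the contraction leaves
unresolved, since trained fields can locally exceed the fixed-point
regime while remaining invertible. A landmark lying on a fold of an
imperfect field has no exact preimage; the residual-minimizing position
is then used (and its error counted in the TRE) as long as the residual
stays sub-pixel, while a residual above 1 px raises an error. At
training time the landmark loss uses the cheap
differentiable first-order rule $p' \approx p - \Phi(p)$, which agrees
with the exact inverse to first order in the field's smoothness and
keeps the training graph differentiable.

**Architecture.** Per level: two 3×3 "same" convolutions with leaky
ReLU (slope 0.2); 2×2 max pooling between encoder levels; 2×2
transposed-convolution upsampling; skip concatenation of the encoder
feature map, instance-normalized (ε = 1e-5, no learned affine) when
enabled (the default); a final 1×1 convolution with two kernels emits
the two displacement channels. The body text of the source method names
Leaky ReLU while its layer tables say ReLU; leaky is the default and
plain ReLU is a configuration switch. Likewise "residual connections"
are mentioned alongside fully specified skip concatenation: skip
concatenation is always present, and optional in-level identity
shortcuts sit behind `residualBlocks` (default off). Kaiming
initialization is used for all layers except the final 1×1 flow head,
which starts near zero (SD $10^{-3}$) so the untrained network predicts
an almost-identity warp — the usual convention for displacement-field
networks, without which early training wastes epochs recovering from a
large random deformation. Initialization is seeded and
bit-reproducible. The
full-scale profile (`fullScaleNetworkConfig()`) is 5 levels with
32/64/128/256/512 filters on 928×1408 inputs; the desk profile used by
the tests and experiments is 3 levels with 8/16/32 filters on 64×64
inputs. No explicit clamp is applied to $|\Phi|$ by default (the
receptive field of the decoder bounds the useful displacement); a
configurable `fieldClamp` exists.

**Autodifferentiation.** No deep-learning framework is used: the
forward pass and its exact reverse-mode differentiation (including the
bilinear sampler's gradients with respect to both image and field, the
instance-norm backward, and the landmark term's scatter onto the field)
are implemented in the package over BLAS-backed im2col convolution
kernels. The test suite verifies every gradient path against central
finite differences to a relative error below $10^{-4}$ on an 8×8 toy
network.

## Loss scale and the regularization weight

The similarity and smoothness terms must be commensurate for a single
$\lambda$ to be meaningful. All images are normalized to $[0, 1]$
before entering any loss, so MSE values live on a unit intensity scale,
and the composite losses pair $\lambda$ with the *per-pixel mean* of
the squared field gradients (`diffusionRegularizer(..., normalize =
TRUE)`). This is the convention of the diffusion-regularized learning
registration literature from which the method adopts its regularizer,
and it is the setting under which the default $\lambda = 0.01$ balances
the two terms: with a raw summed penalty over a 64×64 field the
smoothness term would exceed any attainable MSE improvement by two to
three orders of magnitude and the optimum would be the zero field. The
standalone `diffusionRegularizer()` keeps the literal sum as its
default so the closed-form oracle values (e.g. a linear field's penalty
equals the number of valid forward differences) hold. $\lambda = 0.01$
and $\mu = 1.0$ are mandatory configuration entries; the original study
trains "different $\lambda$ and $\mu$" without reporting the chosen
values, so these defaults are conventions of this package.

With $\mu = 1$ the landmark term (mean squared distance in px²,
typically 1–30 on 64×64 frames) deliberately dominates the image term
during fine-tuning — annotated correspondences are scarce but trusted,
and the diffusion term propagates their corrections smoothly.

## Two-stage training

Stage 1 trains the network unsupervisedly with Adam (moments 0.9/0.999,
ε = 1e-8 — unstated in the source, standard defaults) on unlabeled
pre-registered pairs. Stage 2 transfers all convolutional weights into
the semi-supervised network (identical topology, verified layer by
layer and by parameter checksum) and fine-tunes *all* parameters (no
freezing policy is stated in the source; none is applied) with the
landmark-augmented loss on a small annotated set. The learning rate is
constant until `decayStartEpoch` and then decays linearly to zero at
the final epoch: $lr(e) = lr_0 \cdot \max(0, (E - e)/(E - e_d))$ for
$e \ge e_d$. Annotated landmark coordinates enter only through the loss
as a side list, not as a rasterized input channel — the source mentions
"an additional layer for landmark coordinates" without specifying its
form, and the side-list reading keeps the two networks' convolutional
topologies identical, which the weight transfer requires.

The full-scale protocol (batch 4, lr $10^{-4}$, 200 epochs, decay after
100) is the `TrainConfig()` default. The desk profile
(`deskTrainConfig()`: lr $10^{-3}$, 50 epochs, decay after 25) drives
the 64×64 synthetic experiments; the larger step is needed because 50
epochs on small inputs leave too few updates for the full-scale rate to
converge. Seeded runs are bit-reproducible on a fixed BLAS
configuration: batch shuffling is the only stochastic component and is
driven by the config seed.

## Evaluation

TRE is reported as the mean distance between fixed landmarks and mapped
moving landmarks. The source formula reads "average squared Euclidean
distance", yet its reported values (tens of pixels on 928×1408 frames)
are only plausible as plain Euclidean distances; the package therefore
defaults to the Euclidean convention, offers `"squared"` as the literal
variant, and records the choice in every report. Overall TRE pools all
landmarks across pairs; the per-pair list is retained because the
statistical comparisons operate per image pair. Foreground (on-animal)
and background landmark errors are reported separately; an empty
category is `NA`, never 0. Method comparison follows the source
protocol: Shapiro–Wilk normality on each method's per-pair TRE, then a
paired t-test if both samples look normal (p > 0.05) and the Wilcoxon
signed-rank test otherwise; raw p-values, no multiple-testing
correction. Identical samples short-circuit to p = 1 with a warning.

## Synthetic study conditions

The generator stands in for the farm recordings, which are not
deposited. Its defaults are the study conditions used by the tests and
the acceptance script:

* **Frames** 64×64, intensities in [0, 1]. The pen floor is smooth
  noise with mean 0.2 and SD 0.035 (spatial period 8 px); animals are
  5 brighter ellipses (intensity ≈ 0.45–0.95, semi-major axis 7–11 %
  of the frame — body length 15–20 % of frame width, matching the real
  animals' proportions — random aspect 0.5–0.8 and orientation) with
  per-blob texture, placed with a guaranteed 2.5 px gap. Five blobs at
  64×64 approximate the 10–11 animals per pen at a ~20× larger frame
  area.
* **View geometry** a random homography displacing the frame corners by
  up to 8 px, composed with a smooth residual field: control vectors
  drawn uniformly in the 6 px disc on a 16 px grid, bilinearly
  upsampled (so $|\Phi| \le 6$ px everywhere). `movingPrereg` is the
  side view after warping by the *true* homography — an ideal
  pre-registration — so the deformable stage can be tested in
  isolation; `movingRaw` retains the unregistered view for end-to-end
  runs through `fitProjective()`.
* **Illumination** an affine gain/bias difference between the views
  with amplitude 0.05 (a mild daylight difference; affine because
  grayscale conversion removes chromatic effects and NCC's affine
  invariance then has something measurable to differ on from MSE).
  Additive sensor noise is off by default (`noiseSd = 0`).
* **Landmarks** 6 exact pairs per annotated frame, 3 on blobs
  (foreground) and 3 on the floor (background), mirroring the field
  protocol. Landmark correspondences are mapped through the known
  transforms analytically, so ground truth is exact to the fixed-point
  tolerance (< 0.5 px self-consistency, verified over 50 seeds).

The residual field is constructed in the backward convention, so
`warpImageDense(movingPrereg, trueResidualField)` reproduces the fixed
image up to interpolation, and the true field acts as an oracle
registration method (TRE ≈ 1e-4 px on generated pairs).

What the generator does *not* emulate: occlusions between animals,
perspective foreshortening of the animals themselves (blobs deform only
through the global field), temporal coherence of video, and non-affine
illumination structure. Passing the synthetic experiments therefore
demonstrates that the optimization and geometry machinery is correct at
the study's noise and deformation scales — not that the defaults would
transfer unchanged to farm recordings.

## The desk-scale experiment

`runRecoveryExperiment()` is the package's end-to-end study: 200
unlabeled training pairs, 10 annotated fine-tuning pairs and 10
annotated held-out test pairs under the conditions above;
50-epoch unsupervised training (MSE, $\lambda = 0.01$); warm-started
fine-tuning and a from-scratch semi-supervised ablation on the same 10
annotated pairs ($\mu = 1$). Both fine-tuning arms run the brief
transfer protocol: a fifth of the epochs at a tenth of the unsupervised
learning rate — the usual setting for a small annotated set. With only
ten annotated pairs and a landmark term that dominates the loss by
design, a full-rate, full-length restart overwrites the transferred
representation instead of refining it and *worsens* held-out TRE; the
brief protocol lets the exact landmark correspondences nudge the field
toward the ground truth without overfitting the sixty annotated points. Problem sizes were chosen so the whole
study runs in minutes on one CPU core. The expected qualitative
ordering of held-out TRE is

fine-tuned ≤ unsupervised ≤ projective-only, with from-scratch
semi-supervised ≥ unsupervised,

and the unsupervised stage alone is expected to at least halve the
pre-registration TRE. `scripts/acceptance.R` reruns exactly this
experiment from scratch and writes the numbers it computes; the test
suite asserts the ordering and the halving on the seeded run.

## Numerical choices and degenerate inputs

* Bilinear sampling: corners outside the frame contribute zero, so
  out-of-frame samples fade to 0 smoothly; gradients follow the same
  rule (zero outside).
* `warpPointsDense` errors on out-of-frame input landmarks and on
  non-convergence (residual > 10× tolerance), reporting the worst
  residual.
* `fitProjective` rejects < 4 pairs and rank-deficient (collinear)
  configurations via the SVD spectrum.
* NCC is undefined on constant images and errors rather than returning
  a conventional value.
* Max pooling breaks ties toward the first element in scan order
  (top-left), deterministically.
* All stochastic functions take explicit seeds and restore the
  caller's RNG state.

## Known limitations

* Pure R + BLAS training is CPU-bound: the full-scale 928×1408 / 5-level
  profile is configuration only, far too slow to train here.
* The landmark loss uses the first-order inverse during training; for
  fields with strong local gradients (|∇Φ| approaching 1) the
  approximation degrades, though evaluation always uses the exact
  fixed-point inverse.
* Radial-only distortion; no tangential or fisheye terms.
* No diffeomorphic guarantee: large λ discourages but does not prevent
  folding fields.
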