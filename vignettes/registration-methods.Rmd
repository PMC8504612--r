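---
title: "Unsupervised deformable registration of chest CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised deformable registration of chest CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungwarp)
```

## The registration problem

Deformable (non-rigid) registration aligns a *moving* image $I_m$ to a
*fixed* image $I_f$ through a dense, spatially varying map. lungwarp targets
the intrapatient chest CT setting: two scans of the same patient at different
respiratory phases, already affinely pre-aligned, where breathing motion
deforms the lungs nonlinearly by up to several centimetres. The map is
parameterized as

$$\phi(x) = x + s(x),$$

where $s$ is a dense displacement field carrying one 3-vector per voxel of
the fixed grid, in voxel units. Instead of optimizing $s$ per pair (as
classical iterative methods do), a convolutional network is trained *without
ground-truth correspondences* to predict $s$ from the concatenated pair in a
single forward pass; training minimizes an image-similarity loss through a
differentiable warping layer, plus regularizers.

## The composite loss

`total_loss()` combines three terms,
$L = L_{sim} + \beta R_{jac} + \alpha R_{der}$:

* **Similarity** (`sim_loss`): one minus the locally windowed, *squared*
  normalized cross-correlation. For every voxel $p$ a cubic window is
  mean-centred in both images; the squared windowed covariance is divided by
  the product of the two windowed sums of squares plus a stabilizer
  $\epsilon$ (default $10^{-5}$, denominator only). The per-voxel values are
  averaged, so $NCC \in [0,1]$ and $L_{sim} = 1 - NCC$ is resolution-free.
  Squaring makes the measure invariant to any affine intensity rescaling,
  including contrast inversion. Windowed sums are computed by separable box
  filtering with border-truncated windows, which is algebraically identical
  to the per-voxel loop (the test suite verifies this against a scalar
  oracle). One consequence worth knowing: in windows with (near-)zero
  variance the stabilized ratio scores 0 rather than 1, so *structureless
  regions contribute a constant offset to $L_{sim}$ and no gradient*. The
  loss therefore drives alignment only where the images have local texture —
  in real chest CT, the vessel and airway trees.

* **Folding penalty** (`jac_penalty`): the Jacobian of the *full map*
  $J(p) = I + \partial s/\partial p$ is formed by forward finite differences
  (backward at the far border) and the penalty is
  $\sum_p (|\det J(p)| - \det J(p))$. It is exactly zero whenever every
  determinant is nonnegative and grows as $2|\det|$ summed over folding
  voxels, so it only activates on locally non-injective (anatomically
  implausible) transforms. We read the Jacobian as that of $\phi = id + s$
  rather than of $s$ alone: the identity field then has determinant 1
  everywhere, consistent with "no folding" being the penalty-free state.
  Determinants exactly 0 are *counted* as folding voxels but contribute 0
  penalty; both behaviours are kept as defined.

* **Smoothness penalty** (`grad_penalty`): the sum over voxels of the
  squared Frobenius norm of the finite-difference field gradient (all nine
  partials, same scheme as the Jacobian). Note this is a *sum*, not a mean:
  its magnitude scales with the voxel count, which matters when choosing
  $\alpha$ (below).

All three terms and the warp layer have hand-derived gradients (the package
contains no autodiff framework); every gradient is checked against central
finite differences in the test suite.

## The displacement network

`build_network()` constructs a U-shaped fully convolutional network over
(x, y, z, channel) tensors: a stem convolution, three stride-2 encoder
convolutions (spatial reduction to $(1/2)^3$), three transposed-convolution
decoder stages with skip concatenations, and a final *linear* 3-channel
convolution so displacements of either sign are representable. Every skip
path passes through an inception module — parallel convolutions with
different kernel sizes (default 1, 3, 5) whose outputs are concatenated and
reduced by a 1-kernel convolution — which captures structure at several
spatial scales before it is fused into the decoder. All hidden blocks use
batch normalization (over the spatial extent; training uses batch size 1)
followed by LeakyReLU with slope 0.2. The final convolution is initialized
near zero so an untrained network predicts an almost-identity transform,
which stabilizes early training.

Channel widths are configuration-exposed (`enc_channels`, default
16/32/64). The defaults give a parameter count of the same order as the
published full-scale configuration (~250k), but exact parity is not claimed
— the reference channel widths per layer are not recoverable — and
`count_parameters()` reports the actual count of any configuration. Batch
normalization is placed between convolution and activation, the common
convention where the original ordering is unspecified.

## Spatial transformation layer

`warp_trilinear()` computes $I_m \circ \phi$ by sampling the moving image at
$p + s(p)$ with trilinear interpolation of the eight neighbouring voxels;
`warp_nearest()` is the nearest-neighbour variant used for binary masks
(ties at fraction 0.5 round half-up per axis, so mask warps are
bit-reproducible). Sample coordinates clamp to the volume border rather than
reading zeros: zero-filling would inject spurious edges into the NCC windows
along the boundary. Displacements are in voxel units on the fixed grid —
physical spacing enters only when errors are converted to millimetres.

## TPS augmentation

Training data are enlarged with 3D thin-plate-spline warps
(`random_grid_tps()`, `build_augmented_dataset()`). Source control points
form a $5^3$ lattice over the unit cube; each target point adds an i.i.d.
uniform$(-h, h)$ perturbation per coordinate. The TPS interpolant is an
affine part plus radial kernels $U(r) = r^2\log r$ (natural log; $U(0)=0$ as
the continuous limit), solved per output axis from the classical bordered
$(N{+}4)\times(N{+}4)$ system with the vanishing-moment side conditions
$P^\top w = 0$. The solve is a direct dense one; a $10^{-10}$ diagonal
regularization of the kernel block is applied only when the plain solve
reports near-singularity, and its use is messaged.

$h$ is interpreted in normalized coordinates ($h = 0.1$ moves control points
by up to 10% of each axis), which makes the working range 0.02–0.1
meaningful as "visible deformation without overstretching". Both members of
a pair are warped through the *same* TPS draw, so simulated pairs remain
intrapatient-like: the residual deformation between them is unchanged, only
their shared anatomy varies. With the reference configuration — 25
replicates at each of $h \in \{0.02, 0.05, 0.08, 0.1\}$ — 30 original pairs
become $2\cdot 30\cdot(1 + 100) = 6060$ scans and 6 pairs become 1212,
counting the originals. Per-record seeds derive from the base seed so any
single simulated scan is reproducible in isolation.

## Training and inference

`train()` iterates (moving, fixed) pairs in channel order (moving, fixed),
predicts $s$, warps, and descends the composite loss with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$). The defaults in `train_config()` —
learning rate $10^{-4}$, batch size 1, 20 epochs — mirror the full-scale CT
regime. Per-epoch mean training and validation losses go to
`loss_curve.csv`; the checkpoint with the best validation total loss is
kept (training loss decides when there is no validation split), and
validation passes compute no gradients. Runs are fully seeded:
initialization, shuffling, and the augmentation draws all derive from
configuration seeds. `register_pair()` then registers an unseen pair in one
forward pass.

## Evaluation

* **TRE** (`tre()`): each fixed-image landmark $x_f$ is mapped to
  $x_f + s(x_f)$ ($s$ interpolated trilinearly at the continuous landmark
  position) and compared with its moving-image correspondence in mm via the
  fixed image's spacing; mean and population standard deviation are
  reported. The direction — mapping *fixed* landmarks — matches how the warp
  resamples the moving image onto the fixed grid; TRE is not symmetric under
  swapping the roles.
* **Dice** (`dice()`): volume overlap of the nearest-neighbour-warped moving
  lung mask against the fixed mask; defined as 1 for two empty masks (with a
  message).
* **Folding count** (`folding_count()`): voxels with $\det J \le 0$, over
  the full grid (not restricted to the lung field).

`evaluate_testset()` produces a per-pair table with the unregistered
("initial") baselines plus a summary row of means.

## The synthetic fixture generator

`make_phantom()` builds a smooth [0,1] volume from ~40 random Gaussian blobs
(radii 3–10% of the smallest dimension) inside an ellipsoidal "lung field"
mask. The blob density is deliberately high: it emulates the vascular and
airway texture that gives windowed NCC its gradients in real lung CT. A
smoother phantom would leave most windows structureless and the similarity
term flat — a property of the loss, not of any particular implementation.

`make_pair()` draws a ground-truth TPS, warps the phantom into the fixed
image, and derives the ground-truth displacement field *analytically* (the
transform evaluated per voxel) rather than by inverting a resampled warp, so
parameter-recovery tests are exact up to interpolation. Landmarks are placed
at high-gradient sites inside the mask — homogeneous-region landmarks would
be uninformative — and their moving-image correspondences follow from the
transform itself. `make_suite()` writes a ready-to-train suite with a
manifest.

What the phantoms do *not* emulate: CT noise and artifacts, sliding motion
at the pleura (the TPS is globally smooth), intensity changes from local
density variation during breathing, and full CT resolution. Tests passing on
the suite demonstrate that the machinery — augmentation, network, losses,
gradients, metrics — is correct and that the training loop genuinely
improves alignment; they do not demonstrate clinical-grade accuracy on real
scans.

## Desk-scale study conditions

The acceptance checks and examples run on $32^3$ volumes with
$h \in \{0.02, 0.05\}$ (a 20-pair suite, seed 7). For that regime the
package uses deliberately scaled parameters, chosen once from scale
analysis:

* **NCC window 9** (vs 11 at full CT resolution): the published window is
  ~5% of the long axis at $224\times144\times192$; at $32^3$ a window of 9
  keeps the capture range larger than the ~1.6-voxel deformations while
  remaining local.
* **$\alpha = 10^{-4}$**: $R_{der}$ is a raw sum over voxels, so its scale
  grows with the grid; at $32^3$, $\alpha = 1$ would dwarf the $O(1)$
  similarity term and drive the field to zero. $10^{-4}$ puts the smoothness
  term at a few percent of the total for fields of the ground-truth scale.
* **$\beta \in \{10^{-5}, 10^{-3}\}$**: the two ends of the explored range;
  the folding penalty is inactive (exactly zero) on fold-free fields either
  way, so larger $\beta$ can only reduce the folding count.
* **Toy network** (channels 4/8/16, inception kernels 1 and 3), **Adam at
  $3\times10^{-3}$ for 30 epochs**: a CPU-minutes configuration; the
  full-scale defaults (16/32/64 channels, kernels 1/3/5, learning rate
  $10^{-4}$, 20 epochs) remain the package defaults.

## Numerical choices and conventions

* Axis order is (x, y, z), x fastest, matching R's column-major arrays;
  voxel coordinates are 0-based internally; landmark files default to
  1-based on disk.
* Finite differences: forward, with a backward fallback at the last index of
  each axis; penalties sum over all voxels; $\Omega$ is the full volume, not
  the lung mask.
* The subgradient of $|\det| - \det$ at $\det = 0$ is taken as 0.
* Masks resample by nearest neighbour everywhere; images trilinearly.
* Cropping uses the union of the pair's masks (margin 2 voxels) so both
  images land on one grid; resampling rescales spacing to preserve the
  physical extent.
* `fit_tps()` requires $N \ge 5$ pairwise-distinct, non-coplanar control
  points; violations raise a solver error with a condition-number
  diagnostic.

## Known limitations

The implementation is CPU-only and R/Rcpp-based: full-resolution
($224\times144\times192$) training is functional but slow, and is not
exercised by the tests. The network uses instance statistics for
normalization at inference (batch size 1 training makes running averages
redundant at this scale). Diffeomorphic integration, inverse fields,
multi-resolution pyramids and mutual-information similarity are out of
scope.
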