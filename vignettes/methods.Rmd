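---
title: "Serial-section vessel reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-section vessel reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vasc3d reconstructs a three-dimensional vascular model from an ordered stack
of stained serial tissue sections. Each section is an independent physical
cut, so the stack carries two kinds of error the pipeline must undo:
per-slice misalignment (the sections were mounted and scanned independently)
and the anisotropy of the sampling (in-plane pixels of ~0.28 µm against a
section thickness of 3-4 µm). The pipeline runs in six stages: vessel
segmentation per section, coarse affine registration of consecutive
sections, deformable refinement, mask alignment and inter-slice
interpolation into a voxel volume, topology-preserving skeletonization with
branch statistics, and overlap/similarity evaluation. This vignette explains
the models behind each stage, the tunable parameters and their defaults, and
the design decisions that were genuinely open.

## The synthetic phantom: what it emulates, and what it does not

Real serial-section datasets pair each section with a manually annotated
vessel mask but provide no ground truth for the *misalignment*, which is
exactly what registration must be validated against. The package therefore
ships a generator whose outputs carry full ground truth at every stage.

`generate_phantom()` grows vessel trees as random walks with bounded
curvature (direction jitter `curvature`, default 0.08 per step), biased
along the cutting axis so each tube crosses many section planes, and dilates
the walk polylines into tubes by stamping metric spheres. The analytic
centerline, its branch topology and the per-branch radii stay on the object,
which is what lets skeleton and branch-statistic tests compare against exact
truth rather than against another skeletonization. Defaults — radii 4-7 µm
on a 1 µm isotropic grid, 3 tubes with 2 bifurcations in a 28 µm deep block
— give microvessel-scale tubes that remain several pixels wide in section,
so that sub-pixel registration error degrades overlap smoothly rather than
catastrophically.

`slice_phantom()` implements the physical sectioning geometry: sections
every `thickness_um` starting at z = 0, `floor(depth / thickness) + 1`
sections in total, each plane resampled in-plane to `pixel_um`. The
H&E-like geometry (4 µm sections at 0.28 µm/px) has anisotropy ratio
4/0.28 ≈ 14.3; the package's test stacks use 4 µm at 1 µm/px to keep
image sizes tractable, which preserves the qualitative regime (anisotropy
ratio 4) while scaling the problem down.

`render_stack()` converts binary masks into stain-like RGB sections: flat
vessel and background color distributions per stain style (`he`: eosin-dense
vessel on pink stroma with dark nucleus speckles; `dab`: brown endothelium
on pale counterstain), a smooth multiplicative illumination gradient, and
white gaussian noise (default sd 0.04). Two features matter for what the
tests can claim. First, the stroma texture is a smooth random field evolving
as an AR(1) process across slices (adjacent-slice correlation 0.7):
intensity-based registration aligns *shared structure*, and in real sections
that shared structure is the stroma persisting between neighbouring cuts.
Without it, mutual information has nothing consistent to lock onto and
pairwise registration fails in a way real tissue does not. Second, the
nucleus speckles are a deliberate confounder for the luminance-only Otsu
baseline: they are dark but not vessels, and a color-aware classifier
separates them while a per-block threshold cannot — mirroring the
qualitative gap between the two methods on real stains. The renderer is not
photorealistic: no nuclei inside vessel walls, no stain variation along a
vessel, no scanner optics. Passing tests therefore show that the pipeline's
logic is correct under controlled conditions, not that its accuracy numbers
transfer to tissue.

`perturb_stack()` misaligns each slice independently by a sampled affine
(rotation ≤ 8°, translation ≤ 6% of width, shear ≤ 0.03, scale deviation
≤ 3%) followed by a smooth elastic field (gaussian-smoothed white noise,
RMS 2 px, correlation length 8 px), recording every applied transform.
These defaults put the unregistered stack in the regime the method is
meant for: consecutive-pair mask overlap of roughly 30-50% and a
sequence-wide mutual dice near zero, recovering toward the anatomy-limited
ceiling after registration. Per-slice perturbations are independent — no
drift model — matching the pairwise registration framing.

## Segmentation

`otsu_block_segment()` is the classical baseline: luminance conversion
(0.299/0.587/0.114), tiling into `block_size` squares (default 64),
per-block threshold maximising between-class variance over a 256-bin
histogram, and an all-background rule for blocks whose dynamic range falls
below `min_contrast` (default 0.1) — a flat block contains nothing to
separate, and thresholding it would hallucinate vessels out of noise.
Vessel polarity (stained-dark by default) is a flag because H&E and DAB
differ and nothing in the histogram itself decides it.

The trainable segmenter is a small U-net-style encoder-decoder: two pooling
levels, one 3×3 convolution per block, leaky-ReLU activations, skip
connections by channel concatenation, and a two-class softmax head trained
under cross-entropy (a single foreground class; two-class softmax rather
than a sigmoid keeps the loss exactly the stated cross-entropy). Training
uses AdamW with a one-cycle learning-rate schedule (linear warmup over the
first 30% of steps, cosine decay to 1% of the peak; peak 3e-3 by default),
on 224 px patches split 70/30 into training and validation at patch level.
The package's own network and backward passes are implemented natively
(convolution, pooling, warping gradients in compiled code) — the point is
the training recipe and its validation behaviour, not scale. Validation
dice is computed as an aggregate over the validation patches (summed
intersections over summed sizes) rather than on reassembled slices: after a
patch-level 70/30 shuffle, patches of one slice legitimately land in both
splits, so "full reassembled validation slices" is not well defined; the
aggregate is the same statistic at the same scale. Training stops early
once validation dice exceeds `dice_target` (default 90%), and the
best-validation checkpoint is returned. Inference tiles the image with 50%
overlap and averages class probabilities in the overlaps, so output size
equals input size for any image.

## Coarse registration

Consecutive sections are registered pairwise by maximising the mutual
information of their joint intensity histogram — the area-based criterion
that is robust to stain differences — over a gaussian image pyramid.
MI is computed in bits from a `bins × bins` joint histogram (default 32
bins), over the pixels whose inverse-mapped sample lies inside the moving
image; alignments explaining less than half the frame are rejected, since
shrinking the overlap region can spuriously inflate MI.

The optimiser is a staged derivative-free search rather than a
gradient-based Marquardt-Levenberg scheme: at the coarsest level a joint
grid scan over integer translations (±12% of width) and rotations (±12° in
3° steps) provides the initial pose — MI on weakly-structured images has
local maxima a simplex started at the identity falls into — and each level
then refines by Nelder-Mead on negative MI, rigid parameters first, then
the full 6-parameter affine, warm-starting the next finer level. At the
finest level the simplex is restarted once with a tighter spread, which
recovers the sub-pixel tail when the first simplex stalls on an MI plateau.
This choice trades iteration count for robustness: analytic MI gradients
require Parzen-window machinery with several unstated parameters, while the
staged search meets the package's accuracy bar (mean corner error ≤ 0.5 px
for rotations ≤ 10° and translations ≤ 5% of width) within seconds per
pair at 96 px scale.

Transform convention, stated once and used everywhere: a transform is the
forward map from the moving frame into the fixed frame, acting on
homogeneous (col, row, 1) coordinates about the image centre; warping
resamples through the inverse. Pairwise transforms chain into the frame of
slice 0 (the reference — the anchor is arbitrary and the first section is
the conventional choice); `compose_to_reference()` accepts any reference
index.

## Deformable refinement

The affine stage cannot undo the smooth nonrigid distortion each section
acquires during cutting and mounting. A convolutional flow network (same
encoder-decoder skeleton, two input channels: moving and fixed slice; two
output channels: per-pixel row/col displacement) is trained unsupervised on
all consecutive pairs of one stack with the bidirectional loss

    ncc(warp(moving, f_fwd), fixed) + ncc(warp(fixed, f_bwd), moving)
      + lambda * (grad(f_fwd) + grad(f_bwd))

where `ncc` is one minus the mean local normalized cross-correlation over
9 px windows (intensity-affine invariant, in [0, 2], windows truncated at
borders, variances epsilon-regularised) and `grad` is the mean squared
forward difference of the flow (exactly 1 for a unit-ramp displacement).
The backward direction shares weights — swapping the input channels yields
the backward flow — which encourages inverse-consistent fields. Warping is
backward sampling (each output pixel pulls from the moving image), the
standard convention for spatial-transformer warps. The flow head is
initialised near zero so training starts from the identity deformation,
making the already-aligned case a fixed point rather than something to
unlearn. Defaults: window 9, lambda 1, 30 epochs, AdamW with one-cycle
peak 1e-2. One network serves the whole stack — in an 8-10 section regime
there is too little data to train one per pair.

At application time flows are predicted pairwise in chain order toward the
reference: slice i is warped against the *already refined* slice i-1.
Chaining against the refined predecessor rather than the raw coarse one
prevents the per-pair residuals from re-accumulating along the stack; it is
the package's resolution of an ambiguity the pairwise framing leaves open,
and it is what makes sequence-wide overlap improve monotonically in
practice.

## Volume building

Aligned binary masks are stacked and interpolated to near-isotropic voxels:
`k = round(thickness_um / pixel_um)` sub-planes per gap (k = 14 for the
4 µm / 0.28 µm geometry, i.e. 13 inserted planes), each the per-pixel
linear blend `(1-t)A + tB` of the bounding masks thresholded at 0.5.
Blend-plus-threshold is the simplest faithful reading of "bilinear
interpolation" on binary z-stacks; it interpolates overlapping cross
sections smoothly and switches at the midpoint for disjoint ones, and it
can never create foreground outside the union of the bounding masks.
Components smaller than `min_voxels` (default 64) are removed by
26-connected labeling — at near-isotropic ~1 µm voxels that is a few µm³ of
debris, below any vessel fragment of interest. Volumes export to NIfTI
(spacing in the header) or multi-page TIFF.

## Skeletonization and branch statistics

The volume is thinned to a one-voxel-wide centerline by iterative removal
of simple border voxels: a voxel is removed only if deletion preserves
topology (one 26-connected foreground component in its punctured
neighbourhood and one 6-connected background component among its
18-neighbours touching a face), endpoints (≤ 1 foreground neighbour) are
protected, and removal proceeds in six directional subiterations per cycle
until a fixed point. This is the constrained-erosion family of curve
skeletons; component counts, cycles and Euler characteristic are preserved
by construction, which the tests verify against an independent
cubical-complex Euler oracle on balls, cylinders and tori.

The branch graph places nodes at endpoints and junctions. Under
26-connectivity a voxel branch point is always accompanied by mutually
adjacent junction voxels, so adjacent junction voxels are merged into one
node at their centroid (the unique-junction convention of skeletal
analysis); edges are the voxel chains between nodes with physical euclidean
step lengths. The main branch of a component is defined as its longest
endpoint-to-endpoint path — the highlighted single path per vessel that
branch visualisations show — computed exactly: on trees via weighted graph
distances, on cyclic components by exhaustive simple-path enumeration up to
a 12-endpoint budget and by double sweep beyond it (longest path is
NP-hard in general; the budgeted exact search covers every phantom and any
realistically sized vessel component). Remaining edges are sub-branches.
End erosion is inherent to endpoint-protected thinning: a cylinder of
radius r loses roughly r voxels of length at each flat end, which is why
the length contract is "within 5%" rather than exact.

## Evaluation metrics

Pairwise overlap is the dice coefficient `2|X∩Y| / (|X|+|Y|) × 100`; the
sequence-wide mutual dice generalises it to
`n|X1∩…∩Xn| / Σ|Xi| × 100`. A printed variant of both formulas divides by
the union size instead, which would score 200 for identical masks and
contradicts the convention that 100 means perfect overlap; the package
implements the standard denominators and keeps the printed variants behind
`legacy = TRUE` for comparison. Two empty masks score 100 by convention
(logged): an empty prediction of an empty truth is correct. SSIM uses the
standard constants (K1 = 0.01, K2 = 0.03, L = 1) with a gaussian window of
sigma 1.5 (11 px support, renormalised at borders). The full-sequence SSIM
reported for a stack is the mean of consecutive-pair SSIMs — the labelling
"average SSIM" admits other aggregates, and this is the documented choice.
`registration_report()` emits, per stage (original / coarse / fine), one
row per consecutive pair and one full-sequence row, as CSV.

## Problem sizes, determinism and limitations

The package's tests and the acceptance script run on 8-slice stacks of
96 × 96 px sections with the reduced network widths (8 base channels);
these sizes were chosen so a full study — generation, training, two-stage
registration, reconstruction, analysis — completes in minutes on one CPU
while preserving every qualitative regime of the full-scale problem
(anisotropy, misalignment scale relative to vessel calibre, train/validate
behaviour). Every stochastic step takes an explicit seed, and the pipeline
fans a single global seed out to per-stage seeds, so end-to-end runs are
reproducible bit-for-bit.

Known limitations: the renderer's realism bounds what segmentation accuracy
numbers mean (synthetic colors separate more cleanly than real stains);
pairwise MI registration between sections with genuinely different anatomy
has an irreducible bias that chaining accumulates, so absolute alignment
degrades slowly along long stacks — the fine stage compensates but windowed
mutual-dice evaluation is the honest metric for stacks much longer than
ten sections (an overlapped-batch variant of mutual dice is the natural
extension); and the thinning end-erosion makes branch lengths slight
underestimates near open vessel ends.
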