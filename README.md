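# vasc3d

3D reconstruction and branching analysis of blood vessels from serial
histological sections.

Histology delivers micrometre-resolution images of vasculature, but only as
independent 2D sections: each 3-4 µm cut is mounted, stained and scanned on
its own, so the stack is misaligned slice-to-slice and sampled ~14× more
coarsely along the cutting axis than in-plane. vasc3d rebuilds the 3D
vessel model from such a stack and quantifies its branching. It is aimed at
quantitative pathology and angiogenesis research — anyone with consecutive
stained sections (H&E, CD31/DAB, ...) and vessel annotations who wants a
3D model and branch statistics rather than per-slide measurements.

The pipeline:

1. **Segmentation** — per section, a block-wise Otsu baseline and a small
   U-net-style network trained on 224 px patches (70/30 split, AdamW +
   one-cycle schedule, two-class cross-entropy).
2. **Coarse registration** — consecutive sections aligned by maximising
   mutual information *I(A;B) = H(A) + H(B) − H(A,B)* over an image
   pyramid with a 6-dof affine model; pairwise transforms chained into one
   coordinate system.
3. **Deformable refinement** — a convolutional flow network trained
   unsupervised with a bidirectional local-NCC loss plus a smoothness
   penalty λ·‖∇φ‖²; forward flows warp images and masks.
4. **Reconstruction** — aligned masks interpolated to near-isotropic
   voxels (linear blend + 0.5 threshold, k = round(thickness/pixel)
   sub-planes per gap), small components filtered, export to NIfTI/TIFF.
5. **Skeleton & branches** — topology-preserving thinning to a 1-voxel
   centerline; branch graph with merged junction clusters; per vessel the
   main branch (longest endpoint-to-endpoint path, in µm) and sub-branches.
6. **Evaluation** — pairwise dice 2|X∩Y|/(|X|+|Y|), sequence-wide mutual
   dice n|X₁∩…∩Xₙ|/Σ|Xᵢ|, and SSIM, reported per consecutive pair and for
   the full sequence.

Because public serial-section datasets rarely carry misalignment ground
truth, the package includes a synthetic module: branching-tube phantoms
with analytic centerlines, physical sectioning, stain-like rendering with
slice-coherent stroma texture, and recorded per-slice misalignments
(affine + elastic), so every stage is testable against known truth.

## Worked example

```r
library(vasc3d)

# a 28 um-deep phantom block, sectioned every 4 um at 1 um/px,
# rendered H&E-like and misaligned per slice
phantom <- generate_phantom(grid_shape = c(29, 96, 96), n_tubes = 3,
                            n_bifurcations = 2, seed = 11)
masks  <- slice_phantom(phantom, thickness_um = 4, pixel_um = 1)
stack  <- render_stack(masks, "he", seed = 21)
pert   <- perturb_stack(stack, masks, perturbation_spec(seed = 31))

# register: coarse MI-affine, then deformable refinement
coarse <- register_stack_coarse(pert$stack, pert$masks)
fine   <- register_fine_stack(coarse$images, coarse$masks,
                              fine_config(epochs = 40, seed = 3))

c(original = mutual_dice(pert$masks),
  coarse   = mutual_dice(coarse$masks),
  fine     = mutual_dice(fine$masks))
#>  original    coarse      fine
#> 0.6551004 2.1547994 3.7958251

# rebuild the volume and analyse branching
vol  <- filter_small_objects(interpolate_stack(fine$masks), 64)
skel <- skeletonize_3d(vol)
branch_statistics(build_branch_graph(skel))
```

The mutual dice numbers read as: with per-slice misalignment the eight
masks share almost nothing (0.66%); the affine stage recovers global pose
(2.15%); the flow stage recovers the remaining elastic distortion (3.80%),
approaching the overlap ceiling set by how much the anatomy itself changes
between 4 µm sections. Each branch-statistics row gives, per connected
vessel, its main branch length in µm and the number and lengths of its
sub-branches.

The whole pipeline can also be driven by one YAML config:

```r
res <- run_pipeline(pipeline_config(list(pixel_um = 1, thickness_um = 4,
                                         out_dir = "out", seed = 1)))
res$report   # per-pair + full-sequence SSIM/dice, by stage
```

A thin CLI wrapper lives at `inst/cli/vasc3d.R`
(`Rscript vasc3d.R simulate|run-all|evaluate ...`).

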