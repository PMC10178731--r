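# Per-slice misalignment of synthetic stacks: a sampled affine followed by a
# smooth elastic field, with the true transforms recorded so registration
# accuracy can be measured against ground truth.

#' Specification of per-slice misalignment
#'
#' Magnitudes are sampling half-ranges: each slice draws its parameters
#' uniformly in `[-max, +max]`. Elastic fields are gaussian-smoothed white
#' noise displacement grids scaled to a target RMS magnitude.
#'
#' @param max_rotation_deg rotation half-range, degrees.
#' @param max_translation_frac translation half-range as a fraction of image
#'   width.
#' @param max_shear shear coefficient half-range.
#' @param max_scale_dev anisotropic scale deviation half-range (0.02 allows
#'   scales in \[0.98, 1.02\]).
#' @param elastic_amplitude_px RMS magnitude of the elastic displacement, px
#'   (0 disables the elastic stage).
#' @param elastic_smoothness_px gaussian sigma of the field smoothing, px.
#' @param seed RNG seed; fixes every random draw.
#' @return a `perturbation_spec` object.
#' @export
perturbation_spec <- function(max_rotation_deg = 8, max_translation_frac = 0.06,
                              max_shear = 0.03, max_scale_dev = 0.03,
                              elastic_amplitude_px = 2,
                              elastic_smoothness_px = 8, seed = 1) {
  vals <- c(max_rotation_deg, max_translation_frac, max_shear, max_scale_dev,
            elastic_amplitude_px, elastic_smoothness_px)
  if (any(vals < 0)) stop("perturbation magnitudes must be >= 0")
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_translation_frac = max_translation_frac,
                 max_shear = max_shear, max_scale_dev = max_scale_dev,
                 elastic_amplitude_px = elastic_amplitude_px,
                 elastic_smoothness_px = elastic_smoothness_px,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

# Smoothed-white-noise displacement field with the requested RMS magnitude.
sample_elastic_field <- function(H, W, amplitude_px, smoothness_px) {
  u <- array(0, c(H, W, 2))
  if (amplitude_px <= 0) return(u)
  for (ch in 1:2) {
    f <- smooth_gaussian(matrix(rnorm(H * W), H, W), smoothness_px)
    u[, , ch] <- f / max(sd(f), 1e-12)
  }
  u * amplitude_px / sqrt(2)  # per-component sd so that E|u|^2 = amplitude^2
}

#' Misalign a section stack and its masks, recording the truth
#'
#' Each slice is independently warped by a sampled affine and then by a
#' smooth elastic field (the masks with the identical transforms). The
#' applied transforms are returned so that downstream registration can be
#' scored against them.
#'
#' @param stack a [section_stack()].
#' @param masks a [mask_stack()] paired 1:1 with the stack.
#' @param spec a [perturbation_spec()].
#' @return list with `stack` (perturbed [section_stack()]), `masks`
#'   (perturbed [mask_stack()]) and `truth`, a `perturb_record` holding, per
#'   slice, the applied forward affine (3x3) and elastic field (H, W, 2).
#' @export
perturb_stack <- function(stack, masks, spec = perturbation_spec()) {
  stopifnot(inherits(stack, "section_stack"), inherits(masks, "mask_stack"),
            length(stack) == length(masks))
  n <- length(stack)
  d <- dim(stack$images[[1]])
  H <- d[1]; W <- d[2]
  center <- transform_center(c(H, W))
  with_seed(spec$seed, {
    affines <- vector("list", n)
    flows <- vector("list", n)
    imgs <- vector("list", n)
    msk <- vector("list", n)
    for (i in seq_len(n)) {
      theta <- runif(1, -1, 1) * spec$max_rotation_deg * pi / 180
      tx <- runif(1, -1, 1) * spec$max_translation_frac * W
      ty <- runif(1, -1, 1) * spec$max_translation_frac * W
      sh <- runif(1, -1, 1) * spec$max_shear
      lsx <- log(1 + runif(1, -1, 1) * spec$max_scale_dev)
      lsy <- log(1 + runif(1, -1, 1) * spec$max_scale_dev)
      P <- affine_from_params(tx, ty, theta, lsx, lsy, sh, center = center)
      u <- sample_elastic_field(H, W, spec$elastic_amplitude_px,
                                spec$elastic_smoothness_px)
      affines[[i]] <- P
      flows[[i]] <- u
      im <- array(0, d)
      for (ch in seq_len(d[3]))
        im[, , ch] <- apply_flow(warp_affine(stack$images[[i]][, , ch], P), u)
      imgs[[i]] <- clamp01(im)
      m <- apply_flow(warp_affine(masks$masks[[i]] + 0, P, mode = "image"),
                      u, mode = "mask")
      msk[[i]] <- m
    }
    truth <- structure(list(affines = affines, flows = flows, spec = spec,
                            shape = c(H, W)), class = "perturb_record")
    list(stack = section_stack(imgs, stack$pixel_um, stack$thickness_um,
                               stack$stain_style),
         masks = mask_stack(msk, masks$pixel_um, masks$thickness_um),
         truth = truth)
  })
}

#' Undo a recorded perturbation of one slice
#'
#' Applies the approximate inverse of the recorded elastic field, then the
#' inverse affine. Recovers the unperturbed slice up to interpolation error.
#'
#' @param img (H, W) matrix (one channel or mask).
#' @param truth `perturb_record` from [perturb_stack()].
#' @param index 1-based slice index.
#' @param mode `"image"` or `"mask"`.
#' @return recovered matrix.
#' @export
invert_perturbation <- function(img, truth, index, mode = c("image", "mask")) {
  mode <- match.arg(mode)
  u <- truth$flows[[index]]
  if (max(abs(u)) > 0) img <- apply_flow(img, invert_flow(u), mode = mode)
  warp_affine(img, solve(truth$affines[[index]]), mode = mode)
}

# True absolute forward maps (slice i frame -> reference slice frame),
# ignoring the elastic component: A_i = P_ref %*% solve(P_i).
true_absolute_affines <- function(truth, reference_index = 0) {
  Pr <- truth$affines[[reference_index + 1]]
  lapply(truth$affines, function(P) Pr %*% solve(P))
}
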