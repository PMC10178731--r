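# Stain-like rendering of binary section masks. Emulates the appearance of
# H&E (eosin-dense vessel walls on a pink stroma with scattered dark nuclei)
# and CD31/DAB (brown endothelium on a pale hematoxylin counterstain).
# Not photorealistic: flat color distributions + illumination gradient +
# gaussian texture noise, enough for segmentation and registration to have
# realistic work to do.

stain_palettes <- list(
  he = list(background = c(0.91, 0.79, 0.86),
            vessel = c(0.70, 0.33, 0.45),
            nuclei = c(0.38, 0.27, 0.55)),
  dab = list(background = c(0.88, 0.90, 0.95),
             vessel = c(0.48, 0.31, 0.14),
             nuclei = c(0.62, 0.66, 0.82))
)

#' Render a stain-like RGB image from a binary vessel mask
#'
#' Vessel and background pixels are drawn from distinct color distributions;
#' the background additionally carries nucleus-like dark speckles and a
#' smooth multiplicative illumination gradient, and gaussian noise is added
#' everywhere. Deterministic for a fixed seed.
#'
#' @param mask binary (H, W) matrix.
#' @param stain_style `"he"` or `"dab"`.
#' @param noise_level standard deviation of the additive gaussian noise on
#'   \[0, 1\] intensities.
#' @param nuclei_density expected nucleus-like speckles per pixel of
#'   background.
#' @param texture optional (H, W) multiplicative stroma-texture field
#'   (around 1); [render_stack()] passes a field correlated across slices,
#'   the way real stroma persists through consecutive sections.
#' @param seed RNG seed.
#' @return (H, W, 3) array in \[0, 1\].
#' @export
render_stain <- function(mask, stain_style = c("he", "dab"),
                         noise_level = 0.04, nuclei_density = 0.002,
                         texture = NULL, seed = 1) {
  if (!is_binary(mask)) stop("mask must be binary")
  if (is.character(stain_style) && !all(stain_style %in% names(stain_palettes)))
    stop(sprintf("unknown stain_style '%s'; valid styles: %s",
                 stain_style[1], paste(names(stain_palettes), collapse = ", ")))
  stain_style <- match.arg(stain_style)
  pal <- stain_palettes[[stain_style]]
  H <- nrow(mask); W <- ncol(mask)
  with_seed(seed, {
    img <- array(0, c(H, W, 3))
    bg <- mask == 0
    # nucleus-like speckles: small disks stamped on background only
    nmask <- matrix(0L, H, W)
    n_nuc <- stats::rpois(1, nuclei_density * sum(bg))
    if (n_nuc > 0) {
      ci <- sample.int(H, n_nuc, replace = TRUE)
      cj <- sample.int(W, n_nuc, replace = TRUE)
      rad <- sample(1:3, n_nuc, replace = TRUE)
      for (t in seq_len(n_nuc)) {
        if (mask[ci[t], cj[t]] != 0) next
        ii <- max(1, ci[t] - rad[t]):min(H, ci[t] + rad[t])
        jj <- max(1, cj[t] - rad[t]):min(W, cj[t] + rad[t])
        dd <- outer((ii - ci[t])^2, (jj - cj[t])^2, "+") <= rad[t]^2
        sub <- nmask[ii, jj]
        sub[dd & mask[ii, jj] == 0] <- 1L
        nmask[ii, jj] <- sub
      }
    }
    # illumination: smooth multiplicative gradient across the field
    gdir <- runif(1, 0, 2 * pi)
    gg <- outer(seq(-0.5, 0.5, length.out = H) * sin(gdir),
                seq(-0.5, 0.5, length.out = W) * cos(gdir), "+")
    illum <- 1 + 0.12 * gg
    if (!is.null(texture)) illum <- illum * texture
    for (ch in 1:3) {
      base <- matrix(pal$background[ch], H, W)
      base[nmask == 1] <- pal$nuclei[ch]
      base[mask == 1] <- pal$vessel[ch]
      img[, , ch] <- clamp01(base * illum + rnorm(H * W, 0, noise_level))
    }
    img
  })
}

#' Render a whole mask stack with slice-coherent stroma texture
#'
#' Renders every mask with [render_stain()], adding a smooth 3D texture
#' field that is correlated across consecutive slices (stromal structures in
#' real serial sections persist through neighbouring cuts, and it is this
#' shared texture that intensity-based registration locks onto).
#'
#' @param masks a [mask_stack()].
#' @param stain_style `"he"` or `"dab"`.
#' @param texture_strength multiplicative amplitude of the stroma field.
#' @param texture_scale_px in-plane correlation length (gaussian sigma, px).
#' @param noise_level,nuclei_density per-slice rendering noise, see
#'   [render_stain()].
#' @param seed RNG seed.
#' @return a [section_stack()].
#' @export
render_stack <- function(masks, stain_style = c("he", "dab"),
                         texture_strength = 0.15, texture_scale_px = 6,
                         noise_level = 0.04, nuclei_density = 0.002,
                         seed = 1) {
  stain_style <- match.arg(stain_style)
  n <- length(masks$masks)
  H <- nrow(masks$masks[[1]]); W <- ncol(masks$masks[[1]])
  with_seed(seed, {
    # smooth in-plane noise evolving as an AR(1) process across slices:
    # adjacent sections share ~70% of their stroma structure
    alpha <- 0.7
    fields <- vector("list", n)
    fields[[1]] <- smooth_gaussian(matrix(rnorm(H * W), H, W),
                                   texture_scale_px)
    if (n > 1) for (i in 2:n)
      fields[[i]] <- alpha * fields[[i - 1]] +
        sqrt(1 - alpha^2) * smooth_gaussian(matrix(rnorm(H * W), H, W),
                                            texture_scale_px)
    slice_seeds <- sample.int(1e7, n)
    imgs <- lapply(seq_len(n), function(i) {
      f <- fields[[i]] / max(sd(fields[[i]]), 1e-12)
      render_stain(masks$masks[[i]], stain_style,
                   noise_level = noise_level,
                   nuclei_density = nuclei_density,
                   texture = 1 + texture_strength * tanh(f),
                   seed = slice_seeds[i])
    })
    section_stack(imgs, masks$pixel_um, masks$thickness_um, stain_style)
  })
}
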