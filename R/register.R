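# Stack-level coarse registration: pairwise MI-affine between consecutive
# slices, chaining into the reference frame, and warping of images + masks.

#' Coarsely register a stack of sections
#'
#' Registers every consecutive pair (fixed = slice i, moving = slice i + 1)
#' with [register_pair_affine()], composes the pairwise transforms into the
#' reference slice's coordinate system and warps images (and masks, if
#' given).
#'
#' @param stack [section_stack()] or list of grayscale matrices.
#' @param masks optional [mask_stack()].
#' @param config a [pyramid_config()].
#' @param reference_index 0-based anchor slice (default 0).
#' @return list with `images` (aligned grayscale list), `masks` (aligned
#'   [mask_stack()] or NULL), `pairwise` (list of `affine2d`), `absolute`
#'   (list of `affine2d`, one per slice).
#' @export
register_stack_coarse <- function(stack, masks = NULL,
                                  config = pyramid_config(),
                                  reference_index = 0) {
  imgs <- as_gray_list(stack)
  n <- length(imgs)
  stopifnot(n >= 2)
  pairwise <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    t <- register_pair_affine(imgs[[i]], imgs[[i + 1]], config)
    t$moving <- i
    t$fixed <- i - 1L
    pairwise[[i]] <- t
  }
  absolute <- compose_to_reference(pairwise, reference_index)
  out_imgs <- lapply(seq_len(n), function(i)
    warp_affine(imgs[[i]], absolute[[i]], mode = "image"))
  out_masks <- NULL
  if (!is.null(masks))
    out_masks <- align_masks(masks, absolute)
  list(images = out_imgs, masks = out_masks, pairwise = pairwise,
       absolute = absolute)
}
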