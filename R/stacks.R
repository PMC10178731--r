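# Containers for ordered section data. List order is the physical cutting
# order throughout the package.

#' Ordered stack of RGB section images
#'
#' @param images list of (H, W, 3) numeric arrays in \[0, 1\], all the same
#'   shape, ordered by physical cutting order.
#' @param pixel_um in-plane pixel size, micrometres per pixel (> 0).
#' @param thickness_um physical spacing between consecutive sections (> 0).
#' @param stain_style `"he"` (hematoxylin-eosin-like) or `"dab"`
#'   (CD31/DAB-like immunostain).
#' @return a `section_stack` object.
#' @export
section_stack <- function(images, pixel_um, thickness_um,
                          stain_style = c("he", "dab")) {
  stain_style <- match.arg(stain_style)
  stopifnot(length(images) >= 1, pixel_um > 0, thickness_um > 0)
  d1 <- dim(images[[1]])
  ok <- vapply(images, function(im) length(dim(im)) == 3 &&
                 all(dim(im) == d1), logical(1))
  if (!all(ok)) stop("all section images must share one (H, W, 3) shape")
  structure(list(images = images, pixel_um = pixel_um,
                 thickness_um = thickness_um, stain_style = stain_style),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<section_stack> %d sections of %dx%d px, %.3g um/px, %.3g um thick, stain %s\n",
              length(x$images), d[1], d[2], x$pixel_um, x$thickness_um,
              x$stain_style))
  invisible(x)
}

#' Ordered stack of binary vessel masks
#'
#' @param masks list of (H, W) binary matrices (0/1), one per section.
#' @param pixel_um,thickness_um physical geometry as in [section_stack()].
#' @return a `mask_stack` object.
#' @export
mask_stack <- function(masks, pixel_um, thickness_um) {
  stopifnot(length(masks) >= 1, pixel_um > 0, thickness_um > 0)
  d1 <- dim(masks[[1]])
  masks <- lapply(masks, function(m) {
    if (!all(dim(m) == d1)) stop("all masks must share one shape")
    if (!is_binary(m)) stop("masks must be binary (0/1)")
    matrix(as.integer(m), d1[1], d1[2])
  })
  structure(list(masks = masks, pixel_um = pixel_um,
                 thickness_um = thickness_um),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<mask_stack> %d masks of %dx%d px, %.3g um/px, %.3g um thick\n",
              length(x$masks), d[1], d[2], x$pixel_um, x$thickness_um))
  invisible(x)
}

#' @export
length.section_stack <- function(x) length(x$images)

#' @export
length.mask_stack <- function(x) length(x$masks)
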