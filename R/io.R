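# Disk formats: numbered PNG sections + JSON sidecar for stacks; 0/255 PNG
# masks; JSON-serialised transforms and flows.

#' Write a section stack to a directory
#'
#' Sections become numbered PNG files (`section_000.png`, ...) plus a
#' `stack.json` sidecar holding the physical metadata. If a truth record is
#' given, its affines and elastic fields are stored in the sidecar too.
#'
#' @param stack a [section_stack()].
#' @param dir output directory (created if missing).
#' @param masks optional [mask_stack()], written as `mask_000.png` (0/255).
#' @param truth optional `perturb_record`.
#' @return `dir`, invisibly.
#' @export
write_section_stack <- function(stack, dir, masks = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$images))
    png::writePNG(stack$images[[i]],
                  file.path(dir, sprintf("section_%03d.png", i - 1)))
  if (!is.null(masks))
    for (i in seq_along(masks$masks))
      png::writePNG(masks$masks[[i]] + 0,
                    file.path(dir, sprintf("mask_%03d.png", i - 1)))
  meta <- list(n_sections = length(stack$images),
               pixel_um = stack$pixel_um,
               thickness_um = stack$thickness_um,
               stain_style = stack$stain_style,
               has_masks = !is.null(masks))
  if (!is.null(truth)) {
    meta$truth <- list(
      affines = lapply(truth$affines, function(m) as.vector(t(m))),
      elastic_rms_px = truth$spec$elastic_amplitude_px,
      seed = truth$spec$seed)
  }
  jsonlite::write_json(meta, file.path(dir, "stack.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a section stack written by [write_section_stack()]
#'
#' @param dir directory holding `section_*.png` and `stack.json`.
#' @return list with `stack` ([section_stack()]) and `masks`
#'   ([mask_stack()] or NULL).
#' @export
read_section_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  n <- meta$n_sections
  imgs <- lapply(seq_len(n) - 1, function(i) {
    im <- png::readPNG(file.path(dir, sprintf("section_%03d.png", i)))
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
    im[, , 1:3, drop = FALSE]
  })
  stack <- section_stack(imgs, meta$pixel_um, meta$thickness_um,
                         meta$stain_style)
  masks <- NULL
  if (isTRUE(meta$has_masks)) {
    ms <- lapply(seq_len(n) - 1, function(i) {
      m <- png::readPNG(file.path(dir, sprintf("mask_%03d.png", i)))
      if (length(dim(m)) == 3) m <- m[, , 1]
      matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
    })
    masks <- mask_stack(ms, meta$pixel_um, meta$thickness_um)
  }
  list(stack = stack, masks = masks)
}

#' Serialize affine transforms to JSON
#'
#' @param transforms list of `affine2d`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transforms_json <- function(transforms, path) {
  payload <- lapply(transforms, function(t) list(
    matrix = as.vector(t(t$matrix)), moving = t$moving, fixed = t$fixed,
    mi = attr(t, "mi") %||% NA, converged = attr(t, "converged") %||% NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transforms written by [write_transforms_json()]
#'
#' @param path JSON file.
#' @return list of `affine2d`.
#' @export
read_transforms_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i)
    affine_transform(matrix(unlist(payload$matrix[i]), 3, 3, byrow = TRUE),
                     moving = payload$moving[i], fixed = payload$fixed[i]))
}

#' Write flow fields as multi-page TIFF + JSON metadata
#'
#' Each slice's flow becomes two float TIFF pages (d_row, d_col).
#'
#' @param flows list of [flow_field()] (NULL entries skipped).
#' @param path_prefix files `<prefix>_NNN.tif` and `<prefix>.json`.
#' @return `path_prefix`, invisibly.
#' @export
write_flows <- function(flows, path_prefix) {
  meta <- list()
  for (i in seq_along(flows)) {
    f <- flows[[i]]
    if (is.null(f)) next
    u <- flow_array(f)
    # shift to [0,1] range for TIFF storage; record the offset and scale
    rng <- max(1, max(abs(u)))
    pages <- list((u[, , 1] / rng + 1) / 2, (u[, , 2] / rng + 1) / 2)
    tiff::writeTIFF(pages, sprintf("%s_%03d.tif", path_prefix, i - 1),
                    bits.per.sample = 32L)
    meta[[length(meta) + 1]] <- list(index = i - 1, scale = rng,
                                     moving = f$moving, fixed = f$fixed)
  }
  jsonlite::write_json(meta, paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path_prefix)
}
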