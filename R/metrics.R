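# Evaluation metrics: pairwise dice, sequence-wide mutual dice, SSIM, and
# the per-stage registration report.

#' Dice overlap of two binary masks (percent)
#'
#' `2 |X intersect Y| / (|X| + |Y|) * 100`, so identical non-empty masks
#' score 100 and disjoint masks 0. Two empty masks score 100 by convention
#' (logged). `legacy = TRUE` instead divides by `|X union Y|`, the printed
#' variant some reports use, which yields 200 for identical masks.
#'
#' @param mask_x,mask_y equal-shaped binary matrices/arrays.
#' @param legacy use the union denominator (default FALSE).
#' @return scalar percent.
#' @export
dice <- function(mask_x, mask_y, legacy = FALSE) {
  if (!all(dim(mask_x) == dim(mask_y))) stop("mask shapes differ")
  if (!is_binary(mask_x) || !is_binary(mask_y)) stop("masks must be binary")
  nx <- sum(mask_x != 0); ny <- sum(mask_y != 0)
  inter <- sum(mask_x != 0 & mask_y != 0)
  if (nx + ny == 0) {
    message("dice: both masks empty, returning 100 by convention")
    return(100)
  }
  den <- if (legacy) (nx + ny - inter) else (nx + ny)
  2 * inter / den * 100
}

#' Mutual dice of a mask sequence (percent)
#'
#' `n |X1 intersect ... intersect Xn| / sum_i |Xi| * 100`: the overlap of the
#' entire sequence, 100 for n identical non-empty masks and 0 as soon as the
#' global intersection is empty. `legacy = TRUE` divides by the union size
#' instead.
#'
#' @param masks list of equal-shaped binary masks (n >= 2), or a
#'   [mask_stack()].
#' @param legacy use the union denominator (default FALSE).
#' @return scalar percent.
#' @export
mutual_dice <- function(masks, legacy = FALSE) {
  if (inherits(masks, "mask_stack")) masks <- masks$masks
  n <- length(masks)
  stopifnot(n >= 2)
  d1 <- dim(masks[[1]])
  inter <- masks[[1]] != 0
  uni <- masks[[1]] != 0
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    if (!all(dim(masks[[i]]) == d1)) stop("mask shapes differ")
    if (!is_binary(masks[[i]])) stop("masks must be binary")
    inter <- inter & (masks[[i]] != 0)
    uni <- uni | (masks[[i]] != 0)
    sizes[i] <- sum(masks[[i]] != 0)
  }
  if (sum(sizes) == 0) {
    message("mutual_dice: all masks empty, returning 100 by convention")
    return(100)
  }
  den <- if (legacy) sum(uni) else sum(sizes)
  n * sum(inter) / den * 100
}

#' Structural similarity index of two grayscale images
#'
#' Mean local SSIM with the standard constants (K1 = 0.01, K2 = 0.03,
#' dynamic range L = 1 for \[0, 1\] images) over a gaussian window
#' (sigma 1.5, 11 x 11 support, renormalised at the borders). Symmetric in
#' its arguments; 1 only for identical images.
#'
#' @param image_a,image_b equal-shaped matrices with values in \[0, 1\].
#' @param sigma gaussian window sigma (px).
#' @return scalar in \[-1, 1\].
#' @export
ssim_pair <- function(image_a, image_b, sigma = 1.5) {
  if (!all(dim(image_a) == dim(image_b))) stop("image shapes differ")
  win <- 2 * ceiling(3 * sigma) + 1
  if (any(dim(image_a) < win))
    stop(sprintf("images smaller than the %dx%d SSIM window", win, win))
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_a <- smooth_gaussian(image_a, sigma)
  mu_b <- smooth_gaussian(image_b, sigma)
  va <- smooth_gaussian(image_a^2, sigma) - mu_a^2
  vb <- smooth_gaussian(image_b^2, sigma) - mu_b^2
  cab <- smooth_gaussian(image_a * image_b, sigma) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(ssim_map)
}

#' Per-pair and full-sequence registration report
#'
#' For each registration stage, reports per consecutive pair the image SSIM
#' and the dice of the ground-truth and predicted masks, and one
#' full-sequence row holding the average pairwise SSIM and the mutual dice
#' of each mask sequence. All values in percent; negative SSIM is reported
#' clipped at 0 (with a warning).
#'
#' @param stacks_by_stage named list (stage -> [section_stack()] or list of
#'   grayscale matrices), e.g. stages `original`, `coarse`, `fine`.
#' @param gt_masks named list (stage -> [mask_stack()] or list of masks).
#' @param pred_masks like `gt_masks`, or NULL if no predicted masks exist.
#' @return a `registration_report` data.frame with columns `stage`, `row`,
#'   `ssim_pct`, `dice_gt_pct`, `dice_pred_pct`.
#' @export
registration_report <- function(stacks_by_stage, gt_masks, pred_masks = NULL) {
  stages <- names(stacks_by_stage)
  stopifnot(!is.null(stages), all(stages %in% names(gt_masks)))
  out <- list()
  for (st in stages) {
    imgs <- stacks_by_stage[[st]]
    if (inherits(imgs, "section_stack")) imgs <- lapply(imgs$images, luminance)
    gm <- gt_masks[[st]]
    if (inherits(gm, "mask_stack")) gm <- gm$masks
    pm <- if (!is.null(pred_masks)) pred_masks[[st]] else NULL
    if (inherits(pm, "mask_stack")) pm <- pm$masks
    n <- length(imgs)
    if (length(gm) != n || (!is.null(pm) && length(pm) != n))
      stop(sprintf("stage '%s': stack and mask lengths differ", st))
    ssims <- numeric(n - 1)
    dg <- numeric(n - 1)
    dp <- rep(NA_real_, n - 1)
    for (i in seq_len(n - 1)) {
      ssims[i] <- ssim_pair(imgs[[i]], imgs[[i + 1]]) * 100
      dg[i] <- dice(gm[[i]], gm[[i + 1]])
      if (!is.null(pm)) dp[i] <- dice(pm[[i]], pm[[i + 1]])
    }
    if (any(ssims < 0)) {
      warning("negative SSIM clipped to 0 in the report")
      ssims <- pmax(ssims, 0)
    }
    rows <- data.frame(
      stage = st,
      row = c(sprintf("pair %d,%d", 0:(n - 2), 1:(n - 1)), "full_sequence"),
      ssim_pct = c(ssims, mean(ssims)),
      dice_gt_pct = c(dg, mutual_dice(gm)),
      dice_pred_pct = c(dp, if (!is.null(pm)) mutual_dice(pm) else NA_real_))
    out[[st]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("registration_report", "data.frame")
  res
}

#' @export
print.registration_report <- function(x, ...) {
  cat("Registration report (percent):\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a registration report as CSV
#'
#' @param report a `registration_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
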