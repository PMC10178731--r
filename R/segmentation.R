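# Vessel segmentation: block-wise Otsu baseline and a trainable U-net-style
# network following the patched-dataset recipe (224 px patches, 70/30
# train/validation split, AdamW + one-cycle schedule, two-class softmax
# cross-entropy).

#' Block-based Otsu vessel segmentation
#'
#' The image is converted to luminance, tiled into `block_size` squares, and
#' each block is thresholded at the level maximising the between-class
#' variance of its histogram. Blocks whose dynamic range falls below
#' `min_contrast` are classified all-background (they contain no stained
#' structure to separate). By default the darker (stained) class is vessel;
#' set `polarity = "light"` for stains where vessels are brighter.
#'
#' @param image (H, W) grayscale matrix or (H, W, 3) RGB array in \[0, 1\].
#' @param block_size block side, px (>= 16). A block size exceeding the
#'   image falls back to a single global block (logged, not an error).
#' @param min_contrast minimum within-block dynamic range for thresholding.
#' @param polarity `"dark"` (vessel = class below threshold) or `"light"`.
#' @return binary (H, W) matrix.
#' @export
otsu_block_segment <- function(image, block_size = 64, min_contrast = 0.1,
                               polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  img <- luminance(image)
  stopifnot(block_size >= 16)
  H <- nrow(img); W <- ncol(img)
  if (block_size > max(H, W)) {
    message("otsu_block_segment: block larger than image, using one global block")
    block_size <- max(H, W)
  }
  out <- matrix(0L, H, W)
  rstarts <- seq(1, H, by = block_size)
  cstarts <- seq(1, W, by = block_size)
  for (r0 in rstarts) for (c0 in cstarts) {
    ri <- r0:min(H, r0 + block_size - 1)
    ci <- c0:min(W, c0 + block_size - 1)
    blk <- img[ri, ci, drop = FALSE]
    if (diff(range(blk)) < min_contrast) next  # flat block: background
    th <- otsu_threshold(blk)
    sel <- if (polarity == "dark") blk <= th else blk > th
    out[ri, ci][sel] <- 1L
  }
  out
}

# Otsu's threshold over a 256-bin histogram of [0,1] intensities: the level
# maximising the between-class variance (cumulative-moment formulation).
otsu_threshold <- function(x) {
  nbins <- 256L
  h <- tabulate(pmin(nbins, 1L + as.integer(floor(x * nbins))), nbins = nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 0.5) / nbins)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  k / nbins  # threshold at the upper edge of bin k: class 0 is <= threshold
}

#' Extract training patches from one section
#'
#' Tiles the image and mask with the given stride; right/bottom remainders
#' are padded by mirror reflection so every patch has the full size.
#' Provenance (slice index, row/col offset) is recorded per patch.
#'
#' @param image (H, W, 3) array (or (H, W) matrix, promoted to one channel).
#' @param mask (H, W) binary matrix.
#' @param patch_size patch side, px.
#' @param stride tiling stride, px (defaults to `patch_size`).
#' @param slice_index recorded in the provenance.
#' @return a `patch_dataset`: list with `patches` (list of
#'   `list(image, mask)`) and `provenance` (data.frame).
#' @export
extract_patches <- function(image, mask, patch_size = 224, stride = NULL,
                            slice_index = 0L) {
  stride <- stride %||% patch_size
  if (is.matrix(image)) image <- array(image, c(dim(image), 1))
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  H <- dim(image)[1]; W <- dim(image)[2]
  offs_r <- seq(1, H, by = stride)
  offs_c <- seq(1, W, by = stride)
  # reflect-pad so patches hanging over the right/bottom edge are full-size
  refl <- function(n, idx) {
    m <- idx > n
    idx[m] <- 2 * n - idx[m]  # mirror about the last row/col
    pmin(pmax(idx, 1L), n)
  }
  patches <- list()
  prov <- list()
  for (r0 in offs_r) for (c0 in offs_c) {
    ri <- refl(H, r0 + 0:(patch_size - 1))
    ci <- refl(W, c0 + 0:(patch_size - 1))
    patches[[length(patches) + 1]] <-
      list(image = image[ri, ci, , drop = FALSE],
           mask = matrix(as.integer(mask[ri, ci] != 0), patch_size,
                         patch_size))
    prov[[length(prov) + 1]] <-
      data.frame(slice = slice_index, row = r0 - 1L, col = c0 - 1L)
  }
  structure(list(patches = patches, provenance = do.call(rbind, prov)),
            class = "patch_dataset")
}

# Pool patches from every slice of a rendered stack + its mask stack.
patches_from_stack <- function(stack, masks, patch_size, stride = NULL) {
  sets <- lapply(seq_along(stack$images), function(i)
    extract_patches(stack$images[[i]], masks$masks[[i]], patch_size, stride,
                    slice_index = i - 1L))
  structure(list(
    patches = do.call(c, lapply(sets, function(s) s$patches)),
    provenance = do.call(rbind, lapply(sets, function(s) s$provenance))),
    class = "patch_dataset")
}

#' Split a patch dataset into training and validation sets
#'
#' Shuffled, disjoint, exhaustive split with
#' `|train| = round(train_frac * N)`.
#'
#' @param dataset a `patch_dataset` (N >= 2).
#' @param train_frac training fraction in (0, 1); default 0.7.
#' @param seed RNG seed.
#' @return list with `train` and `validation` patch datasets.
#' @export
split_dataset <- function(dataset, train_frac = 0.7, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  n <- length(dataset$patches)
  if (n < 2) stop("need at least 2 patches to split")
  with_seed(seed, {
    ord <- sample.int(n)
    ntr <- round(train_frac * n)
    ntr <- min(max(ntr, 1L), n - 1L)
    take <- function(ix) structure(
      list(patches = dataset$patches[ix],
           provenance = dataset$provenance[ix, , drop = FALSE]),
      class = "patch_dataset")
    list(train = take(ord[seq_len(ntr)]),
         validation = take(ord[(ntr + 1):n]))
  })
}

#' Segmentation training configuration
#'
#' @param patch_size patch side; must be divisible by 4 (two pooling
#'   levels).
#' @param train_frac training fraction (0, 1).
#' @param max_epochs training epochs.
#' @param base_channels first-level channel width of the encoder.
#' @param max_lr one-cycle peak learning rate.
#' @param dice_target validation dice (percent) at which training stops
#'   early.
#' @param weight_decay AdamW weight decay.
#' @param seed RNG seed for init and shuffling.
#' @return a `seg_config` list.
#' @export
seg_config <- function(patch_size = 224, train_frac = 0.7, max_epochs = 30,
                       base_channels = 8, max_lr = 3e-3, dice_target = 90,
                       weight_decay = 1e-4, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1, patch_size %% 4 == 0)
  structure(list(patch_size = patch_size, train_frac = train_frac,
                 max_epochs = max_epochs, base_channels = base_channels,
                 max_lr = max_lr, dice_target = dice_target,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "seg_config")
}

#' Train the segmentation network
#'
#' Encoder-decoder with skip connections and a two-class softmax head,
#' trained with AdamW under a one-cycle learning-rate schedule by minimising
#' cross-entropy. Validation dice (aggregate over the validation patches) is
#' tracked per epoch; the best-validation weights are returned, and training
#' stops early once `dice_target` is exceeded.
#'
#' @param train,validation `patch_dataset`s (both non-empty).
#' @param config a [seg_config()].
#' @return a `unet_model`: list with `params`, `config` and `report` (a
#'   `train_report` data.frame: epoch, train_loss, val_dice_pct, plus
#'   attributes `best_epoch`, `best_val_dice_pct`).
#' @export
train_unet <- function(train, validation, config = seg_config()) {
  if (config$max_epochs < 1) stop("max_epochs must be >= 1: no training performed")
  if (length(train$patches) == 0 || length(validation$patches) == 0)
    stop("both splits must be non-empty")
  in_ch <- dim(train$patches[[1]]$image)[3]
  with_seed(config$seed, {
    params <- unet_init(in_ch, 2, base = config$base_channels)
    opt <- adamw_init(params)
    ntr <- length(train$patches)
    total_steps <- config$max_epochs * ntr
    step <- 0
    best <- list(dice = -Inf, epoch = NA_integer_, params = params)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_dice_pct = numeric())
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(ntr)
      ep_loss <- 0
      for (i in ord) {
        step <- step + 1
        p <- train$patches[[i]]
        fwd <- unet_forward(params, p$image)
        ce <- softmax_ce(fwd$out, p$mask)
        if (!is.finite(ce$loss))
          stop(sprintf("training diverged at epoch %d (non-finite loss)", ep))
        ep_loss <- ep_loss + ce$loss
        grads <- unet_backward(params, fwd$cache, ce$grad)
        lr <- onecycle_lr(step, total_steps, config$max_lr)
        upd <- adamw_step(params, grads, opt, lr,
                          weight_decay = config$weight_decay)
        params <- upd$params
        opt <- upd$opt
      }
      vd <- validation_dice(params, validation)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ntr,
                                     val_dice_pct = vd))
      if (vd > best$dice) best <- list(dice = vd, epoch = ep, params = params)
      if (vd >= config$dice_target) break
    }
    report <- hist
    attr(report, "best_epoch") <- best$epoch
    attr(report, "best_val_dice_pct") <- best$dice
    class(report) <- c("train_report", "data.frame")
    structure(list(params = best$params, config = config, report = report),
              class = "unet_model")
  })
}

# Aggregate dice over a patch set: summed intersections / summed sizes.
validation_dice <- function(params, dataset) {
  inter <- 0; size <- 0
  for (p in dataset$patches) {
    prob <- unet_predict_prob(params, p$image)
    pred <- prob >= 0.5
    inter <- inter + sum(pred & p$mask == 1)
    size <- size + sum(pred) + sum(p$mask == 1)
  }
  if (size == 0) return(100)
  2 * inter / size * 100
}

unet_predict_prob <- function(params, image) {
  out <- unet_forward(params, image)$out
  1 / (1 + exp(out[, , 1] - out[, , 2]))  # softmax over 2 channels
}

#' @export
print.unet_model <- function(x, ...) {
  r <- x$report
  cat(sprintf("<unet_model> base %d, trained %d epochs, best val dice %.1f%% (epoch %d)\n",
              x$config$base_channels, nrow(r),
              attr(r, "best_val_dice_pct"), attr(r, "best_epoch")))
  invisible(x)
}

#' @export
print.train_report <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("best: epoch %d, val dice %.2f%%\n", attr(x, "best_epoch"),
              attr(x, "best_val_dice_pct")))
  invisible(x)
}

#' Predict a full-section vessel mask
#'
#' Tiled inference with overlapping patches; class probabilities are
#' averaged in overlaps and thresholded, so the output has exactly the input
#' shape.
#'
#' @param model a `unet_model`.
#' @param image (H, W, 3) array (or matrix).
#' @param patch_size inference patch side (defaults to the training size).
#' @param overlap fraction of patch overlap between tiles (default 0.5).
#' @return binary (H, W) matrix.
#' @export
predict_mask <- function(model, image, patch_size = NULL, overlap = 0.5) {
  patch_size <- patch_size %||% model$config$patch_size
  if (is.matrix(image)) image <- array(image, c(dim(image), 1))
  H <- dim(image)[1]; W <- dim(image)[2]
  ps <- min(patch_size, 4 * ((min(H, W)) %/% 4))
  stride <- max(1L, as.integer(round(ps * (1 - overlap))))
  ds <- extract_patches(image, matrix(0L, H, W), ps, stride)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(ds$patches)) {
    p <- ds$patches[[i]]
    pr <- ds$provenance[i, ]
    prob <- unet_predict_prob(model$params, p$image)
    ri <- pr$row + seq_len(ps)
    ci <- pr$col + seq_len(ps)
    keep_r <- ri <= H; keep_c <- ci <= W
    acc[ri[keep_r], ci[keep_c]] <- acc[ri[keep_r], ci[keep_c]] +
      prob[keep_r, keep_c]
    cnt[ri[keep_r], ci[keep_c]] <- cnt[ri[keep_r], ci[keep_c]] + 1
  }
  matrix(as.integer(acc / pmax(cnt, 1) >= 0.5), H, W)
}
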