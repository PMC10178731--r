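# Block-Otsu baseline, patch extraction, dataset splitting and the
# segmentation network.

test_that("block Otsu matches the exhaustive-threshold oracle", {
  set.seed(101)
  for (rep in 1:50) {
    blk <- matrix(runif(24 * 24), 24, 24)
    # bimodal-ish block: push half the pixels darker
    blk[sample(length(blk), 250)] <- blk[sample(length(blk), 250)] * 0.3
    expect_equal(vasc3d:::otsu_threshold(blk), otsu_oracle(blk),
                 tolerance = 1e-12)
  }
})

test_that("two-level block is split between the levels", {
  blk <- matrix(200 / 255, 32, 32)
  blk[, 1:16] <- 50 / 255
  th <- vasc3d:::otsu_threshold(blk)
  expect_gt(th, 50 / 255)
  expect_lt(th, 200 / 255)
  m <- otsu_block_segment(blk, block_size = 32, min_contrast = 0.1)
  expect_equal(m, matrix(as.integer(blk <= th), 32, 32))
})

test_that("constant image maps to all-background", {
  m <- otsu_block_segment(matrix(0.5, 48, 48), block_size = 16)
  expect_true(all(m == 0))
})

test_that("block-based thresholding survives an illumination offset where a global threshold fails", {
  # construct: dark vessels (0.2/0.3) on light background (0.7/0.8), with the
  # right half offset +0.35; a global Otsu then splits left from right
  # instead of vessel from background
  img <- matrix(0.45, 64, 64)
  img[, 1:32] <- 0.7
  img[, 33:64] <- 0.7 + 0.25
  truth <- matrix(0L, 64, 64)
  truth[10:20, 5:15] <- 1L
  truth[40:55, 40:50] <- 1L
  img[truth == 1 & col(img) <= 32] <- 0.2
  img[truth == 1 & col(img) > 32] <- 0.2 + 0.25
  block <- otsu_block_segment(img, block_size = 32, min_contrast = 0.05)
  global <- otsu_block_segment(img, block_size = 64, min_contrast = 0.05)
  expect_equal(dice_oracle(block, truth), 100)
  expect_lt(dice_oracle(global, truth), 100)
})

test_that("oversized blocks fall back to one global block with a message", {
  expect_message(otsu_block_segment(matrix(runif(24 * 24), 24, 24),
                                    block_size = 100),
                 "global block")
})

test_that("patch tiling arithmetic and reflection padding", {
  img <- array(runif(448 * 448 * 3), c(448, 448, 3))
  msk <- matrix(0L, 448, 448)
  ds <- extract_patches(img, msk, patch_size = 224, stride = 224)
  expect_length(ds$patches, 4)

  one <- extract_patches(img[1:224, 1:224, , drop = FALSE], msk[1:224, 1:224],
                         patch_size = 224)
  expect_length(one$patches, 1)
  expect_identical(one$patches[[1]]$image, img[1:224, 1:224, , drop = FALSE])

  img3 <- array(runif(300 * 300 * 3), c(300, 300, 3))
  ds3 <- extract_patches(img3, matrix(0L, 300, 300), 224, 224)
  expect_length(ds3$patches, 4)
  # bottom-right patch starts at offset 224 (0-based) and mirrors rows
  # beyond 300 about the last row: patch row 78 is image row 299, 79 -> 298
  p <- ds3$patches[[4]]
  prov <- ds3$provenance[4, ]
  expect_equal(c(prov$row, prov$col), c(224, 224))
  expect_equal(p$image[76, 1, 1], img3[300, 225, 1])  # last real row
  expect_equal(p$image[77, 1, 1], img3[299, 225, 1])  # mirrored
  expect_equal(p$image[78, 1, 1], img3[298, 225, 1])
  # provenance maps every patch to a unique location
  expect_false(any(duplicated(ds3$provenance[, c("row", "col")])))
})

test_that("dataset split is shuffled, disjoint and exhaustive", {
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  ds <- extract_patches(img, matrix(0L, 96, 96), 32, 32)
  sp <- split_dataset(ds, 0.7, seed = 4)
  expect_length(sp$train$patches, round(0.7 * 9))
  expect_length(sp$validation$patches, 9 - round(0.7 * 9))
  key <- function(d) paste(d$provenance$row, d$provenance$col)
  expect_length(intersect(key(sp$train), key(sp$validation)), 0)
  expect_setequal(c(key(sp$train), key(sp$validation)), key(ds))
  sp2 <- split_dataset(ds, 0.7, seed = 4)
  expect_identical(key(sp$train), key(sp2$train))
  one <- structure(list(patches = ds$patches[1],
                        provenance = ds$provenance[1, , drop = FALSE]),
                   class = "patch_dataset")
  expect_error(split_dataset(one, 0.7), "at least 2")
})

test_that("a 10-patch dataset splits 7/3 at the default fraction", {
  img <- array(runif(64 * 160 * 3), c(64, 160, 3))
  ds <- extract_patches(img, matrix(0L, 64, 160), 32, 32)
  expect_length(ds$patches, 10)
  sp <- split_dataset(ds, 0.7, seed = 1)
  expect_length(sp$train$patches, 7)
  expect_length(sp$validation$patches, 3)
})

test_that("training rejects degenerate configs and reduces the loss", {
  s <- make_study_stack(31, grid = c(21, 64, 64))
  ds <- vasc3d:::patches_from_stack(s$stack, s$masks, 32)
  sp <- split_dataset(ds, 0.7, seed = 2)
  expect_error(train_unet(sp$train, sp$validation,
                          seg_config(patch_size = 32, max_epochs = 0)),
               "max_epochs")
  m <- train_unet(sp$train, sp$validation,
                  seg_config(patch_size = 32, max_epochs = 6,
                             dice_target = 101, seed = 7))
  rep <- m$report
  best <- attr(rep, "best_epoch")
  expect_equal(attr(rep, "best_val_dice_pct"), max(rep$val_dice_pct))
  expect_lt(rep$train_loss[best], rep$train_loss[1])
})

test_that("tiled prediction preserves shape and matches whole-image inference", {
  s <- make_study_stack(32, grid = c(17, 64, 64))
  ds <- vasc3d:::patches_from_stack(s$stack, s$masks, 32)
  sp <- split_dataset(ds, 0.7, seed = 2)
  m <- train_unet(sp$train, sp$validation,
                  seg_config(patch_size = 32, max_epochs = 20, seed = 7))
  img <- s$stack$images[[2]]
  # non-multiple-of-patch input keeps its shape
  sub <- img[1:50, 1:58, , drop = FALSE]
  pm <- predict_mask(m, sub)
  expect_equal(dim(pm), c(50, 58))
  expect_true(all(pm %in% c(0L, 1L)))
  # whole-image pass vs the tiled machinery agree on the interior when a
  # single patch covers the image
  whole <- as.integer(vasc3d:::unet_predict_prob(m$params, img) >= 0.5)
  tiled <- predict_mask(m, img, patch_size = 64, overlap = 0)
  interior <- as.vector(matrix(whole, 64, 64)[9:56, 9:56]) ==
    as.vector(tiled[9:56, 9:56])
  expect_gte(mean(interior), 0.99)
  # deterministic inference for a fixed checkpoint
  expect_identical(tiled, predict_mask(m, img, patch_size = 64,
                                       overlap = 0))
})
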