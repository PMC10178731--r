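# Mutual information, pairwise MI-affine registration, transform chaining
# and affine warping.

test_that("MI of an image with itself equals its histogram entropy", {
  set.seed(11)
  img <- textured_image(64)
  for (bins in c(16, 32, 64)) {
    expect_equal(mutual_information(img, img, bins = bins),
                 entropy_oracle(img, bins), tolerance = 1e-9)
  }
})

test_that("independent noise carries almost no mutual information", {
  set.seed(12)
  a <- matrix(runif(256 * 256), 256, 256)
  b <- matrix(runif(256 * 256), 256, 256)
  expect_lt(mutual_information(a, b, bins = 16), 0.05)
})

test_that("MI is symmetric and invariant under bijective bin relabeling", {
  set.seed(13)
  a <- textured_image(48)
  b <- textured_image(48)
  expect_equal(mutual_information(a, b, 32), mutual_information(b, a, 32),
               tolerance = 1e-12)
  # monotone bijection on intensities permutes the histogram bins
  expect_equal(mutual_information(a, b, 32),
               mutual_information(1 - a, b, 32), tolerance = 1e-9)
})

test_that("constant images give MI 0 with a message", {
  expect_message(v <- mutual_information(matrix(1, 8, 8),
                                         matrix(runif(64), 8, 8)),
                 "constant")
  expect_equal(v, 0)
})

test_that("registering an identical pair returns (almost) the identity", {
  set.seed(14)
  img <- textured_image(96)
  est <- register_pair_affine(img, img)
  expect_lt(vasc3d:::corner_error(est, diag(3), dim(img)), 0.1)
})

test_that("known integer shift is recovered to sub-pixel accuracy", {
  set.seed(15)
  img <- textured_image(96)
  # shift content by (dx, dy) = (5, -3): moving[r, c] = fixed[r + 3, c - 5]
  moving <- matrix(0, 96, 96)
  moving[1:93, 6:96] <- img[4:96, 1:91]
  est <- register_pair_affine(img, moving)
  # forward map moving -> fixed must translate by (-5, +3)
  expect_lt(max(abs(est$matrix[1:2, 3] - c(-5, 3))), 0.5)
})

test_that("known rotation is recovered to 0.2 degrees", {
  set.seed(16)
  img <- textured_image(96)
  Tt <- vasc3d:::affine_from_params(theta = 5 * pi / 180,
                                    center = vasc3d:::transform_center(dim(img)))
  moving <- warp_affine(img, Tt)
  est <- register_pair_affine(img, moving)
  ang <- atan2(est$matrix[2, 1], est$matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-5)), 0.2)
})

test_that("the optimised objective is never below the identity objective", {
  set.seed(17)
  for (rep in 1:5) {
    img <- textured_image(64)
    Tt <- vasc3d:::affine_from_params(runif(1, -3, 3), runif(1, -3, 3),
                                      runif(1, -0.1, 0.1),
                                      center = vasc3d:::transform_center(dim(img)))
    moving <- warp_affine(img, Tt)
    est <- register_pair_affine(img, moving, pyramid_config(n_levels = 2))
    expect_gte(attr(est, "mi") + 1e-9, attr(est, "mi_identity"))
  }
})

test_that("pairwise transforms compose into the reference frame", {
  idn <- lapply(1:3, function(i) affine_transform(diag(3), moving = i,
                                                  fixed = i - 1))
  absn <- compose_to_reference(idn, 0)
  for (t in absn) expect_equal(t$matrix, diag(3))

  T10 <- matrix(c(1, 0, 0, 0.2, 1, 0, 3, -2, 1), 3, 3)  # col-major
  T21 <- matrix(c(0.9, 0.1, 0, 0, 1.1, 0, -1, 4, 1), 3, 3)
  pw <- list(affine_transform(T10, moving = 1, fixed = 0),
             affine_transform(T21, moving = 2, fixed = 1))
  absn <- compose_to_reference(pw, 0)
  expect_equal(absn[[1]]$matrix, diag(3))
  expect_equal(absn[[2]]$matrix, T10)
  expect_equal(absn[[3]]$matrix, T10 %*% T21)  # the 2-step chain by hand

  broken <- list(affine_transform(diag(3), moving = 1, fixed = 0),
                 affine_transform(diag(3), moving = 3, fixed = 2))
  expect_error(compose_to_reference(broken, 0), "chain is broken")
})

test_that("composed recovered transforms align an 8-slice affine-perturbed stack", {
  # identical section content (independent noise only), so the chain error
  # measures registration drift rather than anatomy change
  set.seed(41)
  ph <- generate_phantom(grid_shape = c(21, 96, 96), seed = 41)
  m <- slice_phantom(ph, 4, 1)$masks[[3]]
  base <- render_stain(m, "he", seed = 7)
  imgs <- lapply(1:8, function(i)
    pmin(pmax(base + array(rnorm(length(base), 0, 0.02), dim(base)), 0), 1))
  st <- section_stack(imgs, 1, 4, "he")
  ms <- mask_stack(rep(list(m), 8), 1, 4)
  pert <- perturb_stack(st, ms, perturbation_spec(
    max_rotation_deg = 4, max_translation_frac = 0.02, max_shear = 0.01,
    max_scale_dev = 0.01, elastic_amplitude_px = 0, seed = 43))
  co <- register_stack_coarse(pert$stack, reference_index = 0)
  truth <- vasc3d:::true_absolute_affines(pert$truth, 0)
  errs <- vapply(seq_along(truth), function(i)
    vasc3d:::corner_error(co$absolute[[i]], truth[[i]], c(96, 96)),
    numeric(1))
  expect_lt(mean(errs), 1)
})

test_that("affine warping honours its contract", {
  set.seed(18)
  img <- textured_image(48)
  expect_identical(warp_affine(img, diag(3)), img)
  # integer translation is an exact index shift
  Tt <- diag(3); Tt[1, 3] <- 4; Tt[2, 3] <- -2  # forward (col+4, row-2)
  w <- warp_affine(img, Tt)
  expect_equal(w[1:46, 5:48], img[3:48, 1:44], tolerance = 1e-12)
  # masks stay binary
  m <- matrix(0L, 48, 48); m[10:20, 12:30] <- 1L
  wm <- warp_affine(m + 0, vasc3d:::affine_from_params(1.3, -0.7, 0.1,
                                                       center = c(23.5, 23.5)),
                    mode = "mask")
  expect_true(all(wm %in% c(0, 1)))
  sing <- diag(3); sing[1, 1] <- 0
  expect_error(warp_affine(img, sing), "singular")
})
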