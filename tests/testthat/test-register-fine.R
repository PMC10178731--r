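# Flow fields: local NCC loss, smoothness loss, warping, analytic gradients
# and the deformable training loop.

test_that("ncc_loss agrees with the direct sliding-window oracle", {
  set.seed(51)
  for (rep in 1:20) {
    a <- matrix(runif(32 * 32), 32, 32)
    b <- matrix(runif(32 * 32), 32, 32)
    expect_equal(ncc_loss(a, b, window = 9),
                 1 - mean(ncc_map_oracle(a, b, 9)), tolerance = 1e-6)
  }
})

test_that("NCC is perfect for identical and affinely rescaled images", {
  set.seed(52)
  a <- textured_image(48)
  expect_lte(ncc_loss(a, a, 9), 1e-6)
  expect_lte(ncc_loss(1.7 * a + 0.2, a, 9), 1e-6)
})

test_that("anti-correlated images reach the loss ceiling of 2", {
  set.seed(53)
  a <- matrix(rnorm(40 * 40), 40, 40)
  a <- a - mean(a)
  l <- ncc_loss(-a, a, 7)
  expect_equal(l, 1 - mean(ncc_map_oracle(-a, a, 7)), tolerance = 1e-6)
  expect_equal(l, 2, tolerance = 1e-3)
})

test_that("gradient_loss follows its closed forms", {
  u <- array(3.7, c(20, 30, 2))            # constant flow, any value
  expect_equal(gradient_loss(u), 0)
  ramp <- array(0, c(20, 30, 2))
  ramp[, , 2] <- matrix(rep(0:29, each = 20), 20, 30)  # d_col = col
  expect_equal(gradient_loss(ramp), 1)
  set.seed(54)
  expect_gte(gradient_loss(array(rnorm(20 * 30 * 2), c(20, 30, 2))), 0)
})

test_that("analytic gradients match finite differences", {
  set.seed(55)
  # local NCC gradient w.r.t. the warped image
  a <- matrix(runif(12 * 12), 12, 12)
  b <- matrix(runif(12 * 12), 12, 12)
  g <- vasc3d:::local_ncc_grad(a, b, 5)
  eps <- 1e-6
  for (ix in sample(144, 6)) {
    ap <- a; ap[ix] <- ap[ix] + eps
    am <- a; am[ix] <- am[ix] - eps
    fd <- (ncc_loss(ap, b, 5) - ncc_loss(am, b, 5)) / (2 * eps)
    expect_equal(g[ix], fd, tolerance = 1e-4)
  }
  # smoothness gradient
  u <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  gu <- vasc3d:::gradient_loss_grad(u)
  for (ix in sample(length(u), 6)) {
    up <- u; up[ix] <- up[ix] + eps
    um <- u; um[ix] <- um[ix] - eps
    fd <- (gradient_loss(up) - gradient_loss(um)) / (2 * eps)
    expect_equal(gu[ix], fd, tolerance = 1e-5)
  }
  # bilinear sampler gradient w.r.t. the sampling coordinates
  img <- matrix(runif(100), 10, 10)
  mapr <- matrix(runif(36, 1, 8), 6, 6)
  mapc <- matrix(runif(36, 1, 8), 6, 6)
  gout <- matrix(rnorm(36), 6, 6)
  gr <- vasc3d:::cpp_sample_bilinear_grad(img, mapr, mapc, gout)
  f <- function(mr, mc) sum(gout * vasc3d:::cpp_sample_bilinear(img, mr, mc))
  for (ix in sample(36, 5)) {
    rp <- mapr; rp[ix] <- rp[ix] + eps
    rm <- mapr; rm[ix] <- rm[ix] - eps
    expect_equal(gr$gr[ix], (f(rp, mapc) - f(rm, mapc)) / (2 * eps),
                 tolerance = 1e-4)
  }
  # convolution backward pass
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  w <- array(rnorm(3 * 3 * 2 * 3, 0, 0.3), c(3, 3, 2, 3))
  bb <- rnorm(3)
  gy <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  bw <- vasc3d:::cpp_conv2d_bwd(x, w, gy)
  lossf <- function(xx, ww, bbb)
    sum(gy * vasc3d:::cpp_conv2d_fwd(xx, ww, bbb))
  for (ix in sample(length(x), 4)) {
    xp <- x; xp[ix] <- xp[ix] + eps
    xm <- x; xm[ix] <- xm[ix] - eps
    expect_equal(bw$gx[ix], (lossf(xp, w, bb) - lossf(xm, w, bb)) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (ix in sample(length(w), 4)) {
    wp <- w; wp[ix] <- wp[ix] + eps
    wm <- w; wm[ix] <- wm[ix] - eps
    expect_equal(bw$gw[ix], (lossf(x, wp, bb) - lossf(x, wm, bb)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("flow warping honours its contract", {
  set.seed(56)
  img <- textured_image(40)
  expect_identical(apply_flow(img, vasc3d:::zero_flow(40, 40)), img)
  # constant flow (0, +2): output pulls from 2 columns to the right
  u <- array(0, c(40, 40, 2)); u[, , 2] <- 2
  w <- apply_flow(img, u)
  expect_equal(w[, 1:38], img[, 3:40], tolerance = 1e-12)
  m <- matrix(0L, 40, 40); m[5:15, 5:15] <- 1L
  u2 <- array(rnorm(40 * 40 * 2, 0, 0.8), c(40, 40, 2))
  expect_true(all(apply_flow(m + 0, u2, mode = "mask") %in% c(0, 1)))
  expect_error(apply_flow(img, array(0, c(20, 20, 2))), "shape")
})

test_that("an already-aligned stack learns near-zero flows", {
  # aligned AND anatomically identical slices (independent sensor noise
  # only): the null-deformation case the flow head must not unlearn
  set.seed(61)
  ph <- generate_phantom(grid_shape = c(21, 48, 48), seed = 9)
  m <- slice_phantom(ph, 4, 1)$masks[[3]]
  base <- render_stain(m, "he", seed = 100)
  imgs <- lapply(1:6, function(i)
    pmin(pmax(base + array(rnorm(length(base), 0, 0.02), dim(base)), 0), 1))
  st <- section_stack(imgs, 1, 4, "he")
  model <- train_fine_registration(st, fine_config(epochs = 10, seed = 2))
  g <- lapply(imgs, luminance)
  for (i in 2:3) {
    fl <- predict_flow(model, g[[i - 1]], g[[i]])
    mag <- sqrt(fl$displacement[, , 1]^2 + fl$displacement[, , 2]^2)
    expect_lt(mean(mag), 0.5)
  }
})

test_that("fine registration improves elastic misalignment and is inverse-consistent", {
  s <- make_study_stack(62, grid = c(21, 64, 64),
                        pspec = perturbation_spec(0, 0, 0, 0,
                                                  elastic_amplitude_px = 2.5,
                                                  elastic_smoothness_px = 8,
                                                  seed = 3))
  fine <- register_fine_stack(s$pert$stack, s$pert$masks,
                              fine_config(epochs = 25, seed = 4))
  before <- mean(vapply(1:5, function(i)
    dice(s$pert$masks$masks[[i]], s$pert$masks$masks[[i + 1]]), numeric(1)))
  after <- mean(vapply(1:5, function(i)
    dice(fine$masks$masks[[i]], fine$masks$masks[[i + 1]]), numeric(1)))
  expect_gt(after, before)
  # composing forward and backward flows approximately restores an image
  g <- lapply(s$pert$stack$images, luminance)
  fwd <- predict_flow(fine$model, g[[1]], g[[2]])
  bwd <- predict_flow(fine$model, g[[2]], g[[1]])
  roundtrip <- apply_flow(apply_flow(g[[2]], fwd), bwd)
  inner <- 9:56
  expect_lt(mean(abs(roundtrip[inner, inner] - g[[2]][inner, inner])), 0.06)
})
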