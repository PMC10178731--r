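# Phantom generation, sectioning geometry, stain rendering and recorded
# misalignment.

test_that("straight single tube gives one component and two endpoints", {
  ph <- generate_phantom(grid_shape = c(32, 48, 48), n_tubes = 1,
                         n_bifurcations = 0, curvature = 0, seed = 3)
  lab <- label_vessels(ph$volume)
  expect_equal(max(lab), 1)
  topo <- phantom_topology(ph)
  expect_equal(topo$n_endpoints, 2)
  expect_equal(topo$n_junctions, 0)
})

test_that("bifurcation count is reflected in centerline topology", {
  ph <- generate_phantom(grid_shape = c(32, 96, 96), n_tubes = 1,
                         n_bifurcations = 2, seed = 1)
  # brute-force degree enumeration over the stored polyline graph,
  # independent of phantom_topology(): nodes are (branch, point) pairs,
  # edges consecutive points plus the recorded parent attachments
  cl <- ph$centerline
  key <- function(b, p) paste(b, p)
  deg <- new.env(hash = TRUE)
  bump <- function(k) assign(k, (get0(k, envir = deg) %||% 0) + 1, envir = deg)
  for (b in unique(cl$branch)) {
    pts <- cl[cl$branch == b, ]
    for (i in seq_len(nrow(pts) - 1)) {
      bump(key(b, pts$point[i]))
      bump(key(b, pts$point[i + 1]))
    }
    if (!is.na(pts$parent[1])) {
      bump(key(pts$parent[1], pts$parent_at[1]))
      bump(key(b, 1))
    }
  }
  degs <- unlist(as.list(deg))
  expect_equal(sum(degs == 1), 4)   # 2 tube ends + 2 branch tips
  expect_equal(sum(degs >= 3), 2)   # the two bifurcation points
  # and the packaged topology query agrees
  topo <- phantom_topology(ph)
  expect_equal(topo$n_endpoints, 4)
  expect_equal(topo$n_junctions, 2)
})

test_that("phantom generation is deterministic per seed", {
  a <- generate_phantom(seed = 42)
  b <- generate_phantom(seed = 42)
  expect_identical(a$volume, b$volume)
  expect_identical(a$centerline, b$centerline)
  c <- generate_phantom(seed = 43)
  expect_false(identical(a$volume, c$volume))
})

test_that("sub-voxel radii are rejected with the offending radius named", {
  expect_error(generate_phantom(radius_range_um = c(0.4, 5)),
               "0\\.4.*below one voxel")
})

test_that("sectioning follows the physical geometry", {
  # depth 28 um at 1 um spacing, 4 um sections -> 8 sections
  ph <- generate_phantom(grid_shape = c(29, 48, 48), seed = 2)
  ms <- slice_phantom(ph, thickness_um = 4, pixel_um = 1)
  expect_length(ms$masks, 8)
  # anisotropy ratio of the H&E-like geometry
  ms2 <- slice_phantom(ph, thickness_um = 4, pixel_um = 0.28)
  expect_equal(ms2$thickness_um / ms2$pixel_um, 4 / 0.28, tolerance = 1e-12)
  # sectioning finer than the grid is impossible
  expect_error(slice_phantom(ph, thickness_um = 0.5, pixel_um = 1),
               "cannot section finer")
})

test_that("a plane with no vessel yields an all-zero mask", {
  ph <- generate_phantom(grid_shape = c(20, 40, 40), n_tubes = 1,
                         curvature = 0, seed = 5)
  ph$volume[10, , ] <- 0L  # carve out one plane
  ms <- slice_phantom(ph, thickness_um = 9, pixel_um = 1)
  # plane at z = 9 um maps to the carved grid plane (index 10)
  expect_true(all(ms$masks[[2]] == 0))
})

test_that("stain rendering separates vessel and background colors", {
  ph <- generate_phantom(grid_shape = c(20, 64, 64), seed = 7)
  m <- slice_phantom(ph, 4, 1)$masks[[3]]
  noise <- 0.04
  img <- render_stain(m, "he", noise_level = noise, seed = 9)
  for (ch in 1:3) {
    mv <- mean(img[, , ch][m == 1])
    mb <- mean(img[, , ch][m == 0])
    expect_gt(abs(mv - mb), noise)
  }
  expect_identical(img, render_stain(m, "he", noise_level = noise, seed = 9))
  # all-zero mask never draws from the vessel distribution: with noise off,
  # no pixel equals any vessel palette value
  img0 <- render_stain(matrix(0L, 32, 32), "dab", noise_level = 0, seed = 1)
  pal <- vasc3d:::stain_palettes$dab
  expect_gt(min(abs(img0[, , 1] - pal$vessel[1])), 0.05)
  expect_error(render_stain(m, "xyz"), "valid styles.*he.*dab")
})

test_that("rendered stacks share stroma texture across neighbouring slices", {
  ph <- generate_phantom(grid_shape = c(29, 64, 64), seed = 8)
  ms <- slice_phantom(ph, 4, 1)
  st <- render_stack(ms, "he", seed = 4)
  g <- lapply(st$images, luminance)
  # adjacent sections correlate well above non-adjacent ones
  r_adj <- cor(as.vector(g[[4]]), as.vector(g[[5]]))
  r_far <- cor(as.vector(g[[1]]), as.vector(g[[8]]))
  expect_gt(r_adj, r_far)
})

test_that("zero perturbation is the identity and truth records identities", {
  s <- make_study_stack(21, grid = c(21, 48, 48))
  spec0 <- perturbation_spec(0, 0, 0, 0, 0, 0, seed = 1)
  pt <- perturb_stack(s$stack, s$masks, spec0)
  expect_identical(pt$stack$images, s$stack$images)
  expect_identical(pt$masks$masks, s$masks$masks)
  for (i in seq_along(pt$truth$affines)) {
    expect_equal(pt$truth$affines[[i]], diag(3))
    expect_true(all(pt$truth$flows[[i]] == 0))
  }
})

test_that("recorded inverse transforms undo the perturbation", {
  s <- make_study_stack(22, grid = c(21, 64, 64))
  pt <- perturb_stack(s$stack, s$masks, perturbation_spec(seed = 5))
  inner <- 9:56  # interior, away from the zero-filled warp border
  for (i in c(2, 5)) {
    rec <- invert_perturbation(luminance(pt$stack$images[[i]]), pt$truth, i)
    orig <- luminance(s$stack$images[[i]])
    mae <- mean(abs(rec[inner, inner] - orig[inner, inner]))
    expect_lt(mae, 0.035)  # interpolation + noise-resampling error budget
  }
})

test_that("perturbation is deterministic per seed", {
  s <- make_study_stack(23, grid = c(17, 48, 48))
  a <- perturb_stack(s$stack, s$masks, perturbation_spec(seed = 11))
  b <- perturb_stack(s$stack, s$masks, perturbation_spec(seed = 11))
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth$affines, b$truth$affines)
})
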