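# Thinning, branch graphs, vessel labeling and branch statistics, checked
# against topology and path-enumeration oracles.

test_that("thinning a ball leaves a small central cluster with Euler characteristic 1", {
  ball <- solid_ball(6)
  expect_equal(euler_oracle(ball), 1)
  sk <- skeletonize_3d(ball, c(1, 1, 1))
  expect_lte(sum(sk$voxels), 10)
  expect_gte(sum(sk$voxels), 1)
  expect_equal(euler_oracle(sk$voxels), 1)
  # every skeleton voxel was foreground in the source
  expect_true(all(ball[sk$voxels == 1] == 1))
})

test_that("a solid cylinder thins to a single branch of nearly its length", {
  cyl <- solid_cylinder(radius = 3, len = 100)
  sk <- skeletonize_3d(cyl, c(1, 1, 1))
  g <- build_branch_graph(sk)
  st <- branch_statistics(g)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_sub_branches, 0)
  expect_lte(abs(st$main_branch_um - 100), 5)  # within 5% of the length
})

test_that("a solid torus thins to exactly one independent cycle", {
  tor <- solid_torus()
  expect_equal(euler_oracle(tor), 0)
  sk <- skeletonize_3d(tor, c(1, 1, 1))
  expect_equal(euler_oracle(sk$voxels), 0)
  g <- build_branch_graph(sk)
  cycles <- nrow(g$edges) - nrow(g$nodes) +
    length(unique(g$nodes$component))
  expect_equal(cycles, 1)
})

test_that("thinning preserves component and cycle counts across phantom shapes", {
  shapes <- list(ball = solid_ball(5), cylinder = solid_cylinder(2, 30),
                 torus = solid_torus(6, 2), y = solid_y_arms(20, 15, 10))
  two <- array(0L, c(30, 9, 9))
  two[2:28, 3, 3] <- 1L
  two[2:28, 7, 7] <- 1L
  shapes$h_pair <- two
  for (nm in names(shapes)) {
    v <- shapes[[nm]]
    sk <- skeletonize_3d(v, c(1, 1, 1))
    expect_equal(max(label_vessels(sk$voxels)), max(label_vessels(v)),
                 info = nm)
    expect_equal(euler_oracle(sk$voxels), euler_oracle(v), info = nm)
  }
})

test_that("branch graph reads a straight line, a Y and a single voxel correctly", {
  v <- array(0L, c(3, 3, 12)); v[2, 2, 2:11] <- 1L  # 10-voxel line
  g <- build_branch_graph(as_skeleton(v))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$length_um, 9)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)

  y <- skeletonize_3d(solid_y_arms(40, 30, 20), c(1, 1, 1))
  gy <- build_branch_graph(y)
  expect_equal(sum(gy$nodes$kind == "junction"), 1)
  expect_equal(sum(gy$nodes$kind == "endpoint"), 3)
  expect_equal(nrow(gy$edges), 3)

  v1 <- array(0L, c(3, 3, 3)); v1[2, 2, 2] <- 1L
  g1 <- build_branch_graph(as_skeleton(v1))
  expect_equal(nrow(g1$nodes), 1)
  expect_equal(nrow(g1$edges), 0)
})

test_that("vessel labeling partitions the foreground with stable order", {
  two <- array(0L, c(20, 9, 9))
  two[2:18, 3, 3] <- 1L
  two[2:18, 7, 7] <- 1L
  lab <- label_vessels(two)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab > 0), sum(two))
  expect_equal(sort(unique(as.vector(lab))), 0:2)
  # first component in scan order gets label 1
  first <- which(two == 1)[1]
  expect_equal(lab[first], 1L)
  expect_equal(max(label_vessels(array(0L, c(4, 4, 4)))), 0)
})

test_that("branch statistics match brute-force endpoint-path enumeration", {
  # thinned solid Y with arms 40/30/20: main branch a+b, one sub-branch c
  sk <- skeletonize_3d(solid_y_arms(40, 30, 20), c(1, 1, 1))
  g <- build_branch_graph(sk)
  st <- branch_statistics(g)
  oracle <- longest_path_oracle(g)
  expect_equal(st$main_branch_um, oracle[["1"]], tolerance = 1e-9)
  expect_equal(st$main_branch_um, 70, tolerance = 1.5)
  expect_equal(st$n_sub_branches, 1)
  expect_equal(st$sub_branch_um[[1]], 20, tolerance = 1.5)
  expect_gte(st$main_branch_um, max(st$sub_branch_um[[1]]))

  # and on a random branching phantom (several junctions)
  ph <- generate_phantom(grid_shape = c(40, 64, 64), n_tubes = 1,
                         n_bifurcations = 3, seed = 19)
  skp <- skeletonize_3d(ph$volume, ph$spacing_um)
  gp <- build_branch_graph(skp)
  stp <- branch_statistics(gp)
  lp <- longest_path_oracle(gp)
  for (i in seq_len(nrow(stp)))
    expect_equal(stp$main_branch_um[i],
                 lp[[as.character(stp$component[i])]], tolerance = 1e-9)
})

test_that("two components yield independent statistics rows", {
  two <- array(0L, c(30, 9, 9))
  two[2:28, 3, 3] <- 1L   # length 26
  two[2:16, 7, 7] <- 1L   # length 14
  g <- build_branch_graph(as_skeleton(two))
  st <- branch_statistics(g)
  expect_equal(nrow(st), 2)
  expect_setequal(round(st$main_branch_um), c(26, 14))
  expect_true(all(st$n_sub_branches == 0))
})

test_that("branch totals are invariant under node relabeling", {
  ph <- generate_phantom(grid_shape = c(30, 48, 48), n_tubes = 2,
                         n_bifurcations = 1, seed = 23)
  g <- build_branch_graph(skeletonize_3d(ph$volume, ph$spacing_um))
  # renumber the nodes by a random permutation, consistently in both tables
  set.seed(24)
  perm <- sample(nrow(g$nodes))
  g2 <- g
  g2$nodes$id <- perm[g$nodes$id]
  g2$edges$from <- perm[g$edges$from]
  g2$edges$to <- perm[g$edges$to]
  ord <- order(g2$nodes$id)
  g2$nodes <- g2$nodes[ord, ]
  expect_equal(sum(g2$edges$length_um), sum(g$edges$length_um))
  s1 <- branch_statistics(g)
  s2 <- branch_statistics(g2)
  expect_equal(s2$main_branch_um, s1$main_branch_um, tolerance = 1e-9)
  expect_equal(s2$total_um, s1$total_um, tolerance = 1e-9)
  expect_equal(s2$n_sub_branches, s1$n_sub_branches)
})

test_that("branch table CSV carries the documented columns", {
  sk <- skeletonize_3d(solid_y_arms(20, 15, 10), c(1, 1, 1))
  g <- build_branch_graph(sk)
  f <- tempfile(fileext = ".csv")
  write_branch_csv(g, f)
  df <- read.csv(f)
  expect_named(df, c("component_id", "branch_id", "kind", "length_um",
                     "z0", "y0", "x0", "z1", "y1", "x1"))
  expect_setequal(unique(df$kind), c("main", "sub"))
})
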