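# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written as brute-force / direct-definition code,
# independent of the package's implementation paths.

# -- images ----------------------------------------------------------------

# smooth random texture, the generic registration test image
textured_image <- function(H = 96, W = H, sigma = 2.5) {
  vasc3d:::smooth_gaussian(matrix(runif(H * W), H, W), sigma)
}

# -- overlap oracles -------------------------------------------------------

dice_oracle <- function(a, b) {
  ia <- which(a != 0)
  ib <- which(b != 0)
  if (length(ia) + length(ib) == 0) return(100)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib)) * 100
}

mutual_dice_oracle <- function(masks) {
  sets <- lapply(masks, function(m) which(m != 0))
  inter <- Reduce(intersect, sets)
  tot <- sum(lengths(sets))
  if (tot == 0) return(100)
  length(masks) * length(inter) / tot * 100
}

# -- Otsu oracle: exhaustive scan of all 256 bin thresholds ----------------

otsu_oracle <- function(x) {
  # exhaustive scan over all 256 histogram thresholds; intensities live on
  # the histogram's bin centers, as in any histogram-based Otsu
  nb <- 256L
  best_k <- 1L
  best_v <- -1
  bins <- pmin(nb, 1L + as.integer(floor(x * nb)))
  centers <- (bins - 0.5) / nb
  for (k in seq_len(nb - 1)) {
    lo <- centers[bins <= k]
    hi <- centers[bins > k]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v) {
      best_v <- v
      best_k <- k
    }
  }
  best_k / nb
}

# -- windowed NCC oracle: explicit per-pixel window extraction -------------

ncc_map_oracle <- function(a, b, win) {
  h <- win %/% 2
  H <- nrow(a); W <- ncol(a)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ri <- max(1, i - h):min(H, i + h)
    ci <- max(1, j - h):min(W, j + h)
    wa <- a[ri, ci]; wb <- b[ri, ci]
    ca <- wa - mean(wa); cb <- wb - mean(wb)
    out[i, j] <- sum(ca * cb) /
      sqrt(max(sum(ca^2) * sum(cb^2), 0) + 1e-10)
  }
  out
}

# -- histogram entropy (bits), the MI(A,A) oracle --------------------------

entropy_oracle <- function(x, bins) {
  rng <- range(x)
  ix <- pmin(bins, 1L + as.integer(floor((x - rng[1]) /
                                           (rng[2] - rng[1]) * bins)))
  p <- tabulate(ix, nbins = bins) / length(ix)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# -- Euler characteristic of the occupied cubical complex ------------------
# chi = V - E + F - C over vertices/edges/faces/cubes of the voxel complex.

euler_oracle <- function(vol) {
  d <- dim(vol)
  P <- array(FALSE, d + 2)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol != 0
  # a k-face of the complex exists iff any voxel cube incident to it is
  # occupied; free axes run over voxel cells, bound axes over lattice
  # boundaries with both incident cells OR-ed
  count_elem <- function(free) {
    combos <- expand.grid(lapply(1:3, function(a)
      if (a %in% free) 1L else 0:1))
    acc <- NULL
    for (r in seq_len(nrow(combos))) {
      o <- as.integer(combos[r, ])
      ix <- lapply(1:3, function(a)
        if (a %in% free) 2:(d[a] + 1) else (1 + o[a]):(d[a] + 1 + o[a]))
      s <- P[ix[[1]], ix[[2]], ix[[3]]]
      acc <- if (is.null(acc)) s else acc | s
    }
    sum(acc)
  }
  V <- count_elem(integer(0))
  E <- count_elem(1) + count_elem(2) + count_elem(3)
  Fc <- count_elem(c(1, 2)) + count_elem(c(1, 3)) + count_elem(c(2, 3))
  V - E + Fc - sum(vol != 0)
}

# -- longest endpoint-to-endpoint path by exhaustive DFS -------------------

longest_path_oracle <- function(graph) {
  # per component: enumerate all simple paths between all endpoint pairs
  res <- list()
  for (cc in sort(unique(graph$nodes$component))) {
    nodes <- graph$nodes[graph$nodes$component == cc, ]
    edges <- graph$edges[graph$edges$component == cc, ]
    terms <- nodes$id[nodes$degree <= 1]
    best <- 0
    if (length(terms) >= 2 && nrow(edges) > 0) {
      adjacency <- lapply(nodes$id, function(v)
        which(edges$from == v | edges$to == v))
      names(adjacency) <- as.character(nodes$id)
      dfs <- function(v, target, used, len) {
        if (v == target && any(used)) {
          best <<- max(best, len)
          return(invisible())
        }
        for (ei in adjacency[[as.character(v)]]) {
          if (used[ei]) next
          w <- if (edges$from[ei] == v) edges$to[ei] else edges$from[ei]
          used[ei] <- TRUE
          dfs(w, target, used, len + edges$length_um[ei])
          used[ei] <- FALSE
        }
      }
      for (i in seq_along(terms)) for (j in seq_along(terms)) {
        if (j <= i) next
        dfs(terms[i], terms[j], rep(FALSE, nrow(edges)), 0)
      }
    }
    res[[as.character(cc)]] <- best
  }
  res
}

# -- small solid phantoms --------------------------------------------------

solid_ball <- function(r = 6, pad = 2) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  v <- array(0L, c(n, n, n))
  for (k in 1:n) for (j in 1:n) for (i in 1:n)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r^2) v[i, j, k] <- 1L
  v
}

solid_cylinder <- function(radius = 3, len = 100, pad = 2) {
  side <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  v <- array(0L, c(len + 2 * pad, side, side))
  for (k in (pad + 1):(pad + len)) for (j in 1:side) for (i in 1:side)
    if ((j - ctr)^2 + (i - ctr)^2 <= radius^2) v[k, j, i] <- 1L
  v
}

solid_torus <- function(R = 8, r = 2) {
  n <- 2 * (R + r) + 5
  ctr <- (n + 1) / 2
  h <- 2 * r + 5
  v <- array(0L, c(h, n, n))
  for (k in 1:h) for (j in 1:n) for (i in 1:n) {
    rho <- sqrt((i - ctr)^2 + (j - ctr)^2)
    if ((rho - R)^2 + (k - (h + 1) / 2)^2 <= r^2) v[k, j, i] <- 1L
  }
  v
}

# solid Y: three orthogonal solid arms meeting at one point, returning both
# the volume and the arm lengths
solid_y_arms <- function(a = 40, b = 30, c = 20, radius = 2) {
  pad <- radius + 2
  v <- array(0L, c(2 * pad + 1, b + c + 2 * pad + 1, a + 2 * pad + 1))
  zc <- pad + 1
  yj <- c + pad + 1   # junction y
  xj <- pad + 1       # junction x
  stamp <- function(z, y, x) {
    for (dz in -radius:radius) for (dy in -radius:radius)
      for (dx in -radius:radius)
        if (dz^2 + dy^2 + dx^2 <= radius^2)
          v[z + dz, y + dy, x + dx] <<- 1L
  }
  for (t in 0:a) stamp(zc, yj, xj + t)      # arm a along +x
  for (t in 0:b) stamp(zc, yj + t, xj)      # arm b along +y
  for (t in 0:c) stamp(zc, yj - t, xj)      # arm c along -y
  v
}

# skeleton object straight from a voxel array
as_skeleton <- function(v, spacing = c(1, 1, 1)) {
  structure(list(voxels = v, spacing_um = spacing), class = "skeleton3d")
}

# quick rendered + perturbed stack for registration tests
make_study_stack <- function(seed, grid = c(29, 96, 96), n_tubes = 3,
                             n_bif = 2, pspec = NULL) {
  ph <- generate_phantom(grid_shape = grid, n_tubes = n_tubes,
                         n_bifurcations = n_bif, seed = seed)
  ms <- slice_phantom(ph, thickness_um = 4, pixel_um = 1)
  st <- render_stack(ms, "he", seed = seed + 1000)
  pspec <- pspec %||% perturbation_spec(seed = seed + 2000)
  pert <- perturb_stack(st, ms, pspec)
  list(phantom = ph, masks = ms, stack = st, pert = pert)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
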