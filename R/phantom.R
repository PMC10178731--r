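# Synthetic 3D vessel phantoms: random-walk tube polylines with bounded
# curvature, dilated to tubes, with analytic centerline topology retained so
# skeleton and branch statistics can be checked against ground truth.

#' Generate a branching-tube vessel phantom
#'
#' Tubes are grown as random walks through the physical volume with bounded
#' curvature, biased along the z (cutting) axis so each tube crosses many
#' section planes. Bifurcations attach child walks to interior points of
#' existing tubes, so every tube tree is connected by construction. The walk
#' polylines (the analytic centerlines) and per-branch radii are stored on
#' the returned object.
#'
#' @param grid_shape voxel grid `(nz, ny, nx)`.
#' @param n_tubes number of independent tube trees.
#' @param n_bifurcations total number of bifurcation points, distributed at
#'   random over the tubes.
#' @param radius_range_um tube radius range, micrometres; every radius must
#'   cover at least one voxel at the given spacing.
#' @param spacing_um voxel size `(z, y, x)` in micrometres.
#' @param curvature per-step direction jitter of the walk (0 gives straight
#'   tubes).
#' @param seed RNG seed; fixes every random draw.
#' @return a `vessel_phantom` with fields `volume` (binary (nz, ny, nx)
#'   array), `spacing_um`, `centerline` (data.frame of polyline points with
#'   tube/branch ids, voxel coordinates), `tube_radii_um` (per branch).
#' @export
generate_phantom <- function(grid_shape = c(32, 96, 96), n_tubes = 1,
                             n_bifurcations = 0,
                             radius_range_um = c(4, 7),
                             spacing_um = c(1, 1, 1), curvature = 0.08,
                             seed = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2),
            all(spacing_um > 0), length(radius_range_um) == 2)
  rmin_vox <- min(radius_range_um) / max(spacing_um)
  if (rmin_vox < 1)
    stop(sprintf("tube radius %.3g um is below one voxel at spacing %.3g um",
                 min(radius_range_um), max(spacing_um)))
  with_seed(seed, {
    ext <- (grid_shape - 1) * spacing_um  # physical extent (z, y, x), um
    rmax <- max(radius_range_um)
    margin <- rmax + max(spacing_um)
    step <- min(spacing_um)
    branches <- list()
    bid <- 0L

    walk <- function(start, dir, n_steps, lo, hi) {
      pts <- matrix(NA_real_, n_steps + 1, 3)
      pts[1, ] <- start
      for (s in seq_len(n_steps)) {
        dir <- dir + rnorm(3, 0, curvature)
        dir <- dir / sqrt(sum(dir^2))
        p <- pts[s, ] + step * dir
        for (a in 1:3) {  # reflect at the padded bounds
          if (p[a] < lo[a]) { p[a] <- 2 * lo[a] - p[a]; dir[a] <- -dir[a] }
          if (p[a] > hi[a]) { p[a] <- 2 * hi[a] - p[a]; dir[a] <- -dir[a] }
        }
        pts[s + 1, ] <- p
      }
      pts
    }

    # tubes span the full depth (vessels are cut at the block faces) but
    # keep an in-plane margin so sections do not clip them laterally
    lo <- c(0, margin, margin)
    hi <- pmax(ext - c(0, margin, margin), lo + 1e-6)
    # enough steps that a z-biased walk reliably traverses the full depth
    n_main_steps <- max(8L, as.integer(ceiling(1.6 * (hi[1] - lo[1]) / step)))

    for (tube in seq_len(n_tubes)) {
      start <- c(lo[1], runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
      dir <- c(1, rnorm(2, 0, 0.3))
      dir <- dir / sqrt(sum(dir^2))
      bid <- bid + 1L
      branches[[bid]] <- list(tube = tube, branch = bid,
                              pts = walk(start, dir, n_main_steps, lo, hi),
                              radius = runif(1, radius_range_um[1],
                                             radius_range_um[2]))
    }

    if (n_bifurcations > 0) for (b in seq_len(n_bifurcations)) {
      parent <- branches[[sample(length(branches), 1)]]
      np <- nrow(parent$pts)
      at <- sample(seq(max(2, round(np * 0.2)), max(3, round(np * 0.8))), 1)
      p0 <- parent$pts[at, ]
      pdir <- parent$pts[min(at + 1, np), ] - parent$pts[max(at - 1, 1), ]
      pdir <- pdir / sqrt(sum(pdir^2))
      # deviate the child direction by 30-60 degrees off the parent axis
      perp <- rnorm(3); perp <- perp - sum(perp * pdir) * pdir
      perp <- perp / sqrt(sum(perp^2))
      ang <- runif(1, 30, 60) * pi / 180
      cdir <- cos(ang) * pdir + sin(ang) * perp
      bid <- bid + 1L
      branches[[bid]] <- list(tube = parent$tube, branch = bid,
                              parent = parent$branch, parent_at = at,
                              pts = walk(p0, cdir,
                                         max(5L, n_main_steps %/% 2L), lo, hi),
                              radius = parent$radius * 0.8)
    }

    vol <- rasterize_tubes(branches, grid_shape, spacing_um)
    cl <- do.call(rbind, lapply(branches, function(br) {
      data.frame(tube = br$tube, branch = br$branch,
                 parent = br$parent %||% NA_integer_,
                 parent_at = br$parent_at %||% NA_integer_,
                 point = seq_len(nrow(br$pts)),
                 z = br$pts[, 1] / spacing_um[1],
                 y = br$pts[, 2] / spacing_um[2],
                 x = br$pts[, 3] / spacing_um[3])
    }))
    structure(list(volume = vol, spacing_um = spacing_um, centerline = cl,
                   tube_radii_um = vapply(branches, function(b) b$radius,
                                          numeric(1)),
                   grid_shape = grid_shape, seed = seed),
              class = "vessel_phantom")
  })
}

# Stamp spheres (physical-metric ellipsoids in voxel space) along densely
# resampled centerlines.
rasterize_tubes <- function(branches, grid_shape, spacing_um) {
  vol <- array(0L, grid_shape)
  nzyx <- grid_shape
  offsets_cache <- new.env()
  for (br in branches) {
    r <- br$radius
    key <- sprintf("%.4f", r)
    if (is.null(offsets_cache[[key]])) {
      nr <- ceiling(r / spacing_um)
      g <- expand.grid(dz = -nr[1]:nr[1], dy = -nr[2]:nr[2], dx = -nr[3]:nr[3])
      keep <- (g$dz * spacing_um[1])^2 + (g$dy * spacing_um[2])^2 +
        (g$dx * spacing_um[3])^2 <= r^2
      offsets_cache[[key]] <- as.matrix(g[keep, ])
    }
    off <- offsets_cache[[key]]
    pts <- br$pts
    # densify so consecutive stamps overlap
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    dense <- lapply(seq_along(seg), function(i) {
      k <- max(1L, ceiling(seg[i] / (0.5 * min(spacing_um))))
      t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
      outer(1 - t, pts[i, ]) + outer(t, pts[i + 1, ])
    })
    dense <- rbind(do.call(rbind, dense), pts[nrow(pts), , drop = FALSE])
    vox <- unique(round(sweep(dense, 2, spacing_um, "/")))
    for (i in seq_len(nrow(vox))) {
      p <- sweep(off, 2, vox[i, ], "+")
      keep <- p[, 1] >= 0 & p[, 1] < nzyx[1] & p[, 2] >= 0 & p[, 2] < nzyx[2] &
        p[, 3] >= 0 & p[, 3] < nzyx[3]
      p <- p[keep, , drop = FALSE]
      vol[1 + p[, 1] + nzyx[1] * p[, 2] + nzyx[1] * nzyx[2] * p[, 3]] <- 1L
    }
  }
  vol
}

#' @export
print.vessel_phantom <- function(x, ...) {
  topo <- phantom_topology(x)
  cat(sprintf("<vessel_phantom> grid %s, %.3g/%.3g/%.3g um spacing, %d branches, %d endpoints, %d junctions, %d fg voxels\n",
              paste(x$grid_shape, collapse = "x"), x$spacing_um[1],
              x$spacing_um[2], x$spacing_um[3],
              length(x$tube_radii_um), topo$n_endpoints, topo$n_junctions,
              sum(x$volume)))
  invisible(x)
}

#' Topology of a phantom's centerline graph
#'
#' Builds the graph of stored polylines (consecutive points connected;
#' each child branch attached at its recorded parent point) and counts node
#' degrees.
#'
#' @param phantom a `vessel_phantom`.
#' @return list with `n_endpoints` (degree-1 nodes), `n_junctions`
#'   (degree >= 3 nodes) and the degree table.
#' @export
phantom_topology <- function(phantom) {
  cl <- phantom$centerline
  key <- function(b, p) paste(b, p, sep = ":")
  edges <- character(0)
  for (b in unique(cl$branch)) {
    pts <- cl[cl$branch == b, ]
    n <- nrow(pts)
    if (n >= 2)
      edges <- c(edges, rbind(key(b, pts$point[-n]), key(b, pts$point[-1])))
    pa <- pts$parent[1]
    if (!is.na(pa))
      edges <- c(edges, key(pa, pts$parent_at[1]), key(b, 1))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  # child branches start AT the parent point: merge coincident nodes
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  # the first point of a child branch duplicates the parent's point spatially
  # but has its own id; contract nodes joined by the attachment edge length-0
  list(n_endpoints = sum(deg == 1), n_junctions = sum(deg >= 3),
       degrees = deg)
}

#' Section a phantom into a stack of binary masks
#'
#' Samples axial planes every `thickness_um` (starting at z = 0, the first
#' cutting plane) and resamples each plane in-plane to `pixel_um`.
#' The number of sections is `floor(depth / thickness_um) + 1`, with
#' `depth = (nz - 1) * spacing_z`.
#'
#' @param phantom a `vessel_phantom`.
#' @param thickness_um section thickness (>= phantom z spacing).
#' @param pixel_um target in-plane pixel size.
#' @return a [mask_stack()] of binary section masks.
#' @export
slice_phantom <- function(phantom, thickness_um = 4, pixel_um = 0.28) {
  sp <- phantom$spacing_um
  if (thickness_um < sp[1])
    stop(sprintf("thickness %.3g um is below the phantom z spacing %.3g um: cannot section finer than the phantom grid",
                 thickness_um, sp[1]))
  d <- dim(phantom$volume)
  depth <- (d[1] - 1) * sp[1]
  n_sec <- floor(depth / thickness_um) + 1
  H2 <- max(1L, as.integer(round(d[2] * sp[2] / pixel_um)))
  W2 <- max(1L, as.integer(round(d[3] * sp[3] / pixel_um)))
  masks <- lapply(seq_len(n_sec) - 1, function(s) {
    zi <- 1 + as.integer(round(s * thickness_um / sp[1]))
    zi <- min(max(zi, 1L), d[1])
    plane <- phantom$volume[zi, , ]
    if (all(dim(plane) == c(H2, W2))) return(matrix(as.integer(plane), H2, W2))
    r <- resize_matrix(plane + 0, H2, W2)
    matrix(as.integer(r >= 0.5), H2, W2)
  })
  mask_stack(masks, pixel_um = pixel_um, thickness_um = thickness_um)
}
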