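# Skeletonization and branch analysis: topology-preserving thinning of the
# vessel volume, a branch graph over the skeleton voxels, and per-vessel
# branch statistics (main branch, sub-branches).

#' Skeletonize a 3D binary volume
#'
#' Iterative removal of simple border voxels (26-connectivity for the
#' foreground, 6 for the background, endpoint-protecting, six directional
#' subiterations per cycle) until a fixed point: a one-voxel-wide,
#' topology-preserving centerline in the spirit of Lee's thinning.
#'
#' @param volume a [vessel_volume()] or binary (z, y, x) array.
#' @param spacing_um spacing if a bare array is given.
#' @return a `skeleton3d` object with fields `voxels` and `spacing_um`.
#' @export
skeletonize_3d <- function(volume, spacing_um = NULL) {
  if (inherits(volume, "vessel_volume")) {
    spacing_um <- volume$spacing_um
    volume <- volume$voxels
  }
  stopifnot(length(dim(volume)) == 3)
  if (!is_binary(volume)) stop("volume must be binary")
  spacing_um <- spacing_um %||% c(1, 1, 1)
  sk <- cpp_skeletonize3d(array(as.integer(volume), dim(volume)))
  structure(list(voxels = sk, spacing_um = as.numeric(spacing_um)),
            class = "skeleton3d")
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %s voxels of %d foreground, spacing %.3g/%.3g/%.3g um\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  invisible(x)
}

#' Label connected vessels
#'
#' 26-connected component labeling with stable label order (components are
#' numbered by their first voxel in array scan order).
#'
#' @param x a [vessel_volume()], `skeleton3d`, or binary 3D array.
#' @return integer array of the same shape; 0 is background.
#' @export
label_vessels <- function(x) {
  v <- if (inherits(x, "vessel_volume")) x$voxels
       else if (inherits(x, "skeleton3d")) x$voxels
       else x
  stopifnot(length(dim(v)) == 3)
  if (!is_binary(v)) stop("input must be binary")
  cpp_label3d(array(as.integer(v), dim(v)), 26L)
}

# 26-neighborhood offsets as a 26 x 3 matrix.
neigh26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
})

#' Build the branch graph of a skeleton
#'
#' Nodes are endpoints (exactly one 26-neighbor; isolated voxels count too)
#' and junctions. Because a voxel branch point is always accompanied by
#' mutually adjacent junction voxels under 26-connectivity, adjacent
#' junction voxels (degree >= 3) are merged into one junction node at their
#' centroid, in the spirit of unique-junction skeletal analysis. Edges are
#' the voxel chains traced between nodes; edge length is the sum of
#' physical euclidean steps along the chain plus the step from each merged
#' junction's centroid to the chain end. Pure cycles (all voxels degree 2)
#' get one anchor node carrying a self-loop edge.
#'
#' @param skeleton a `skeleton3d`.
#' @return a `branch_graph`: list with `nodes` (data.frame: id, z, y, x
#'   (possibly fractional centroids), degree, kind, component), `edges`
#'   (data.frame: id, from, to, length_um, n_voxels, component) and `paths`
#'   (list of voxel-coordinate matrices of the traced chains).
#' @export
build_branch_graph <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton3d"))
  sp <- skeleton$spacing_um
  d <- dim(skeleton$voxels)
  idx <- which(skeleton$voxels != 0)
  empty <- structure(list(
    nodes = data.frame(id = integer(), z = numeric(), y = numeric(),
                       x = numeric(), degree = integer(),
                       kind = character(), component = integer()),
    edges = data.frame(id = integer(), from = integer(), to = integer(),
                       length_um = numeric(), n_voxels = integer(),
                       component = integer()),
    paths = list(), spacing_um = sp), class = "branch_graph")
  if (length(idx) == 0) return(empty)
  coord <- cbind((idx - 1) %% d[1],
                 ((idx - 1) %/% d[1]) %% d[2],
                 (idx - 1) %/% (d[1] * d[2]))  # (z, y, x), 0-based
  nv <- length(idx)
  # adjacency by 26-neighborhood offset matching
  adj <- vector("list", nv)
  for (k in seq_len(nrow(neigh26))) {
    z <- coord[, 1] + neigh26[k, 1]
    y <- coord[, 2] + neigh26[k, 2]
    x <- coord[, 3] + neigh26[k, 3]
    ok <- z >= 0 & z < d[1] & y >= 0 & y < d[2] & x >= 0 & x < d[3]
    m <- rep(NA_integer_, nv)
    m[ok] <- match(1 + z[ok] + d[1] * y[ok] + d[1] * d[2] * x[ok], idx)
    hit <- which(!is.na(m))
    for (i in hit) adj[[i]] <- c(adj[[i]], m[i])
  }
  deg <- lengths(adj)
  # connected components of the voxel graph
  comp_of <- integer(nv)
  cid <- 0L
  for (s in seq_len(nv)) {
    if (comp_of[s] > 0L) next
    cid <- cid + 1L
    stack <- s
    comp_of[s] <- cid
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (q in adj[[p]]) if (comp_of[q] == 0L) {
        comp_of[q] <- cid
        stack <- c(stack, q)
      }
    }
  }
  # node voxels: endpoints/isolated (deg <= 1) and junction voxels
  # (deg >= 3); adjacent junction voxels merge into one cluster node
  is_junc <- deg >= 3L
  cluster_of <- integer(nv)  # 0 = not a junction voxel
  ncl <- 0L
  for (s in which(is_junc)) {
    if (cluster_of[s] > 0L) next
    ncl <- ncl + 1L
    stack <- s
    cluster_of[s] <- ncl
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (q in adj[[p]]) if (is_junc[q] && cluster_of[q] == 0L) {
        cluster_of[q] <- ncl
        stack <- c(stack, q)
      }
    }
  }
  # anchor one voxel in every component with no endpoint and no junction
  anchor <- logical(nv)
  for (cc in seq_len(cid)) {
    members <- which(comp_of == cc)
    if (!any(deg[members] != 2L)) anchor[members[1]] <- TRUE
  }
  is_nodevox <- deg <= 1L | is_junc | anchor
  # node numbering: each endpoint/anchor voxel is its own node, each
  # junction cluster one node
  node_of <- integer(nv)
  node_pos <- list()  # (z, y, x) voxel coords, possibly fractional
  node_kind <- character(0)
  node_comp <- integer(0)
  node_deg <- integer(0)
  nid <- 0L
  for (v in which(is_nodevox & !is_junc)) {
    nid <- nid + 1L
    node_of[v] <- nid
    node_pos[[nid]] <- coord[v, ]
    node_kind[nid] <- if (deg[v] <= 1L) "endpoint" else "anchor"
    node_comp[nid] <- comp_of[v]
    node_deg[nid] <- deg[v]
  }
  if (ncl > 0) for (cl in seq_len(ncl)) {
    members <- which(cluster_of == cl)
    nid <- nid + 1L
    node_of[members] <- nid
    node_pos[[nid]] <- colMeans(coord[members, , drop = FALSE])
    node_kind[nid] <- "junction"
    node_comp[nid] <- comp_of[members[1]]
    node_deg[nid] <- max(deg[members])
  }
  phys <- function(p) p * sp  # voxel (z,y,x) -> um
  dist_um <- function(p, q) sqrt(sum((phys(p) - phys(q))^2))
  # an edge is either (a) a maximal chain of degree-2 non-node voxels plus
  # its two terminal node voxels, or (b) a direct adjacency between voxels
  # of two different nodes (deduplicated per node pair)
  edges <- list()
  paths <- list()
  add_edge <- function(path_vox) {
    t1 <- path_vox[1]; t2 <- path_vox[length(path_vox)]
    from_id <- node_of[t1]; to_id <- node_of[t2]
    pvox <- coord[path_vox, , drop = FALSE]
    pts <- lapply(seq_len(nrow(pvox)), function(i) pvox[i, ])
    if (node_kind[from_id] == "junction") pts[[1]] <- node_pos[[from_id]]
    if (node_kind[to_id] == "junction") pts[[length(pts)]] <- node_pos[[to_id]]
    len <- 0
    for (i in seq_len(length(pts) - 1))
      len <- len + dist_um(pts[[i]], pts[[i + 1]])
    edges[[length(edges) + 1]] <<-
      data.frame(from = from_id, to = to_id, length_um = len,
                 n_voxels = length(path_vox), component = comp_of[t1])
    paths[[length(edges)]] <<- pvox
  }
  chain_seen <- logical(nv)
  for (q in which(!is_nodevox)) {
    if (chain_seen[q]) next
    chain_seen[q] <- TRUE
    walk_dir <- function(first) {
      out <- integer(0)
      prev <- q; cur <- first
      repeat {
        out <- c(out, cur)
        if (is_nodevox[cur]) break
        chain_seen[cur] <<- TRUE
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0) break
        prev <- cur; cur <- nxt[1]
      }
      out
    }
    nbrs <- adj[[q]]
    left <- walk_dir(nbrs[1])
    right <- if (length(nbrs) > 1) walk_dir(nbrs[2]) else integer(0)
    add_edge(c(rev(left), q, right))
  }
  pair_seen <- new.env(hash = TRUE)
  for (v0 in which(is_nodevox)) for (nb in adj[[v0]]) {
    if (!is_nodevox[nb]) next
    if (node_of[nb] == node_of[v0]) next
    key <- paste(min(node_of[v0], node_of[nb]),
                 max(node_of[v0], node_of[nb]), sep = "-")
    if (!is.null(pair_seen[[key]])) next
    pair_seen[[key]] <- TRUE
    add_edge(c(v0, nb))
  }
  nodes <- data.frame(
    id = seq_len(nid),
    z = vapply(node_pos, `[`, numeric(1), 1),
    y = vapply(node_pos, `[`, numeric(1), 2),
    x = vapply(node_pos, `[`, numeric(1), 3),
    degree = node_deg, kind = node_kind, component = node_comp)
  edges <- if (length(edges)) {
    e <- do.call(rbind, edges)
    e$id <- seq_len(nrow(e))
    e[, c("id", "from", "to", "length_um", "n_voxels", "component")]
  } else {
    data.frame(id = integer(), from = integer(), to = integer(),
               length_um = numeric(), n_voxels = integer(),
               component = integer())
  }
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 spacing_um = sp), class = "branch_graph")
}

#' @export
print.branch_graph <- function(x, ...) {
  cat(sprintf("<branch_graph> %d nodes (%d endpoints, %d junctions), %d edges, %d components\n",
              nrow(x$nodes), sum(x$nodes$kind == "endpoint"),
              sum(x$nodes$kind == "junction"), nrow(x$edges),
              length(unique(x$nodes$component))))
  invisible(x)
}

#' Per-vessel branch statistics
#'
#' For every connected component, the main branch is the maximum-length
#' endpoint-to-endpoint path over the branch graph (edge lengths in
#' micrometres); the remaining edges are sub-branches. For components whose
#' graph contains cycles, the longest simple path is found by exhaustive
#' path enumeration when the component has at most `endpoint_budget`
#' endpoint nodes, otherwise by a double-sweep heuristic.
#'
#' @param graph a `branch_graph`.
#' @param endpoint_budget exhaustive-search limit for cyclic components.
#' @return a `branch_stats` data.frame, one row per component:
#'   `component`, `main_branch_um`, `n_sub_branches`, `sub_branch_um`
#'   (list column), `total_um`, `n_edges`.
#' @export
branch_statistics <- function(graph, endpoint_budget = 12) {
  stopifnot(inherits(graph, "branch_graph"))
  comps <- sort(unique(graph$nodes$component))
  res <- lapply(comps, function(cc) {
    nodes <- graph$nodes[graph$nodes$component == cc, ]
    edges <- graph$edges[graph$edges$component == cc, ]
    if (nrow(edges) == 0)
      return(data.frame(component = cc, main_branch_um = 0,
                        n_sub_branches = 0L,
                        sub_branch_um = I(list(numeric(0))),
                        total_um = 0, n_edges = 0L))
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$from),
                 to = as.character(edges$to),
                 weight = edges$length_um, eid = edges$id),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$id)))
    terminals <- as.character(nodes$id[nodes$degree <= 1])
    if (length(terminals) == 0)  # pure cycle: anchor node only
      terminals <- as.character(nodes$id[1])
    has_cycle <- nrow(edges) > nrow(nodes) - 1
    best <- list(len = 0, eids = integer(0))
    consider <- function(len, eids) {
      if (len > best$len) best <<- list(len = len, eids = eids)
    }
    if (length(terminals) == 1) {
      consider(0, integer(0))
    } else if (!has_cycle) {
      # tree: the unique path between endpoints is the shortest path
      dm <- igraph::distances(g, v = terminals, to = terminals)
      pick <- which(dm == max(dm), arr.ind = TRUE)[1, ]
      sp <- igraph::shortest_paths(g, from = terminals[pick[1]],
                                   to = terminals[pick[2]],
                                   output = "epath")$epath[[1]]
      consider(max(dm), igraph::edge_attr(g, "eid", sp))
    } else if (length(terminals) <= endpoint_budget) {
      for (i in seq_along(terminals)) for (j in seq_along(terminals)) {
        if (j <= i) next
        ps <- igraph::all_simple_paths(g, from = terminals[i],
                                       to = terminals[j])
        for (p in ps) {
          ep <- igraph::E(g, path = p)
          consider(sum(igraph::edge_attr(g, "weight", ep)),
                   igraph::edge_attr(g, "eid", ep))
        }
      }
      if (best$len == 0 && length(terminals) == 1) consider(0, integer(0))
    } else {
      # double sweep: farthest node from an arbitrary start, then farthest
      # from there, shortest (weighted) path between the two
      d1 <- igraph::distances(g, v = terminals[1])
      a <- colnames(d1)[which.max(d1)]
      d2 <- igraph::distances(g, v = a)
      b <- colnames(d2)[which.max(d2)]
      sp <- igraph::shortest_paths(g, from = a, to = b,
                                   output = "epath")$epath[[1]]
      consider(max(d2), igraph::edge_attr(g, "eid", sp))
    }
    sub <- edges$length_um[!(edges$id %in% best$eids)]
    data.frame(component = cc, main_branch_um = best$len,
               n_sub_branches = length(sub),
               sub_branch_um = I(list(sort(sub, decreasing = TRUE))),
               total_um = sum(edges$length_um), n_edges = nrow(edges))
  })
  out <- do.call(rbind, res)
  class(out) <- c("branch_stats", "data.frame")
  out
}

#' Write a branch table as CSV
#'
#' One row per branch: component, branch id, kind (main/sub), length and the
#' path endpoints in voxel coordinates.
#'
#' @param graph a `branch_graph`.
#' @param stats the matching [branch_statistics()] result (recomputed if
#'   NULL).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_branch_csv <- function(graph, path, stats = NULL) {
  if (is.null(stats)) stats <- branch_statistics(graph)
  e <- graph$edges
  kind <- rep("sub", nrow(e))
  for (i in seq_len(nrow(stats))) {
    cc <- stats$component[i]
    sub_lens <- stats$sub_branch_um[[i]]
    ecc <- e$component == cc
    # mark main-branch edges: those not accounted as sub-branches
    is_sub <- ecc & e$length_um %in% sub_lens
    kind[ecc & !is_sub] <- "main"
  }
  ep <- t(vapply(seq_len(nrow(e)), function(i) {
    p <- graph$paths[[e$id[i]]]
    c(p[1, ], p[nrow(p), ])
  }, numeric(6)))
  df <- data.frame(component_id = e$component, branch_id = e$id, kind = kind,
                   length_um = e$length_um,
                   z0 = ep[, 1], y0 = ep[, 2], x0 = ep[, 3],
                   z1 = ep[, 4], y1 = ep[, 5], x1 = ep[, 6])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
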