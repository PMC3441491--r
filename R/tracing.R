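#' Detect the soma as an approximate Chebyshev center
#'
#' The soma is the brightest, roughly spherical blob of the stack. Its
#' center is approximated by the point of Q that is deepest inside the
#' binarized neuron: for every candidate the radius of the largest physical
#' ball (micrometers, realized on the anisotropic grid) entirely contained
#' in the foreground is computed via an exact anisotropic 3D Euclidean
#' distance transform, and the candidate with the largest radius wins; exact
#' radius ties are broken by the larger intensity sum inside the ball.
#'
#' @param q a `skeleton_points` object.
#' @param stack the [image_stack] the mask came from.
#' @param vol the cleaned [binary_volume].
#' @return An object of class `soma_estimate`: `index` (row of `q$pts`),
#'   `point` (voxel), `position_um`, `radius_um`, `intensity_sum`.
#' @export
detect_soma <- function(q, stack, vol) {
  stopifnot(inherits(q, "skeleton_points"), nrow(q$pts) > 0L,
            inherits(vol, "binary_volume"), any(vol$mask))
  vs <- q$voxel_size
  d3 <- edt_3d(vol)
  rad <- d3[vox_lin(q$pts, q$dim)]
  rmax <- max(rad)
  cands <- which(rad == rmax)
  sums <- vapply(cands, function(i)
    ball_intensity_sum(stack, q$pts[i, ], rmax), numeric(1L))
  best <- cands[which.max(sums)]
  structure(list(index = best, point = q$pts[best, ],
                 position_um = drop(vox_to_um(q$pts[best, , drop = FALSE], vs)),
                 radius_um = rmax,
                 intensity_sum = max(sums)),
            class = "soma_estimate")
}

# exact anisotropic 3D EDT of a binary volume (distance to the nearest
# background voxel, micrometers); the volume border counts as background
edt_3d <- function(vol) {
  d <- dim(vol$mask)
  vs <- vol$voxel_size
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- vol$mask
  dd <- cpp_edt(pad, dim(pad), c(vs[["y"]], vs[["x"]], vs[["z"]]))
  array(dd, dim(pad))[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)]
}

ball_intensity_sum <- function(stack, center, radius_um) {
  vs <- stack$voxel_size
  d <- dim(stack$data)
  r_vox <- ceiling(radius_um / c(vs[["y"]], vs[["x"]], vs[["z"]]))
  lo <- pmax(center - r_vox, 1L)
  hi <- pmin(center + r_vox, d)
  yy <- lo[1L]:hi[1L]; xx <- lo[2L]:hi[2L]; zz <- lo[3L]:hi[3L]
  g <- expand.grid(y = yy, x = xx, z = zz)
  dy <- (g$y - center[1L]) * vs[["y"]]
  dx <- (g$x - center[2L]) * vs[["x"]]
  dz <- (g$z - center[3L]) * vs[["z"]]
  inside <- dy^2 + dx^2 + dz^2 <= radius_um^2
  sum(stack$data[as.matrix(g)[inside, , drop = FALSE]])
}

#' Build the weighted voxel graph
#'
#' Vertices are the points of Q; edges join 26-adjacent pairs. The base
#' weight `w_d` is the Euclidean step length in voxel-index units (1, sqrt 2
#' or sqrt 3). Near candidate branch points, edges receive a bonus: around
#' every flagged point a box approximating a ball of physical radius `R_um`
#' (half-widths `round(R_um / pitch)` voxels per axis, the 6 x 6 x 2 box at
#' the default 0.33/0.33/1.0 um pitch) is considered, and every edge with
#' both endpoints inside gets `w_b = eta - d`, `d` the voxel-space distance
#' from the branch point to the edge midpoint (the largest bonus wins when
#' boxes overlap; elsewhere `w_b = 0`). The traversal cost is
#' `f = w_d / (1 + w_b)`, so shortest paths are drawn through visual
#' bifurcations and traced branches meet at a single junction.
#'
#' @param q a `skeleton_points` object with branch candidates flagged.
#' @param eta bonus scale (default 10); inside the default box `d < eta`, so
#'   the bonus stays positive.
#' @param R_um physical bonus radius in micrometers (default 1.0).
#' @return An object of class `voxel_graph`: the igraph, the edge table
#'   `(i, j, w_d, w_b, cost)`, and `q`.
#' @export
build_graph <- function(q, eta = 10, R_um = 1.0) {
  stopifnot(inherits(q, "skeleton_points"), nrow(q$pts) > 0L)
  occ <- occupancy(q)
  dim3 <- q$dim
  offs <- offsets26()
  half <- offs[offs[, 3L] > 0L |
               (offs[, 3L] == 0L & (offs[, 2L] > 0L |
                (offs[, 2L] == 0L & offs[, 1L] > 0L))), , drop = FALSE]
  ei <- list(); ej <- list(); ew <- list()
  for (r in seq_len(nrow(half))) {
    dy <- half[r, 1L]; dx <- half[r, 2L]; dz <- half[r, 3L]
    yy <- q$pts[, 1L] + dy; xx <- q$pts[, 2L] + dx; zz <- q$pts[, 3L] + dz
    ok <- yy >= 1L & yy <= dim3[1L] & xx >= 1L & xx <= dim3[2L] &
          zz >= 1L & zz <= dim3[3L]
    nl <- occ$lin[ok] + dy + dim3[1L] * (dx + dim3[2L] * dz)
    jj <- occ$idmap[nl]
    hit <- jj > 0L
    ei[[r]] <- which(ok)[hit]
    ej[[r]] <- jj[hit]
    ew[[r]] <- rep(sqrt(dy^2 + dx^2 + dz^2), sum(hit))
  }
  ei <- unlist(ei); ej <- unlist(ej); w_d <- unlist(ew)
  n <- nrow(q$pts)
  ekey <- pmin(ei, ej) * (n + 1) + pmax(ei, ej)   # exact for n << 2^26
  w_b <- numeric(length(ei))
  bp_idx <- which(q$branch)
  if (length(bp_idx)) {
    vs <- q$voxel_size
    hw <- pmax(1L, round(R_um / c(vs[["y"]], vs[["x"]], vs[["z"]])))
    box <- as.matrix(expand.grid(dy = -hw[1L]:hw[1L], dx = -hw[2L]:hw[2L],
                                 dz = -hw[3L]:hw[3L]))
    mid <- (q$pts[ei, , drop = FALSE] + q$pts[ej, , drop = FALSE]) / 2
    for (b in bp_idx) {
      vox <- box + rep(q$pts[b, ], each = nrow(box))
      ok <- vox[, 1L] >= 1L & vox[, 1L] <= dim3[1L] &
            vox[, 2L] >= 1L & vox[, 2L] <= dim3[2L] &
            vox[, 3L] >= 1L & vox[, 3L] <= dim3[3L]
      ids <- occ$idmap[vox_lin(vox[ok, , drop = FALSE], dim3)]
      ids <- ids[ids > 0L]
      if (length(ids) < 2L) next
      prs <- utils::combn(sort(ids), 2L)
      keys <- prs[1L, ] * (n + 1) + prs[2L, ]
      er <- match(keys, ekey)
      er <- er[!is.na(er)]
      if (!length(er)) next
      dmid <- sqrt(rowSums((mid[er, , drop = FALSE] -
                            rep(q$pts[b, ], each = length(er)))^2))
      w_b[er] <- pmax(w_b[er], eta - dmid)
    }
  }
  cost <- w_d / (1 + w_b)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ei, ej))
  igraph::E(g)$weight <- cost
  structure(list(g = g,
                 edges = data.frame(i = ei, j = ej, w_d = w_d, w_b = w_b,
                                    cost = cost),
                 q = q, eta = eta, R_um = R_um),
            class = "voxel_graph")
}

#' Trace branches by Dijkstra shortest paths
#'
#' Computes the minimum-cost path from the soma center to every candidate
#' end point (all edge costs are positive, so Dijkstra applies).
#' Unreachable end points are dropped with a warning.
#'
#' @param graph a `voxel_graph`.
#' @param soma a `soma_estimate` (or a vertex index).
#' @param ends vertex indices of the end-point candidates; defaults to the
#'   flagged end candidates of the graph's point set.
#' @return An object of class `branch_set`: `paths` (list of vertex index
#'   sequences from the soma to each end point), `q`, `soma_index`.
#' @export
shortest_path_branches <- function(graph, soma, ends = NULL) {
  stopifnot(inherits(graph, "voxel_graph"))
  src <- if (inherits(soma, "soma_estimate")) soma$index else as.integer(soma)
  n <- nrow(graph$q$pts)
  if (src < 1L || src > n) stop("soma vertex not in graph")
  if (is.null(ends)) ends <- which(graph$q$end)
  ends <- setdiff(as.integer(ends), src)
  if (!length(ends))
    return(structure(list(paths = list(), q = graph$q, soma_index = src),
                     class = "branch_set"))
  sp <- suppressWarnings(
    igraph::shortest_paths(graph$g, from = src, to = ends,
                           mode = "all", output = "vpath"))
  paths <- lapply(sp$vpath, as.integer)
  reach <- lengths(paths) > 0L
  if (any(!reach))
    warning(sum(!reach), " end point(s) unreachable from the soma; dropped")
  structure(list(paths = paths[reach], q = graph$q, soma_index = src),
            class = "branch_set")
}

branch_lengths_um <- function(branches) {
  vs <- branches$q$voxel_size
  vapply(branches$paths, function(p)
    polyline_length(vox_to_um(branches$q$pts[p, , drop = FALSE], vs)),
    numeric(1L))
}

#' Prune short branches
#'
#' Removes every branch whose physical length is less than `min_ratio`
#' times the longest branch's length (strict inequality; a branch exactly at
#' the ratio is kept). Such short branches are typically paths in the
#' interior of the soma, not neuron fibers.
#'
#' @param branches a `branch_set`.
#' @param min_ratio length ratio threshold (default 0.2).
#' @return A pruned `branch_set`.
#' @export
prune_short_branches <- function(branches, min_ratio = 0.2) {
  stopifnot(inherits(branches, "branch_set"))
  if (!length(branches$paths)) return(branches)
  len <- branch_lengths_um(branches)
  branches$paths <- branches$paths[len >= min_ratio * max(len)]
  branches
}

#' False end points near an accepted branch
#'
#' Per-slice skeletonization creates spurious 3D end points along thick
#' fibers. Given a just-accepted branch P, any pending end point closer to P
#' than the mean EDT radius of P (converted to micrometers) is considered
#' false, and its branch is discarded.
#'
#' @param path vertex index sequence of the accepted branch.
#' @param q the `skeleton_points` the indices refer to.
#' @param pending vertex indices of end points not yet processed.
#' @return Integer subset of `pending` to drop.
#' @export
remove_false_endpoints <- function(path, q, pending) {
  if (!length(pending)) return(integer(0))
  vs <- q$voxel_size
  rbar <- mean(q$radius[path]) * (vs[["x"]] + vs[["y"]]) / 2
  pum <- vox_to_um(q$pts[path, , drop = FALSE], vs)
  eum <- vox_to_um(q$pts[pending, , drop = FALSE], vs)
  dd <- cpp_min_dists(as_num_matrix(eum), as_num_matrix(pum))
  pending[dd < rbar]
}

#' Merge traced branches into a single rooted tree
#'
#' Iteratively accepts the longest remaining branch and post-processes it:
#' walking from its tip toward the soma, the first point within
#' `t_bplist_um` of a recorded branch point q is identified with q and the
#' soma-side prefix is taken from the branch that created q; failing that,
#' the first point within `t_bps2d_um` of a candidate 2D branch point is
#' snapped onto it. Whenever an accepted branch diverges from the existing
#' tree, the divergence point is recorded in BpList. After each acceptance,
#' pending end points closer to the new branch than its mean fiber radius
#' are discarded as false end points.
#'
#' @param branches a (pruned) `branch_set`.
#' @param soma a `soma_estimate`.
#' @param t_bplist_um snap distance to recorded branch points (default 1.0).
#' @param t_bps2d_um snap distance to candidate 2D branch points
#'   (default 0.75).
#' @return A [neuron_tree] (micrometer coordinates, voxel size attached),
#'   with attributes `bplist` (voxel indices of recorded branch points) and
#'   `n_false_endpoints`.
#' @export
merge_branches <- function(branches, soma, t_bplist_um = 1.0,
                           t_bps2d_um = 0.75) {
  stopifnot(inherits(branches, "branch_set"), inherits(soma, "soma_estimate"))
  q <- branches$q
  vs <- q$voxel_size
  n <- nrow(q$pts)
  all_um <- vox_to_um(q$pts, vs)
  bps2d <- which(q$branch)

  in_tree <- logical(n)
  parent <- integer(n)               # 0 = root, NA pattern unused
  order_added <- integer(0)
  bplist <- integer(0)
  n_false <- 0L

  paths <- branches$paths
  lens <- branch_lengths_um(branches)
  tips <- vapply(paths, function(p) p[length(p)], integer(1L))
  ord <- order(-lens, tips)
  paths <- paths[ord]; tips <- tips[ord]
  pending <- rep(TRUE, length(paths))

  path_to_root <- function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(v, out) }
    out
  }

  first_near <- function(path, targets, thr) {
    # first index walking tip -> soma whose point lies within thr of a target
    tum <- all_um[targets, , drop = FALSE]
    pum <- all_um[path, , drop = FALSE]
    dd <- cpp_min_dists(as_num_matrix(pum), as_num_matrix(tum))
    hits <- which(dd <= thr)
    if (!length(hits)) return(NULL)
    i <- max(hits)                    # nearest to the tip
    pd <- sqrt(rowSums((tum - rep(pum[i, ], each = nrow(tum)))^2))
    list(i = i, target = targets[which.min(pd)])
  }

  for (step in seq_along(paths)) {
    if (!any(pending)) break
    k <- which(pending)[1L]           # paths already sorted longest first
    pending[k] <- FALSE
    P <- paths[[k]]
    if (any(in_tree)) {
      hit <- if (length(bplist))
        first_near(P, bplist, t_bplist_um) else NULL
      if (!is.null(hit)) {
        # reroute: prefix from the tree path to q, then the tip side of P
        pre <- path_to_root(hit$target)
        suf <- if (hit$i < length(P)) P[(hit$i + 1L):length(P)] else integer(0)
        P <- c(pre, suf)
      } else if (length(bps2d)) {
        hit2 <- first_near(P, bps2d, t_bps2d_um)
        if (!is.null(hit2) && P[hit2$i] != hit2$target)
          P[hit2$i] <- hit2$target
      }
    }
    P <- P[!duplicated(P)]
    # divergence from the existing tree: longest prefix already in the tree
    j <- 0L
    while (j < length(P) && in_tree[P[j + 1L]]) j <- j + 1L
    if (j > 0L && any(in_tree)) {
      bp <- P[j]
      if (!(bp %in% bplist)) bplist <- c(bplist, bp)
    }
    if (j < length(P)) {
      add <- P[(j + 1L):length(P)]
      prev <- if (j > 0L) P[j] else 0L
      for (v in add) {
        if (in_tree[v]) break        # guard against re-entering the tree
        in_tree[v] <- TRUE
        parent[v] <- prev
        order_added <- c(order_added, v)
        prev <- v
      }
    }
    # false-end-point removal against the branch just accepted
    idx_pending <- which(pending)
    drop_tips <- remove_false_endpoints(P, q, tips[idx_pending])
    if (length(drop_tips)) {
      n_false <- n_false + length(drop_tips)
      pending[idx_pending[tips[idx_pending] %in% drop_tips]] <- FALSE
    }
  }

  if (!length(order_added)) {
    v <- branches$soma_index
    in_tree[v] <- TRUE; parent[v] <- 0L; order_added <- v
  }
  tree <- tree_from_parents(order_added, parent, q, soma)
  attr(tree, "bplist") <- bplist
  attr(tree, "n_false_endpoints") <- n_false
  tree
}

tree_from_parents <- function(order_added, parent, q, soma) {
  vs <- q$voxel_size
  id_of <- integer(nrow(q$pts))
  id_of[order_added] <- seq_along(order_added)
  um <- vox_to_um(q$pts[order_added, , drop = FALSE], vs)
  rad_um <- q$radius[order_added] * (vs[["x"]] + vs[["y"]]) / 2
  par_id <- ifelse(parent[order_added] == 0L, -1L,
                   id_of[pmax(parent[order_added], 1L)])
  type <- ifelse(par_id == -1L, 1L, 3L)
  if (!is.null(soma)) rad_um[par_id == -1L] <- soma$radius_um
  neuron_tree(data.frame(id = seq_along(order_added), type = type,
                         x = um[, 1L], y = um[, 2L], z = um[, 3L],
                         radius = rad_um, parent = par_id),
              voxel_size = vs)
}
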