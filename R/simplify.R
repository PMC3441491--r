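#' Epsilon-approximate a polyline
#'
#' Returns a subsequence of the vertices, always containing both endpoints,
#' such that every original vertex lies within `epsilon` of the simplified
#' polyline (split-based Douglas-Peucker recursion on the farthest-deviating
#' vertex). With `epsilon = 0` the path is returned unchanged.
#'
#' @param xyz numeric matrix of vertices (rows), at least 2.
#' @param epsilon tolerance, in the units of `xyz`; the default, the body
#'   diagonal of one voxel, is the smallest value that erases single-voxel
#'   grid zigzag when coordinates are voxel indices.
#' @return Integer indices of the retained vertices (increasing, includes 1
#'   and `nrow(xyz)`).
#' @export
approximate_path <- function(xyz, epsilon = sqrt(3)) {
  xyz <- as_num_matrix(xyz)
  n <- nrow(xyz)
  stopifnot(n >= 2L, epsilon >= 0)
  if (epsilon <= 0) return(seq_len(n))
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- point_segment_dist(xyz[mid, , drop = FALSE], xyz[i, ], xyz[j, ])
    w <- which.max(d)
    if (d[w] > epsilon) {
      split <- mid[w]
      keep[split] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, split)
      stack[[length(stack) + 1L]] <- c(split, j)
    }
  }
  which(keep)
}

# distance from each row of p to the segment a--b
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  if (len2 == 0) return(sqrt(rowSums((p - rep(a, each = nrow(p)))^2)))
  t <- pmin(1, pmax(0, as.vector((p - rep(a, each = nrow(p))) %*% ab) / len2))
  proj <- rep(a, each = nrow(p)) + outer(t, ab)
  sqrt(rowSums((p - proj)^2))
}

#' Simplify a neuron tree by per-segment polyline approximation
#'
#' Each path between consecutive topology nodes (root, bifurcations,
#' leaves) is simplified independently with [approximate_path()], so the
#' tree topology is untouched: root, branch points, and leaves are always
#' retained, with their radii. Because the grid zigzag the simplification
#' removes arises in voxel space, deviation is measured in voxel-index units
#' by default; `space = "physical"` measures it in micrometers instead.
#'
#' @param tree a [neuron_tree].
#' @param epsilon tolerance (default `sqrt(3)` voxel units).
#' @param space `"voxel"` (requires the tree to carry a voxel size) or
#'   `"physical"`.
#' @return A simplified [neuron_tree].
#' @export
simplify_tree <- function(tree, epsilon = sqrt(3),
                          space = c("voxel", "physical")) {
  stopifnot(inherits(tree, "neuron_tree"))
  space <- match.arg(space)
  xyz <- as.matrix(tree[, c("x", "y", "z")])
  if (space == "voxel") {
    vs <- attr(tree, "voxel_size")
    if (is.null(vs))
      stop("tree carries no voxel size; use space = \"physical\"")
    xyz <- um_to_voxunits(xyz, vs)
  }
  n <- nrow(tree)
  pid <- match(tree$parent, tree$id)       # NA at root
  nchild <- tabulate(pid[!is.na(pid)], nbins = n)
  topo <- is.na(pid) | nchild != 1L        # root, leaves, bifurcations
  keep <- logical(n)
  keep[topo] <- TRUE
  # walk down from every topology node through runs of pass-through nodes
  children <- split(seq_len(n)[!is.na(pid)], pid[!is.na(pid)])
  for (s in which(topo)) {
    for (ch in children[[as.character(s)]]) {
      run <- s
      v <- ch
      while (!topo[v]) { run <- c(run, v); v <- children[[as.character(v)]] }
      run <- c(run, v)
      if (length(run) > 2L)
        keep[run[approximate_path(xyz[run, , drop = FALSE], epsilon)]] <- TRUE
    }
  }
  sub <- which(keep)
  newid <- integer(n)
  newid[sub] <- seq_along(sub)
  # reconnect parents through dropped pass-through nodes
  up <- function(v) { while (!keep[v]) v <- pid[v]; v }
  newpar <- vapply(sub, function(v)
    if (is.na(pid[v])) -1L else newid[up(pid[v])], integer(1L))
  out <- data.frame(id = seq_along(sub), type = tree$type[sub],
                    x = tree$x[sub], y = tree$y[sub], z = tree$z[sub],
                    radius = tree$radius[sub], parent = newpar)
  neuron_tree(out, voxel_size = attr(tree, "voxel_size"))
}
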