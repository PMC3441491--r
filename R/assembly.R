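#' Build the fragment component graph
#'
#' Signal dropout leaves the skeleton point set Q in several 26-connected
#' fragments. Each fragment becomes a vertex; two fragments are joined by an
#' edge when the Euclidean distance (in isotropic voxel-index units) between
#' their closest points is below `gap_fraction` of the largest stack
#' dimension. Edge weights are those closest-pair distances and the stored
#' closest pairs are exact.
#'
#' @param q a `skeleton_points` object.
#' @param gap_fraction admissible gap as a fraction of the largest image
#'   dimension (default 0.05).
#' @return An object of class `component_graph`: component labels per point,
#'   an edge table `(a, b, ia, ib, dist)` with point indices of the closest
#'   pair, and the gap limit used.
#' @export
build_component_graph <- function(q, gap_fraction = 0.05) {
  stopifnot(inherits(q, "skeleton_points"), nrow(q$pts) > 0L)
  arr <- array(FALSE, q$dim)
  arr[vox_lin(q$pts, q$dim)] <- TRUE
  lab <- array(cpp_label(arr, q$dim, FALSE), q$dim)
  comp <- lab[vox_lin(q$pts, q$dim)]
  ncomp <- max(comp)
  gap_limit <- gap_fraction * max(q$dim)
  idx_by_comp <- split(seq_len(nrow(q$pts)), comp)
  edges <- NULL
  if (ncomp > 1L) {
    bbox <- lapply(idx_by_comp, function(ii)
      rbind(lo = apply(q$pts[ii, , drop = FALSE], 2L, min),
            hi = apply(q$pts[ii, , drop = FALSE], 2L, max)))
    rows <- list()
    for (a in seq_len(ncomp - 1L))
      for (b in (a + 1L):ncomp) {
        # bounding boxes give a cheap lower bound on the closest-pair distance
        gap <- pmax(bbox[[a]]["lo", ] - bbox[[b]]["hi", ],
                    bbox[[b]]["lo", ] - bbox[[a]]["hi", ], 0)
        if (sqrt(sum(gap^2)) >= gap_limit) next
        cp <- cpp_closest_pair(as_num_matrix(q$pts[idx_by_comp[[a]], , drop = FALSE]),
                               as_num_matrix(q$pts[idx_by_comp[[b]], , drop = FALSE]))
        if (cp$dist < gap_limit)
          rows[[length(rows) + 1L]] <-
            data.frame(a = a, b = b,
                       ia = idx_by_comp[[a]][cp$i],
                       ib = idx_by_comp[[b]][cp$j],
                       dist = cp$dist)
      }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  if (is.null(edges))
    edges <- data.frame(a = integer(0), b = integer(0), ia = integer(0),
                        ib = integer(0), dist = numeric(0))
  structure(list(comp = comp, n_components = ncomp, edges = edges,
                 gap_limit = gap_limit),
            class = "component_graph")
}

# Kruskal MST with deterministic (weight, a, b) tie-break
kruskal_mst <- function(n, edges) {
  if (nrow(edges) == 0L) return(edges)
  ord <- order(edges$dist, edges$a, edges$b)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sel <- logical(nrow(edges))
  for (r in ord) {
    ra <- find(edges$a[r]); rb <- find(edges$b[r])
    if (ra != rb) { parent[ra] <- rb; sel[r] <- TRUE }
  }
  edges[sel, , drop = FALSE]
}

#' Connect skeleton fragments along the minimum spanning tree
#'
#' Computes the Kruskal MST of the component graph and, for every selected
#' edge, inserts straight-line bridge points between the closest pair at a
#' spacing of about one voxel (rounded to the grid, deduplicated). Bridge
#' points inherit a radius interpolated between the pair's radii. If the
#' component graph is disconnected (some gaps exceed the limit) only the
#' largest 26-connected component of the result is kept.
#'
#' @param q a `skeleton_points` object.
#' @param graph a `component_graph` from [build_component_graph()]; built
#'   from `q` if missing.
#' @return A `skeleton_points` object forming a single 26-connected
#'   component, with attributes `n_components_before` and `mst_edges`.
#' @export
mst_connect <- function(q, graph = NULL) {
  stopifnot(inherits(q, "skeleton_points"))
  if (nrow(q$pts) == 0L) return(q)
  if (is.null(graph)) graph <- build_component_graph(q)
  mst <- kruskal_mst(graph$n_components, graph$edges)
  newpts <- list(); newrad <- list()
  occ_lin <- vox_lin(q$pts, q$dim)
  if (nrow(mst) > 0L) {
    for (r in seq_len(nrow(mst))) {
      pa <- q$pts[mst$ia[r], ]; pb <- q$pts[mst$ib[r], ]
      ra <- q$radius[mst$ia[r]]; rb <- q$radius[mst$ib[r]]
      nstep <- ceiling(mst$dist[r])
      if (nstep < 2) next
      tt <- seq_len(nstep - 1L) / nstep
      bp <- round(outer(tt, pb - pa) + rep(pa, each = length(tt)))
      storage.mode(bp) <- "integer"
      keep <- !duplicated(vox_lin(bp, q$dim)) &
              !(vox_lin(bp, q$dim) %in% occ_lin)
      bp <- bp[keep, , drop = FALSE]
      if (nrow(bp) == 0L) next
      newpts[[length(newpts) + 1L]] <- bp
      newrad[[length(newrad) + 1L]] <- ra + tt[keep] * (rb - ra)
    }
  }
  pts <- rbind(q$pts, do.call(rbind, newpts))
  rad <- c(q$radius, unlist(newrad))
  out <- skeleton_points(pts, rad, q$dim, q$voxel_size)
  # keep the largest 26-connected component
  arr <- array(FALSE, out$dim)
  arr[vox_lin(out$pts, out$dim)] <- TRUE
  lab <- array(cpp_label(arr, out$dim, FALSE), out$dim)
  comp <- lab[vox_lin(out$pts, out$dim)]
  sizes <- tabulate(comp)
  keep <- comp == which.max(sizes)
  out <- skeleton_points(out$pts[keep, , drop = FALSE], out$radius[keep],
                         out$dim, out$voxel_size)
  attr(out, "n_components_before") <- graph$n_components
  attr(out, "mst_edges") <- mst
  out
}
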