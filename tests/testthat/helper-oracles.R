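# independent brute-force oracles used across the suite

# flood-fill component sizes on a logical volume; slicewise = 2D 8-neighbor
# per slice, otherwise 3D 26-neighbor
flood_label <- function(mask, slicewise = FALSE) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1L], p[2L], p[3L]] > 0L) next
    nxt <- nxt + 1L
    stack <- list(p)
    lab[p[1L], p[2L], p[3L]] <- nxt
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      zr <- if (slicewise) 0L else (-1L):1L
      for (dz in zr) for (dx in (-1L):1L) for (dy in (-1L):1L) {
        if (dz == 0L && dx == 0L && dy == 0L) next
        w <- v + c(dy, dx, dz)
        if (any(w < 1L) || any(w > d)) next
        if (mask[w[1L], w[2L], w[3L]] && lab[w[1L], w[2L], w[3L]] == 0L) {
          lab[w[1L], w[2L], w[3L]] <- nxt
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# brute-force 2D EDT of one slice: per foreground pixel, scan all background
brute_edt_slice <- function(sl) {
  d <- dim(sl)
  out <- matrix(0, d[1L], d[2L])
  bg <- which(!sl, arr.ind = TRUE)
  fg <- which(sl, arr.ind = TRUE)
  if (nrow(bg) == 0L) { out[sl] <- max(d); return(out) }
  for (r in seq_len(nrow(fg))) {
    p <- fg[r, ]
    out[p[1L], p[2L]] <- sqrt(min((bg[, 1L] - p[1L])^2 + (bg[, 2L] - p[2L])^2))
  }
  out
}

# all simple paths i -> j in an undirected weighted graph (edge list), with
# their total weights; used as the Dijkstra oracle on tiny graphs
enumerate_path_costs <- function(n, edges, from, to) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$w[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- Inf
  visit <- function(v, seen, cost) {
    if (cost >= best) return()
    if (v == to) { best <<- cost; return() }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb)))
      if (!seen[nb[r, 1L]])
        visit(nb[r, 1L], `[<-`(seen, nb[r, 1L], TRUE), cost + nb[r, 2L])
  }
  visit(from, `[<-`(logical(n), from, TRUE), 0)
  best
}

# minimum spanning-tree weight of a component graph by exhaustive Prufer
# enumeration of all labeled spanning trees (n <= 6); missing edges get
# infinite weight
brute_mst_weight <- function(n, edges) {
  if (n == 1L) return(0)
  wmat <- matrix(Inf, n, n)
  for (r in seq_len(nrow(edges))) {
    wmat[edges$a[r], edges$b[r]] <- edges$dist[r]
    wmat[edges$b[r], edges$a[r]] <- edges$dist[r]
  }
  if (n == 2L) return(wmat[1L, 2L])
  prufer_tree_edges <- function(code) {
    deg <- rep(1L, n)
    for (v in code) deg[v] <- deg[v] + 1L
    code <- c(code)
    ed <- matrix(0L, n - 1L, 2L)
    k <- 0L
    for (v in code) {
      leaf <- which(deg == 1L)[1L]
      k <- k + 1L
      ed[k, ] <- c(leaf, v)
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    rest <- which(deg == 1L)
    ed[n - 1L, ] <- rest
    ed
  }
  codes <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(codes))) {
    ed <- prufer_tree_edges(codes[r, ])
    w <- sum(wmat[ed])
    if (w < best) best <- w
  }
  best
}

# a random irreducible digital arc: consecutive points are 26-adjacent and
# no point is adjacent to any earlier point except its predecessor
random_digital_arc <- function(len, dim3) {
  pts <- matrix(0L, len, 3L)
  pts[1L, ] <- sapply(dim3, function(m) sample(5:(m - 5L), 1L))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, ]
  for (k in 2:len) {
    cand <- sweep(offs, 2L, pts[k - 1L, ], "+")
    keep <- rep(TRUE, nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (any(cand[r, ] < 1L) || any(cand[r, ] > dim3)) { keep[r] <- FALSE; next }
      ref <- if (k > 2L) pts[1:(k - 2L), , drop = FALSE] else NULL
      if (!is.null(ref) &&
          any(apply(abs(sweep(ref, 2L, cand[r, ], "-")), 1L, max) <= 1L))
        keep[r] <- FALSE
    }
    if (!any(keep)) return(pts[1:(k - 1L), , drop = FALSE])
    cand <- cand[keep, , drop = FALSE]
    pts[k, ] <- cand[sample(nrow(cand), 1L), ]
  }
  pts
}

# skeleton_points object from a bare point matrix
sk_from_points <- function(pts, dim3 = c(32L, 32L, 32L),
                           voxel_size = c(x = 0.33, y = 0.33, z = 1.0)) {
  skeleton_points(pts, rep(1, nrow(pts)), dim3, voxel_size)
}

# small deterministic phantom spec used by pipeline-level tests
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(160L, 160L, 48L), n_branch_points = 3L,
               seg_len_range_um = c(6, 12), ...)
}
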