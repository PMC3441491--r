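#' Per-slice 2D Euclidean distance transform
#'
#' For every slice independently, each foreground pixel receives its
#' Euclidean distance (in pixels) to the nearest background pixel of that
#' slice; background pixels are 0. The value at a centerline pixel estimates
#' the local fiber radius.
#'
#' @param vol a [binary_volume].
#' @return numeric array of the same shape.
#' @export
edt_2d <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  m <- vol$mask
  out <- array(0, dim(m))
  cap <- max(dim(m)[1:2])
  for (k in seq_len(dim(m)[3L])) {
    sl <- m[, , k]
    if (!any(sl)) next
    d <- EBImage::distmap(sl * 1)
    d[!is.finite(d)] <- cap        # slice with no background at all
    out[, , k] <- d
  }
  out
}

# re-seed 2D components that thinning erased completely (e.g. 2x2 blocks)
# with their maximal-EDT pixel, so every component keeps >= 1 skeleton point
reseed_lost_components <- function(sl, th, ed) {
  lab <- cpp_label(as.logical(sl), c(dim(sl), 1L), TRUE)
  lab <- array(lab, dim(sl))
  lost <- setdiff(unique(lab[sl]), unique(lab[th & sl]))
  for (lb in lost) {
    idx <- which(lab == lb)
    th[idx[which.max(ed[idx])]] <- TRUE
  }
  th
}

#' Per-slice skeletonization
#'
#' Thins every slice of the cleaned mask to an 8-connected, one-pixel-wide
#' skeleton (Zhang-Suen thinning; the identity on curves that are already
#' one pixel wide) and attaches the 2D EDT value at each retained pixel as
#' its local radius. The union of all slice skeletons is the candidate
#' centerline point set Q.
#'
#' @param vol a [binary_volume].
#' @param edt EDT array from [edt_2d()] (computed if missing).
#' @return A `skeleton_points` object: voxel points `(y, x, z)` with
#'   per-point radius (pixels) and candidate end/branch flags (initially
#'   unset).
#' @export
skeletonize_slices <- function(vol, edt = NULL) {
  stopifnot(inherits(vol, "binary_volume"))
  if (is.null(edt)) edt <- edt_2d(vol)
  m <- vol$mask
  pts <- vector("list", dim(m)[3L])
  rad <- vector("list", dim(m)[3L])
  for (k in seq_len(dim(m)[3L])) {
    sl <- m[, , k]
    if (!any(sl)) next
    th <- cpp_thin(sl)
    th <- reseed_lost_components(sl, th, edt[, , k])
    w <- which(th, arr.ind = TRUE)
    pts[[k]] <- cbind(y = w[, 1L], x = w[, 2L], z = k)
    rad[[k]] <- edt[, , k][w]
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts)) pts <- matrix(integer(0), 0L, 3L,
                                  dimnames = list(NULL, c("y", "x", "z")))
  skeleton_points(pts, unlist(rad), dim(m), vol$voxel_size)
}

#' @rdname skeletonize_slices
#' @param pts integer matrix of voxel points `(y, x, z)`.
#' @param radius per-point 2D EDT radius in pixels.
#' @param dim3 shape of the source volume.
#' @param voxel_size voxel pitch in micrometers.
#' @export
skeleton_points <- function(pts, radius, dim3,
                            voxel_size = c(x = 0.33, y = 0.33, z = 1.0)) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "integer"
  colnames(pts) <- c("y", "x", "z")
  n <- nrow(pts)
  if (length(radius) == 0L) radius <- numeric(n)
  stopifnot(length(radius) == n, all(radius >= 0))
  structure(list(pts = pts, radius = as.numeric(radius),
                 end = logical(n), branch = logical(n),
                 dim = as.integer(dim3),
                 voxel_size = norm_voxel_size(voxel_size)),
            class = "skeleton_points")
}

# logical occupancy array and id lookup for a point set
occupancy <- function(q) {
  lin <- vox_lin(q$pts, q$dim)
  idmap <- integer(prod(q$dim))
  idmap[lin] <- seq_len(nrow(q$pts))
  list(lin = lin, idmap = idmap)
}

# number of 26-neighbors within the set for every point
neighbor_counts <- function(q, occ = occupancy(q)) {
  n <- nrow(q$pts)
  cnt <- integer(n)
  dim3 <- q$dim
  offs <- offsets26()
  for (r in seq_len(nrow(offs))) {
    dy <- offs[r, 1L]; dx <- offs[r, 2L]; dz <- offs[r, 3L]
    yy <- q$pts[, 1L] + dy; xx <- q$pts[, 2L] + dx; zz <- q$pts[, 3L] + dz
    ok <- yy >= 1L & yy <= dim3[1L] & xx >= 1L & xx <= dim3[2L] &
          zz >= 1L & zz <= dim3[3L]
    nl <- occ$lin[ok] + dy + dim3[1L] * (dx + dim3[2L] * dz)
    cnt[ok] <- cnt[ok] + (occ$idmap[nl] > 0L)
  }
  cnt
}

#' Flag candidate 3D end points
#'
#' A point of Q is a candidate end point (a potential branch tip) when all
#' of its 26-neighbors within Q — at most three of them — lie on one side,
#' i.e. form a single mutually 26-connected cluster (an isolated point also
#' qualifies). This flags every true extremity of an irreducible one-voxel
#' digital curve, including tube tips whose per-slice skeleton ends carry a
#' same-side companion in the adjacent slice, while an interior curve point
#' (two neighbors on opposite sides) is never flagged. Spurious candidates
#' are filtered downstream (false-end-point removal, short-branch pruning).
#'
#' @param q a `skeleton_points` object (after [mst_connect()]).
#' @return `q` with its `end` flags set.
#' @export
detect_end_candidates <- function(q) {
  stopifnot(inherits(q, "skeleton_points"))
  occ <- occupancy(q)
  cnt <- neighbor_counts(q, occ)
  flag <- cnt == 0L
  check <- which(cnt >= 1L & cnt <= 3L)
  for (i in check) {
    nb <- point_neighbors(q, i, occ)
    if (neighbor_groups(nb) == 1L) flag[i] <- TRUE
  }
  q$end <- flag
  q
}

# coordinates of the 26-neighbors of point i that belong to Q
point_neighbors <- function(q, i, occ) {
  dim3 <- q$dim
  offs <- offsets26()
  nb <- matrix(rep(q$pts[i, ], each = nrow(offs)), ncol = 3L) + offs
  ok <- nb[, 1L] >= 1L & nb[, 1L] <= dim3[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= dim3[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= dim3[3L]
  nb <- nb[ok, , drop = FALSE]
  nb[occ$idmap[vox_lin(nb, dim3)] > 0L, , drop = FALSE]
}

#' Flag candidate branch points
#'
#' A point p is a candidate branch (junction) point when its 26-neighborhood
#' within Q contains exactly four or five points and, with p removed, those
#' neighbors fall into at least three mutually disconnected groups. The
#' group condition is invariant under rotations and reflections of the
#' neighborhood.
#'
#' @param q a `skeleton_points` object (after [mst_connect()]).
#' @return `q` with its `branch` flags set.
#' @export
detect_branch_candidates <- function(q) {
  stopifnot(inherits(q, "skeleton_points"))
  occ <- occupancy(q)
  cnt <- neighbor_counts(q, occ)
  cand <- which(cnt == 4L | cnt == 5L)
  flag <- logical(nrow(q$pts))
  for (i in cand) {
    nb <- point_neighbors(q, i, occ)
    if (neighbor_groups(nb, face = TRUE) >= 3L) flag[i] <- TRUE
  }
  q$branch <- flag
  q
}

# number of connected groups among a handful of voxel points; `face = TRUE`
# joins only face (6-)adjacent voxels — the strict notion used to count the
# separate arms meeting at a junction — while the default joins any
# 26-adjacent pair (the loose notion used to ask whether all neighbors of a
# tip lie on one side)
neighbor_groups <- function(nb, face = FALSE) {
  k <- nrow(nb)
  if (k == 0L) return(0L)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k) {
      d <- abs(nb[i, ] - nb[j, ])
      adj <- if (face) sum(d) == 1L else all(d <= 1L)
      if (adj) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  length(unique(vapply(seq_len(k), find, integer(1L))))
}
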