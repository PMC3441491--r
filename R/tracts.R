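#' Region-of-interest primitives
#'
#' Brain regions (neuropils) are represented by simple geometric primitives
#' in the common coordinate space of the reconstructions: a ball or an
#' axis-aligned box.
#'
#' @param center,radius ball center `(x, y, z)` and radius.
#' @param name label for reports.
#' @return An object of class `region`.
#' @export
region_sphere <- function(center, radius, name = "sphere") {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = radius, name = name), class = "region")
}

#' @rdname region_sphere
#' @param lo,hi box corners `(x, y, z)`, componentwise `lo <= hi`.
#' @export
region_box <- function(lo, hi, name = "box") {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(lo <= hi))
  structure(list(kind = "box", lo = as.numeric(lo), hi = as.numeric(hi),
                 name = name), class = "region")
}

#' @rdname region_sphere
#' @param region a `region`.
#' @param pts numeric matrix of `(x, y, z)` points.
#' @return `region_contains`: logical vector; `region_distance`: distance
#'   from each point to the region (0 inside).
#' @export
region_contains <- function(region, pts) {
  pts <- as_num_matrix(pts)
  if (region$kind == "sphere") {
    rowSums((pts - rep(region$center, each = nrow(pts)))^2) <= region$radius^2
  } else {
    apply(pts, 1L, function(p) all(p >= region$lo & p <= region$hi))
  }
}

#' @rdname region_sphere
#' @export
region_distance <- function(region, pts) {
  pts <- as_num_matrix(pts)
  if (region$kind == "sphere") {
    pmax(sqrt(rowSums((pts - rep(region$center, each = nrow(pts)))^2)) -
           region$radius, 0)
  } else {
    d <- pmax(rep(region$lo, each = nrow(pts)) - pts,
              pts - rep(region$hi, each = nrow(pts)), 0)
    sqrt(rowSums(d^2))
  }
}

#' Select neurons innervating two regions
#'
#' Keeps the trees that have at least one node in region `a` and at least
#' one in region `b`, and (optionally) no node in any exclusion region.
#'
#' @param trees list of [neuron_tree]s in a common coordinate space.
#' @param a,b `region` objects.
#' @param exclude optional list of `region`s that disqualify a neuron.
#' @return Integer indices of the selected trees.
#' @export
select_innervating <- function(trees, a, b, exclude = list()) {
  hits <- vapply(trees, function(tr) {
    pts <- as.matrix(tr[, c("x", "y", "z")])
    if (!any(region_contains(a, pts)) || !any(region_contains(b, pts)))
      return(FALSE)
    for (ex in exclude)
      if (any(region_contains(ex, pts))) return(FALSE)
    TRUE
  }, logical(1L))
  which(hits)
}

#' Extract the path connecting two regions through a tree
#'
#' Takes the unique tree path between the `a`-node nearest to `b` and the
#' `b`-node nearest to `a`, then trims nodes that are still inside the
#' source regions so the path runs from the exit of `a` to the entry of
#' `b`.
#'
#' @param tree a [neuron_tree] innervating both regions.
#' @param a,b `region` objects.
#' @return numeric matrix of ordered `(x, y, z)` path points.
#' @export
extract_path <- function(tree, a, b) {
  pts <- as.matrix(tree[, c("x", "y", "z")])
  inA <- which(region_contains(a, pts))
  inB <- which(region_contains(b, pts))
  if (!length(inA) || !length(inB)) stop("tree does not innervate both regions")
  na <- inA[which.min(region_distance(b, pts[inA, , drop = FALSE]))]
  nb <- inB[which.min(region_distance(a, pts[inB, , drop = FALSE]))]
  path <- tree_path(tree, na, nb)
  # trim: keep from the last run of in-A nodes at the start to the first
  # in-B node at the end
  inA_p <- region_contains(a, pts[path, , drop = FALSE])
  inB_p <- region_contains(b, pts[path, , drop = FALSE])
  s <- 1L
  while (s < length(path) && inA_p[s + 1L]) s <- s + 1L
  e <- length(path)
  first_b <- which(inB_p & seq_along(path) >= s)
  if (length(first_b)) e <- first_b[1L]
  pts[path[s:e], , drop = FALSE]
}

# vertex path between two nodes of a tree (via lowest common ancestor)
tree_path <- function(tree, i, j) {
  pid <- match(tree$parent, tree$id)
  anc <- function(v) { out <- v
    while (!is.na(pid[v])) { v <- pid[v]; out <- c(out, v) }
    out }
  ai <- anc(i); aj <- anc(j)
  common <- intersect(ai, aj)[1L]
  up <- ai[seq_len(match(common, ai))]
  down <- rev(aj[seq_len(match(common, aj) - 1L)])
  c(up, down)
}

#' Resample a path to k equidistant points
#'
#' @param xyz numeric matrix of ordered path points.
#' @param k number of output points.
#' @return `k x 3` matrix of points equally spaced in arc length.
#' @export
resample_path <- function(xyz, k = 20L) {
  xyz <- as_num_matrix(xyz)
  stopifnot(nrow(xyz) >= 2L, k >= 2L)
  seg <- sqrt(rowSums(diff(xyz)^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = k)
  out <- matrix(0, k, 3L)
  for (c3 in 1:3)
    out[, c3] <- approx(s, xyz[, c3], xout = target, ties = "ordered")$y
  out
}

#' Hierarchically cluster region-to-region paths into tracts
#'
#' Each path is resampled to `k_points` equidistant points and flattened
#' into a coordinate vector; the distance between two paths is the Euclidean
#' distance between those vectors, minimized over the two traversal
#' orientations (path direction is arbitrary). Agglomerative clustering
#' (stats::hclust) groups the paths; the tree is cut either at a requested
#' number of clusters or where the merge height grows by the largest factor.
#'
#' @param paths list of path coordinate matrices (each `n_i x 3`).
#' @param k_points resampling resolution (default 20).
#' @param linkage hclust linkage method (default `"complete"`).
#' @param n_clusters number of clusters, or `NULL` for the automatic
#'   largest-height-ratio cut.
#' @return An object of class `tract_clusters`: `labels`, `hclust`,
#'   `n_clusters`, `dist`.
#' @export
cluster_paths <- function(paths, k_points = 20L, linkage = "complete",
                          n_clusters = NULL) {
  stopifnot(length(paths) >= 2L)
  if (!is.null(n_clusters) && n_clusters > length(paths))
    stop("fewer paths than clusters")
  vecs <- lapply(paths, function(p) {
    r <- resample_path(p, k_points)
    list(fwd = as.vector(t(r)), rev = as.vector(t(r[nrow(r):1L, ])))
  })
  np <- length(paths)
  D <- matrix(0, np, np)
  for (i in seq_len(np - 1L))
    for (j in (i + 1L):np) {
      d1 <- sqrt(sum((vecs[[i]]$fwd - vecs[[j]]$fwd)^2))
      d2 <- sqrt(sum((vecs[[i]]$fwd - vecs[[j]]$rev)^2))
      D[i, j] <- D[j, i] <- min(d1, d2)
    }
  hc <- hclust(as.dist(D), method = linkage)
  if (is.null(n_clusters)) {
    # cut where the merge height grows by the largest factor: the ratio is
    # scale-free, so very unequal between-cluster distances do not mask the
    # within/between boundary the way an absolute gap would
    h <- hc$height
    if (length(h) < 2L) n_clusters <- 1L
    else {
      eps <- 1e-8 * max(h)
      ratio <- (h[-1L] + eps) / (h[-length(h)] + eps)
      n_clusters <- np - which.max(ratio)
    }
    n_clusters <- max(1L, min(np, n_clusters))
  }
  labels <- cutree(hc, k = n_clusters)
  structure(list(labels = labels, hclust = hc, n_clusters = n_clusters,
                 dist = as.dist(D), k_points = k_points),
            class = "tract_clusters")
}

#' Simulate bundles of jittered tract paths
#'
#' Generates `n_bundles` smooth 3D centroid curves far apart relative to the
#' within-bundle jitter, then `n_per_bundle` jittered, randomly oriented
#' copies of each — a test bed with known cluster labels.
#'
#' @param n_bundles number of bundles (default 3).
#' @param n_per_bundle paths per bundle (default 20).
#' @param n_points points per generated path.
#' @param separation distance scale between bundle centroids.
#' @param jitter sd of the per-path offset and pointwise wobble.
#' @param seed integer seed.
#' @return List with `paths` (list of matrices) and `labels` (true bundle
#'   of each path).
#' @export
simulate_tract_bundles <- function(n_bundles = 3L, n_per_bundle = 20L,
                                   n_points = 40L, separation = 25,
                                   jitter = 1, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  tt <- seq(0, 1, length.out = n_points)
  paths <- list(); labels <- integer(0)
  origins <- matrix(0, 0L, 3L)
  for (b in seq_len(n_bundles)) {
    # bundle origins are kept at least `separation` apart
    repeat {
      origin <- rnorm(3L) * separation
      if (nrow(origins) == 0L ||
          min(sqrt(rowSums(sweep(origins, 2L, origin, "-")^2))) >= separation)
        break
    }
    origins <- rbind(origins, origin)
    dir <- unit(rnorm(3L))
    bend <- rnorm(3L) * separation / 4
    centroid <- cbind(origin[1L] + dir[1L] * tt * 60 + bend[1L] * tt^2,
                      origin[2L] + dir[2L] * tt * 60 + bend[2L] * tt^2,
                      origin[3L] + dir[3L] * tt * 60 + bend[3L] * tt^2)
    for (i in seq_len(n_per_bundle)) {
      off <- rnorm(3L, sd = jitter)
      p <- centroid + rep(off, each = n_points) +
        matrix(rnorm(3L * n_points, sd = jitter / 3), n_points, 3L)
      if (runif(1L) < 0.5) p <- p[n_points:1L, ]
      paths[[length(paths) + 1L]] <- p
      labels <- c(labels, b)
    }
  }
  list(paths = paths, labels = labels)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}
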