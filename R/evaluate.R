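#' Resample a neuron tree to a uniform point density
#'
#' Places points along every parent-child edge at arc-length intervals no
#' larger than `spacing` (all original nodes are kept), so that two
#' reconstructions of different node densities can be compared point-to-set.
#'
#' @param tree a [neuron_tree].
#' @param spacing maximum gap between consecutive sample points, in the
#'   units of the tree coordinates.
#' @return numeric matrix of sampled `(x, y, z)` points.
#' @export
resample_to_density <- function(tree, spacing) {
  stopifnot(inherits(tree, "neuron_tree"), spacing > 0)
  xyz <- as.matrix(tree[, c("x", "y", "z")])
  pid <- match(tree$parent, tree$id)
  out <- list(xyz)
  for (i in which(!is.na(pid))) {
    a <- xyz[pid[i], ]; b <- xyz[i, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- ceiling(len / spacing)
    if (nseg > 1L) {
      tt <- seq_len(nseg - 1L) / nseg
      out[[length(out) + 1L]] <- rep(a, each = length(tt)) + outer(tt, b - a)
    }
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y", "z")
  res
}

#' Distance from points to a point set
#'
#' Exact nearest-neighbor Euclidean distance from each query point to a
#' reference set.
#'
#' @param p numeric matrix of query points (rows).
#' @param set numeric matrix of reference points (rows); must be nonempty.
#' @return numeric vector of distances, one per query row.
#' @export
point_to_set_distance <- function(p, set) {
  p <- as_num_matrix(p)
  set <- as_num_matrix(set)
  if (nrow(set) == 0L) stop("reference point set is empty")
  cpp_min_dists(p, set)
}

#' Directed reconstruction distance between two point sets
#'
#' For every point of `n1` the distance to the nearest point of `n2` is
#' computed; the aggregate (mean by default) is the directed distance
#' Dis(N1, N2). Distances are measured in whatever units the inputs carry;
#' for stack-based comparisons the convention is isotropic voxel units, each
#' voxel a unit cube (see [tree_distance()]). The distribution is also
#' binned at one-unit width. Directed: Dis(N1, N2) != Dis(N2, N1) in
#' general.
#'
#' @param n1,n2 numeric point matrices (rows), both nonempty and
#'   density-matched (see [resample_to_density()]).
#' @param aggregate `"mean"`, `"max"`, or `"rms"`.
#' @return An object of class `distance_report`: `value`, `aggregate`,
#'   `per_point`, `histogram` (data frame `bin_lo`, `count`), and
#'   `frac_within` (fraction of points within 1, 2, ... units).
#' @export
reconstruction_distance <- function(n1, n2,
                                    aggregate = c("mean", "max", "rms")) {
  aggregate <- match.arg(aggregate)
  n1 <- as_num_matrix(n1); n2 <- as_num_matrix(n2)
  if (nrow(n1) == 0L || nrow(n2) == 0L) stop("empty point set")
  d <- cpp_min_dists(n1, n2)
  value <- switch(aggregate,
                  mean = mean(d),
                  max = max(d),
                  rms = sqrt(mean(d^2)))
  nb <- max(1L, floor(max(d)) + 1L)
  hist <- data.frame(bin_lo = seq_len(nb) - 1L,
                     count = tabulate(pmin(floor(d), nb - 1L) + 1L,
                                      nbins = nb))
  kk <- seq_len(max(3L, nb))
  structure(list(value = value, aggregate = aggregate, per_point = d,
                 histogram = hist,
                 frac_within = vapply(kk, function(k) mean(d <= k),
                                      numeric(1L))),
            class = "distance_report")
}

#' Reconstruction distance between two neuron trees in voxel units
#'
#' Convenience wrapper: converts both trees from micrometers to isotropic
#' voxel units (each voxel a unit cube), density-matches them by resampling
#' at `spacing` voxel units, and computes the directed distance from the
#' first tree to the second.
#'
#' @param tree1,tree2 [neuron_tree]s in micrometer coordinates.
#' @param voxel_size voxel pitch used for the unit-cube conversion; taken
#'   from `tree1` when absent.
#' @param spacing resampling interval in voxel units (default 1).
#' @param aggregate passed to [reconstruction_distance()].
#' @return A `distance_report`.
#' @export
tree_distance <- function(tree1, tree2, voxel_size = NULL, spacing = 1,
                          aggregate = "mean") {
  if (is.null(voxel_size)) voxel_size <- attr(tree1, "voxel_size")
  if (is.null(voxel_size)) stop("voxel_size required")
  voxel_size <- norm_voxel_size(voxel_size)
  tv <- function(tr) {
    xyz <- um_to_voxunits(as.matrix(tr[, c("x", "y", "z")]), voxel_size)
    t2 <- tr
    t2$x <- xyz[, 1L]; t2$y <- xyz[, 2L]; t2$z <- xyz[, 3L]
    resample_to_density(t2, spacing)
  }
  reconstruction_distance(tv(tree1), tv(tree2), aggregate = aggregate)
}
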