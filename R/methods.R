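#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d (ny x nx x nz), pitch %.3g/%.3g/%.3g um\n",
              d[1L], d[2L], d[3L], x$voxel_size[["x"]], x$voxel_size[["y"]],
              x$voxel_size[["z"]]))
  cat(sprintf("  intensity range [%d, %d]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d, %d foreground voxels\n",
              d[1L], d[2L], d[3L], sum(x$mask)))
  invisible(x)
}

#' @export
print.skeleton_points <- function(x, ...) {
  cat(sprintf("<skeleton_points> %d points, %d end candidates, %d branch candidates\n",
              nrow(x$pts), sum(x$end), sum(x$branch)))
  invisible(x)
}

#' @export
print.soma_estimate <- function(x, ...) {
  cat(sprintf("<soma_estimate> center (%.2f, %.2f, %.2f) um, radius %.2f um\n",
              x$position_um[1L], x$position_um[2L], x$position_um[3L],
              x$radius_um))
  invisible(x)
}

#' @export
print.neuron_tree <- function(x, ...) {
  pid <- match(x$parent, x$id)
  nleaf <- sum(tabulate(pid[!is.na(pid)], nbins = nrow(x)) == 0L)
  cat(sprintf("<neuron_tree> %d nodes, %d tips, total length %.1f um\n",
              nrow(x), nleaf, total_length_um(x)))
  invisible(x)
}

total_length_um <- function(tree) {
  xyz <- as.matrix(tree[, c("x", "y", "z")])
  pid <- match(tree$parent, tree$id)
  i <- which(!is.na(pid))
  sum(sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[pid[i], , drop = FALSE])^2)))
}

#' @export
summary.neuron_tree <- function(object, ...) {
  pid <- match(object$parent, object$id)
  nchild <- tabulate(pid[!is.na(pid)], nbins = nrow(object))
  out <- list(n_nodes = nrow(object),
              n_tips = sum(nchild == 0L),
              n_branch_points = sum(nchild >= 2L),
              total_length_um = total_length_um(object),
              radius_range_um = range(object$radius))
  class(out) <- "summary.neuron_tree"
  out
}

#' @export
print.summary.neuron_tree <- function(x, ...) {
  cat("Neuron tree summary\n")
  cat(sprintf("  nodes:          %d\n", x$n_nodes))
  cat(sprintf("  tips:           %d\n", x$n_tips))
  cat(sprintf("  branch points:  %d\n", x$n_branch_points))
  cat(sprintf("  total length:   %.1f um\n", x$total_length_um))
  cat(sprintf("  radius range:   %.2f - %.2f um\n",
              x$radius_range_um[1L], x$radius_range_um[2L]))
  invisible(x)
}

#' Plot a neuron tree projection
#'
#' Draws the tree as line segments in a 2D projection, root marked.
#'
#' @param x a [neuron_tree].
#' @param plane `"xy"`, `"xz"`, or `"yz"`.
#' @param ... passed to [graphics::segments()].
#' @export
plot.neuron_tree <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1L]]
  u <- x[[ax[1L]]]; v <- x[[ax[2L]]]
  pid <- match(x$parent, x$id)
  i <- which(!is.na(pid))
  plot(u, v, type = "n", xlab = paste(ax[1L], "(um)"),
       ylab = paste(ax[2L], "(um)"), asp = 1)
  segments(u[pid[i]], v[pid[i]], u[i], v[i], ...)
  root <- which(x$parent == -1)
  points(u[root], v[root], pch = 19, col = "red", cex = 1.2)
  invisible(x)
}

#' @export
print.neuron_trace <- function(x, ...) {
  cat("<neuron_trace>\n")
  print(x$tree)
  cat(sprintf("  soma at (%.1f, %.1f, %.1f) um, radius %.2f um\n",
              x$soma$position_um[1L], x$soma$position_um[2L],
              x$soma$position_um[3L], x$soma$radius_um))
  cat(sprintf("  %d skeleton points in %d fragment(s); %d branches traced, %d pruned, %d false tips removed\n",
              x$report$n_skeleton_points, x$report$n_components_before,
              x$report$n_branches_traced, x$report$n_branches_pruned,
              x$report$n_false_endpoints))
  cat(sprintf("  nodes %d -> %d after simplification\n",
              x$report$n_nodes_raw, x$report$n_nodes_final))
  invisible(x)
}

#' @export
summary.neuron_trace <- function(object, ...) {
  s <- summary(object$tree)
  cat("Trace report\n")
  vc <- object$report$voxel_counts
  cat(sprintf("  voxels: %d binarized -> %d (2D clean) -> %d (3D clean) -> %d (closed)\n",
              vc[["binarized"]], vc[["after_2d"]], vc[["after_3d"]],
              vc[["after_close"]]))
  cat(sprintf("  stage times (s): %s\n",
              paste(sprintf("%s %.2f", names(object$report$timings),
                            unlist(object$report$timings)), collapse = ", ")))
  print(s)
  invisible(s)
}

#' @export
plot.neuron_trace <- function(x, ...) plot(x$tree, ...)

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report> Dis = %.4f (%s over %d points); %.1f%% within 3 units\n",
              x$value, x$aggregate, length(x$per_point),
              100 * x$frac_within[3L]))
  invisible(x)
}

#' Plot a reconstruction-distance histogram
#'
#' @param x a `distance_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.distance_report <- function(x, ...) {
  barplot(x$histogram$count, names.arg = x$histogram$bin_lo,
          xlab = "distance (voxels)", ylab = "points", ...)
  invisible(x)
}

#' @export
print.trace_control <- function(x, ...) {
  cat("<trace_control>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
print.component_graph <- function(x, ...) {
  cat(sprintf("<component_graph> %d components, %d admissible edges (gap limit %.1f vox)\n",
              x$n_components, nrow(x$edges), x$gap_limit))
  invisible(x)
}

#' @export
print.tract_clusters <- function(x, ...) {
  cat(sprintf("<tract_clusters> %d paths in %d clusters: %s\n",
              length(x$labels), x$n_clusters,
              paste(tabulate(x$labels), collapse = ", ")))
  invisible(x)
}
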