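#' Binarize a stack by the brightest-fraction heuristic
#'
#' A voxel is "visible" when its intensity exceeds `visible_min` (default 10
#' on the 0-255 scale). The heuristic keeps the brightest
#' `keep_fraction` of the visible voxels: with `t = floor(keep_fraction *
#' n_visible)`, the output contains every voxel whose intensity is at least
#' that of the t-th brightest visible voxel. Ties at the threshold intensity
#' are all kept, so the output can be slightly larger than `t`. Noisy stacks
#' are binarized with `keep_fraction = 0.2` instead of the default 0.7 (see
#' [trace_control()]'s `noisy_mode`).
#'
#' @param stack an [image_stack].
#' @param visible_min visibility threshold (strict; intensity must exceed it).
#' @param keep_fraction fraction of visible voxels to keep, in (0, 1\].
#' @return A [binary_volume].
#' @export
binarize <- function(stack, visible_min = 10, keep_fraction = 0.7) {
  stopifnot(inherits(stack, "image_stack"),
            keep_fraction > 0, keep_fraction <= 1)
  v <- stack$data
  vis <- v > visible_min
  nvis <- sum(vis)
  t <- floor(keep_fraction * nvis)
  if (nvis == 0L || t < 1L)
    return(binary_volume(array(FALSE, dim(v)), stack$voxel_size))
  # counts per intensity level; threshold = intensity of the t-th brightest
  cnt <- tabulate(v[vis] + 1L, nbins = 256L)           # index i = intensity i-1
  n_ge <- rev(cumsum(rev(cnt)))                        # n_ge[i] = #{>= i-1}
  theta <- max(which(n_ge >= t)) - 1L
  binary_volume(array(v >= theta, dim(v)), stack$voxel_size)
}

label_sizes <- function(mask, slicewise) {
  lab <- cpp_label(as.logical(mask), dim(mask), slicewise)
  list(lab = lab, sizes = tabulate(lab))
}

#' Remove small per-slice 2D components
#'
#' Clears, independently in every slice, each 8-connected 2D component with
#' fewer than `min_pixels` pixels.
#'
#' @param vol a [binary_volume].
#' @param min_pixels minimum component size kept (default 9).
#' @return A [binary_volume].
#' @export
remove_small_2d <- function(vol, min_pixels = 9) {
  stopifnot(inherits(vol, "binary_volume"))
  ls <- label_sizes(vol$mask, slicewise = TRUE)
  keep <- ls$lab > 0L & ls$sizes[pmax(ls$lab, 1L)] >= min_pixels
  binary_volume(array(keep, dim(vol$mask)), vol$voxel_size)
}

#' Remove small 3D components
#'
#' Clears every 26-connected 3D component with fewer than `min_voxels`
#' voxels.
#'
#' @param vol a [binary_volume].
#' @param min_voxels minimum component size kept (default 30).
#' @return A [binary_volume].
#' @export
remove_small_3d <- function(vol, min_voxels = 30) {
  stopifnot(inherits(vol, "binary_volume"))
  ls <- label_sizes(vol$mask, slicewise = FALSE)
  keep <- ls$lab > 0L & ls$sizes[pmax(ls$lab, 1L)] >= min_voxels
  binary_volume(array(keep, dim(vol$mask)), vol$voxel_size)
}

#' Per-slice morphological closing
#'
#' Applies a 2D morphological closing (dilation then erosion, 3x3 square
#' structuring element) to every slice, smoothing rough component boundaries
#' that would otherwise sprout spurious skeleton branchlets.
#'
#' @param vol a [binary_volume].
#' @return A [binary_volume]; closing is extensive, so the output contains
#'   the input.
#' @export
close_2d <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  m <- vol$mask
  kern <- EBImage::makeBrush(3L, shape = "box")
  out <- m
  for (k in seq_len(dim(m)[3L])) {
    sl <- m[, , k]
    if (!any(sl)) next
    out[, , k] <- EBImage::closing(sl * 1, kern) > 0.5
  }
  binary_volume(out, vol$voxel_size)
}

#' Run the full preprocessing chain
#'
#' Binarization, 2D then 3D small-component removal, and per-slice closing,
#' in that order.
#'
#' @param stack an [image_stack].
#' @param control a [trace_control()] list.
#' @return A [binary_volume] with a `counts` attribute holding the voxel
#'   count after each stage.
#' @export
preprocess_stack <- function(stack, control = trace_control()) {
  kf <- if (isTRUE(control$noisy_mode)) control$noisy_keep_fraction
        else control$keep_fraction
  vol <- binarize(stack, control$visible_min, kf)
  n1 <- sum(vol$mask)
  vol <- remove_small_2d(vol, control$min_comp_2d)
  n2 <- sum(vol$mask)
  vol <- remove_small_3d(vol, control$min_comp_3d)
  n3 <- sum(vol$mask)
  vol <- close_2d(vol)
  attr(vol, "counts") <- c(binarized = n1, after_2d = n2, after_3d = n3,
                           after_close = sum(vol$mask))
  vol
}
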