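#' Construct an image stack
#'
#' An `image_stack` holds an 8-bit grayscale confocal volume as an array with
#' dim `(ny, nx, nz)` (image rows, image columns, slices) together with the
#' physical voxel pitch. The default pitch, 0.33 x 0.33 x 1.0 um, is the
#' standard acquisition setting for single-neuron stacks of the fly brain.
#'
#' @param data numeric or integer 3D array with intensities in \[0, 255\].
#' @param voxel_size voxel pitch in micrometers, `c(x, y, z)`.
#' @return An object of class `image_stack` with elements `data` (integer
#'   array) and `voxel_size`.
#' @export
image_stack <- function(data, voxel_size = c(x = 0.33, y = 0.33, z = 1.0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, all(dim(data) >= 1L))
  if (any(data < 0 | data > 255))
    stop("intensities must lie in [0, 255]")
  storage.mode(data) <- "integer"
  structure(list(data = data, voxel_size = norm_voxel_size(voxel_size)),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Read a grayscale image stack from disk
#'
#' Accepts either a multi-page TIFF or a directory of equally sized 2D TIFF
#' slices; in the directory case files are sorted lexicographically and taken
#' as increasing z. 16-bit images are rescaled linearly to \[0, 255\].
#'
#' @param path a multi-page TIFF file or a directory of 2D TIFFs.
#' @param voxel_size voxel pitch in micrometers, `c(x, y, z)`.
#' @return An [image_stack].
#' @export
read_stack <- function(path, voxel_size = c(x = 0.33, y = 0.33, z = 1.0)) {
  if (!file.exists(path)) stop("no such path: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("slices have inconsistent dimensions")
  arr <- simplify2array(pages)            # (ny, nx, nz)
  mx <- max(arr)
  if (mx > 255) {
    if (mx > 65535) stop("unsupported bit depth (max intensity ", mx, ")")
    arr <- round(arr * (255 / 65535))
  }
  image_stack(arr, voxel_size)
}

#' Write an image stack or binary volume as a multi-page 8-bit TIFF
#'
#' @param x an [image_stack] or [binary_volume].
#' @param path output file.
#' @export
write_stack <- function(x, path) {
  arr <- if (inherits(x, "binary_volume")) unclass(x$mask) * 255L else x$data
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Construct a binary volume
#'
#' @param mask logical 3D array, same shape as its source stack.
#' @param voxel_size voxel pitch in micrometers.
#' @return An object of class `binary_volume` with elements `mask` and
#'   `voxel_size`.
#' @export
binary_volume <- function(mask, voxel_size = c(x = 0.33, y = 0.33, z = 1.0)) {
  stopifnot(is.logical(mask), is.array(mask), length(dim(mask)) == 3L)
  structure(list(mask = mask, voxel_size = norm_voxel_size(voxel_size)),
            class = "binary_volume")
}

#' @export
dim.binary_volume <- function(x) dim(x$mask)

#' Convert voxel indices to physical coordinates
#'
#' Voxel indices are 1-based; voxel `(1, 1, 1)` maps to the physical origin,
#' so a point at voxel column `x` sits at `(x - 1) * dx` micrometers, and
#' likewise for y and z. Linear in its voxel argument.
#'
#' @param pts integer matrix with columns `(y, x, z)` of voxel indices.
#' @param voxel_size voxel pitch in micrometers, `c(x, y, z)`.
#' @return numeric matrix with columns `(x, y, z)` in micrometers.
#' @export
to_physical <- function(pts, voxel_size) {
  pts <- as_num_matrix(pts)
  stopifnot(ncol(pts) == 3L)
  vox_to_um(pts, norm_voxel_size(voxel_size))
}

#' Construct a neuron tree
#'
#' A `neuron_tree` is a rooted centerline tree: one node per row with a
#' physical position (micrometers), a local radius, and a parent reference.
#' Exactly one node (the soma) has parent `-1`; parents must appear before
#' their children, and the parent relation must form a single connected
#' acyclic tree.
#'
#' @param nodes data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @param voxel_size optional voxel pitch the tree was traced at (used by
#'   voxel-space operations such as [simplify_tree()]).
#' @return An object of class `neuron_tree` (a validated data frame).
#' @export
neuron_tree <- function(nodes, voxel_size = NULL) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(is.data.frame(nodes), all(need %in% names(nodes)))
  nodes <- nodes[, need]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  pos <- match(nodes$parent, nodes$id)
  bad <- nodes$parent != -1 & is.na(pos)
  if (any(bad)) stop("parent id not found: ", nodes$parent[which(bad)[1L]])
  if (any(pos >= seq_len(nrow(nodes)), na.rm = TRUE))
    stop("parents must precede their children")
  if (!is.null(voxel_size)) voxel_size <- norm_voxel_size(voxel_size)
  structure(nodes, class = c("neuron_tree", "data.frame"),
            voxel_size = voxel_size)
}

#' Read an SWC morphology file
#'
#' @param path SWC file (7 whitespace-separated columns, `#` comments).
#' @return A [neuron_tree].
#' @export
read_swc <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  ord <- order(tab$id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  neuron_tree(tab)
}

#' Write a neuron tree as an SWC file
#'
#' Positions and radii are written in micrometers; the root carries type 1
#' (soma) and all other nodes type 3.
#'
#' @param tree a [neuron_tree].
#' @param path output file.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by flytrace", con)
  writeLines("# columns: id type x y z radius parent (um)", con)
  fmt <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                 tree$id, tree$type, tree$x, tree$y, tree$z, tree$radius,
                 tree$parent)
  writeLines(fmt, con)
  invisible(path)
}
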