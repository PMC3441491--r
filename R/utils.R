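# internal helpers shared across the pipeline

# linear index of 1-based (y, x, z) voxel coordinates in an (ny, nx, nz) array
vox_lin <- function(pts, dim3) {
  pts[, 1L] + dim3[1L] * ((pts[, 2L] - 1L) + dim3[2L] * (pts[, 3L] - 1L))
}

lin_vox <- function(lin, dim3) {
  m <- arrayInd(lin, .dim = dim3)
  colnames(m) <- c("y", "x", "z")
  m
}

# the 26 neighbor offsets as an integer matrix (dy, dx, dz)
offsets26 <- function() {
  g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

# normalize a voxel_size argument into a named c(x=, y=, z=) vector
norm_voxel_size <- function(voxel_size) {
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (!is.null(names(voxel_size)) && all(c("x", "y", "z") %in% names(voxel_size)))
    voxel_size <- voxel_size[c("x", "y", "z")]
  names(voxel_size) <- c("x", "y", "z")
  voxel_size
}

# physical (x, y, z) micron coordinates of 1-based (y, x, z) voxel points
vox_to_um <- function(pts, voxel_size) {
  cbind(x = (pts[, 2L] - 1) * voxel_size[["x"]],
        y = (pts[, 1L] - 1) * voxel_size[["y"]],
        z = (pts[, 3L] - 1) * voxel_size[["z"]])
}

# voxel-unit (x, y, z) coordinates (isotropic unit-cube metric) of micron points
um_to_voxunits <- function(xyz_um, voxel_size) {
  cbind(xyz_um[, 1L] / voxel_size[["x"]],
        xyz_um[, 2L] / voxel_size[["y"]],
        xyz_um[, 3L] / voxel_size[["z"]])
}

# Euclidean length of a polyline given as an n x 3 coordinate matrix
polyline_length <- function(xyz) {
  if (nrow(xyz) < 2L) return(0)
  d <- diff(xyz)
  sum(sqrt(rowSums(d * d)))
}

as_num_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}
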