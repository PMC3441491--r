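#' Specification of a synthetic neuron phantom
#'
#' Describes a randomly grown ground-truth neuron and how it is rendered
#' into a noisy 8-bit stack. Defaults emulate a single GFP-labeled neuron in
#' a confocal stack at the standard 0.33 x 0.33 x 1.0 um pitch: a bright
#' spherical soma, a binary branching tree with gently tortuous fibers of
#' 0.5-2 um radius, intensity falling off linearly from the centerline to
#' 40% at the tube wall, zero background, and optional additive Gaussian
#' noise with standard deviation `noise_sigma` on the 0-255 scale (the
#' levels studied are 20, 30, 40, 50, 60).
#'
#' @param shape stack dimensions `(ny, nx, nz)` (default 256 x 256 x 128).
#' @param voxel_size voxel pitch `c(x, y, z)` in micrometers.
#' @param n_branch_points number of bifurcations (default 5).
#' @param seg_len_range_um segment length between branch events, micrometers.
#' @param tortuosity sd (radians) of the per-step direction perturbation.
#' @param branch_angle_range_deg opening angle between sibling branches.
#' @param tube_radius_range_um fiber tube radius range, micrometers.
#' @param soma_radius_um soma ball radius, micrometers.
#' @param min_separation_um clearance kept between non-adjacent fiber
#'   sections during growth (default 5), so distinct branches never run
#'   close enough to be confused with one another.
#' @param tip_taper_um terminal branches taper linearly to the minimum tube
#'   radius over this final arc length (default 3), as real neurites do.
#' @param step_um centerline node spacing, micrometers.
#' @param lateral_blur_um apparent widening of fibers by the lateral
#'   point-spread function, micrometers added to the tube radius in x/y
#'   (default 0.2, matching a 20x / NA 1.2 water objective).
#' @param centerline_intensity intensity on the centerline (0-255).
#' @param wall_fraction intensity at the tube wall as a fraction of the
#'   centerline intensity.
#' @param background background intensity.
#' @param noise_sigma Gaussian noise sd; 0 means noiseless.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L, 128L),
                         voxel_size = c(x = 0.33, y = 0.33, z = 1.0),
                         n_branch_points = 5L,
                         seg_len_range_um = c(8, 25),
                         tortuosity = 0.12,
                         branch_angle_range_deg = c(30, 70),
                         tube_radius_range_um = c(0.5, 2),
                         soma_radius_um = 3,
                         min_separation_um = 5,
                         tip_taper_um = 3,
                         step_um = 0.5,
                         lateral_blur_um = 0.2,
                         centerline_intensity = 220,
                         wall_fraction = 0.4,
                         background = 0,
                         noise_sigma = 0) {
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_branch_points >= 0L,
            noise_sigma >= 0, soma_radius_um > 0,
            all(tube_radius_range_um > 0))
  structure(list(shape = as.integer(shape),
                 voxel_size = norm_voxel_size(voxel_size),
                 n_branch_points = as.integer(n_branch_points),
                 seg_len_range_um = seg_len_range_um,
                 tortuosity = tortuosity,
                 branch_angle_range_deg = branch_angle_range_deg,
                 tube_radius_range_um = tube_radius_range_um,
                 soma_radius_um = soma_radius_um,
                 min_separation_um = min_separation_um,
                 tip_taper_um = tip_taper_um, step_um = step_um,
                 lateral_blur_um = lateral_blur_um,
                 centerline_intensity = centerline_intensity,
                 wall_fraction = wall_fraction, background = background,
                 noise_sigma = noise_sigma),
            class = "phantom_spec")
}

unit <- function(v) v / sqrt(sum(v * v))

rotate_about <- function(v, axis, theta) {
  # Rodrigues rotation of v about unit axis
  axis <- unit(axis)
  v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Generate a ground-truth phantom tree
#'
#' Grows a random rooted tree inside the stack volume: a trunk leaves the
#' soma and each segment ends either in a bifurcation (until the budget of
#' `n_branch_points` is spent) or in a terminal tip. Direction is perturbed
#' at every step (tortuosity) and steered back when a fiber approaches the
#' stack boundary, so the tree always fits with a margin of at least the
#' maximum tube radius. Deterministic given `seed`. Successive branch
#' points are separated by more than 2 um by construction (minimum segment
#' length).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return A [neuron_tree] (micrometers; voxel size attached). Node radii
#'   are tube radii; the root carries the soma radius.
#' @export
generate_tree <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  vs <- spec$voxel_size
  ext <- (spec$shape - 1L) * c(vs[["y"]], vs[["x"]], vs[["z"]])  # y,x,z um
  ext_xyz <- ext[c(2L, 1L, 3L)]
  margin <- spec$soma_radius_um + max(spec$tube_radius_range_um) + 1
  if (any(ext_xyz <= 2 * margin + 2)) stop("stack too small for the phantom")
  lo <- rep(margin, 3L); hi <- ext_xyz - margin
  soma <- lo + c(0.35, 0.35, 0.35) * (hi - lo) +
    runif(3L) * 0.3 * (hi - lo)
  nodes <- list(list(pos = soma, parent = -1L, radius = spec$soma_radius_um))
  budget <- spec$n_branch_points
  center <- (lo + hi) / 2
  grow_segment <- function(start_id, dir, radius) {
    # grow one segment of steps; returns the id of its last node and the
    # final direction. Steps keep min_separation_um clearance from every
    # fiber section laid before this segment (junction vicinity excepted),
    # deflecting away when crowded and stopping early as a last resort.
    L <- runif(1L, spec$seg_len_range_um[1L], spec$seg_len_range_um[2L])
    nstep <- max(2L, ceiling(L / spec$step_um))
    pid <- start_id
    pos <- nodes[[start_id]]$pos
    older <- do.call(rbind, lapply(nodes, `[[`, "pos"))
    near_start <- sqrt(rowSums(sweep(older, 2L, pos, "-")^2)) <
      spec$min_separation_um
    foreign <- older[!near_start, , drop = FALSE]
    for (s in seq_len(nstep)) {
      placed <- FALSE
      for (try in 1:4) {
        dir <- unit(dir + rnorm(3L, sd = spec$tortuosity))
        nxt <- pos + dir * spec$step_um
        if (any(nxt < lo) || any(nxt > hi)) {
          dir <- unit(dir + 1.5 * unit(center - pos))
          nxt <- pmin(pmax(pos + dir * spec$step_um, lo), hi)
        }
        if (nrow(foreign)) {
          dd <- sqrt(rowSums(sweep(foreign, 2L, nxt, "-")^2))
          if (min(dd) < spec$min_separation_um) {
            dir <- unit(dir + unit(nxt - foreign[which.min(dd), ]))
            next
          }
        }
        placed <- TRUE
        break
      }
      if (!placed) break                    # crowded: terminate this tip
      pos <- nxt
      nodes[[length(nodes) + 1L]] <<- list(pos = pos, parent = pid,
                                           radius = radius)
      pid <- length(nodes)
    }
    list(id = pid, dir = dir)
  }
  trunk_rad <- runif(1L, mean(spec$tube_radius_range_um),
                     spec$tube_radius_range_um[2L])
  # breadth-first growth: every active tip either bifurcates (while the
  # branch-point budget lasts) or terminates, so tip depths differ by at
  # most one level and no root-to-tip path is disproportionately short
  queue <- list(list(start = 1L, dir = unit(rnorm(3L)), radius = trunk_rad))
  while (length(queue)) {
    tip <- queue[[1L]]; queue <- queue[-1L]
    seg <- grow_segment(tip$start, tip$dir, tip$radius)
    if (budget > 0L) {
      budget <- budget - 1L
      ang <- runif(1L, spec$branch_angle_range_deg[1L],
                   spec$branch_angle_range_deg[2L]) * pi / 180
      axis <- unit(pracma_cross(seg$dir, rnorm(3L)))
      for (sgn in c(-0.5, 0.5)) {
        child_dir <- unit(rotate_about(seg$dir, axis, sgn * ang))
        child_rad <- runif(1L, spec$tube_radius_range_um[1L],
                           min(tip$radius, spec$tube_radius_range_um[2L]))
        queue[[length(queue) + 1L]] <-
          list(start = seg$id, dir = child_dir, radius = child_rad)
      }
    }
  }
  pos <- do.call(rbind, lapply(nodes, `[[`, "pos"))
  radius <- vapply(nodes, `[[`, numeric(1L), "radius")
  parent <- vapply(nodes, `[[`, integer(1L), "parent")
  # taper terminal branches to the minimum tube radius over the last
  # tip_taper_um of arc, as real neurites thin toward their tips
  if (spec$tip_taper_um > 0) {
    rmin <- spec$tube_radius_range_um[1L]
    is_parent <- seq_along(nodes) %in% parent
    for (leaf in setdiff(which(!is_parent), 1L)) {
      arc <- 0
      v <- leaf
      while (v > 1L && arc < spec$tip_taper_um) {
        w <- arc / spec$tip_taper_um
        radius[v] <- min(radius[v], rmin + (radius[v] - rmin) * w)
        p <- parent[v]
        if (p < 1L) break
        arc <- arc + sqrt(sum((pos[v, ] - pos[p, ])^2))
        v <- p
      }
    }
  }
  neuron_tree(data.frame(id = seq_along(nodes),
                         type = ifelse(seq_along(nodes) == 1L, 1L, 3L),
                         x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                         radius = radius, parent = parent),
              voxel_size = vs)
}

#' Rasterize a phantom tree into an image stack
#'
#' Renders every fiber as a tube: a voxel whose physical distance to the
#' centerline is below the local tube radius receives the centerline
#' intensity attenuated linearly to `wall_fraction` at the wall; the soma is
#' rendered as a ball the same way. Overlaps keep the maximum. Anisotropic
#' voxel sizes are honored.
#'
#' @param tree a [neuron_tree] (micrometers).
#' @param spec the [phantom_spec()] used to generate it.
#' @return An [image_stack].
#' @export
rasterize <- function(tree, spec) {
  stopifnot(inherits(tree, "neuron_tree"), inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size
  pitch <- c(vs[["y"]], vs[["x"]], vs[["z"]])      # per array axis
  d <- spec$shape
  arr <- array(as.numeric(spec$background), d)
  xyz <- as.matrix(tree[, c("x", "y", "z")])
  pid <- match(tree$parent, tree$id)
  half_z <- vs[["z"]] / 2
  blur_xy <- spec$lateral_blur_um
  paint_capsule <- function(a, b, r, flat = FALSE) {
    # a, b physical (x,y,z); tube of radius r between them. The optics widen
    # the apparent fiber: the confocal slice integrates +-half_z um axially
    # and the lateral point-spread adds ~lateral_blur_um, so the rendered
    # cross-section is an ellipse with semi-axes (r + blur, r + blur,
    # r + half_z). Fibers look z-elongated and thin tubes stay visible even
    # between slice planes — the ovalization the 2D-slice strategy expects.
    rxy <- r + blur_xy
    rz <- r + half_z
    lo_um <- pmin(a, b) - rz; hi_um <- pmax(a, b) + rz
    lo <- pmax(floor(lo_um[c(2L, 1L, 3L)] / pitch) + 1L, 1L)
    hi <- pmin(ceiling(hi_um[c(2L, 1L, 3L)] / pitch) + 1L, d)
    if (any(lo > hi)) return(invisible())
    g <- as.matrix(expand.grid(y = lo[1L]:hi[1L], x = lo[2L]:hi[2L],
                               z = lo[3L]:hi[3L]))
    sc <- c(rxy, rxy, rz)
    pos <- cbind((g[, 2L] - 1) * vs[["x"]], (g[, 1L] - 1) * vs[["y"]],
                 (g[, 3L] - 1) * vs[["z"]])
    u <- point_segment_dist(sweep(pos, 2L, sc, "/"),
                            a / sc, b / sc)      # normalized elliptic radius
    ins <- u <= 1
    if (!any(ins)) return(invisible())
    val <- if (flat) rep(spec$centerline_intensity, sum(ins))
           else spec$centerline_intensity *
             (1 - (1 - spec$wall_fraction) * u[ins])
    lin <- vox_lin(g[ins, , drop = FALSE], d)
    arr[lin] <<- pmax(arr[lin], val)
    invisible()
  }
  # the soma is a uniformly bright ball: in real stacks it is the
  # highest-intensity structure, which the binarization must not erode
  root <- which(is.na(pid))
  paint_capsule(xyz[root, ], xyz[root, ], tree$radius[root], flat = TRUE)
  for (i in which(!is.na(pid)))
    paint_capsule(xyz[pid[i], ], xyz[i, ], tree$radius[i])
  arr <- round(pmin(pmax(arr, 0), 255))
  image_stack(arr, vs)
}

#' Add clamped Gaussian noise to a stack
#'
#' Independent Gaussian noise of standard deviation `sigma` per voxel,
#' rounded and clamped to the 8-bit range. Deterministic given `seed`;
#' `sigma = 0` returns the stack unchanged.
#'
#' @param stack an [image_stack].
#' @param sigma noise standard deviation on the 0-255 scale.
#' @param seed integer seed.
#' @return An [image_stack].
#' @export
add_noise <- function(stack, sigma, seed = 1L) {
  stopifnot(inherits(stack, "image_stack"), sigma >= 0)
  if (sigma == 0) return(stack)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  noisy <- stack$data + rnorm(length(stack$data), sd = sigma)
  image_stack(array(round(pmin(pmax(noisy, 0), 255)), dim(stack$data)),
              stack$voxel_size)
}

#' Generate a complete phantom: ground-truth tree plus (noisy) stack
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (drives both the tree and the noise).
#' @return A list with elements `tree` ([neuron_tree]), `stack`
#'   ([image_stack]), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  tree <- generate_tree(spec, seed = seed)
  stack <- rasterize(tree, spec)
  if (spec$noise_sigma > 0)
    stack <- add_noise(stack, spec$noise_sigma, seed = seed + 1L)
  list(tree = tree, stack = stack, spec = spec)
}
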