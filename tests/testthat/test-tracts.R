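bent_tree <- function(xs, ys, zs = 0) {
  n <- length(xs)
  neuron_tree(data.frame(id = 1:n, type = c(1L, rep(3L, n - 1L)),
                         x = xs, y = ys, z = zs, radius = 1,
                         parent = c(-1L, 1:(n - 1L))))
}

test_that("region primitives classify and measure points correctly", {
  sp <- region_sphere(c(0, 0, 0), 2)
  bx <- region_box(c(0, 0, 0), c(1, 1, 1))
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(0.5, 0.5, 0.5), c(2, 2, 2))
  expect_identical(region_contains(sp, pts), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(region_contains(bx, pts), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(region_distance(sp, pts), c(0, 1, 0, sqrt(12) - 2))
  expect_equal(region_distance(bx, pts), c(0, 2, 0, sqrt(3)))
})

test_that("innervation selection requires both regions and no exclusions", {
  a <- region_sphere(c(0, 0, 0), 1.5)
  b <- region_sphere(c(10, 0, 0), 1.5)
  ex <- region_sphere(c(5, 5, 0), 1.5)
  crossing <- bent_tree(0:10, rep(0, 11))
  outside <- bent_tree(0:10, rep(20, 11))
  touching_ex <- bent_tree(c(0:5, 5, 6:10), c(rep(0, 6), 5, rep(0, 5)))
  got <- select_innervating(list(crossing, outside, touching_ex), a, b,
                            exclude = list(ex))
  expect_identical(got, 1L)
  expect_identical(select_innervating(list(crossing, outside), a, b), 1L)
})

test_that("extract_path returns the between-region segment, ignoring side branches", {
  a <- region_sphere(c(0, 0, 0), 1.5)
  b <- region_sphere(c(10, 0, 0), 1.5)
  tr <- bent_tree(0:10, rep(0, 11))
  p <- extract_path(tr, a, b)
  # runs from the exit of a to the entry of b
  expect_lte(p[1L, 1L], 1.5)
  expect_gte(p[nrow(p), 1L], 8.5)
  expect_true(all(diff(p[, 1L]) > 0))

  # a branched tree: the side branch is not part of the path
  n <- 11L
  side <- data.frame(id = 12:16, type = 3L, x = 5, y = 1:5, z = 0,
                     radius = 1, parent = c(6L, 12:15))
  tr2 <- neuron_tree(rbind(as.data.frame(tr), side))
  p2 <- extract_path(tr2, a, b)
  expect_true(all(p2[, 2L] == 0))          # stays on the trunk
})

test_that("path clustering is orientation- and order-invariant and exact on bundles", {
  # two identical paths (one reversed) land in one cluster at distance 0
  p <- cbind(0:10, (0:10)^1.5 / 5, 0)
  cl <- cluster_paths(list(p, p[nrow(p):1L, ]), n_clusters = 1L)
  expect_equal(max(cl$dist), 0)

  sim <- simulate_tract_bundles(n_bundles = 3L, n_per_bundle = 20L, seed = 6)
  cl3 <- cluster_paths(sim$paths, n_clusters = 3L)
  expect_equal(adjusted_rand_index(cl3$labels, sim$labels), 1)
  # automatic largest-gap cut finds the same structure
  cl_auto <- cluster_paths(sim$paths)
  expect_equal(cl_auto$n_clusters, 3L)
  expect_equal(adjusted_rand_index(cl_auto$labels, sim$labels), 1)

  # shuffling input order and flipping orientations changes nothing
  set.seed(2)
  perm <- sample(length(sim$paths))
  flipped <- lapply(sim$paths[perm], function(m)
    if (runif(1) < 0.5) m[nrow(m):1L, ] else m)
  cl_p <- cluster_paths(flipped, n_clusters = 3L)
  expect_equal(adjusted_rand_index(cl_p$labels, sim$labels[perm]), 1)

  expect_error(cluster_paths(sim$paths[1:2], n_clusters = 5L), "fewer paths")
})

test_that("resample_path spaces points evenly along arc length", {
  p <- cbind(c(0, 1, 1, 4), c(0, 0, 2, 2), 0)
  r <- resample_path(p, 7L)
  expect_equal(nrow(r), 7L)
  seg <- sqrt(rowSums(diff(r)^2))
  expect_equal(seg, rep(sum(c(1, 2, 3)) / 6, 6), tolerance = 0.2)
  expect_equal(r[1L, ], p[1L, ])
  expect_equal(r[7L, ], p[4L, ])
})
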