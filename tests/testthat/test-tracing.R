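make_ball_stack <- function(center_um, radius_um, dim3 = c(64L, 64L, 24L),
                            vs = c(x = 0.33, y = 0.33, z = 1.0),
                            intensity = 200L, base = NULL) {
  g <- as.matrix(expand.grid(y = 1:dim3[1L], x = 1:dim3[2L], z = 1:dim3[3L]))
  pos <- cbind((g[, 2L] - 1) * vs[["x"]], (g[, 1L] - 1) * vs[["y"]],
               (g[, 3L] - 1) * vs[["z"]])
  d <- sqrt(rowSums(sweep(pos, 2L, center_um, "-")^2))
  arr <- if (is.null(base)) array(0L, dim3) else base
  arr[g[d <= radius_um, , drop = FALSE]] <- intensity
  image_stack(arr, vs)
}

test_that("soma detection recovers the center and radius of a ball", {
  ctr <- c(10, 10, 11)
  st <- make_ball_stack(ctr, 5)
  vol <- binary_volume(st$data > 0, st$voxel_size)
  q <- skeletonize_slices(vol)
  soma <- detect_soma(q, st, vol)
  expect_lt(sqrt(sum((soma$position_um - ctr)^2)), 1)
  expect_lt(abs(soma$radius_um - 5), 1)
})

test_that("equal-radius soma candidates are broken by intensity", {
  vs <- c(x = 0.33, y = 0.33, z = 1.0)
  # two lattice-aligned identical balls; the second is brighter
  c1 <- c(14, 15, 5) * c(0.33, 0.33, 1.0)
  c2 <- c(75, 15, 5) * c(0.33, 0.33, 1.0)
  st <- make_ball_stack(c1, 2.5, c(48L, 96L, 12L), vs, intensity = 150L)
  st <- make_ball_stack(c2, 2.5, c(48L, 96L, 12L), vs, intensity = 250L,
                        base = st$data)
  vol <- binary_volume(st$data > 0, vs)
  q <- skeletonize_slices(vol)
  soma <- detect_soma(q, st, vol)
  expect_lt(abs(soma$position_um[1L] - c2[1L]), 1)   # brighter ball wins
})

test_that("edge costs implement the branch-point bonus", {
  pts <- cbind(y = 10L, x = 5:15, z = 5L)
  q <- sk_from_points(pts, c(32L, 32L, 32L))
  q$branch[6L] <- TRUE                      # point at x = 10
  g <- build_graph(q)
  ed <- g$edges
  expect_true(all(ed$w_d == 1))
  # incident edges have midpoints 0.5 voxels from the branch point
  mids <- (pts[ed$i, 2L] + pts[ed$j, 2L]) / 2
  near <- which(abs(mids - 10) == 0.5)
  expect_equal(ed$w_b[near], c(9.5, 9.5))
  expect_equal(ed$cost[near], rep(1 / 10.5, 2L))
  # edges outside the box carry no bonus and cost w_d
  faraway <- which(abs(mids - 10) > 4)
  expect_true(all(ed$w_b[faraway] == 0))
  expect_true(all(ed$cost[faraway] == ed$w_d[faraway]))
  # a larger eta never increases any edge cost
  g12 <- build_graph(q, eta = 12)
  expect_true(all(g12$edges$cost <= ed$cost + 1e-12))
})

test_that("bonus edges attract shortest paths through junctions", {
  # two parallel corridors from left to right; one passes a branch point
  top <- cbind(y = 5L, x = 1:9, z = 5L)
  bot <- cbind(y = 7L, x = 1:9, z = 5L)
  pts <- rbind(top, bot, c(6L, 1L, 5L), c(6L, 9L, 5L))
  q <- sk_from_points(pts, c(32L, 32L, 32L))
  q$branch[5L] <- TRUE                      # on the top corridor
  g <- build_graph(q)
  br <- shortest_path_branches(g, nrow(pts) - 1L, nrow(pts))
  expect_true(all(q$pts[br$paths[[1L]], 1L][2:8] == 5L))
})

test_that("Dijkstra equals exhaustive enumeration on a weighted diamond", {
  pts <- rbind(c(5L, 5L, 5L), c(4L, 6L, 5L), c(6L, 6L, 5L), c(5L, 7L, 5L))
  q <- sk_from_points(pts, c(16L, 16L, 16L))
  q$branch[2L] <- TRUE                      # makes the two routes unequal
  g <- build_graph(q)
  br <- shortest_path_branches(g, 1L, 4L)
  ekey <- paste(pmin(g$edges$i, g$edges$j), pmax(g$edges$i, g$edges$j))
  p <- br$paths[[1L]]
  got <- sum(g$edges$cost[match(paste(pmin(head(p, -1), p[-1]),
                                      pmax(head(p, -1), p[-1])), ekey)])
  oracle <- enumerate_path_costs(4L, data.frame(i = g$edges$i, j = g$edges$j,
                                                w = g$edges$cost), 1L, 4L)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(2L %in% p)                     # route through the bonus vertex

  expect_error(shortest_path_branches(g, 99L), "not in graph")
  expect_length(shortest_path_branches(g, 1L, integer(0))$paths, 0L)
})

test_that("short branches are pruned by the 0.2 length ratio, strictly", {
  vs <- c(x = 1, y = 1, z = 1)
  pts <- rbind(cbind(y = 1L, x = 1:101, z = 1L),    # rows 1:101, length 100
               cbind(y = 2L, x = 1:21, z = 1L),     # rows 102:122, length 20
               cbind(y = 3L, x = 1:20, z = 1L))     # rows 123:142, length 19
  q <- skeleton_points(pts, rep(1, nrow(pts)), c(8L, 128L, 4L), vs)
  br <- structure(list(paths = list(1:101, 102:122, 123:142), q = q,
                       soma_index = 1L), class = "branch_set")
  out <- prune_short_branches(br)
  expect_length(out$paths, 2L)               # ratio exactly 0.2 is kept
  expect_true(all(vapply(out$paths, length, 1L) >= 21L))
  one <- structure(list(paths = list(123:142), q = q, soma_index = 1L),
                   class = "branch_set")
  expect_length(prune_short_branches(one)$paths, 1L)
})

test_that("branch merging records junctions and snaps nearby divergences", {
  vs <- c(x = 1, y = 1, z = 1)
  dim3 <- c(32L, 64L, 8L)
  trunk <- cbind(y = 10L, x = 1:30, z = 2L)         # rows 1:30
  armA <- cbind(y = 11:20, x = 20L, z = 2L)         # rows 31:40
  armB <- cbind(y = 9:1, x = 21L, z = 2L)           # rows 41:49
  pts <- rbind(trunk, armA, armB)
  q <- skeleton_points(pts, rep(1, nrow(pts)), dim3, vs)
  soma <- structure(list(index = 1L, point = pts[1L, ],
                         position_um = c(0, 9, 1), radius_um = 1,
                         intensity_sum = 0), class = "soma_estimate")
  br <- structure(list(paths = list(1:30, c(1:20, 31:40), c(1:21, 41:49)),
                       q = q, soma_index = 1L), class = "branch_set")
  tree <- merge_branches(br, soma)
  expect_s3_class(tree, "neuron_tree")
  expect_gte(length(attr(tree, "bplist")), 1L)
  # branch B is rerouted through A's recorded junction: one bifurcation node
  pid <- match(tree$parent, tree$id)
  nchild <- tabulate(pid[!is.na(pid)], nbins = nrow(tree))
  expect_equal(sum(nchild >= 2L), 1L)

  one <- structure(list(paths = list(1:30), q = q, soma_index = 1L),
                   class = "branch_set")
  t1 <- merge_branches(one, soma)
  expect_equal(nrow(t1), 30L)
  expect_length(attr(t1, "bplist"), 0L)
  expect_equal(t1$radius[t1$parent == -1], 1)        # root carries soma radius
})

test_that("false end points near an accepted branch are dropped", {
  vs <- c(x = 1, y = 1, z = 1)
  pts <- rbind(cbind(y = 10L, x = 1:20, z = 2L),
               c(11L, 10L, 2L),                      # 1 um from the branch
               c(10L, 10L, 5L))                      # 3 um away
  q <- skeleton_points(pts, c(rep(2, 20), 1, 1), c(32L, 32L, 8L), vs)
  # mean branch radius = 2 px -> rbar = 2 um at unit pitch
  expect_identical(remove_false_endpoints(1:20, q, c(21L, 22L)), 21L)
  expect_identical(remove_false_endpoints(1:20, q, integer(0)), integer(0))
})
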