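test_that("component graph edges obey the 5% gap rule with exact closest pairs", {
  # single component
  seg <- cbind(y = 5L, x = 3:12, z = 5L)
  g1 <- build_component_graph(sk_from_points(seg, c(512L, 512L, 60L)))
  expect_equal(g1$n_components, 1L)
  expect_equal(nrow(g1$edges), 0L)

  # two points 3 voxels apart in a 512-wide stack: limit 25.6 -> one edge
  two <- rbind(c(10L, 10L, 10L), c(10L, 13L, 10L))
  g2 <- build_component_graph(sk_from_points(two, c(512L, 512L, 60L)))
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$dist, 3)

  # 30 voxels apart: 30 > 25.6 -> no edge
  far <- rbind(c(10L, 10L, 10L), c(10L, 40L, 10L))
  g3 <- build_component_graph(sk_from_points(far, c(512L, 512L, 60L)))
  expect_equal(nrow(g3$edges), 0L)

  # closest pairs match a brute-force double loop
  set.seed(14)
  for (rep in 1:10) {
    pts <- unique(cbind(sample(1:30, 25L, TRUE), sample(1:30, 25L, TRUE),
                        sample(1:30, 25L, TRUE)))
    q <- sk_from_points(pts, c(30L, 30L, 30L))
    g <- build_component_graph(q, gap_fraction = 1)
    for (r in seq_len(nrow(g$edges))) {
      ia <- which(g$comp == g$edges$a[r]); ib <- which(g$comp == g$edges$b[r])
      dd <- outer(seq_along(ia), seq_along(ib), Vectorize(function(i, j)
        sqrt(sum((pts[ia[i], ] - pts[ib[j], ])^2))))
      expect_equal(g$edges$dist[r], min(dd))
    }
  }
})

test_that("Kruskal MST weight equals exhaustive spanning-tree enumeration", {
  set.seed(31)
  for (rep in 1:30) {
    ncomp <- sample(3:6, 1L)
    # scatter small clusters far apart inside a 64^3 stack
    centers <- cbind(sample(seq(8, 56, 4), ncomp), sample(seq(8, 56, 4), ncomp),
                     sample(seq(8, 56, 4), ncomp))
    pts <- do.call(rbind, lapply(seq_len(ncomp), function(i)
      sweep(as.matrix(expand.grid(0:1, 0:1, 0)), 2L, centers[i, ], "+")))
    q <- sk_from_points(pts, c(64L, 64L, 64L))
    g <- build_component_graph(q, gap_fraction = 2)  # admit all pairs
    mst <- flytrace:::kruskal_mst(g$n_components, g$edges)
    expect_equal(sum(mst$dist), brute_mst_weight(g$n_components, g$edges),
                 tolerance = 1e-10)
    # independent cross-check against igraph's MST
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$edges$a, to = g$edges$b),
      directed = FALSE,
      vertices = data.frame(name = seq_len(g$n_components)))
    igraph::E(ig)$weight <- g$edges$dist
    expect_equal(sum(mst$dist), sum(igraph::E(igraph::mst(ig))$weight),
                 tolerance = 1e-10)
  }
})

test_that("MST prefers short gaps over one long edge", {
  # 3 collinear clusters with gaps 2 and 3; the far pair (6) must be unused
  pts <- rbind(c(5L, 2L, 5L), c(5L, 3L, 5L),
               c(5L, 5L, 5L), c(5L, 6L, 5L),
               c(5L, 9L, 5L), c(5L, 10L, 5L))
  q <- sk_from_points(pts, c(64L, 64L, 64L))
  g <- build_component_graph(q, gap_fraction = 1)
  mst <- flytrace:::kruskal_mst(g$n_components, g$edges)
  expect_equal(sort(mst$dist), c(2, 3))
})

test_that("bridging inserts unit-spaced points and yields one component", {
  # gap of 4 along x: 3 interior bridge points expected
  pts <- rbind(c(5L, 3L, 5L), c(5L, 7L, 5L))
  q <- sk_from_points(pts, c(64L, 64L, 64L))
  out <- mst_connect(q, build_component_graph(q, gap_fraction = 0.2))
  expect_equal(nrow(out$pts), 5L)
  expect_setequal(out$pts[, 2L], 3:7)
  # bridge radii interpolate between the endpoints
  expect_true(all(out$radius >= 1 & out$radius <= 1))

  # already-connected input is unchanged
  seg <- cbind(y = 5L, x = 3:12, z = 5L)
  qs <- sk_from_points(seg, c(64L, 64L, 64L))
  expect_equal(mst_connect(qs)$pts, qs$pts)

  # disconnected graph (gap beyond limit): largest component kept
  pts2 <- rbind(cbind(y = 5L, x = 1:5, z = 5L), c(40L, 40L, 20L))
  q2 <- sk_from_points(pts2, c(64L, 64L, 64L))
  out2 <- mst_connect(q2)
  expect_equal(nrow(out2$pts), 5L)

  set.seed(8)
  for (rep in 1:6) {
    pts <- unique(cbind(sample(3:28, 20L, TRUE), sample(3:28, 20L, TRUE),
                        sample(3:28, 20L, TRUE)))
    qr <- sk_from_points(pts, c(30L, 30L, 30L))
    out <- mst_connect(qr, build_component_graph(qr, gap_fraction = 1))
    arr <- array(FALSE, c(30L, 30L, 30L))
    arr[out$pts] <- TRUE
    lab <- flood_label(arr, slicewise = FALSE)
    expect_equal(max(lab), 1L)           # exactly one 26-connected component
  }
})
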