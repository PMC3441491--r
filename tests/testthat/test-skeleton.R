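test_that("per-slice EDT matches hand values and a brute-force scan", {
  m <- array(FALSE, c(11L, 11L, 1L))
  m[3:9, 3:9, 1L] <- TRUE
  d <- edt_2d(binary_volume(m))
  expect_equal(d[6, 6, 1L], 4)             # center of a filled 7x7 square
  s <- array(FALSE, c(5L, 5L, 1L)); s[3, 3, 1L] <- TRUE
  expect_equal(edt_2d(binary_volume(s))[3, 3, 1L], 1)
  expect_true(all(edt_2d(binary_volume(array(FALSE, c(4, 4, 1)))) == 0))

  set.seed(3)
  for (rep in 1:5) {
    sl <- matrix(runif(12 * 12) < 0.4, 12L, 12L)
    vol <- binary_volume(array(sl, c(12L, 12L, 1L)))
    expect_equal(edt_2d(vol)[, , 1L], brute_edt_slice(sl))
  }
})

test_that("skeletonization is the identity on thin curves and centers tubes", {
  # 1-pixel-wide straight line
  m <- array(FALSE, c(9L, 20L, 1L))
  m[5, 3:18, 1L] <- TRUE
  q <- skeletonize_slices(binary_volume(m))
  expect_equal(nrow(q$pts), 16L)
  expect_true(all(q$pts[, 1L] == 5L))

  # filled disk reduces to a small central cluster
  dsk <- array(FALSE, c(21L, 21L, 1L))
  for (i in 1:21) for (j in 1:21)
    if ((i - 11)^2 + (j - 11)^2 <= 64) dsk[i, j, 1L] <- TRUE
  qd <- skeletonize_slices(binary_volume(dsk))
  expect_lte(nrow(qd$pts), 9L)
  ctr <- colMeans(qd$pts[, 1:2, drop = FALSE])
  expect_lt(sqrt(sum((ctr - c(11, 11))^2)), 2)

  # 3 x 20 rectangle thins to (approximately) the central row
  rect <- array(FALSE, c(9L, 24L, 1L))
  rect[4:6, 3:22, 1L] <- TRUE
  qr <- skeletonize_slices(binary_volume(rect))
  expect_true(all(qr$pts[, 1L] == 5L))
  expect_gte(nrow(qr$pts), 16L)

  # skeleton is always inside the mask, and carries the slice EDT radius
  expect_true(all(rect[qr$pts]))
  expect_true(all(qr$radius >= 1))
})

test_that("every 2D component keeps at least one skeleton point", {
  set.seed(9)
  for (rep in 1:6) {
    m <- array(runif(16 * 16 * 2) < 0.25, c(16L, 16L, 2L))
    q <- skeletonize_slices(binary_volume(m))
    lab <- flood_label(m, slicewise = TRUE)
    have <- unique(lab[q$pts])
    expect_setequal(setdiff(unique(as.vector(lab)), 0L), have)
  }
})

test_that("end candidates are exactly the extremities of irreducible arcs", {
  # isolated point
  q1 <- detect_end_candidates(sk_from_points(cbind(5L, 5L, 5L)))
  expect_true(q1$end)
  # straight 26-connected segment: interior not flagged, ends flagged
  seg <- cbind(y = 5L, x = 3:12, z = 5L)
  q2 <- detect_end_candidates(sk_from_points(seg))
  expect_identical(which(q2$end), c(1L, 10L))

  set.seed(21)
  for (rep in 1:12) {
    arc <- random_digital_arc(sample(10:40, 1L), c(40L, 40L, 40L))
    q <- detect_end_candidates(sk_from_points(arc, c(40L, 40L, 40L)))
    expect_identical(which(q$end), c(1L, nrow(arc)))
  }
})

test_that("tube tips with same-side companions are still flagged as ends", {
  # a tip whose two neighbors both lie on one side (adjacent slices overlap)
  pts <- rbind(c(10L, 10L, 10L),           # tip
               c(9L, 10L, 10L), c(9L, 10L, 11L),
               c(8L, 10L, 11L), c(7L, 10L, 11L))
  q <- detect_end_candidates(sk_from_points(pts))
  expect_true(q$end[1L])
})

test_that("branch candidates need 4-5 neighbors forming >= 3 arms", {
  # '+' junction in one slice: 4 neighbors, 4 face-separated arms
  ctr <- cbind(10L, 10L, 5L)
  plus <- rbind(ctr, c(9L, 10L, 5L), c(11L, 10L, 5L),
                c(10L, 9L, 5L), c(10L, 11L, 5L),
                c(8L, 10L, 5L), c(12L, 10L, 5L),
                c(10L, 8L, 5L), c(10L, 12L, 5L))
  qp <- detect_branch_candidates(sk_from_points(plus))
  expect_true(qp$branch[1L])

  # interior of a straight line: 2 neighbors, never a branch candidate
  seg <- cbind(y = 5L, x = 3:12, z = 5L)
  qs <- detect_branch_candidates(sk_from_points(seg))
  expect_false(any(qs$branch))

  # T-junction with only 3 neighbors: not flagged (needs 4 or 5)
  tj <- rbind(ctr, c(9L, 10L, 5L), c(11L, 10L, 5L), c(10L, 11L, 5L),
              c(8L, 10L, 5L), c(12L, 10L, 5L), c(10L, 12L, 5L))
  qt <- detect_branch_candidates(sk_from_points(tj))
  expect_false(qt$branch[1L])
})
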