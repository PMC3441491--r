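test_that("binarize keeps the brightest fraction of visible voxels, with ties", {
  arr <- array(0L, c(2L, 3L, 1L))
  arr[1:6] <- c(5L, 10L, 11L, 20L, 200L, 255L)
  st <- image_stack(arr)
  # visible = {11, 20, 200, 255}; t = floor(0.7 * 4) = 2 -> keep {200, 255}
  m <- binarize(st)$mask
  expect_identical(sort(arr[m]), c(200L, 255L))

  expect_false(any(binarize(image_stack(array(0L, c(3, 3, 2))))$mask))

  m1 <- binarize(st, keep_fraction = 1)$mask
  expect_identical(which(m1), which(arr > 10L))

  # ties at the threshold intensity are all kept
  arr2 <- array(0L, c(2L, 5L, 1L))
  arr2[1:10] <- c(50L, 50L, 50L, 50L, 90L, 90L, 0L, 0L, 0L, 0L)
  m2 <- binarize(image_stack(arr2), keep_fraction = 0.5)$mask
  # visible = 6 voxels, t = 3; 3rd brightest is 50 -> all four 50s kept
  expect_equal(sum(m2), 6L)
})

test_that("binarize output grows monotonically with keep_fraction", {
  set.seed(11)
  for (rep in 1:20) {
    arr <- array(sample(0:255, 8^3, TRUE), c(8L, 8L, 8L))
    st <- image_stack(arr)
    fr <- sort(runif(3, 0.05, 1))
    masks <- lapply(fr, function(f) binarize(st, keep_fraction = f)$mask)
    expect_true(all(masks[[2L]][masks[[1L]]]))
    expect_true(all(masks[[3L]][masks[[2L]]]))
    # kept count is at least floor(f * n_visible)
    nv <- sum(arr > 10L)
    for (k in 1:3) expect_gte(sum(masks[[k]]), floor(fr[k] * nv))
  }
})

test_that("2D filter drops components under 9 pixels and keeps the rest", {
  m <- array(FALSE, c(12L, 16L, 1L))
  m[2:3, 2:5, 1L] <- TRUE                 # 8 pixels
  m[7:9, 2:4, 1L] <- TRUE                 # 9 pixels
  out <- remove_small_2d(binary_volume(m))$mask
  expect_equal(sum(out), 9L)
  expect_true(all(out[7:9, 2:4, 1L]))
  expect_false(any(remove_small_2d(binary_volume(array(FALSE, c(4, 4, 2))))$mask))
  big <- array(FALSE, c(12L, 12L, 1L)); big[2:11, 2:11, 1L] <- TRUE
  expect_identical(remove_small_2d(binary_volume(big))$mask, big)
})

test_that("3D filter uses 26-connectivity and the 30-voxel threshold", {
  m <- array(FALSE, c(10L, 10L, 10L))
  m[2:30] <- TRUE                          # 29 voxels along a column run
  m2 <- array(FALSE, c(10L, 10L, 10L))
  m2[2:31] <- TRUE                         # 30 voxels
  expect_false(any(remove_small_3d(binary_volume(m))$mask))
  expect_equal(sum(remove_small_3d(binary_volume(m2))$mask), 30L)
  # diagonal-touching voxels are one component
  dg <- array(FALSE, c(6L, 6L, 6L))
  dg[2, 2, 2] <- dg[3, 3, 3] <- TRUE
  expect_false(any(remove_small_3d(binary_volume(dg), min_voxels = 3)$mask))
  expect_equal(sum(remove_small_3d(binary_volume(dg), min_voxels = 2)$mask), 2L)
})

test_that("small-component filters match a flood-fill oracle and are idempotent", {
  set.seed(5)
  for (rep in 1:8) {
    m <- array(runif(14^3) < 0.12, c(14L, 14L, 14L))
    vol <- binary_volume(m)
    for (sl in c(TRUE, FALSE)) {
      thr <- if (sl) 4L else 6L
      out <- if (sl) remove_small_2d(vol, thr) else remove_small_3d(vol, thr)
      lab <- flood_label(m, slicewise = sl)
      sizes <- tabulate(lab)
      keep_oracle <- array(lab > 0L & sizes[pmax(lab, 1L)] >= thr, dim(m))
      expect_identical(out$mask, keep_oracle)
      expect_false(any(out$mask & !m))     # never adds voxels
      again <- if (sl) remove_small_2d(out, thr) else remove_small_3d(out, thr)
      expect_identical(again$mask, out$mask)
    }
  }
})

test_that("per-slice closing fills holes, is extensive and idempotent", {
  m <- array(FALSE, c(9L, 9L, 2L))
  m[3:7, 3:7, 1L] <- TRUE
  m[5, 5, 1L] <- FALSE
  out <- close_2d(binary_volume(m))
  expect_true(out$mask[5, 5, 1L])
  expect_true(all(out$mask[m]))
  expect_identical(close_2d(out)$mask, out$mask)
  expect_false(any(out$mask[, , 2L]))
})
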