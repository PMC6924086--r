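test_that("convolve2d matches the direct-summation oracle", {
  set.seed(11)
  img <- matrix(runif(64, 0, 255), 8, 8)
  # identity kernel
  expect_equal(convolve2d(img, matrix(1, 1, 1)), img)
  # impulse response of a true convolution reproduces the kernel over
  # offsets from the impulse site
  k <- matrix(1:9, 3, 3)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- convolve2d(imp, k)
  expect_equal(out[4:6, 4:6], k)
  # random image x random kernels vs quadruple-loop oracle
  for (i in 1:5) {
    k <- matrix(rnorm(9), 3, 3)
    expect_lt(max(abs(convolve2d(img, k) - conv_oracle(img, k))), 1e-9)
  }
  k5 <- matrix(rnorm(15), 5, 3)
  expect_lt(max(abs(convolve2d(img, k5) - conv_oracle(img, k5))), 1e-9)
  expect_error(convolve2d(img, matrix(1, 2, 2)), "odd")
  expect_error(convolve2d(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
})

test_that("edge map vanishes on constants and peaks on a step edge", {
  expect_true(all(edge_map(matrix(7, 10, 10)) == 0))
  # vertical step edge: uniform maximum response along the step columns
  img <- cbind(matrix(0, 12, 6), matrix(100, 12, 6))
  e <- edge_map(img)
  peak_cols <- which(colSums(e) == max(colSums(e)))
  expect_true(all(peak_cols %in% 6:7))
  expect_equal(sd(e[, 6]), 0)
  expect_error(edge_map(matrix(1, 2, 5)), "at least 3x3")
})

test_that("edge map equals the two-kernel brute-force construction", {
  set.seed(21)
  img <- outer(1:16, 1:16, function(a, b) a + 2 * b) + matrix(rnorm(256), 16)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  oracle <- sqrt(conv_oracle(img, sx)^2 + conv_oracle(img, t(sx))^2)
  expect_lt(max(abs(edge_map(img) - oracle)), 1e-9)
})

test_that("band threshold is inclusive at both ends", {
  set.seed(5)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  m <- threshold_band(img, 100, 200)
  expect_equal(sum(m), sum(img >= 100 & img <= 200))
  expect_true(all(threshold_band(img, 0, 255) == 1L))
  # point band selects exactly the matching value
  v <- img[4, 7]
  expect_equal(sum(threshold_band(img, v, v)), sum(img == v))
  expect_error(threshold_band(img, 10, 5), "inverted")
})

test_that("morphology follows the set definitions exactly", {
  set.seed(31)
  m <- random_mask(12, 12)
  # singleton element is the identity for both operations
  origin <- cbind(dx = 0L, dy = 0L)
  expect_equal(unname(erode(m, origin)), m, ignore_attr = TRUE)
  expect_equal(unname(dilate(m, origin)), m, ignore_attr = TRUE)
  # full frame eroded by 3x3 box: interior survives, border goes
  full <- matrix(1L, 8, 8)
  er <- erode(full, se_box(1))
  expect_true(all(er[2:7, 2:7] == 1L))
  expect_true(all(er[1, ] == 0L) && all(er[, 8] == 0L))
  # impulse dilated by B is B translated to the impulse
  imp <- matrix(0L, 9, 9); imp[5, 5] <- 1L
  b <- se_disc(2)
  di <- dilate(imp, b)
  expect_equal(sum(di), nrow(b))
  expect_true(all(di[cbind(5 + b[, "dy"], 5 + b[, "dx"])] == 1L))
  # random masks and elements vs enumeration oracles
  for (i in 1:10) {
    m <- random_mask(sample(6:14, 1), sample(6:14, 1))
    b <- random_se()
    expect_identical(unname(unclass(erode(m, b)))[seq_len(nrow(m)), ],
                     erode_oracle(m, b))
    expect_identical(unname(unclass(dilate(m, b)))[seq_len(nrow(m)), ],
                     dilate_oracle(m, b))
  }
})

test_that("opening removes small detail, is anti-extensive and idempotent", {
  # an isolated pixel vanishes under a 3x3 box opening
  lone <- matrix(0L, 7, 7); lone[4, 4] <- 1L
  expect_true(all(open_mask(lone, se_box(1)) == 0L))
  # a large blob survives
  blob <- matrix(0L, 12, 12); blob[3:10, 3:10] <- 1L
  expect_equal(unname(unclass(open_mask(blob, se_box(1)))), unclass(blob),
               ignore_attr = TRUE)
  set.seed(41)
  for (i in 1:10) {
    m <- random_mask(14, 14)
    b <- random_se()
    op <- open_mask(m, b)
    expect_true(all(op <= m))                       # anti-extensive
    expect_equal(unname(open_mask(op, b)), unname(op), ignore_attr = TRUE)
  }
})

test_that("erosion-dilation duality holds under complement and reflection", {
  set.seed(51)
  for (i in 1:8) {
    m <- random_mask(10, 10)
    b <- random_se()
    b_ref <- b; b_ref[, 1:2] <- -b_ref[, 1:2]
    # pad so that frame effects (outside = 0) cancel in the comparison
    pad <- matrix(0L, 16, 16); pad[4:13, 4:13] <- m
    lhs <- erode(pad, b)
    rhs <- 1L - dilate(1L - pad, b_ref)
    expect_identical(unname(unclass(lhs))[4:13, 4:13],
                     unname(unclass(rhs))[4:13, 4:13])
  }
})

test_that("centroid search averages member pixels and orders components", {
  m <- matrix(0L, 40, 60)
  m[11:21, 31:41] <- 1L  # rows 10-20, cols 30-40 (0-based)
  out <- find_centers(m, 20)
  expect_equal(out$x, 35)
  expect_equal(out$y, 15)
  expect_equal(out$pixel_count, 121L)
  # empty mask
  expect_equal(nrow(find_centers(matrix(0L, 5, 5))), 0L)
  # ordering: descending size, ties by (y, x)
  m2 <- matrix(0L, 30, 30)
  m2[2:4, 2:4] <- 1L        # 9 px at (2,2)
  m2[20:24, 20:24] <- 1L    # 25 px
  m2[2:4, 12:14] <- 1L      # 9 px at (12,2)
  out2 <- find_centers(m2, 1)
  expect_equal(out2$pixel_count, c(25L, 9L, 9L))
  expect_equal(out2$x[2:3], c(2, 12))
  # centers of generated discs recovered from the scene mask
  sc <- gen_disc_scene(64, rbind(c(20, 20), c(50, 44)), 6,
                       fg = 255, bg = 0, noise_sd = 0)
  det <- find_centers(threshold_band(sc$image, 128, 255), 20)
  for (i in 1:2) {
    derr <- sqrt((det$x - sc$centers[i, 1])^2 + (det$y - sc$centers[i, 2])^2)
    expect_lt(min(derr), 0.3)
  }
})

test_that("integer translation of a mask translates centroids exactly", {
  set.seed(61)
  m <- matrix(0L, 30, 30)
  m[5:12, 7:15] <- 1L
  m[20:26, 18:27] <- random_mask(7, 10, p = 0.8)
  base <- find_centers(m, 5)
  shifted <- matrix(0L, 30, 30)
  shifted[4:30, ] <- m[1:27, ]   # dy = +3
  sh <- find_centers(shifted, 5)
  expect_equal(sh$x, base$x)
  expect_equal(sh$y, base$y + 3)
})

test_that("the disc pipeline recovers known centers and is shift-equivariant", {
  set.seed(71)
  ctr <- random_centers(3, 96, 6)
  sc <- gen_disc_scene(96, ctr, 6, fg = 200, bg = 60, noise_sd = 5, seed = 7)
  det <- detect_discs(sc$image)
  expect_equal(nrow(det), 3L)
  for (i in 1:3) {
    derr <- sqrt((det$x - ctr[i, 1])^2 + (det$y - ctr[i, 2])^2)
    expect_lt(min(derr), 0.5)
  }
  # blank image: nothing found
  expect_equal(nrow(detect_discs(matrix(60, 64, 64))), 0L)
  # translation equivariance of the whole pipeline
  ctr2 <- ctr + matrix(c(5, -3), 3, 2, byrow = TRUE)
  sc2 <- gen_disc_scene(96, ctr2, 6, fg = 200, bg = 60, noise_sd = 5, seed = 7)
  det2 <- detect_discs(sc2$image)
  expect_equal(nrow(det2), 3L)
  for (i in 1:3) {
    d1 <- det[which.min((det$x - ctr[i, 1])^2 + (det$y - ctr[i, 2])^2), ]
    d2 <- det2[which.min((det2$x - ctr2[i, 1])^2 + (det2$y - ctr2[i, 2])^2), ]
    expect_lt(abs(d2$x - d1$x - 5), 0.2)
    expect_lt(abs(d2$y - d1$y + 3), 0.2)
  }
})

test_that("track assembly links detections and respects gaps", {
  # one disc drifting rightward
  frames <- lapply(0:5, function(t) data.frame(x = 10 + 2 * t, y = 20))
  tr <- assemble_tracks(frames)
  expect_equal(unique(tr$disc_id), 1L)
  expect_equal(nrow(tr), 6L)
  # two well-separated discs stay two clean tracks
  frames2 <- lapply(0:4, function(t)
    data.frame(x = c(10 + t, 60 - t), y = c(10, 50)))
  tr2 <- assemble_tracks(frames2)
  expect_equal(length(unique(tr2$disc_id)), 2L)
  expect_true(all(table(tr2$disc_id) == 5L))
  # a missing detection leaves a gap, not a merge
  frames3 <- list(data.frame(x = c(10, 60), y = c(10, 50)),
                  data.frame(x = 60.5, y = 50.2),
                  data.frame(x = c(11, 61), y = c(10.5, 50.4)))
  tr3 <- assemble_tracks(frames3)
  expect_equal(length(unique(tr3$disc_id)), 2L)
  t1 <- tr3[tr3$x < 30, ]
  expect_equal(t1$frame, c(1L, 3L))  # gap at frame 2
  # far jumps open new tracks instead of teleporting one
  frames4 <- list(data.frame(x = 10, y = 10), data.frame(x = 90, y = 90))
  tr4 <- assemble_tracks(frames4, max_jump = 15)
  expect_equal(length(unique(tr4$disc_id)), 2L)
})
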