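# Colour / motion / shape / size-change descriptors.

test_that("region partition sizes match brute-force pixel counts", {
  mask <- matrix(FALSE, 4, 4)
  mask[cbind(c(1, 1, 2, 2, 3, 3, 4), c(1, 2, 1, 2, 3, 4, 4))] <- TRUE
  part <- partition_regions(c(10, 10), c(2, 2, 6, 6), mask)
  expect_equal(unname(region_sizes(part)), c(7, 9, 84))

  # brute-force recount over the full frame
  hand_full <- matrix(FALSE, 10, 10); hand_full[3:6, 3:6] <- mask
  inbox <- matrix(FALSE, 10, 10); inbox[3:6, 3:6] <- TRUE
  expect_equal(unname(region_sizes(part)),
               c(sum(hand_full), sum(inbox & !hand_full), sum(!inbox)))

  full <- partition_regions(c(10, 10), c(0, 0, 10, 10), matrix(TRUE, 10, 10))
  expect_equal(unname(region_sizes(full)["background"]), 0)
  expect_equal(unname(region_sizes(full)["nonhand"]), 0)
  expect_error(partition_regions(c(10, 10), c(2, 2, 2, 6), mask), "bbox")
  empty <- partition_regions(c(10, 10), c(2, 2, 6, 6), matrix(FALSE, 4, 4))
  expect_true(empty$empty_hand)
})

test_that("uniform frames give an all-zero colour block", {
  fr <- uniform_frame(40, 60)
  mask <- matrix(c(TRUE, FALSE), 10, 10)   # all three regions non-empty
  part <- partition_regions(c(40, 60), c(5, 5, 15, 15), mask)
  cb <- hsv_histogram_diff(fr, part)
  expect_length(cb, 144)
  expect_true(all(cb == 0))
})

test_that("two-colour frames put exactly +1/-1 in the differing bins", {
  cfg <- feature_config()
  rgb_a <- as.numeric(grDevices::col2rgb(grDevices::hsv(0.10, 0.30, 0.90))) / 255
  rgb_b <- as.numeric(grDevices::col2rgb(grDevices::hsv(0.60, 0.80, 0.40))) / 255
  bbox <- c(10, 10, 20, 20)
  fr <- two_colour_frame(40, 60, bbox, rgb_a, rgb_b)
  part <- partition_regions(c(40, 60), bbox, matrix(TRUE, 10, 10))
  cb <- hsv_histogram_diff(fr, part, cfg)
  # layout: pairs (hand-nonhand, hand-background, nonhand-background) x
  # channels (H, S, V) x 16 bins; the hand-background block is entries 49..96
  hb <- cb[49:96]
  for (ch in 0:2) {
    seg <- hb[(ch * 16 + 1):(ch * 16 + 16)]
    expect_equal(sum(seg == 1), 1)
    expect_equal(sum(seg == -1), 1)
    expect_equal(sum(seg != 0), 2)
    expect_equal(sum(seg), 0)
  }
  # hand-nonhand block: non-hand region is empty -> zero histogram, so the
  # difference equals the hand histogram
  hn <- cb[1:48]
  expect_equal(sum(hn == 1), 3)
})

test_that("colour features are invariant to pixel positions within regions", {
  set.seed(8)
  fr <- array(stats::runif(30 * 40 * 3), c(30, 40, 3))
  bbox <- c(8, 6, 24, 22)
  mask <- matrix(stats::runif(16 * 16) < 0.5, 16, 16)
  part <- partition_regions(c(30, 40), bbox, mask)
  cb1 <- hsv_histogram_diff(fr, part)

  # permute pixels inside each region
  fr2 <- fr
  rows <- 7:22; cols <- 9:24
  idx_hand <- which(mask)
  perm <- sample(idx_hand)
  for (ch in 1:3) {
    sub <- fr2[rows, cols, ch]
    sub[idx_hand] <- sub[perm]
    fr2[rows, cols, ch] <- sub
  }
  cb2 <- hsv_histogram_diff(fr2, part)
  expect_equal(cb2, cb1, tolerance = 1e-12)
})

test_that("colour and motion histogram differences are bounded and balanced", {
  task <- tiny_task()
  fe <- extract_task_features(task)
  ok <- !apply(fe$X, 1, function(r) any(is.na(r)))
  cfg <- feature_config()
  hist_cols <- seq_len(cfg$len_colour + cfg$len_motion)
  vals <- fe$X[ok, hist_cols, drop = FALSE]
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
  # each 16-bin difference block sums to ~0 (difference of two simplex vectors)
  for (blk in seq_len((cfg$len_colour + cfg$len_motion) / 16)) {
    seg <- vals[, ((blk - 1) * 16 + 1):(blk * 16), drop = FALSE]
    expect_true(all(abs(rowSums(seg)) < 1e-9))
  }
})

test_that("zero motion concentrates magnitude mass in the lowest bin", {
  fr <- array(stats::runif(40 * 60 * 3), c(40, 60, 3))
  part <- partition_regions(c(40, 60), c(10, 10, 26, 26), matrix(c(TRUE, FALSE), 16, 16))
  flow <- list(u = matrix(0, 40, 60), v = matrix(0, 40, 60))
  h <- flow_region_histograms(flow, part)
  for (reg in h) expect_equal(reg$mag[1], 1)
  mb <- flow_histograms(fr, fr, part)
  expect_length(mb, 96)
  expect_true(all(abs(mb) < 1e-12))
})

test_that("uniform global translation leaves pairwise flow differences small", {
  set.seed(3)
  big <- matrix(stats::runif(220 * 340), 220, 340)
  I0 <- big[11:190, 11:330]
  I1 <- big[13:192, 11:330]   # content shifts -2 rows
  flow <- dense_flow(I0, I1)
  fr0 <- array(rep(I0, 3), c(180, 320, 3))
  part <- partition_regions(c(180, 320), c(100, 60, 160, 120), matrix(TRUE, 60, 60))
  mb <- flow_histograms(fr0, fr0, part, flow = flow)
  # hand-background block is entries 33..64; mass differences stay small
  expect_lt(max(abs(mb[33:64])), 0.2)
})

test_that("a horizontally moving hand dominates the rightward direction bin", {
  set.seed(4)
  H <- 120; W <- 160
  smooth_noise <- function(h, w, coarse = 10) {
    egohand:::resize_bilinear(matrix(stats::runif(coarse * coarse), coarse, coarse), h, w)
  }
  bg <- smooth_noise(H, W, 24)
  patch <- smooth_noise(30, 30, 8)
  put <- function(bg, patch, r0, c0) {
    bg[r0:(r0 + 29), c0:(c0 + 29)] <- patch
    bg
  }
  I0 <- put(bg, patch, 46, 61)
  I1 <- put(bg, patch, 46, 66)   # +5 px in x
  flow <- dense_flow(I0, I1)
  part <- partition_regions(c(H, W), c(60, 45, 90, 75), matrix(TRUE, 30, 30))
  h <- flow_region_histograms(flow, part)
  # hand-region direction mass concentrates in the bins containing angle 0
  expect_gt(h$hand$dir[1] + h$hand$dir[16], 0.5)
  expect_equal(which.max(h$hand$dir) %in% c(1L, 16L), TRUE)
  # and magnitude mass sits clearly above the near-zero bins (> 1 px/frame)
  expect_gt(sum(h$hand$mag[3:16]), 0.5)
})

test_that("HOG has fixed length, zero response to uniform crops, and edge response", {
  cfg <- feature_config()
  fr <- uniform_frame(80, 80)
  d <- hog_descriptor(fr, c(10, 10, 50, 50), cfg)
  expect_length(d, 1764)
  expect_true(all(d == 0))

  # vertical step edge: gradient is horizontal -> orientation bin 1
  fr2 <- uniform_frame(80, 80, c(0.1, 0.1, 0.1))
  fr2[, 41:80, ] <- 0.9
  d2 <- hog_descriptor(fr2, c(20, 20, 60, 60), cfg)
  expect_length(d2, 1764)
  expect_true(all(is.finite(d2)))
  by_bin <- sapply(1:9, function(b) sum(d2[seq(b, 1764, by = 9)]))
  expect_equal(which.max(by_bin), 1L)

  expect_error(hog_descriptor(fr, c(10, 10, 10, 50)), "bbox")
})

test_that("hand size change follows the stated arithmetic and padding", {
  cfg <- feature_config()
  expect_equal(hand_size_change(rep(100, 11), 400, cfg), rep(0, 10))
  expect_equal(hand_size_change(seq(100, 300, by = 20), 400, cfg), rep(0.05, 10))
  # hand disappears after 4 frames: 3 real differences then zeros
  sc <- hand_size_change(c(100, 110, 130, 120), 400, cfg)
  expect_equal(sc, c(10, 20, -10, rep(0, 7)) / 400)
  expect_error(hand_size_change(numeric(0), 400, cfg), "areas")
  expect_error(hand_size_change(c(1, 2), 0, cfg), "box_area")
})

test_that("feature vectors have the documented lengths per variant", {
  cfg <- feature_config()
  expect_equal(feature_length(cfg, "interaction"), 144 + 96 + 1764)
  expect_equal(feature_length(cfg, "role"), 144 + 96 + 1764 + 10)
  task <- tiny_task()
  ob <- task$observations[[1]]
  v_int <- build_feature_vector(task, ob$frame, ob$side, "interaction", cfg)
  v_role <- build_feature_vector(task, ob$frame, ob$side, "role", cfg)
  expect_length(v_int, feature_length(cfg, "interaction"))
  expect_length(v_role, feature_length(cfg, "role"))
  expect_equal(v_role[seq_along(v_int)], v_int)
  expect_true(all(is.finite(v_int)))
})

test_that("absent hands return the no-box marker", {
  task <- tiny_task()
  expect_false(is_no_box(build_feature_vector(task, 0L, "left", "interaction")))
  task$observations[["0_left"]] <- NULL
  v <- build_feature_vector(task, 0L, "left", "interaction")
  expect_true(is_no_box(v))
  expect_equal(v$frame_index, 0L)
})

test_that("batch extraction agrees with single-instance extraction", {
  task <- tiny_task()
  fe <- extract_task_features(task)
  meta <- fe$meta
  pick <- which(!meta$no_box)[c(1, 7)]
  for (k in pick) {
    v <- build_feature_vector(task, meta$frame_index[k], meta$hand_side[k], "role")
    expect_equal(unname(fe$X[k, ]), unname(v), tolerance = 1e-12)
  }
  # no NaN/Inf anywhere among boxed rows
  boxed <- fe$X[!meta$no_box, , drop = FALSE]
  expect_true(all(is.finite(boxed)))
  # no-box rows are flagged and NA
  if (any(meta$no_box)) {
    expect_true(all(is.na(fe$X[meta$no_box, 1])))
  }
})

test_that("feature tables round-trip through CSV", {
  task <- tiny_task()
  fe <- extract_task_features(task)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fe, path)
  back <- read_feature_csv(path)
  expect_equal(back$meta$frame_index, fe$meta$frame_index)
  expect_equal(unname(back$X), unname(fe$X), tolerance = 1e-12)
})
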