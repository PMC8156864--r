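test_that("temporal median background follows order statistics", {
  f <- matrix(7, 4, 4)
  expect_equal(build_background(list(f, f, f)), f)
  fs <- list(matrix(1, 2, 2), matrix(2, 2, 2), matrix(9, 2, 2))
  expect_equal(build_background(fs), matrix(2, 2, 2))
  # even n: lower of the two central values
  fs <- list(matrix(1, 1, 1), matrix(4, 1, 1), matrix(9, 1, 1),
             matrix(2, 1, 1))
  expect_equal(build_background(fs)[1, 1], 2)
  expect_error(build_background(list()), "empty")
})

test_that("a briefly-covered pixel recovers the true background", {
  # dark block passes over each pixel in fewer than half the frames
  frames <- lapply(1:12, function(t) {
    f <- matrix(255, 8, 20)
    f[3:5, t:(t + 2)] <- 0
    f
  })
  bg <- build_background(frames, 12)
  expect_true(all(bg == 255))
})

test_that("segmentation extracts size-filtered 8-connected blobs", {
  bg <- matrix(200, 30, 30)
  expect_length(segment_blobs(bg, bg, 25, 4, 100), 0)
  fr <- bg
  fr[5:10, 5:12] <- 30          # 48 px blob
  fr[20, 20] <- 30              # 1 px speck, filtered
  blobs <- segment_blobs(fr, bg, 25, 4, 100, t = 3L)
  expect_length(blobs, 1)
  expect_equal(blobs[[1]]$t, 3L)
  expect_equal(unname(blobs[[1]]$box), c(4, 4, 8, 6))
  expect_equal(nrow(blobs[[1]]$pixels), 48)
  expect_equal(dim(blobs[[1]]$patch), c(6, 8))
})

test_that("diagonally-touching components merge (8-connectivity)", {
  bg <- matrix(200, 10, 10)
  fr <- bg
  fr[2:3, 2:3] <- 0
  fr[4:5, 4:5] <- 0 # touches only diagonally
  blobs <- segment_blobs(fr, bg, 25, 2, 100)
  expect_length(blobs, 1)
  expect_equal(nrow(blobs[[1]]$pixels), 8)
})

test_that("labeling matches a brute-force flood fill on random masks", {
  set.seed(5)
  for (rep in 1:10) {
    mask <- matrix(runif(32 * 32) < 0.35, 32, 32)
    lab <- schooltrack:::label_components8(mask)
    ref <- flood_fill_labels(mask)
    expect_equal(max(lab), max(ref))
    # identical partitions up to label naming
    key <- paste(lab[mask], ref[mask])
    expect_equal(length(unique(key)), max(ref))
  }
})

test_that("raising the threshold never increases foreground", {
  set.seed(9)
  bg <- matrix(200, 20, 20)
  fr <- bg - matrix(sample(0:80, 400, TRUE), 20, 20)
  counts <- vapply(c(10, 25, 40, 60), function(th)
    sum(abs(bg - fr) > th), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("blob pixel sets are disjoint and inside their boxes", {
  sim <- simulate_school(school_config(n_fish = 3, n_frames = 1,
                                       arena = c(300, 240), seed = 4))
  blobs <- segment_blobs(sim$frames[[1]], matrix(230, 240, 300),
                         25, 100, 5000)
  expect_length(blobs, 3)
  all_pix <- do.call(rbind, lapply(blobs, `[[`, "pixels"))
  expect_equal(nrow(all_pix), nrow(unique(all_pix)))
  for (b in blobs) {
    expect_true(all(b$pixels[, "x"] >= b$box[["x"]] &
                    b$pixels[, "x"] < b$box[["x"]] + b$box[["w"]]))
    expect_true(all(b$pixels[, "y"] >= b$box[["y"]] &
                    b$pixels[, "y"] < b$box[["y"]] + b$box[["h"]]))
  }
})
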