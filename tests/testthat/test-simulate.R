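test_that("a single-fish simulation has the promised shape", {
  sim <- simulate_school(school_config(n_fish = 1, n_frames = 10, seed = 1))
  expect_length(sim$frames, 10)
  expect_equal(nrow(sim$truth), 10)
  expect_true(all(!sim$truth$occluded))
  for (f in sim$frames) {
    blobs <- segment_blobs(f, matrix(230, nrow(f), ncol(f)), 25, 100, 5000)
    expect_length(blobs, 1)
  }
})

test_that("identical seed and config reproduce bit-identical output", {
  cfg <- school_config(n_fish = 3, n_frames = 5, seed = 77)
  a <- simulate_school(cfg)
  b <- simulate_school(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
})

test_that("a scripted crossing produces occlusion inside its window", {
  cfg <- school_config(n_fish = 2, n_frames = 70, arena = c(360, 280),
                       seed = 2,
                       crossing_script = list(list(fish = c(1, 2),
                                                   frames = c(30, 50))))
  sim <- simulate_school(cfg)
  occ <- sim$truth[sim$truth$occluded, ]
  expect_gt(nrow(occ), 0)
  expect_true(any(occ$frame >= 30 & occ$frame <= 50))
  # the flag is symmetric: both fish are marked on the same frames
  tab <- table(occ$frame)
  expect_true(all(tab == 2))
})

test_that("the renderer obeys its geometric contracts", {
  canvas <- matrix(230, 120, 160)
  pose <- list(x = 80, y = 60, heading = 0, bend = 0, length = 70, width = 12)
  r <- render_fish(pose, canvas)
  img <- r$canvas
  # straight horizontal fish: mask symmetric about the heading axis
  mask <- matrix(FALSE, 120, 160)
  mask[r$mask] <- TRUE
  expect_equal(mask[61 + 1:20, ], mask[61 - 1:20, ])
  # straight centerline is collinear
  pts <- schooltrack:::fish_centerline(80, 60, 0, 0, 70)
  expect_equal(max(abs(pts[, 2] - 60)), 0, tolerance = 1e-12)
  # darkest rendered pixel near the truth head is the head level
  hp <- schooltrack:::fish_head_point(80, 60, 0, 70, 12)
  nb <- img[round(hp[2]) + 1 + (-3:3), round(hp[1]) + 1 + (-3:3)]
  expect_equal(min(nb), 20, tolerance = 1)
})

test_that("overlapping fish take the darker pixel", {
  canvas <- matrix(230, 100, 150)
  p1 <- list(x = 70, y = 50, heading = 0, bend = 0, length = 70, width = 12)
  p2 <- list(x = 80, y = 50, heading = pi / 3, bend = 0, length = 70, width = 12)
  r1 <- render_fish(p1, canvas)
  solo1 <- r1$canvas
  solo2 <- render_fish(p2, canvas)$canvas
  both <- render_fish(p2, solo1)$canvas
  expect_equal(both, pmin(solo1, solo2))
})

test_that("occluded flags agree with direct mask intersection", {
  cfg <- school_config(n_fish = 2, n_frames = 40, arena = c(300, 240),
                       seed = 9,
                       crossing_script = list(list(fish = c(1, 2),
                                                   frames = c(10, 30))))
  sim <- simulate_school(cfg)
  for (t in seq(2, 40, by = 2)) {
    tr <- sim$truth[sim$truth$frame == t, ]
    canvas <- matrix(230, 240, 300)
    masks <- lapply(1:2, function(i) {
      heading <- atan2(tr$head_y[i] - tr$body_y[i], tr$head_x[i] - tr$body_x[i])
      render_fish(list(x = tr$body_x[i], y = tr$body_y[i], heading = heading,
                       bend = tr$bend[i], length = 70, width = 12),
                  canvas)$mask
    })
    overlap <- length(intersect(masks[[1]], masks[[2]])) > 0
    expect_equal(tr$occluded, rep(overlap, 2))
  }
})

test_that("ground truth round-trips through CSV", {
  sim <- simulate_school(school_config(n_fish = 3, n_frames = 5, seed = 12))
  path <- tempfile(fileext = ".csv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back, sim$truth, tolerance = 0)
  expect_equal(nrow(back), 15)
  # empty truth writes a header-only file
  write_truth(sim$truth[0, ], path)
  expect_equal(nrow(read_truth(path)), 0)
  expect_equal(length(readLines(path)), 1)
})

test_that("an overcrowded arena refuses placement", {
  expect_error(simulate_school(school_config(n_fish = 40,
                                             arena = c(200, 160), seed = 1)),
               "arena too small")
})
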