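test_that("iou matches hand-computed values", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou(c(0, 0, 0, 0), c(0, 0, 2, 2)), 0) # degenerate
})

test_that("box inflation is linear in the motion state", {
  b0 <- box_from_state(c(5, 5), c(4, 4), 0, 1)
  expect_equal(b0, c(3, 3, 7, 7))
  b1 <- box_from_state(c(5, 5), c(4, 4), 180, 1)
  expect_equal(b1[3] - b1[1], 8)
  sides <- vapply(c(0, 30, 60, 120, 180), function(w) {
    b <- box_from_state(c(0, 0), c(10, 10), w, 1.5)
    b[3] - b[1]
  }, 0)
  expect_true(all(diff(sides) > 0))
  expect_error(box_from_state(c(0, 0), c(4, 4), -1), "omega")
})

test_that("cost matrix is 1 - IOU with degenerate shapes allowed", {
  b <- c(0, 0, 2, 2)
  expect_equal(build_cost_matrix(list(b), list(b))[1, 1], 0)
  C <- build_cost_matrix(list(c(0, 0, 1, 1)), list(c(5, 5, 6, 6)))
  expect_equal(C[1, 1], 1)
  expect_equal(dim(build_cost_matrix(list(), list(b))), c(0L, 1L))
})

test_that("Kalman filter converges on a noiseless constant-velocity target", {
  kf <- kf_create(c(0, 0), process_noise = 3, measurement_noise = 1)
  # stationary: prediction leaves position unchanged
  expect_equal(kf_predict(kf)$x[1:2], c(0, 0))
  v <- c(2.5, -1.25)
  errs <- numeric(0)
  for (t in 1:60) {
    kf <- kf_predict(kf)
    z <- v * t
    errs <- c(errs, sqrt(sum((kf$x[1:2] - z)^2)))
    kf <- kf_update(kf, z)
  }
  expect_lt(sqrt(sum((kf$x[3:4] - v)^2)) / sqrt(sum(v^2)), 0.01)
  expect_lt(mean(errs[40:60]), mean(errs[3:10]))
})

test_that("cold start spawns temporary tracks only", {
  cfg <- pipeline_config()
  st <- tracker_create(cfg, matrix(230, 50, 50))
  dets <- list(
    heads = data.frame(t = 1, x0 = c(1, 11, 21, 31, 41), y0 = 1,
                       x1 = c(5, 15, 25, 35, 45), y1 = 5, area = 9),
    bodies = data.frame(t = integer(), rx = numeric(), ry = numeric(),
                        omega = numeric(), n_lines = integer()))
  rec <- tracker_step(st, matrix(230, 50, 50), detections = dets)
  expect_equal(nrow(rec), 0)
  expect_length(st$heads, 0)
  expect_length(st$head_temp, 5)
})

test_that("a persistent detection is promoted after min_hits frames", {
  cfg <- pipeline_config()
  st <- tracker_create(cfg, matrix(230, 50, 50))
  mk <- function(x) list(
    heads = data.frame(t = 1, x0 = x, y0 = 20, x1 = x + 6, y1 = 26, area = 20),
    bodies = data.frame(t = integer(), rx = numeric(), ry = numeric(),
                        omega = numeric(), n_lines = integer()))
  recs <- lapply(1:5, function(t)
    tracker_step(st, matrix(230, 50, 50), detections = mk(10 + 3 * t)))
  expect_equal(vapply(recs, nrow, 0L), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(recs[[3]]$id, 1L)
  # disappearing for max_age + 1 frames retires the identity
  none <- list(heads = mk(0)$heads[0, ], bodies = mk(0)$bodies)
  for (k in 1:(cfg$tracker$max_age + 1)) tracker_step(st, matrix(230, 50, 50),
                                                      detections = none)
  expect_length(st$heads, 0)
  expect_equal(st$lost$id, 1L)
})

test_that("confirmed identities stay pairwise distinct", {
  sim <- simulate_school(school_config(n_fish = 4, n_frames = 60, seed = 21))
  bg <- build_background(sim$frames, 50)
  st <- tracker_create(pipeline_config(), bg)
  for (t in seq_along(sim$frames)) {
    tracker_step(st, sim$frames[[t]])
    ids <- vapply(st$heads, function(x) x$id, 0L)
    expect_equal(anyDuplicated(ids), 0)
  }
})
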