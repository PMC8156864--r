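test_that("precision/recall/rates follow their formulas", {
  pr <- precision_recall(197, 3, 1)
  expect_equal(pr[["precision"]], 98.5)
  expect_equal(pr[["recall"]], 100 * 197 / 198)
  expect_equal(unname(precision_recall(10, 0, 0)), c(100, 100))
  expect_true(is.na(precision_recall(0, 0, 5)[["precision"]]))

  expect_equal(occlusion_rate(95, 5, 240), 7.916667, tolerance = 1e-6)
  expect_equal(round(occlusion_rate(546, 20, 200), 2), 13.65)
  expect_equal(occlusion_rate(0, 10, 100), 0)
  expect_error(occlusion_rate(1, 0, 10), "denominator")

  expect_equal(detection_rate_from_occlusions(93, 100), 93)
  expect_equal(detection_rate_from_occlusions(7, 7), 100)
  expect_equal(detection_rate_from_occlusions(0, 5), 0)
  expect_true(is.na(detection_rate_from_occlusions(0, 0)))

  expect_equal(ctr(c(10, 9, 8), 3, 10), 90)
  expect_equal(ctr(rep(20, 4), 4, 20), 100)
  expect_equal(ctr(rep(0, 4), 4, 20), 0)
  expect_error(ctr(c(1, 2), 3, 10), "per individual")

  expect_equal(cir(95, 95), 100)
  expect_equal(round(cir(43, 44), 1), 97.7)
  expect_equal(cir(0, 1), 0)
  expect_true(is.na(cir(3, 0)))
})

make_truth <- function(n_fish, n_frames, occluded_frames = integer()) {
  g <- expand.grid(id = seq_len(n_fish), frame = seq_len(n_frames))
  data.frame(frame = g$frame, id = g$id,
             head_x = 100 * g$id + g$frame, head_y = 50 * g$id,
             body_x = 100 * g$id + g$frame - 20, body_y = 50 * g$id,
             bend = 0, occluded = g$frame %in% occluded_frames)
}

test_that("a perfect prediction scores perfectly", {
  tr <- make_truth(3, 10, occluded_frames = 5:6)
  pred <- data.frame(frame = tr$frame, id = tr$id + 10,
                     head_x = tr$head_x, head_y = tr$head_y,
                     body_x = NA, body_y = NA, omega = 0,
                     provenance = "head_tracked")
  rep <- evaluate_tracking(pred, tr, dist_max = 20)
  expect_equal(rep$ctr, 100)
  expect_equal(rep$cir, 100)
  expect_equal(rep$ids, 0)
  expect_equal(unname(rep$counts), c(30L, 0L, 0L))
})

test_that("a permanent swap after the crossing fails CIR and counts IDS", {
  tr <- make_truth(2, 10, occluded_frames = 5)
  pred <- data.frame(frame = tr$frame, id = tr$id,
                     head_x = tr$head_x, head_y = tr$head_y)
  swap <- pred$frame > 5
  pred$id[swap] <- 3L - pred$id[swap] # 1 <-> 2 after the event
  m <- match_pred_to_truth(pred, tr, dist_max = 20)
  expect_equal(sum(m$events$identities_kept, na.rm = TRUE), 0)
  expect_equal(count_id_switches(m$correspondence), 2)
  # a swap that swaps back costs four switches
  pred2 <- data.frame(frame = tr$frame, id = tr$id,
                      head_x = tr$head_x, head_y = tr$head_y)
  mid <- pred2$frame %in% 6:7
  pred2$id[mid] <- 3L - pred2$id[mid]
  m2 <- match_pred_to_truth(pred2, tr, dist_max = 20)
  expect_equal(count_id_switches(m2$correspondence), 4)
})

test_that("a missing fish appears as false negatives in CTR", {
  tr <- make_truth(5, 100)
  pred <- data.frame(frame = tr$frame, id = tr$id,
                     head_x = tr$head_x, head_y = tr$head_y)
  pred <- pred[pred$id != 5, ]
  m <- match_pred_to_truth(pred, tr, dist_max = 20)
  expect_equal(unname(m$counts[["fn"]]), 100)
  expect_equal(ctr(m$per_target, m$n_individuals, m$n_frames), 80)
})

test_that("counts are conserved and metrics ignore label values", {
  tr <- make_truth(3, 20, occluded_frames = 9:10)
  set.seed(2)
  pred <- data.frame(frame = tr$frame, id = tr$id,
                     head_x = tr$head_x + rnorm(60), head_y = tr$head_y)
  m <- match_pred_to_truth(pred, tr, dist_max = 20)
  expect_equal(unname(m$counts[["tp"]] + m$counts[["fn"]]), nrow(tr))
  expect_equal(unname(m$counts[["tp"]] + m$counts[["fp"]]), nrow(pred))
  relab <- pred
  relab$id <- relab$id * 7 + 100
  m2 <- match_pred_to_truth(relab, tr, dist_max = 20)
  expect_equal(m2$per_target, m$per_target)
  expect_equal(m2$events$identities_kept, m$events$identities_kept)
})
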