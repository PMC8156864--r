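test_that("assignment solves the textbook 2x2 case", {
  C <- rbind(c(0.2, 0.9), c(0.8, 0.1))
  a <- assign(C, iou_min = 0)
  expect_equal(a$matches, cbind(row = c(1L, 2L), col = c(1L, 2L)))
  expect_equal(a$delta, 0.3)
})

test_that("assignment cost equals the exhaustive minimum on random matrices", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    C <- matrix(runif(n * m), n, m)
    sol <- solve_assignment(C)
    expect_equal(sol$cost, brute_force_assignment(C), tolerance = 1e-12)
    expect_equal(nrow(sol$matches), min(n, m))
  }
})

test_that("empty and degenerate shapes are handled", {
  expect_equal(nrow(solve_assignment(matrix(numeric(), 0, 3))$matches), 0)
  a <- assign(matrix(numeric(), 0, 0))
  expect_equal(nrow(a$matches), 0)
  expect_equal(a$delta, 0)
})

test_that("the IOU gate cancels weak matches on both sides", {
  a <- assign(matrix(1.0, 1, 1), iou_min = 0.3)
  expect_equal(nrow(a$matches), 0)
  expect_equal(a$unmatched_trks, 1L)
  expect_equal(a$unmatched_dets, 1L)
})
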