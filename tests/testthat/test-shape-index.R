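test_that("Gaussian derivative responses are exact on polynomial images", {
  img <- outer(1:48, 1:48, function(y, x) 0 * x)
  h <- hessian_response(img + 7, 2)
  expect_equal(max(abs(h$Lxx)), 0, tolerance = 1e-10)
  expect_equal(max(abs(h$Lxy)), 0, tolerance = 1e-10)
  expect_equal(max(abs(h$Lyy)), 0, tolerance = 1e-10)

  img <- outer(1:48, 1:48, function(y, x) x^2)
  h <- hessian_response(img, 2)
  expect_equal(h$Lxx[24, 24], 2, tolerance = 1e-8)
  expect_equal(h$Lyy[24, 24], 0, tolerance = 1e-8)
  expect_equal(h$Lxy[24, 24], 0, tolerance = 1e-8)

  img <- outer(1:48, 1:48, function(y, x) x * y)
  h <- hessian_response(img, 2)
  expect_equal(h$Lxy[24, 24], 1, tolerance = 1e-8)
  expect_equal(h$Lxx[24, 24], 0, tolerance = 1e-8)
})

test_that("Hessian eigenvalues match the closed form and are ordered", {
  ev <- hessian_eigenvalues(list(Lxx = matrix(2), Lyy = matrix(0),
                                 Lxy = matrix(0)))
  expect_equal(c(ev$K1, ev$K2), c(2, 0))
  ev <- hessian_eigenvalues(list(Lxx = matrix(0), Lyy = matrix(0),
                                 Lxy = matrix(1)))
  expect_equal(c(ev$K1, ev$K2), c(1, -1))
  ev <- hessian_eigenvalues(list(Lxx = matrix(-3), Lyy = matrix(-1),
                                 Lxy = matrix(0)))
  expect_equal(c(ev$K1, ev$K2), c(-1, -3))
  # K1 >= K2 on random fields
  set.seed(1)
  f <- list(Lxx = matrix(rnorm(100), 10), Lyy = matrix(rnorm(100), 10),
            Lxy = matrix(rnorm(100), 10))
  ev <- hessian_eigenvalues(f)
  expect_true(all(ev$K1 >= ev$K2))
})

test_that("shape index closed-form cases hold", {
  c0 <- 3.7
  expect_equal(shape_index(matrix(0), matrix(-c0))[1, 1], 1 / 2,
               tolerance = 1e-12)
  expect_equal(shape_index(matrix(c0), matrix(0))[1, 1], -1 / 2,
               tolerance = 1e-12)
  expect_equal(shape_index(matrix(c0), matrix(-c0))[1, 1], 0,
               tolerance = 1e-12)
  expect_equal(shape_index(matrix(c0), matrix(c0))[1, 1], -1)
  expect_equal(shape_index(matrix(-c0), matrix(-c0))[1, 1], 1)
  expect_true(is.na(shape_index(matrix(0), matrix(0))[1, 1]))
})

test_that("category table partitions [-1,1] with left-closed intervals", {
  expect_equal(as.character(classify_shape_category(-1)), "spherical cup")
  expect_equal(as.character(classify_shape_category(-7 / 8)), "trough")
  expect_equal(as.character(classify_shape_category(-1 / 2)), "rut")
  expect_equal(as.character(classify_shape_category(1 / 2)), "ridge")
  expect_equal(as.character(classify_shape_category(1)), "spherical cap")
  expect_error(classify_shape_category(1.5), "lie in")
})

test_that("trace/determinant conservation and sign antisymmetry hold", {
  set.seed(7)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  h <- hessian_response(img, 3)
  ev <- hessian_eigenvalues(h)
  expect_equal(ev$K1 + ev$K2, h$Lxx + h$Lyy, tolerance = 1e-9)
  expect_equal(ev$K1 * ev$K2, h$Lxx * h$Lyy - h$Lxy^2, tolerance = 1e-9)
  s_pos <- shape_index(ev$K1, ev$K2)
  hn <- hessian_response(-img, 3)
  evn <- hessian_eigenvalues(hn)
  s_neg <- shape_index(evn$K1, evn$K2)
  ok <- !is.na(s_pos) & !is.na(s_neg)
  expect_gt(mean(ok), 0.99)
  expect_equal(s_pos[ok], -s_neg[ok], tolerance = 1e-9)
})

test_that("shape index is invariant under 90-degree rotation", {
  set.seed(8)
  img <- matrix(runif(40 * 40, 0, 255), 40, 40)
  s1 <- shape_index_map(img, 3)$s
  rot <- t(img)[, nrow(img):1] # 90 deg rotation
  s2 <- shape_index_map(rot, 3)$s
  s2_back <- t(s2[, ncol(s2):1])
  ok <- !is.na(s1) & !is.na(s2_back)
  expect_gt(mean(ok), 0.98)
  expect_equal(s1[ok], s2_back[ok], tolerance = 1e-9)
})
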