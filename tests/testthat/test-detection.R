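blank_blob <- function() {
  structure(list(t = 1L, i = 1L, box = c(x = 0, y = 0, w = 20, h = 20),
                 pixels = cbind(x = integer(), y = integer()),
                 patch = matrix(230, 20, 20)), class = "blob")
}

test_that("blank patches yield no features", {
  expect_equal(nrow(detect_heads(blank_blob())), 0)
  expect_equal(nrow(detect_ridge_lines(blank_blob())$lines), 0)
})

test_that("Hough recovers an ideal segment in (rho, theta) convention", {
  # vertical segment x = 10: x cos(0) + y sin(0) = 10
  ln <- schooltrack:::hough_peak_lines(rep(10, 30), 1:30,
                                       detect_params()$hough)
  expect_equal(nrow(ln), 1)
  expect_equal(ln$theta[1], 0)
  expect_equal(ln$rho[1], 10, tolerance = 1)
  # horizontal segment y = 20 -> (20, pi/2)
  ln <- schooltrack:::hough_peak_lines(1:30, rep(20, 30),
                                       detect_params()$hough)
  expect_equal(ln$theta[1], pi / 2, tolerance = 0.02)
  expect_equal(ln$rho[1], 20, tolerance = 1)
})

test_that("line clustering behaves like DBSCAN by definition", {
  db <- detect_params()$dbscan
  db$min_samples <- 3
  # fewer than min_samples identical lines -> all noise
  two <- data.frame(rho = c(0, 0), theta = c(0.3, 0.3))
  expect_true(all(is.na(cluster_lines(two, db))))
  # k copies of one line form a single cluster
  five <- data.frame(rho = rep(2, 5), theta = rep(0.3, 5))
  expect_equal(cluster_lines(five, db), rep(1L, 5))
  # two bundles from perpendicular fish split into two clusters
  set.seed(3)
  bundle <- function(th, rho) data.frame(
    rho = rho + runif(4, -2, 2), theta = th + runif(4, -0.03, 0.03))
  lines <- rbind(bundle(0.2, 5), bundle(0.2 + pi / 2, -40))
  lab <- cluster_lines(lines, db)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:4])), 1)
  # agreement with an independent DBSCAN implementation
  D <- outer(seq_len(8), seq_len(8), function(i, j)
    schooltrack:::line_feature_dist(lines$theta[i] * 180 / pi, lines$rho[i],
                                    lines$theta[j] * 180 / pi, lines$rho[j],
                                    db$rho_scale, db$theta_scale))
  ref <- dbscan_by_definition(matrix(D, 8, 8), db$eps, db$min_samples)
  expect_equal(is.na(lab), is.na(ref))
  expect_equal(length(unique(lab[!is.na(lab)])),
               length(unique(ref[!is.na(ref)])))
})

test_that("body point and omega follow the cluster geometry", {
  cl <- data.frame(rho = c(0, 0), theta = c(0, pi / 2))
  b <- body_from_cluster(cl)
  expect_equal(unname(b$R), c(0, 0), tolerance = 1e-6)
  expect_equal(b$omega, 90)
  cl <- data.frame(rho = c(3, 4, 5), theta = c(10, 25, 40) * pi / 180)
  expect_equal(body_from_cluster(cl)$omega, 30, tolerance = 1e-9)
  # all-parallel cluster: omega 0, point on the middle line
  cl <- data.frame(rho = seq(9.8, 10.2, 0.1), theta = rep(pi / 6, 5))
  b <- body_from_cluster(cl)
  expect_equal(b$omega, 0)
  resid <- b$R[["x"]] * cos(pi / 6) + b$R[["y"]] * sin(pi / 6) - 10
  expect_lt(abs(resid), 0.5)
})

test_that("a lone fish yields one containing head box and one close body", {
  f <- render_lone_fish(0.6, 0.1, seed = 31)
  blobs <- segment_blobs(f$frame, f$background, 25, 100, 5000, t = 1L)
  expect_length(blobs, 1)
  h <- detect_heads(blobs[[1]], detect_params(), f$frame)
  expect_equal(nrow(h), 1)
  expect_true(f$head[1] >= h$x0 && f$head[1] <= h$x1 &&
              f$head[2] >= h$y0 && f$head[2] <= h$y1)
  d <- detect_frame(f$frame, f$background, pipeline_config(), t = 1L)
  expect_equal(nrow(d$bodies), 1)
  expect_lt(dist_to_centerline(c(d$bodies$rx, d$bodies$ry),
                               f$pose$x, f$pose$y, f$pose$heading,
                               f$pose$bend, 70), 5)
})

test_that("detections are translation-equivariant", {
  f <- render_lone_fish(1.1, 0.2, seed = 32, arena = c(260, 220),
                        noise_sd = 0)
  g <- render_lone_fish(1.1, 0.2, seed = 32, arena = c(260, 220),
                        noise_sd = 0, x = 130 + 17, y = 110 + 9)
  bf <- segment_blobs(f$frame, f$background, 25, 100, 5000)[[1]]
  bgl <- segment_blobs(g$frame, g$background, 25, 100, 5000)[[1]]
  hf <- detect_heads(bf, detect_params(), f$frame)
  hg <- detect_heads(bgl, detect_params(), g$frame)
  expect_equal(hg$x0, hf$x0 + 17)
  expect_equal(hg$y0, hf$y0 + 9)
  df <- detect_frame(f$frame, f$background, pipeline_config())
  dg <- detect_frame(g$frame, g$background, pipeline_config())
  expect_equal(dg$bodies$rx, df$bodies$rx + 17, tolerance = 1e-6)
  expect_equal(dg$bodies$ry, df$bodies$ry + 9, tolerance = 1e-6)
})

test_that("two crossing fish give separable body clusters", {
  set.seed(33)
  canvas <- matrix(230, 240, 300)
  p1 <- list(x = 150, y = 120, heading = 0.4, bend = 0, length = 70, width = 12)
  p2 <- list(x = 153, y = 118, heading = 0.4 + 1.2, bend = 0.15,
             length = 70, width = 12)
  canvas <- render_fish(p1, canvas)$canvas
  canvas <- render_fish(p2, canvas)$canvas
  fr <- pmin(pmax(canvas + matrix(rnorm(240 * 300, 0, 2), 240), 0), 255)
  d <- detect_frame(fr, matrix(230, 240, 300), pipeline_config(), t = 1L)
  expect_gte(nrow(d$bodies), 2)
  near <- function(p) min(sqrt((d$bodies$rx - p$x)^2 + (d$bodies$ry - p$y)^2))
  expect_lt(near(p1), 20)
  expect_lt(near(p2), 20)
})
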