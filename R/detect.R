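#' Detection parameters
#'
#' Defaults chosen for fish rendered/filmed at roughly the scale of the
#' bundled simulator (body width ~10 px): `sigma_ridge` about half the body
#' width, `sigma_head` about half the head width.
#'
#' @param sigma_head,sigma_ridge Gaussian scales (px) for the head-cup and
#'   body-ridge features.
#' @param centerline_polarity `"dark"` (fish darker than background; the
#'   centerline is a rut) or `"bright"` (inverted footage; a ridge).
#' @param head_area_min,head_area_max size bounds (px^2) for cup components
#'   accepted as heads.
#' @param hough list: `theta_res_deg` (accumulator angle resolution),
#'   `rho_res` (px), `vote_min` (fraction of the strongest accumulator peak a
#'   returned line must reach), `vote_floor` (absolute minimum supporting
#'   pixels), `support_radius` (px; pixels within this distance of an
#'   accepted line are consumed before searching for the next peak).
#' @param dbscan list: `rho_scale` (px), `theta_scale` (deg), `eps`,
#'   `min_samples` for clustering ridge lines into fish.
#' @return list of detection parameters.
#' @export
detect_params <- function(sigma_head = 5, sigma_ridge = 4,
                          centerline_polarity = c("dark", "bright"),
                          head_area_min = 4, head_area_max = 300,
                          hough = list(theta_res_deg = 2, rho_res = 1,
                                       vote_min = 0.12, vote_floor = 6,
                                       support_radius = 0.9),
                          dbscan = list(rho_scale = 15, theta_scale = 15,
                                        eps = 2, min_samples = 1)) {
  stopifnot(sigma_head > 0, sigma_ridge > 0,
            head_area_min > 0, head_area_min < head_area_max)
  list(sigma_head = sigma_head, sigma_ridge = sigma_ridge,
       centerline_polarity = match.arg(centerline_polarity),
       head_area_min = head_area_min, head_area_max = head_area_max,
       hough = hough, dbscan = dbscan)
}

# shape-index map of a blob patch with spatial context: uses the frame
# around the box when available, otherwise reflect-pads the patch. Returns
# fields cropped back to the blob box.
blob_shape_map <- function(blob, sigma, frame = NULL) {
  pad <- as.integer(ceiling(4 * sigma))
  b <- blob$box
  if (is.null(frame)) {
    img <- blob$patch
    off <- c(0L, 0L)
  } else {
    x0 <- max(0L, b[["x"]] - pad); y0 <- max(0L, b[["y"]] - pad)
    x1 <- min(ncol(frame) - 1L, b[["x"]] + b[["w"]] - 1L + pad)
    y1 <- min(nrow(frame) - 1L, b[["y"]] + b[["h"]] - 1L + pad)
    img <- frame[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
    off <- c(b[["x"]] - x0, b[["y"]] - y0) # blob origin inside img
  }
  sm <- shape_index_map(img, sigma)
  rows <- (off[2L] + 1L):(off[2L] + b[["h"]])
  cols <- (off[1L] + 1L):(off[1L] + b[["w"]])
  for (f in c("s", "K1", "K2", "category", "Lxx", "Lxy", "Lyy"))
    sm[[f]] <- sm[[f]][rows, cols, drop = FALSE]
  sm
}

# logical matrix (blob-box shape) marking the blob's foreground pixels
blob_pixel_mask <- function(blob) {
  b <- blob$box
  m <- matrix(FALSE, b[["h"]], b[["w"]])
  m[cbind(blob$pixels[, "y"] - b[["y"]] + 1L,
          blob$pixels[, "x"] - b[["x"]] + 1L)] <- TRUE
  m
}

#' Detect fish heads in a blob as spherical-cup regions
#'
#' Computes the shape index of the blob patch at `sigma_head`, keeps
#' spherical-cup pixels (`s < -7/8`; the head is a compact dark minimum)
#' restricted to the blob's foreground pixels, takes 8-connected components,
#' filters them by area, and returns each component's tight bounding box in
#' frame coordinates.
#'
#' @param blob a `blob` from [segment_blobs()].
#' @param params [detect_params()].
#' @param frame optional full frame for convolution context.
#' @return data.frame with columns `t`, `x0`, `y0`, `x1`, `y1`
#'   (0-based corner coordinates, inclusive), `area`.
#' @export
detect_heads <- function(blob, params = detect_params(), frame = NULL) {
  sm <- blob_shape_map(blob, params$sigma_head, frame)
  cup <- !is.na(sm$s) & sm$s < -7 / 8 & blob_pixel_mask(blob)
  empty <- data.frame(t = integer(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), area = numeric())
  if (!any(cup)) return(empty)
  lab <- label_components8(cup)
  b <- blob$box
  out <- lapply(setdiff(unique(as.vector(lab)), 0L), function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    if (nrow(w) < params$head_area_min || nrow(w) > params$head_area_max)
      return(NULL)
    data.frame(t = blob$t,
               x0 = b[["x"]] + min(w[, 2L]) - 1L,
               y0 = b[["y"]] + min(w[, 1L]) - 1L,
               x1 = b[["x"]] + max(w[, 2L]) - 1L,
               y1 = b[["y"]] + max(w[, 1L]) - 1L,
               area = nrow(w))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

# thinned centerline mask: centerline-category pixels that are local maxima
# of principal curvature strength across the line direction
centerline_points <- function(sm, inside, polarity) {
  if (polarity == "dark") {
    cand <- !is.na(sm$s) & sm$s >= -5 / 8 & sm$s < -3 / 8 & inside # rut
    strength <- sm$K1
    core <- !is.na(sm$s) & sm$s < -7 / 8 # cup core (head blob)
  } else {
    cand <- !is.na(sm$s) & sm$s >= 3 / 8 & sm$s < 5 / 8 & inside   # ridge
    strength <- -sm$K2
    core <- !is.na(sm$s) & sm$s > 7 / 8
  }
  # the head blob is ringed by centerline-category pixels at this scale;
  # drop candidates adjacent to a blob core so they cannot vote as ridge
  halo_r <- 2L
  if (any(core) && halo_r > 0L) {
    halo <- EBImage::dilate(core * 1,
                            EBImage::makeBrush(2L * halo_r + 1L, "box")) > 0
    cand <- cand & !halo
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  # cross-line direction = eigenvector of the dominant eigenvalue
  a <- 0.5 * atan2(2 * sm$Lxy[idx], sm$Lxx[idx] - sm$Lyy[idx])
  dx <- round(cos(a)); dy <- round(sin(a))
  nr <- nrow(sm$s); nc <- ncol(sm$s)
  val_at <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    v <- rep(-Inf, length(r))
    v[ok] <- strength[cbind(r[ok], c[ok])]
    v
  }
  v0 <- strength[idx]
  keep <- v0 >= val_at(idx[, 1L] + dy, idx[, 2L] + dx) &
          v0 >= val_at(idx[, 1L] - dy, idx[, 2L] - dx)
  cbind(x = idx[keep, 2L] - 1L, y = idx[keep, 1L] - 1L)
}

#' Detect ridge lines of fish centerlines in a blob
#'
#' The centerline mask (rut category for dark fish, ridge for bright fish,
#' thinned by non-maximum suppression across the line direction) is fed to a
#' standard (rho, theta) Hough transform with anti-aliased rho voting.
#' Accumulator peaks are extracted greedily by deflation: the strongest cell
#' is accepted as a line, the mask pixels within `support_radius` of it are
#' consumed, and the accumulator is rebuilt from the remainder until the
#' best peak falls below `vote_min` of the first peak or below `vote_floor`
#' pixels of support. A straight fish therefore yields one line; a bending
#' fish yields one line per resolvable body segment. rho is measured from
#' the blob-box centre; `origin` records that reference in frame
#' coordinates.
#'
#' @inheritParams detect_heads
#' @return list with `lines` (data.frame `rho`, `theta` in `[0, pi)`,
#'   `votes`), `origin` (frame coords of the rho origin), `points`
#'   (centerline pixels, frame coords).
#' @export
detect_ridge_lines <- function(blob, params = detect_params(), frame = NULL) {
  sm <- blob_shape_map(blob, params$sigma_ridge, frame)
  pts <- centerline_points(sm, blob_pixel_mask(blob), params$centerline_polarity)
  b <- blob$box
  origin <- c(b[["x"]] + (b[["w"]] - 1) / 2, b[["y"]] + (b[["h"]] - 1) / 2)
  if (nrow(pts) == 0L)
    return(list(lines = data.frame(rho = numeric(), theta = numeric(),
                                   votes = numeric()),
                origin = origin, points = pts))
  fx <- pts[, "x"] + b[["x"]]; fy <- pts[, "y"] + b[["y"]]
  ln <- hough_peak_lines(fx - origin[1L], fy - origin[2L], params$hough)
  list(lines = ln, origin = origin, points = cbind(x = fx, y = fy))
}

# Hough peaks by greedy deflation (compiled): accept the strongest line,
# consume its supporting pixels, recompute until support falls below the
# thresholds
hough_peak_lines <- function(x, y, hp) {
  thetas <- seq(0, 180 - hp$theta_res_deg, by = hp$theta_res_deg) * pi / 180
  m <- hough_deflate(x, y, thetas, hp$rho_res, hp$vote_min,
                     if (is.null(hp$vote_floor)) 6 else hp$vote_floor,
                     if (is.null(hp$support_radius)) 0.9 else hp$support_radius,
                     1.5)
  as.data.frame(m)
}

# distance between two lines in scaled (rho, theta) feature space,
# circular in theta with the (theta + 180, -rho) equivalence
line_feature_dist <- function(th1, r1, th2, r2, rho_scale, theta_scale) {
  dth <- abs(th1 - th2); dr <- abs(r1 - r2)
  flip <- dth > 90
  dr[flip] <- abs(r1 + r2)[flip]
  dth[flip] <- 180 - dth[flip]
  sqrt((dth / theta_scale)^2 + (dr / rho_scale)^2)
}

#' Cluster ridge lines into fish with DBSCAN
#'
#' DBSCAN (by definition: core points with at least `min_samples`
#' neighbours within `eps`, clusters grown by density reachability) over the
#' scaled feature vectors `(rho / rho_scale, theta / theta_scale)`. Theta
#' distance is circular on `[0, 180)` degrees. Lines not reachable from any
#' core point are noise and discarded.
#'
#' @param lines data.frame with `rho`, `theta` (radians in `[0, pi)`).
#' @param dbscan list with `rho_scale`, `theta_scale` (degrees), `eps`,
#'   `min_samples`.
#' @return integer vector of cluster labels (1, 2, ...; `NA` = noise),
#'   one per line.
#' @export
cluster_lines <- function(lines, dbscan = detect_params()$dbscan) {
  n <- nrow(lines)
  if (n == 0L) return(integer())
  th <- lines$theta * 180 / pi; rh <- lines$rho
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    line_feature_dist(th[i], rh[i], th[j], rh[j],
                      dbscan$rho_scale, dbscan$theta_scale))
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= dbscan$eps))
  core <- lengths(nbr) >= dbscan$min_samples
  lab <- rep(0L, n); cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      if (lab[q] == 0L) {
        lab[q] <- cl
        if (core[q]) queue <- c(queue, nbr[[q]][lab[nbr[[q]]] == 0L])
      }
    }
  }
  lab[lab == 0L] <- NA_integer_
  lab
}

# circular unwrap of line angles (degrees, period 180) about their mean
unwrap_thetas <- function(th_deg) {
  ang <- th_deg * pi / 90
  mu <- atan2(mean(sin(ang)), mean(cos(ang))) * 90 / pi
  mu + ((th_deg - mu + 90) %% 180 - 90)
}

#' Body point and motion state from a cluster of ridge lines
#'
#' The body point `R` minimises the sum of squared perpendicular distances
#' to the cluster's lines (their least-squares intersection). The normal
#' equations are Tikhonov-regularised towards an anchor -- the centroid of
#' the centerline pixels supporting the lines when available, else the
#' centroid of the per-line foot points -- which resolves the degenerate
#' all-parallel case without moving a well-conditioned solution. The motion
#' state `omega` is the angular spread `max(theta) - min(theta)` in degrees
#' after circular unwrapping, capped at 180.
#'
#' @param cluster data.frame of lines (`rho`, `theta`) in one cluster.
#' @param points optional two-column matrix of supporting pixel coordinates
#'   (same frame as `rho`).
#' @return list with `R` (`c(x, y)`), `omega` (degrees), `n_lines`.
#' @export
body_from_cluster <- function(cluster, points = NULL) {
  n <- nrow(cluster)
  if (is.null(n) || n == 0L) stop("empty cluster")
  th <- cluster$theta; rh <- cluster$rho
  feet <- cbind(rh * cos(th), rh * sin(th))
  anchor <- colMeans(feet)
  if (!is.null(points) && nrow(points)) {
    d <- vapply(seq_len(n), function(j)
      abs(points[, 1L] * cos(th[j]) + points[, 2L] * sin(th[j]) - rh[j]),
      numeric(nrow(points)))
    d <- matrix(d, nrow = nrow(points))
    supp <- points[apply(d, 1L, min) <= 1.5, , drop = FALSE]
    if (nrow(supp)) anchor <- colMeans(supp)
  }
  A <- matrix(0, 2L, 2L); b <- c(0, 0)
  for (j in seq_len(n)) {
    nv <- c(cos(th[j]), sin(th[j]))
    A <- A + tcrossprod(nv)
    b <- b + nv * rh[j]
  }
  lam <- 1e-2 * n
  R <- as.numeric(solve(A + lam * diag(2L), b + lam * anchor))
  om <- if (n < 2L) 0 else {
    u <- unwrap_thetas(th * 180 / pi)
    min(diff(range(u)), 180)
  }
  list(R = c(x = R[1L], y = R[2L]), omega = om, n_lines = n)
}

#' Detect all heads and bodies in one frame
#'
#' Composition of the detection stage: [segment_blobs()], then per blob
#' [detect_heads()] and [detect_ridge_lines()], [cluster_lines()] and
#' [body_from_cluster()].
#'
#' @param frame,background numeric matrices.
#' @param config a [pipeline_config()].
#' @param t frame index attached to the detections.
#' @return list with `heads` (data.frame `t`, `x0`, `y0`, `x1`, `y1`,
#'   `area`) and `bodies` (data.frame `t`, `rx`, `ry`, `omega`, `n_lines`).
#' @export
detect_frame <- function(frame, background, config = pipeline_config(),
                         t = NA_integer_) {
  seg <- config$segmentation
  blobs <- segment_blobs(frame, background, seg$diff_threshold,
                         seg$area_min, seg$area_max, t = t)
  heads <- list(); bodies <- list()
  for (blob in blobs) {
    heads[[length(heads) + 1L]] <- detect_heads(blob, config$detection, frame)
    rl <- detect_ridge_lines(blob, config$detection, frame)
    if (nrow(rl$lines) == 0L) next
    lab <- cluster_lines(rl$lines, config$detection$dbscan)
    for (cl in setdiff(unique(lab), NA_integer_)) {
      bd <- body_from_cluster(rl$lines[which(lab == cl), , drop = FALSE],
                              sweep_origin(rl$points, rl$origin))
      bodies[[length(bodies) + 1L]] <- data.frame(
        t = t, rx = bd$R[["x"]] + rl$origin[1L], ry = bd$R[["y"]] + rl$origin[2L],
        omega = bd$omega, n_lines = bd$n_lines)
    }
  }
  list(heads = rbind_or_empty(heads,
         data.frame(t = integer(), x0 = numeric(), y0 = numeric(),
                    x1 = numeric(), y1 = numeric(), area = numeric())),
       bodies = rbind_or_empty(bodies,
         data.frame(t = integer(), rx = numeric(), ry = numeric(),
                    omega = numeric(), n_lines = integer())))
}

sweep_origin <- function(points, origin) {
  if (nrow(points) == 0L) return(points)
  cbind(points[, 1L] - origin[1L], points[, 2L] - origin[2L])
}

rbind_or_empty <- function(lst, empty) {
  lst <- Filter(function(d) !is.null(d) && nrow(d) > 0L, lst)
  if (length(lst) == 0L) empty else do.call(rbind, lst)
}
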