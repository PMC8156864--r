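#' Configuration for the synthetic fish-school generator
#'
#' The generator emulates the footage the tracker is designed for: dark,
#' elongated, bendable fish bodies with a darker head blob, swimming over a
#' bright backlit arena with smooth near-constant-velocity motion, gentle
#' random-walk turns, soft mutual avoidance and smooth wall avoidance.
#' A `crossing_script` forces chosen pairs onto colliding paths so occlusion
#' events happen at known frames.
#'
#' @param n_fish number of fish (>= 1).
#' @param n_frames number of frames.
#' @param arena `c(width, height)` in pixels.
#' @param background_level,body_level,head_level 8-bit intensities with
#'   `head_level < body_level < background_level` (dark fish, darker head,
#'   bright background).
#' @param noise_sd standard deviation of additive Gaussian pixel noise,
#'   applied after rendering and clipped to `[0, 255]`.
#' @param fish_length,fish_width capsule body dimensions in pixels
#'   (`length > width`).
#' @param speed_range per-fish base speed range, px/frame.
#' @param turn_sd per-frame heading random-walk standard deviation (radians).
#' @param seed integer seed controlling kinematics and pixel noise.
#' @param crossing_script optional list of crossing events, each a list with
#'   `fish = c(i, j)` and `frames = c(first, last)`; the pair is steered onto
#'   straight paths that meet mid-window.
#' @return object of class `school_config` (a validated list).
#' @export
school_config <- function(n_fish = 5, n_frames = 100, arena = c(640, 480),
                          background_level = 230, body_level = 170,
                          head_level = 20, noise_sd = 2,
                          fish_length = 70, fish_width = 12,
                          speed_range = c(2.5, 3.5), turn_sd = 0.08,
                          seed = 1, crossing_script = NULL) {
  stopifnot(n_fish >= 1, n_frames >= 1, length(arena) == 2, all(arena > 0),
            head_level < body_level, body_level < background_level,
            noise_sd >= 0, fish_length > fish_width, fish_width > 0)
  if (!is.null(crossing_script)) {
    for (ev in crossing_script) {
      stopifnot(length(ev$fish) == 2, all(ev$fish %in% seq_len(n_fish)),
                length(ev$frames) == 2, ev$frames[1] <= ev$frames[2],
                ev$frames[1] >= 1, ev$frames[2] <= n_frames)
    }
  }
  structure(list(
    n_fish = as.integer(n_fish), n_frames = as.integer(n_frames),
    arena = as.numeric(arena), background_level = background_level,
    body_level = body_level, head_level = head_level, noise_sd = noise_sd,
    fish_length = fish_length, fish_width = fish_width,
    speed_range = as.numeric(speed_range), turn_sd = turn_sd,
    seed = as.integer(seed), crossing_script = crossing_script
  ), class = "school_config")
}

# geometry helpers ----------------------------------------------------------

# 5-segment centerline polyline of a fish pose; row 1 is the nose.
# The bend is distributed over the joints with mid-body emphasis (C-shaped
# flexion, as in real turning fish), so most of the direction change is
# visible on the trunk rather than at the tapered ends.
fish_centerline <- function(x, y, heading, bend, length) {
  nseg <- 5L
  seg <- length / nseg
  angs <- heading + pi + bend * cumsum(c(0, 0.15, 0.35, 0.35, 0.15))
  pts <- matrix(0, nseg + 1L, 2L)
  pts[1L, ] <- c(x + cos(heading) * length / 2, y + sin(heading) * length / 2)
  for (k in seq_len(nseg))
    pts[k + 1L, ] <- pts[k, ] + seg * c(cos(angs[k]), sin(angs[k]))
  pts
}

# head-ellipse centre: set back from the nose along the heading
fish_head_point <- function(x, y, heading, length, width) {
  ha <- 0.7 * width
  nose <- c(x + cos(heading) * length / 2, y + sin(heading) * length / 2)
  nose - c(cos(heading), sin(heading)) * 0.9 * ha
}

#' Render one fish onto a canvas
#'
#' Draws a tapered capsule body of intensity `body_level` along a 5-segment
#' polyline bent by `pose$bend` (C-shaped, with mid-body emphasis), and a
#' round head at the front end graded from `head_level` at its centre to
#' `body_level` at its rim. Where fish overlap, the darker pixel wins
#' (minimum rule), matching backlit footage.
#'
#' @param pose list with `x`, `y` (centre, px), `heading` (radians),
#'   `bend` (radians, `|bend| <= pi/2`), `length`, `width` (px).
#' @param canvas numeric matrix to draw on.
#' @param body_level,head_level intensities.
#' @return list with `canvas` (updated) and `mask` (integer vector of
#'   1-based linear pixel indices covered by this fish).
#' @export
render_fish <- function(pose, canvas, body_level = 170, head_level = 20) {
  stopifnot(abs(pose$bend) <= pi / 2, pose$length > pose$width)
  pts <- fish_centerline(pose$x, pose$y, pose$heading, pose$bend, pose$length)
  wid <- pose$width
  h <- nrow(canvas); w <- ncol(canvas)
  x0 <- max(0, floor(min(pts[, 1L]) - wid)); x1 <- min(w - 1, ceiling(max(pts[, 1L]) + wid))
  y0 <- max(0, floor(min(pts[, 2L]) - wid)); y1 <- min(h - 1, ceiling(max(pts[, 2L]) + wid))
  if (x1 < x0 || y1 < y0) stop("pose outside canvas")
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)); py <- rep(ys, length(xs))
  # capsule stroke with taper: full half-width at the head end of the
  # trunk, narrowing to a quarter width at the tail tip
  nseg <- nrow(pts) - 1L
  body <- rep(FALSE, length(px))
  for (k in seq_len(nseg)) {
    a <- pts[k, ]; b <- pts[k + 1L, ]
    abx <- b[1L] - a[1L]; aby <- b[2L] - a[2L]
    L2 <- abx^2 + aby^2
    tt <- pmin(1, pmax(0, ((px - a[1L]) * abx + (py - a[2L]) * aby) / L2))
    d <- sqrt((px - (a[1L] + tt * abx))^2 + (py - (a[2L] + tt * aby))^2)
    frac <- (k - 1L + tt) / nseg # 0 at nose, 1 at tail tip
    body <- body | (d <= (wid / 2) * (1 - 0.75 * frac))
  }
  ha <- 0.7 * wid; hb <- 0.7 * wid
  hc <- fish_head_point(pose$x, pose$y, pose$heading, pose$length, wid)
  ca <- cos(pose$heading); sa <- sin(pose$heading)
  ex <- (px - hc[1L]) * ca + (py - hc[2L]) * sa
  ey <- -(px - hc[1L]) * sa + (py - hc[2L]) * ca
  re2 <- (ex / ha)^2 + (ey / hb)^2
  head <- re2 <= 1
  lin <- px * h + py + 1L # 1-based linear index of (row py+1, col px+1)
  sel <- body | head
  v <- canvas[lin[sel]]
  vb <- body[sel]; vh <- head[sel]
  v[vb] <- pmin(v[vb], body_level)
  # head is graded: darkest at its centre, rising linearly in elliptical
  # radius to body level at the rim -- the conical profile concentrates an
  # isotropic concavity at the centre at every smoothing scale
  v[vh] <- pmin(v[vh], head_level + (body_level - head_level) * sqrt(re2[sel][vh]))
  canvas[lin[sel]] <- v
  list(canvas = canvas, mask = lin[sel])
}

# smallest signed angular difference a - b in (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Simulate a synthetic fish school with exact ground truth
#'
#' Deterministic for a fixed seed. Fish follow smooth random-walk headings,
#' softly avoid each other (unless scripted to cross), steer away from the
#' arena walls at a bounded turn rate, and bend transiently while turning.
#' Scripted crossings steer a pair onto oblique paths that meet mid-window,
#' which guarantees mask overlap (occlusion) there.
#'
#' @param config a [school_config()].
#' @return list with `frames` (list of numeric matrices, intensities 0-255),
#'   `truth` (data.frame: `frame`, `id`, `head_x`, `head_y`, `body_x`,
#'   `body_y`, `bend`, `occluded`), and `config`.
#' @export
simulate_school <- function(config) {
  stopifnot(inherits(config, "school_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    base::assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  W <- cfg$arena[1L]; H <- cfg$arena[2L]
  margin <- cfg$fish_length / 2 + 4
  if (W - 2 * margin < 1 || H - 2 * margin < 1)
    stop("arena too small for the configured fish length")
  # initial placement without overlap
  min_sep <- 1.2 * cfg$fish_length
  pos <- matrix(NA_real_, cfg$n_fish, 2L)
  for (i in seq_len(cfg$n_fish)) {
    ok <- FALSE
    for (try in 1:200) {
      p <- c(stats::runif(1, margin, W - 1 - margin),
             stats::runif(1, margin, H - 1 - margin))
      if (i == 1L || all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
            matrix(p, i - 1L, 2L, byrow = TRUE))^2)) >= min_sep)) {
        pos[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("arena too small to place ", cfg$n_fish, " fish without overlap")
  }
  heading <- stats::runif(cfg$n_fish, 0, 2 * pi)
  base_speed <- stats::runif(cfg$n_fish, cfg$speed_range[1L], cfg$speed_range[2L])
  speed <- base_speed
  bend <- rep(0, cfg$n_fish)

  # scripted-crossing bookkeeping
  script <- cfg$crossing_script
  scripted <- matrix(FALSE, cfg$n_fish, cfg$n_frames) # fish x frame: under script
  plan <- vector("list", length(script))              # per event: headings/speeds

  frames <- vector("list", cfg$n_frames)
  truth <- vector("list", cfg$n_frames)

  for (t in seq_len(cfg$n_frames)) {
    # -- kinematics update ---------------------------------------------------
    turn <- stats::rnorm(cfg$n_fish, 0, cfg$turn_sd)
    # activate scripts
    if (!is.null(script)) for (e in seq_along(script)) {
      ev <- script[[e]]
      if (t == ev$frames[1L]) {
        i <- ev$fish[1L]; j <- ev$fish[2L]
        # aim point off the perpendicular bisector so the pair meets at an
        # oblique angle (50-110 deg) rather than head-on
        mid <- (pos[i, ] + pos[j, ]) / 2
        dvec <- pos[j, ] - pos[i, ]
        dlen <- sqrt(sum(dvec^2))
        alpha <- stats::runif(1, 50, 110) * pi / 180
        side <- sample(c(-1, 1), 1)
        hoff <- (dlen / 2) / tan(alpha / 2)
        nhat <- c(-dvec[2L], dvec[1L]) / max(dlen, 1e-9)
        M <- mid + side * hoff * nhat
        M[1L] <- min(max(M[1L], margin + 10), W - 1 - margin - 10)
        M[2L] <- min(max(M[2L], margin + 10), H - 1 - margin - 10)
        plan[[e]] <- list(M = M, tm = floor(mean(ev$frames)))
      }
      if (t >= ev$frames[1L] && t <= ev$frames[2L]) scripted[ev$fish, t] <- TRUE
    }
    for (i in seq_len(cfg$n_fish)) {
      if (scripted[i, t]) {
        # scripted approach: steer continuously towards the meeting point
        # until the meeting frame, then hold a straight pass-through course
        for (e in seq_along(script)) {
          ev <- script[[e]]
          if (t >= ev$frames[1L] && t <= ev$frames[2L] && i %in% ev$fish) {
            if (t <= plan[[e]]$tm) {
              M <- plan[[e]]$M
              desired <- atan2(M[2L] - pos[i, 2L], M[1L] - pos[i, 1L])
              turn[i] <- max(-0.3, min(0.3, angle_diff(desired, heading[i])))
              heading[i] <- heading[i] + turn[i]
              nsteps <- max(1L, plan[[e]]$tm - t + 1L)
              speed[i] <- min(6, max(1.5, sqrt(sum((M - pos[i, ])^2)) / nsteps))
            } else {
              turn[i] <- 0
            }
          }
        }
      } else {
        speed[i] <- base_speed[i]
        # soft avoidance of nearest neighbour
        if (cfg$n_fish > 1L) {
          d2 <- rowSums((pos - matrix(pos[i, ], cfg$n_fish, 2L, byrow = TRUE))^2)
          d2[i] <- Inf
          j <- which.min(d2)
          if (d2[j] < (1.8 * cfg$fish_length)^2 && !scripted[j, t]) {
            away <- atan2(pos[i, 2L] - pos[j, 2L], pos[i, 1L] - pos[j, 1L])
            turn[i] <- turn[i] + 0.15 * angle_diff(away, heading[i])
          }
        }
        # wall avoidance: steer towards the mirrored (reflected) heading at
        # a bounded rate, so the pose stays continuous the way a real fish
        # turning away from a wall does
        look <- 6 * speed[i]
        dx <- cos(heading[i]); dy <- sin(heading[i])
        if ((pos[i, 1L] + dx * look < margin && dx < 0) ||
            (pos[i, 1L] + dx * look > W - 1 - margin && dx > 0)) dx <- -dx
        if ((pos[i, 2L] + dy * look < margin && dy < 0) ||
            (pos[i, 2L] + dy * look > H - 1 - margin && dy > 0)) dy <- -dy
        steer <- angle_diff(atan2(dy, dx), heading[i])
        turn[i] <- turn[i] + max(-0.3, min(0.3, steer))
        turn[i] <- max(-0.35, min(0.35, turn[i]))
        heading[i] <- heading[i] + turn[i]
      }
      nx <- pos[i, 1L] + cos(heading[i]) * speed[i]
      ny <- pos[i, 2L] + sin(heading[i]) * speed[i]
      # hard backstop: the steering normally keeps fish off the walls; the
      # clamp guarantees the whole body stays inside the frame
      nx <- min(max(nx, margin), W - 1 - margin)
      ny <- min(max(ny, margin), H - 1 - margin)
      pos[i, ] <- c(nx, ny)
      # transient bend follows turning, relaxes back to straight
      bend[i] <- max(-pi / 3, min(pi / 3, 0.55 * bend[i] + 2.5 * turn[i]))
    }

    # -- render --------------------------------------------------------------
    canvas <- matrix(cfg$background_level, H, W)
    masks <- vector("list", cfg$n_fish)
    heads <- matrix(0, cfg$n_fish, 2L)
    for (i in seq_len(cfg$n_fish)) {
      pose <- list(x = pos[i, 1L], y = pos[i, 2L], heading = heading[i],
                   bend = bend[i], length = cfg$fish_length, width = cfg$fish_width)
      r <- render_fish(pose, canvas, cfg$body_level, cfg$head_level)
      canvas <- r$canvas
      masks[[i]] <- r$mask
      heads[i, ] <- fish_head_point(pos[i, 1L], pos[i, 2L], heading[i],
                                    cfg$fish_length, cfg$fish_width)
    }
    occ <- rep(FALSE, cfg$n_fish)
    if (cfg$n_fish > 1L) {
      for (i in seq_len(cfg$n_fish - 1L)) for (j in (i + 1L):cfg$n_fish) {
        if (length(intersect(masks[[i]], masks[[j]])) > 0L) occ[c(i, j)] <- TRUE
      }
    }
    if (cfg$noise_sd > 0) {
      canvas <- canvas + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W)
      canvas <- pmin(pmax(canvas, 0), 255)
    }
    frames[[t]] <- canvas
    truth[[t]] <- data.frame(
      frame = t, id = seq_len(cfg$n_fish),
      head_x = heads[, 1L], head_y = heads[, 2L],
      body_x = pos[, 1L], body_y = pos[, 2L],
      bend = bend, occluded = occ)
  }
  list(frames = frames, truth = do.call(rbind, truth), config = cfg)
}

#' Write / read ground truth CSV
#'
#' Numeric columns are written with 17 significant digits so the file
#' round-trips losslessly.
#'
#' @param truth ground-truth data.frame as produced by [simulate_school()].
#' @param path file path.
#' @return `read_truth` returns the data.frame; `write_truth` returns `path`
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  for (cl in c("head_x", "head_y", "body_x", "body_y", "bend"))
    out[[cl]] <- trimws(formatC(truth[[cl]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, colClasses = c(
    frame = "integer", id = "integer", head_x = "numeric", head_y = "numeric",
    body_x = "numeric", body_y = "numeric", bend = "numeric",
    occluded = "logical"))
}
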