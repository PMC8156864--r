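#' Tracker parameters
#'
#' @param iou_min IOU gate in `[0, 1]`: assignments with overlap below this
#'   are cancelled.
#' @param max_age frames a track may stay unassociated before removal.
#' @param min_hits consecutive associations a temporary track needs for
#'   promotion to a confirmed identity.
#' @param omega_gain dimensionless box-inflation factor `k`: predicted box
#'   sides are scaled by `1 + k * omega / 180`, enlarging the search region
#'   for strongly bending (fast-turning) fish.
#' @param head_box_size,body_box_size default `(w, h)` in px for predicted
#'   boxes before any detection size is seen (bodies are tracked as
#'   fixed-size boxes centred on the body point).
#' @param process_noise Kalman process-noise scale, px/frame (of the order
#'   of the expected unmodelled per-frame displacement).
#' @param measurement_noise measurement-noise standard deviation, px.
#' @return list of tracker parameters.
#' @export
tracker_params <- function(iou_min = 0.1, max_age = 5, min_hits = 3,
                           omega_gain = 2, head_box_size = c(20, 20),
                           body_box_size = c(48, 48),
                           process_noise = 3, measurement_noise = 1) {
  stopifnot(max_age >= 1, min_hits >= 1, iou_min >= 0, iou_min <= 1,
            omega_gain >= 0)
  list(iou_min = iou_min, max_age = max_age, min_hits = min_hits,
       omega_gain = omega_gain, head_box_size = head_box_size,
       body_box_size = body_box_size, process_noise = process_noise,
       measurement_noise = measurement_noise)
}

# constant-velocity Kalman filter, state (u, v, u', v') ----------------------

.kf_F <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1))
.kf_H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))

#' Constant-velocity Kalman filter primitives
#'
#' State is `(u, v, du, dv)`: position and per-frame velocity in px. The
#' initial velocity is zero with large uncertainty, so it converges onto the
#' observed displacement within a few updates.
#'
#' @param z position measurement `c(u, v)`.
#' @param process_noise,measurement_noise see [tracker_params()].
#' @param kf a filter state from `kf_create`.
#' @return `kf_create` and the two steps return the filter state: a list
#'   with `x` (state vector) and `P` (covariance).
#' @export
kf_create <- function(z, process_noise = 1, measurement_noise = 1) {
  list(x = c(z[1], z[2], 0, 0),
       P = diag(c(measurement_noise^2, measurement_noise^2, 1e3, 1e3)),
       # velocity random walk ~1 px/frame^2 at the default scale: strong
       # enough to follow turns, weak enough to keep direction memory
       # through a few corrupted measurements
       Q = diag(process_noise^2 * c(0.25, 0.25, 0.11, 0.11)),
       R = diag(rep(measurement_noise^2, 2)))
}

#' @rdname kf_create
#' @export
kf_predict <- function(kf) {
  kf$x <- as.numeric(.kf_F %*% kf$x)
  kf$P <- .kf_F %*% kf$P %*% t(.kf_F) + kf$Q
  kf
}

#' @rdname kf_create
#' @export
kf_update <- function(kf, z, R = kf$R) {
  y <- z - as.numeric(.kf_H %*% kf$x)
  S <- .kf_H %*% kf$P %*% t(.kf_H) + R
  K <- kf$P %*% t(.kf_H) %*% solve(S)
  kf$x <- kf$x + as.numeric(K %*% y)
  kf$P <- (diag(4) - K %*% .kf_H) %*% kf$P
  kf
}

# boxes are c(x0, y0, x1, y1) in continuous coordinates, x1 > x0 ------------

#' Box from a track state: centre, base size, motion-state inflation
#'
#' Sides are `base_size * (1 + k * omega / 180)`: a fish with a large
#' ridge-line spread (bending, turning) gets a larger association box to
#' absorb the extra prediction error.
#'
#' @param center `c(x, y)`.
#' @param base_size `c(w, h)` px.
#' @param omega motion-state angle in degrees, `>= 0`.
#' @param k inflation gain.
#' @return box `c(x0, y0, x1, y1)`.
#' @export
box_from_state <- function(center, base_size, omega = 0, k = 1) {
  if (omega < 0) stop("'omega' must be >= 0")
  side <- base_size * (1 + k * omega / 180)
  c(center[1] - side[1] / 2, center[2] - side[2] / 2,
    center[1] + side[1] / 2, center[2] + side[2] / 2)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b boxes `c(x0, y0, x1, y1)`.
#' @return IOU in `[0, 1]`; 0 for disjoint or degenerate boxes.
#' @export
iou <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

#' IOU-distance cost matrix between predicted and detected boxes
#'
#' @param preds,dets lists of boxes.
#' @return matrix `C` with `C[n, m] = 1 - iou(preds[[n]], dets[[m]])`.
#' @export
build_cost_matrix <- function(preds, dets) {
  C <- matrix(1, length(preds), length(dets))
  for (n in seq_along(preds)) for (m in seq_along(dets))
    C[n, m] <- 1 - iou(preds[[n]], dets[[m]])
  C
}

#' Gated minimum-cost assignment (SORT association step)
#'
#' Solves the rectangular assignment problem by the Hungarian algorithm and
#' then cancels matches whose IOU falls below `iou_min` (cost above
#' `1 - iou_min`), reporting both sides unmatched.
#'
#' @param C cost matrix (rows = trackers, cols = detections), entries in
#'   `[0, 1]`.
#' @param iou_min gate.
#' @return list `matches` (two-column matrix of (tracker, detection) index
#'   pairs), `unmatched_trks`, `unmatched_dets`, `delta` (sum of matched
#'   costs).
#' @export
assign <- function(C, iou_min = 0) {
  sol <- solve_assignment(C)
  m <- sol$matches
  if (nrow(m)) {
    keep <- C[m] <= 1 - iou_min + 1e-12
    m <- m[keep, , drop = FALSE]
  }
  list(matches = m,
       unmatched_trks = setdiff(seq_len(nrow(C)), m[, 1]),
       unmatched_dets = setdiff(seq_len(ncol(C)), m[, 2]),
       delta = if (nrow(m)) sum(C[m]) else 0)
}

# track constructors ---------------------------------------------------------

new_track <- function(kind, center, base_size, tp, frame) {
  list(id = NA_integer_, kind = kind,
       kf = kf_create(center, tp$process_noise, tp$measurement_noise),
       base_size = base_size, omega_last = 0,
       hits = 1L, time_since_update = 0L, status = "temporary",
       start_frame = frame, paired_head_id = NA_integer_,
       head_offset = c(0, 0), matched = TRUE)
}

track_center <- function(tr) tr$kf$x[1:2]

track_box <- function(tr, tp) {
  box_from_state(track_center(tr), tr$base_size, tr$omega_last, tp$omega_gain)
}

# cup-component boxes fluctuate in size frame to frame; pad them to at
# least head_box_size (about the head's physical extent) so the IOU gate
# reflects centre agreement rather than component-area jitter
det_head_boxes <- function(heads, tp) {
  lapply(seq_len(nrow(heads)), function(i) {
    cx <- (heads$x0[i] + heads$x1[i] + 1) / 2
    cy <- (heads$y0[i] + heads$y1[i] + 1) / 2
    w <- max(heads$x1[i] + 1 - heads$x0[i], tp$head_box_size[1])
    h <- max(heads$y1[i] + 1 - heads$y0[i], tp$head_box_size[2])
    c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  })
}

det_body_boxes <- function(bodies, tp) {
  lapply(seq_len(nrow(bodies)), function(i)
    box_from_state(c(bodies$rx[i], bodies$ry[i]), tp$body_box_size))
}

#' Create a streaming tracker
#'
#' The tracker is an environment holding confirmed and temporary head and
#' body tracks, the retired-ID pool and the trajectory accumulated so far.
#' Feed frames with [tracker_step()]; results never depend on future frames.
#'
#' @param config a [pipeline_config()].
#' @param background background image from [build_background()].
#' @return object of class `school_tracker` (an environment).
#' @export
tracker_create <- function(config, background) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$background <- background
  st$heads <- list(); st$head_temp <- list()
  st$bodies <- list(); st$body_temp <- list()
  st$lost <- data.frame(id = integer(), x = numeric(), y = numeric(),
                        frame = integer())
  st$next_id <- 1L
  st$frame_idx <- 0L
  st$records <- list()
  class(st) <- "school_tracker"
  st
}

# run one association stage (confirmed + temporary tracks vs detections);
# returns updated lists and indices of detections left unmatched.
# When ambig_radius is set, a detection whose position is predicted by two
# or more tracks at once is the corrupted centroid of merged features
# (fish overlapping); it is discarded so both tracks keep coasting on
# their own motion instead of being dragged to the midpoint.
associate_stage <- function(tracks, temp, det_boxes, tp, ambig_radius = NULL) {
  soft <- rep(FALSE, length(det_boxes))
  for (i in seq_along(tracks)) {
    tracks[[i]]$kf <- kf_predict(tracks[[i]]$kf)
    tracks[[i]]$time_since_update <- tracks[[i]]$time_since_update + 1L
    tracks[[i]]$matched <- FALSE
  }
  for (i in seq_along(temp)) {
    temp[[i]]$kf <- kf_predict(temp[[i]]$kf)
    temp[[i]]$time_since_update <- temp[[i]]$time_since_update + 1L
    temp[[i]]$matched <- FALSE
  }
  det_left <- seq_along(det_boxes)
  if (!is.null(ambig_radius) && length(det_left) && length(tracks) > 1L) {
    preds <- vapply(tracks, track_center, numeric(2L))
    soft <- vapply(seq_along(det_boxes), function(m) {
      b <- det_boxes[[m]]
      cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
      sum(sqrt((preds[1L, ] - cx)^2 + (preds[2L, ] - cy)^2) < ambig_radius) >= 2L
    }, TRUE)
  }
  upd <- function(tr, box, softened) {
    z <- c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
    # a detection claimed by two predictions at once is the corrupted
    # centroid of merged features: take it with heavily inflated
    # measurement noise so the track is not dragged off its course
    R <- if (softened) 25 * tr$kf$R else tr$kf$R
    tr$kf <- kf_update(tr$kf, z, R)
    tr$base_size <- c(box[3] - box[1], box[4] - box[2])
    tr$hits <- tr$hits + 1L
    tr$time_since_update <- 0L
    tr$matched <- TRUE
    tr
  }
  if (length(tracks) && length(det_left)) {
    C <- build_cost_matrix(lapply(tracks, track_box, tp = tp),
                           det_boxes[det_left])
    a <- assign(C, tp$iou_min)
    for (r in seq_len(nrow(a$matches))) {
      n <- a$matches[r, 1]; m <- det_left[a$matches[r, 2]]
      tracks[[n]] <- upd(tracks[[n]], det_boxes[[m]], soft[m])
      tracks[[n]]$det_idx <- m
    }
    det_left <- det_left[a$unmatched_dets]
  }
  if (length(temp) && length(det_left)) {
    C <- build_cost_matrix(lapply(temp, track_box, tp = tp),
                           det_boxes[det_left])
    a <- assign(C, tp$iou_min)
    for (r in seq_len(nrow(a$matches))) {
      n <- a$matches[r, 1]; m <- det_left[a$matches[r, 2]]
      temp[[n]] <- upd(temp[[n]], det_boxes[[m]], soft[m])
      temp[[n]]$det_idx <- m
    }
    det_left <- det_left[a$unmatched_dets]
  }
  list(tracks = tracks, temp = temp, unmatched_dets = det_left)
}

#' Advance the tracker by one frame
#'
#' Runs detection on the frame, associates head detections with head tracks
#' (confirmed first, then temporary; leftovers spawn new temporary tracks),
#' promotes temporary tracks that reach `min_hits` (relinking them to the
#' nearest lost identity if any), removes tracks unassociated longer than
#' `max_age`, then runs the same machinery on body detections and uses
#' matched body tracks to recover the head positions of unmatched head
#' tracks (body fallback). Appends one trajectory record per confirmed
#' identity.
#'
#' @param st a `school_tracker`.
#' @param frame numeric matrix.
#' @param detections optional precomputed result of [detect_frame()] for
#'   this frame (used by the CLI to avoid detecting twice).
#' @return invisibly, the records appended for this frame (data.frame).
#' @export
tracker_step <- function(st, frame, detections = NULL) {
  cfg <- st$config
  tp <- cfg$tracker
  st$frame_idx <- st$frame_idx + 1L
  t <- st$frame_idx
  if (is.null(detections))
    detections <- detect_frame(frame, st$background, cfg, t = t)
  heads <- detections$heads; bodies <- detections$bodies

  # ---- head stage ----------------------------------------------------------
  hb <- det_head_boxes(heads, tp)
  stg <- associate_stage(st$heads, st$head_temp, hb, tp,
                         ambig_radius = 0.7 * min(tp$head_box_size))
  st$heads <- stg$tracks; st$head_temp <- stg$temp
  # new temporary tracks from unmatched head detections
  for (m in stg$unmatched_dets) {
    b <- hb[[m]]
    st$head_temp[[length(st$head_temp) + 1L]] <-
      new_track("head", c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2),
                c(b[3] - b[1], b[4] - b[2]), tp, t)
  }
  # temporary lifecycle: drop stale, promote mature
  keep <- logical(length(st$head_temp))
  for (i in seq_along(st$head_temp)) {
    tr <- st$head_temp[[i]]
    if (!tr$matched && tr$time_since_update > tp$max_age) next # noise
    if (tr$matched && tr$hits >= tp$min_hits) {
      tr$status <- "confirmed"
      pos <- track_center(tr)
      # a coasting confirmed track nearby is the same fish whose detections
      # this temporary track has been stealing: hand the identity over
      # instead of spawning a duplicate
      coasting <- which(vapply(st$heads, function(h)
        !h$matched && h$time_since_update >= 1L, TRUE))
      if (length(coasting)) {
        d <- vapply(coasting, function(j)
          sum((track_center(st$heads[[j]]) - pos)^2), 0)
        coasting <- coasting[sqrt(d) <= 60]
        d <- sqrt(d[sqrt(d) <= 60])
      }
      if (length(coasting)) {
        j <- coasting[which.min(d)]
        old <- st$heads[[j]]
        tr$id <- old$id
        tr$omega_last <- old$omega_last
        st$heads[[j]] <- tr
      } else if (nrow(st$lost)) {
        d <- sqrt((st$lost$x - pos[1])^2 + (st$lost$y - pos[2])^2)
        j <- which.min(d)
        tr$id <- st$lost$id[j]
        st$lost <- st$lost[-j, , drop = FALSE]
        st$heads[[length(st$heads) + 1L]] <- tr
      } else {
        tr$id <- st$next_id
        st$next_id <- st$next_id + 1L
        st$heads[[length(st$heads) + 1L]] <- tr
      }
    } else keep[i] <- TRUE
  }
  st$head_temp <- st$head_temp[keep]
  # confirmed lifecycle: terminate overdue tracks, retire their IDs
  keep <- logical(length(st$heads))
  for (i in seq_along(st$heads)) {
    tr <- st$heads[[i]]
    if (tr$time_since_update > tp$max_age) {
      pos <- track_center(tr)
      st$lost <- rbind(st$lost, data.frame(id = tr$id, x = pos[1],
                                           y = pos[2], frame = t))
    } else keep[i] <- TRUE
  }
  st$heads <- st$heads[keep]

  # ---- body stage ----------------------------------------------------------
  bb <- det_body_boxes(bodies, tp)
  stg <- associate_stage(st$bodies, st$body_temp, bb, tp)
  st$bodies <- stg$tracks; st$body_temp <- stg$temp
  for (m in stg$unmatched_dets) {
    st$body_temp[[length(st$body_temp) + 1L]] <-
      new_track("body", c(bodies$rx[m], bodies$ry[m]), tp$body_box_size, tp, t)
  }
  keep <- logical(length(st$body_temp))
  for (i in seq_along(st$body_temp)) {
    tr <- st$body_temp[[i]]
    if (!tr$matched && tr$time_since_update > tp$max_age) next
    if (tr$matched && tr$hits >= tp$min_hits) {
      tr$status <- "confirmed"
      st$bodies[[length(st$bodies) + 1L]] <- tr
    } else keep[i] <- TRUE
  }
  st$body_temp <- st$body_temp[keep]
  st$bodies <- Filter(function(tr) tr$time_since_update <= tp$max_age, st$bodies)
  # refresh omega on matched body tracks; keep bodies at fixed box size
  for (i in seq_along(st$bodies)) {
    tr <- st$bodies[[i]]
    tr$base_size <- tp$body_box_size
    if (tr$matched) tr$omega_last <- bodies$omega[tr$det_idx]
    st$bodies[[i]] <- tr
  }

  # ---- head-body pairing by co-location -----------------------------------
  # sticky: an established pairing survives as long as that head is still
  # matched and co-located, so a crossing fish cannot steal the body track
  head_ids <- vapply(st$heads, function(x) x$id, 0L)
  for (i in seq_along(st$bodies)) {
    tr <- st$bodies[[i]]
    if (!tr$matched) next
    box <- track_box(tr, tp)
    inbox <- vapply(st$heads, function(h) {
      p <- track_center(h)
      h$matched && p[1] >= box[1] && p[1] <= box[3] &&
        p[2] >= box[2] && p[2] <= box[4]
    }, TRUE)
    cand <- which(inbox)
    if (length(cand)) {
      cur <- if (!is.na(tr$paired_head_id))
        which(head_ids == tr$paired_head_id & inbox) else integer()
      j <- if (length(cur)) cur[1L] else {
        bp <- track_center(tr)
        d <- vapply(cand, function(j) sum((track_center(st$heads[[j]]) - bp)^2), 0)
        cand[which.min(d)]
      }
      tr$paired_head_id <- st$heads[[j]]$id
      tr$head_offset <- track_center(st$heads[[j]]) - track_center(tr)
      st$heads[[j]]$omega_last <- tr$omega_last
      st$bodies[[i]] <- tr
    }
  }

  # ---- duplicate-track hygiene --------------------------------------------
  # two confirmed head tracks converged onto the same fish: keep the one
  # that is currently associated (or fresher), retire the other
  if (length(st$heads) > 1L) {
    drop <- rep(FALSE, length(st$heads))
    for (i in seq_len(length(st$heads) - 1L)) {
      if (drop[i]) next
      for (j in (i + 1L):length(st$heads)) {
        if (drop[j]) next
        d <- sqrt(sum((track_center(st$heads[[i]]) -
                       track_center(st$heads[[j]]))^2))
        dv <- sqrt(sum((st$heads[[i]]$kf$x[3:4] - st$heads[[j]]$kf$x[3:4])^2))
        # same place AND same motion = duplicate; two fish passing each
        # other are close but move differently and must both survive
        if (d < 12 && dv < 2) {
          worse <- if (st$heads[[i]]$matched != st$heads[[j]]$matched) {
            if (st$heads[[i]]$matched) j else i
          } else if (st$heads[[i]]$time_since_update !=
                     st$heads[[j]]$time_since_update) {
            if (st$heads[[i]]$time_since_update >
                st$heads[[j]]$time_since_update) i else j
          } else if (st$heads[[i]]$hits >= st$heads[[j]]$hits) j else i
          drop[worse] <- TRUE
        }
      }
    }
    if (any(drop)) {
      for (i in which(drop)) {
        pos <- track_center(st$heads[[i]])
        st$lost <- rbind(st$lost, data.frame(id = st$heads[[i]]$id,
                                             x = pos[1], y = pos[2], frame = t))
      }
      st$heads <- st$heads[!drop]
    }
  }

  # ---- body-fallback head recovery + records ------------------------------
  body_pair_ids <- vapply(st$bodies, function(x) x$paired_head_id, 0L)
  head_ids_now <- vapply(st$heads, function(x) x$id, 0L)
  recs <- list()
  for (i in seq_along(st$heads)) {
    tr <- st$heads[[i]]
    prov <- "head_tracked"
    if (!tr$matched) {
      j <- which(body_pair_ids == tr$id &
                 vapply(st$bodies, function(x) isTRUE(x$matched), TRUE))
      if (length(j)) {
        j <- j[1L]
        bt <- st$bodies[[j]]
        # the head leads the body along the swimming direction; the stored
        # offset vector goes stale when the fish turns, so keep only its
        # magnitude and take the direction from the body track's velocity
        off <- bt$head_offset
        bv <- bt$kf$x[3:4]
        if (sqrt(sum(bv^2)) > 1.5)
          off <- sqrt(sum(off^2)) * bv / sqrt(sum(bv^2))
        z <- track_center(bt) + off
        # innovation gate: a recovery far from the prediction means the
        # paired body is not this fish (a stale pairing or a spurious
        # cluster); coasting on the motion model is safer
        if (sqrt(sum((z - track_center(tr))^2)) > 15) j <- integer()
        # reject a recovery that would land on top of another live head
        # track: that is a duplicate of a tracked fish, not an occluded one
        if (length(j)) {
          others <- vapply(st$heads[-i], function(h)
            h$matched && sqrt(sum((track_center(h) - z)^2)) < 12, TRUE)
          if (any(others)) j <- integer()
        }
      }
      if (length(j)) {
        # the recovered position is a weak, derived measurement: it holds
        # the track in place but never overwrites the head's own velocity
        vel <- tr$kf$x[3:4]
        tr$kf <- kf_update(tr$kf, z)
        tr$kf$x[3:4] <- vel
        tr$time_since_update <- 0L
        tr$hits <- tr$hits + 1L
        tr$omega_last <- st$bodies[[j]]$omega_last
        prov <- "body_fallback"
      } else {
        prov <- "coasted"
      }
      st$heads[[i]] <- tr
    }
    pos <- track_center(tr)
    # paired matched body point, if any, for the record
    bxy <- c(NA_real_, NA_real_)
    j <- which(body_pair_ids == tr$id &
               vapply(st$bodies, function(x) isTRUE(x$matched), TRUE))
    if (length(j)) bxy <- track_center(st$bodies[[j[1L]]])
    recs[[length(recs) + 1L]] <- data.frame(
      frame = t, id = tr$id, head_x = pos[1], head_y = pos[2],
      body_x = bxy[1], body_y = bxy[2], omega = tr$omega_last,
      provenance = prov, stringsAsFactors = FALSE)
  }
  out <- rbind_or_empty(recs, empty_trajectory())
  st$records[[length(st$records) + 1L]] <- out
  invisible(out)
}

empty_trajectory <- function() {
  data.frame(frame = integer(), id = integer(), head_x = numeric(),
             head_y = numeric(), body_x = numeric(), body_y = numeric(),
             omega = numeric(), provenance = character(),
             stringsAsFactors = FALSE)
}

#' Trajectory accumulated by a tracker
#'
#' @param st a `school_tracker`.
#' @return data.frame with columns `frame`, `id`, `head_x`, `head_y`,
#'   `body_x`, `body_y`, `omega`, `provenance`.
#' @export
tracker_trajectory <- function(st) {
  rbind_or_empty(st$records, empty_trajectory())
}

#' Track a full frame sequence
#'
#' Builds the background from the first `n_background` frames, then streams
#' every frame through [tracker_step()]. Strictly online: the output for
#' frame `t` depends only on frames `<= t` (plus the background).
#'
#' @param frames list of numeric matrices.
#' @param config a [pipeline_config()].
#' @param background optional precomputed background (skips the median).
#' @param verbose print per-frame counts.
#' @return trajectory data.frame (see [tracker_trajectory()]).
#' @export
track_frames <- function(frames, config = pipeline_config(),
                         background = NULL, verbose = FALSE) {
  if (is.null(background))
    background <- build_background(frames, config$segmentation$n_background)
  st <- tracker_create(config, background)
  for (t in seq_along(frames)) {
    rec <- tracker_step(st, frames[[t]])
    if (verbose)
      message(sprintf("frame %d: %d identities", t, nrow(rec)))
  }
  tracker_trajectory(st)
}
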