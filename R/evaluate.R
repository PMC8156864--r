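#' Detection precision and recall
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, as percentages.
#' Zero denominators yield `NA` (undefined).
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric `c(precision, recall)` in percent.
#' @export
precision_recall <- function(tp, fp, fn) {
  c(precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_)
}

#' Occlusion rate
#'
#' Occlusions per individual per frame:
#' `100 * n_occlusions / (n_individuals * n_frames)` (percent).
#'
#' @param n_occlusions,n_individuals,n_frames counts.
#' @return percentage.
#' @export
occlusion_rate <- function(n_occlusions, n_individuals, n_frames) {
  if (any(n_individuals <= 0) || any(n_frames <= 0)) stop("zero denominator")
  100 * n_occlusions / (n_individuals * n_frames)
}

#' Detection rate from occlusions
#'
#' Fraction of occlusion events in which every involved fish was still
#' detected, as a percentage; `NA` when there were no occlusions.
#'
#' @param n_correct,n_occlusions counts.
#' @return percentage.
#' @export
detection_rate_from_occlusions <- function(n_correct, n_occlusions) {
  if (n_occlusions <= 0) return(NA_real_)
  100 * n_correct / n_occlusions
}

#' Correct tracking ratio (CTR)
#'
#' Sum over targets of their correctly tracked frame counts, divided by
#' `n_individuals * n_frames`, as a percentage.
#'
#' @param correct_frames_per_target integer vector, one entry per target.
#' @param n_individuals,n_frames counts; `length(correct_frames_per_target)`
#'   must equal `n_individuals` and no entry may exceed `n_frames`.
#' @return percentage.
#' @export
ctr <- function(correct_frames_per_target, n_individuals, n_frames) {
  if (length(correct_frames_per_target) != n_individuals)
    stop("need one correct-frame count per individual")
  if (any(correct_frames_per_target > n_frames))
    stop("correct-frame count exceeds n_frames")
  100 * sum(correct_frames_per_target) / (n_individuals * n_frames)
}

#' Correct identification ratio (CIR)
#'
#' Fraction of occlusion events after which *every* involved fish carries
#' its pre-occlusion identity, as a percentage; `NA` when there were no
#' occlusions.
#'
#' @param n_all_correct_after_occlusion,n_occlusions counts.
#' @return percentage.
#' @export
cir <- function(n_all_correct_after_occlusion, n_occlusions) {
  if (n_occlusions <= 0) return(NA_real_)
  100 * n_all_correct_after_occlusion / n_occlusions
}

# occlusion events from truth flags: maximal runs of consecutive frames in
# which >= 2 fish are flagged occluded (fish sets of overlapping runs merged)
occlusion_events <- function(truth) {
  occ_frames <- sort(unique(truth$frame[truth$occluded]))
  if (length(occ_frames) == 0L)
    return(data.frame(start = integer(), end = integer(), fish = I(list())))
  runs <- split(occ_frames, cumsum(c(1L, diff(occ_frames) != 1L)))
  out <- lapply(runs, function(fr) {
    ids <- sort(unique(truth$id[truth$occluded & truth$frame %in% fr]))
    data.frame(start = min(fr), end = max(fr), fish = I(list(ids)))
  })
  do.call(rbind, out)
}

#' Match a predicted trajectory to ground truth
#'
#' Per frame, a minimum-cost matching (Hungarian, Euclidean distance
#' between predicted and truth head points) with pairs beyond `dist_max`
#' rejected. A truth fish's *established* predicted ID is the one matched at
#' its first matched frame; a frame counts as "correct" for CTR when the
#' fish is matched to that ID. Occlusion events are taken from the truth
#' occluded flags; each event's identity outcome is judged at the first
#' frame after the event at which every involved fish is matched.
#'
#' @param pred trajectory data.frame (`frame`, `id`, `head_x`, `head_y`).
#' @param truth ground-truth data.frame from [simulate_school()].
#' @param dist_max correctness radius in px (default: half the default
#'   fish length).
#' @param burn_in frames at the start excluded from the counts (tracker
#'   confirmation takes `min_hits` frames; default 0).
#' @return list with `counts` (tp, fp, fn), `correspondence` (data.frame
#'   `frame`, `truth_id`, `pred_id`, `dist`, `correct`), `per_target`
#'   (correct-frame counts), `events` (per occlusion event: frames, fish,
#'   `identities_kept`), `n_frames`, `n_individuals`.
#' @export
match_pred_to_truth <- function(pred, truth, dist_max = 35, burn_in = 0) {
  frames <- sort(unique(truth$frame))
  frames <- frames[frames > burn_in]
  ids <- sort(unique(truth$id))
  established <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  tp <- 0L; fp <- 0L; fn <- 0L
  corr <- list()
  for (t in frames) {
    tr <- truth[truth$frame == t, , drop = FALSE]
    pr <- pred[pred$frame == t, , drop = FALSE]
    if (nrow(pr) == 0L) { fn <- fn + nrow(tr); next }
    D <- outer(seq_len(nrow(tr)), seq_len(nrow(pr)), function(i, j)
      sqrt((tr$head_x[i] - pr$head_x[j])^2 + (tr$head_y[i] - pr$head_y[j])^2))
    D <- matrix(D, nrow(tr), nrow(pr))
    sol <- solve_assignment(D)
    m <- sol$matches[D[sol$matches] <= dist_max, , drop = FALSE]
    tp <- tp + nrow(m)
    fp <- fp + nrow(pr) - nrow(m)
    fn <- fn + nrow(tr) - nrow(m)
    if (nrow(m)) {
      tid <- tr$id[m[, 1L]]; pid <- pr$id[m[, 2L]]
      newly <- is.na(established[as.character(tid)])
      established[as.character(tid[newly])] <- pid[newly]
      corr[[length(corr) + 1L]] <- data.frame(
        frame = t, truth_id = tid, pred_id = pid, dist = D[m],
        correct = pid == established[as.character(tid)])
    }
  }
  corr <- rbind_or_empty(corr, data.frame(
    frame = integer(), truth_id = integer(), pred_id = integer(),
    dist = numeric(), correct = logical()))
  per_target <- vapply(ids, function(i)
    sum(corr$correct[corr$truth_id == i]), 0L)
  names(per_target) <- ids
  # occlusion-event identity outcomes
  ev <- occlusion_events(truth[truth$frame > burn_in, , drop = FALSE])
  kept <- rep(NA, nrow(ev)) # NA = no post-event frame to judge on
  for (e in seq_len(nrow(ev))) {
    fish <- ev$fish[[e]]
    pre <- vapply(fish, function(i) {
      h <- corr[corr$truth_id == i & corr$frame < ev$start[e], , drop = FALSE]
      if (nrow(h)) as.numeric(h$pred_id[nrow(h)]) else NA_real_
    }, 0)
    after <- sort(unique(corr$frame[corr$frame > ev$end[e]]))
    for (t in after) {
      sub <- corr[corr$frame == t & corr$truth_id %in% fish, , drop = FALSE]
      if (nrow(sub) == length(fish)) {
        kept[e] <- !anyNA(pre) &&
          all(sub$pred_id[match(fish, sub$truth_id)] == pre)
        break
      }
    }
  }
  ev$identities_kept <- kept
  list(counts = c(tp = tp, fp = fp, fn = fn),
       correspondence = corr, per_target = per_target, events = ev,
       n_frames = length(frames), n_individuals = length(ids))
}

#' Count identity switches
#'
#' Number of times a truth identity's matched predicted ID differs from its
#' previously matched predicted ID (standard MOT IDS).
#'
#' @param correspondence the `correspondence` data.frame from
#'   [match_pred_to_truth()].
#' @return integer.
#' @export
count_id_switches <- function(correspondence) {
  n <- 0L
  for (i in unique(correspondence$truth_id)) {
    p <- correspondence$pred_id[correspondence$truth_id == i]
    if (length(p) > 1L) n <- n + sum(p[-1L] != p[-length(p)])
  }
  n
}

# per-event detection outcome: TRUE when, in every frame of the event, each
# involved fish has at least one detection (head centre or body point)
# within dist_max of its truth head or body point
occlusion_detection_outcomes <- function(detections, truth, dist_max = 35) {
  ev <- occlusion_events(truth)
  ok <- logical(nrow(ev))
  heads <- detections$heads; bodies <- detections$bodies
  for (e in seq_len(nrow(ev))) {
    fish <- ev$fish[[e]]
    good <- TRUE
    for (t in ev$start[e]:ev$end[e]) {
      h <- heads[heads$t == t, , drop = FALSE]
      b <- bodies[bodies$t == t, , drop = FALSE]
      px <- c((h$x0 + h$x1) / 2, b$rx); py <- c((h$y0 + h$y1) / 2, b$ry)
      for (i in fish) {
        tr <- truth[truth$frame == t & truth$id == i, , drop = FALSE]
        d <- sqrt(pmin((px - tr$head_x)^2 + (py - tr$head_y)^2,
                       (px - tr$body_x)^2 + (py - tr$body_y)^2))
        if (!length(d) || min(d) > dist_max) { good <- FALSE; break }
      }
      if (!good) break
    }
    ok[e] <- good
  }
  ev$detected <- ok
  ev
}

#' Full evaluation report
#'
#' Computes precision, recall, occlusion rate, CTR, CIR and identity
#' switches from a predicted trajectory and ground truth; optionally the
#' detection rate from occlusions when raw per-frame detections are given.
#' Percentages are rounded to 2 decimals; raw counts are included.
#'
#' @inheritParams match_pred_to_truth
#' @param detections optional list with `heads` and `bodies` data.frames
#'   (concatenated [detect_frame()] outputs) for the occlusion detection
#'   rate.
#' @return list of class `eval_report`.
#' @export
evaluate_tracking <- function(pred, truth, dist_max = 35, burn_in = 0,
                              detections = NULL) {
  m <- match_pred_to_truth(pred, truth, dist_max, burn_in)
  pr <- precision_recall(m$counts[["tp"]], m$counts[["fp"]], m$counts[["fn"]])
  n_ev <- nrow(m$events)
  occ_rate <- occlusion_rate(n_ev, m$n_individuals, max(m$n_frames, 1L))
  det_rate <- NA_real_
  if (!is.null(detections)) {
    evd <- occlusion_detection_outcomes(detections, truth, dist_max)
    det_rate <- detection_rate_from_occlusions(sum(evd$detected), nrow(evd))
  }
  out <- list(
    precision = round(pr[["precision"]], 2),
    recall = round(pr[["recall"]], 2),
    occlusion_rate = round(occ_rate, 2),
    detection_rate_from_occlusions = round(det_rate, 2),
    ctr = round(ctr(m$per_target, m$n_individuals, m$n_frames), 2),
    cir = round(cir(sum(m$events$identities_kept, na.rm = TRUE),
                    sum(!is.na(m$events$identities_kept))), 2),
    ids = count_id_switches(m$correspondence),
    counts = m$counts, n_events = n_ev,
    matching = m)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Tracking evaluation\n")
  cat(sprintf("  precision: %s%%  recall: %s%%\n", x$precision, x$recall))
  cat(sprintf("  occlusion rate: %s%%  (%d events)\n", x$occlusion_rate, x$n_events))
  if (!is.na(x$detection_rate_from_occlusions))
    cat(sprintf("  detection rate from occlusions: %s%%\n",
                x$detection_rate_from_occlusions))
  cat(sprintf("  CTR: %s%%  CIR: %s%%  IDS: %d\n", x$ctr,
              ifelse(is.na(x$cir), "NA", x$cir), x$ids))
  invisible(x)
}
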