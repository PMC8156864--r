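# independent oracles used across tests

# exhaustive minimum-cost assignment for matrices up to ~7x7
brute_force_assignment <- function(C) {
  n <- nrow(C); m <- ncol(C)
  if (n <= m) {
    perms <- gtools_permutations(m, n)
    best <- Inf
    for (r in seq_len(nrow(perms))) {
      cost <- sum(C[cbind(seq_len(n), perms[r, ])])
      if (cost < best) best <- cost
    }
  } else {
    best <- brute_force_assignment(t(C))
  }
  best
}

# all k-permutations of 1..n, small n only
gtools_permutations <- function(n, k) {
  if (k == 0L) return(matrix(integer(), 1L, 0L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- gtools_permutations(n, k - 1L)
    rest <- matrix(setdiff(seq_len(n), i)[rest], nrow(rest), k - 1L)
    if (k == 1L) out <- rbind(out, matrix(i, 1L, 1L))
    else {
      sub <- gtools_permutations_exclude(n, k - 1L, i)
      out <- rbind(out, cbind(i, sub))
    }
  }
  out
}
gtools_permutations_exclude <- function(n, k, excl) {
  pool <- setdiff(seq_len(n), excl)
  if (k == 1L) return(matrix(pool, ncol = 1L))
  out <- NULL
  for (i in pool) {
    sub <- gtools_permutations_exclude(n, k - 1L, c(excl, i))
    out <- rbind(out, cbind(i, sub))
  }
  out
}

# recursive flood fill, 8-connected, for labeling equivalence checks
flood_fill_labels <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c))
    lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# DBSCAN by definition over a precomputed distance matrix
dbscan_by_definition <- function(D, eps, min_samples) {
  n <- nrow(D)
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbr) >= min_samples
  lab <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i]) || !core[i]) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      if (is.na(lab[q])) {
        lab[q] <- cl
        if (core[q]) queue <- c(queue, nbr[[q]][is.na(lab[nbr[[q]]])])
      }
    }
  }
  lab
}

# distance from point to the truth centerline polyline of a pose
dist_to_centerline <- function(p, cx, cy, heading, bend, len) {
  pts <- schooltrack:::fish_centerline(cx, cy, heading, bend, len)
  d <- Inf
  for (k in seq_len(nrow(pts) - 1L)) {
    a <- pts[k, ]; b <- pts[k + 1L, ]
    ab <- b - a; L2 <- sum(ab^2)
    tt <- min(1, max(0, sum((p - a) * ab) / L2))
    d <- min(d, sqrt(sum((p - a - tt * ab)^2)))
  }
  d
}

# render a lone fish on a plain background, with seeded noise
render_lone_fish <- function(heading, bend, seed, arena = c(240, 200),
                             noise_sd = 2, x = NULL, y = NULL) {
  set.seed(seed)
  if (is.null(x)) x <- arena[1] / 2
  if (is.null(y)) y <- arena[2] / 2
  pose <- list(x = x, y = y, heading = heading, bend = bend,
               length = 70, width = 12)
  canvas <- matrix(230, arena[2], arena[1])
  fr <- render_fish(pose, canvas)$canvas
  if (noise_sd > 0)
    fr <- pmin(pmax(fr + matrix(rnorm(length(fr), 0, noise_sd),
                                nrow(fr)), 0), 255)
  list(frame = fr, pose = pose,
       head = schooltrack:::fish_head_point(x, y, heading, 70, 12),
       background = matrix(230, arena[2], arena[1]))
}
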