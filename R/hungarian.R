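#' Minimum-cost rectangular assignment (Hungarian algorithm)
#'
#' Kuhn-Munkres in the O(n^3) potentials formulation. Rectangular matrices
#' are handled by padding to square with a large constant; padded matches are
#' dropped from the result, so the smaller side is matched injectively.
#'
#' @param C numeric cost matrix (rows = workers/trackers, cols = jobs/
#'   detections). May have zero rows or columns.
#' @return list with `matches` (two-column integer matrix of `(row, col)`
#'   pairs, ordered by row) and `cost` (sum of matched entries).
#' @export
solve_assignment <- function(C) {
  n <- nrow(C); m <- ncol(C)
  if (is.null(n) || n == 0L || m == 0L)
    return(list(matches = matrix(integer(), 0L, 2L), cost = 0))
  N <- max(n, m)
  big <- max(C[is.finite(C)], 0) + 1
  sq <- matrix(big, N, N)
  sq[seq_len(n), seq_len(m)] <- C
  # potentials method; 1-based translation of the classic implementation
  INF <- .Machine$double.xmax / 4
  u <- numeric(N + 1L); v <- numeric(N + 1L)
  p <- integer(N + 1L) # p[j]: row matched to column j (0 = none); p[N+1] workspace
  way <- integer(N + 1L)
  for (i in seq_len(N)) {
    p[N + 1L] <- i
    j0 <- N + 1L
    minv <- rep(INF, N + 1L)
    used <- rep(FALSE, N + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(N)) {
        if (!used[j]) {
          cur <- sq[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(N + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == N + 1L) break
    }
  }
  rows <- p[seq_len(N)]
  keep <- which(rows >= 1L & rows <= n & seq_len(N) <= m)
  matches <- cbind(row = rows[keep], col = keep)
  matches <- matches[order(matches[, 1L]), , drop = FALSE]
  list(matches = matches,
       cost = sum(C[matches]))
}
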