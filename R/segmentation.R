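#' Build a static background image by temporal median filtering
#'
#' Each output pixel is the per-pixel temporal median over the first `n`
#' frames. For even `n` the lower of the two central order statistics is
#' used, so integer inputs stay integer-exact.
#'
#' @param frames list of numeric matrices, all the same shape.
#' @param n number of frames to use (default: all supplied).
#' @return numeric matrix, the background image.
#' @export
build_background <- function(frames, n = length(frames)) {
  if (length(frames) == 0L) stop("'frames' is empty")
  n <- min(as.integer(n), length(frames))
  if (n < 1L) stop("'n' must be >= 1")
  dims <- dim(frames[[1L]])
  if (!all(vapply(frames[seq_len(n)], function(f) identical(dim(f), dims), TRUE)))
    stop("all frames must have the same shape")
  m <- vapply(frames[seq_len(n)], as.vector, numeric(prod(dims)))
  m <- matrix(m, nrow = prod(dims), ncol = n)
  if (n == 1L) return(matrix(m, dims[1L], dims[2L]))
  k <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L # lower median
  med <- apply(m, 1L, function(v) sort.int(v, partial = k)[k])
  matrix(med, dims[1L], dims[2L])
}

#' Segment moving blobs by background differencing
#'
#' Foreground is `abs(background - frame) > diff_threshold`; 8-connected
#' components with pixel count inside `[area_min, area_max]` become blobs.
#' Blob indices are assigned in raster order (top-left corner: first by `y`,
#' then by `x`).
#'
#' @param frame,background numeric matrices of the same shape.
#' @param diff_threshold intensity difference threshold (default 25, about
#'   10\% of the 8-bit range).
#' @param area_min,area_max inclusive component-size bounds in pixels.
#' @param t frame index stored on the returned blobs (default `NA`).
#' @return list of `blob` objects; each has fields `t`, `i`,
#'   `box = c(x, y, w, h)` (0-based top-left, half-open), `pixels` (two-column
#'   matrix of 0-based `(x, y)` foreground coordinates) and `patch` (the
#'   grayscale sub-image of `frame` over the box).
#' @export
segment_blobs <- function(frame, background, diff_threshold = 25,
                          area_min = 100, area_max = 5000, t = NA_integer_) {
  if (!identical(dim(frame), dim(background)))
    stop("'frame' and 'background' must have the same shape")
  if (!(area_min > 0 && area_min < area_max))
    stop("need 0 < area_min < area_max")
  mask <- abs(background - frame) > diff_threshold
  lab <- label_components8(mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0L) return(list())
  blobs <- list()
  for (id in ids) {
    w <- which(lab == id, arr.ind = TRUE)
    if (nrow(w) < area_min || nrow(w) > area_max) next
    x <- w[, 2L] - 1L; y <- w[, 1L] - 1L
    x0 <- min(x); y0 <- min(y)
    box <- c(x = x0, y = y0, w = max(x) - x0 + 1L, h = max(y) - y0 + 1L)
    blobs[[length(blobs) + 1L]] <- structure(
      list(t = t, i = NA_integer_, box = box,
           pixels = cbind(x = x, y = y),
           patch = frame[(y0 + 1L):(y0 + box[["h"]]),
                         (x0 + 1L):(x0 + box[["w"]]), drop = FALSE]),
      class = "blob")
  }
  if (length(blobs) == 0L) return(list())
  ord <- order(vapply(blobs, function(b) b$box[["y"]], 0),
               vapply(blobs, function(b) b$box[["x"]], 0))
  blobs <- blobs[ord]
  for (i in seq_along(blobs)) blobs[[i]]$i <- i
  blobs
}

# 8-connected component labeling (compiled two-pass union-find)
label_components8 <- function(mask) {
  label8(mask & TRUE)
}
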