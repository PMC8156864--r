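#' Read an ordered sequence of grayscale frames
#'
#' `path` may be a directory of numbered PNG/TIFF images (read in filename
#' order) or a character vector of image files. Colour images are converted
#' to grayscale by the standard luma weighting
#' `0.299 R + 0.587 G + 0.114 B`. Intensities are returned on the 0-255
#' scale. Video containers (AVI/MP4) are not supported; export the video as
#' an image sequence first.
#'
#' @param path directory or vector of image file paths.
#' @return list of numeric matrices.
#' @export
read_frames <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    f <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                    full.names = TRUE)
    sort(f)
  } else path
  if (any(grepl("\\.(avi|mp4|mov|mkv)$", files, ignore.case = TRUE)))
    stop("video containers are not supported; supply a directory of ",
         "numbered PNG/TIFF frames instead")
  files <- files[file.exists(files)]
  if (length(files) == 0L) stop("no image frames found in ", path)
  frames <- lapply(files, read_gray_image)
  dims <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), TRUE)))
    stop("frames have inconsistent shapes")
  frames
}

read_gray_image <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
  else tiff::readTIFF(file)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    img <- if (nch >= 3L)
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    else img[, , 1L]
  }
  img * 255
}

#' Write frames as a zero-padded numbered PNG sequence
#'
#' @param frames list of numeric matrices (0-255).
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return character vector of files written, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame_") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, sprintf("%s%06d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames))
    png::writePNG(pmin(pmax(frames[[i]] / 255, 0), 1), files[i])
  invisible(files)
}

#' Write / read a trajectory CSV
#'
#' Columns `frame`, `id`, `head_x`, `head_y`, `body_x`, `body_y`, `omega`,
#' `provenance`; numeric columns keep 17 significant digits so the file
#' round-trips losslessly.
#'
#' @param traj trajectory data.frame from [track_frames()].
#' @param path file path.
#' @return `read_trajectory` returns the data.frame; `write_trajectory`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- traj
  for (cl in c("head_x", "head_y", "body_x", "body_y", "omega"))
    out[[cl]] <- ifelse(is.na(traj[[cl]]), "",
                        trimws(formatC(traj[[cl]], digits = 17, format = "g")))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path, colClasses = c(
    frame = "integer", id = "integer", head_x = "numeric", head_y = "numeric",
    body_x = "numeric", body_y = "numeric", omega = "numeric",
    provenance = "character"))
  d
}

#' Write / read a detections CSV
#'
#' Long format with a `kind` column: head rows carry the box corners
#' (`x0`, `y0`, `x1`, `y1`), body rows carry the body point and motion state
#' (`rx`, `ry`, `omega`); the other columns are empty.
#'
#' @param detections list with `heads` and `bodies` data.frames.
#' @param path file path.
#' @return `read_detections` returns the list; `write_detections` returns
#'   `path` invisibly.
#' @export
write_detections <- function(detections, path) {
  h <- detections$heads; b <- detections$bodies
  fmt <- function(x) ifelse(is.na(x), "", trimws(formatC(x, digits = 17, format = "g")))
  rows <- rbind(
    if (nrow(h)) data.frame(frame = h$t, kind = "head", x0 = fmt(h$x0),
                            y0 = fmt(h$y0), x1 = fmt(h$x1), y1 = fmt(h$y1),
                            rx = "", ry = "", omega = ""),
    if (nrow(b)) data.frame(frame = b$t, kind = "body", x0 = "", y0 = "",
                            x1 = "", y1 = "", rx = fmt(b$rx), ry = fmt(b$ry),
                            omega = fmt(b$omega)))
  if (is.null(rows))
    rows <- data.frame(frame = integer(), kind = character(), x0 = character(),
                       y0 = character(), x1 = character(), y1 = character(),
                       rx = character(), ry = character(), omega = character())
  rows <- rows[order(rows$frame, rows$kind), , drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  num <- function(x) suppressWarnings(as.numeric(x))
  h <- d[d$kind == "head", , drop = FALSE]
  b <- d[d$kind == "body", , drop = FALSE]
  list(heads = data.frame(t = as.integer(h$frame), x0 = num(h$x0),
                          y0 = num(h$y0), x1 = num(h$x1), y1 = num(h$y1),
                          area = NA_real_),
       bodies = data.frame(t = as.integer(b$frame), rx = num(b$rx),
                           ry = num(b$ry), omega = num(b$omega),
                           n_lines = NA_integer_))
}
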