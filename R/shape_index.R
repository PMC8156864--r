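#' Gaussian second-derivative (Hessian) responses of an image
#'
#' Convolves an image with the three second-order derivatives of an isotropic
#' Gaussian of standard deviation `sigma`, yielding the scale-space Hessian
#' field \eqn{(L_{xx}, L_{xy}, L_{yy})}. Coordinates follow the package
#' convention: origin at the top-left pixel, `x` rightward (columns), `y`
#' downward (rows), 0-based. Kernels are truncated at `4 * sigma`; image
#' boundaries are handled by reflection.
#'
#' @param image numeric matrix (rows = y, cols = x), any intensity scale.
#' @param sigma Gaussian scale in pixels, `> 0`.
#' @return an object of class `hessian_field`: list with image-shaped
#'   matrices `Lxx`, `Lxy`, `Lyy` and the scalar `sigma`.
#' @examples
#' h <- hessian_response(matrix(outer(1:32, 1:32, function(y, x) x^2), 32), 2)
#' h$Lxx[16, 16] # ~2: second derivative of x^2
#' @export
hessian_response <- function(image, sigma) {
  if (!is.matrix(image) || length(image) < 1L)
    stop("'image' must be a non-empty numeric matrix")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single value > 0")
  k <- gauss_deriv_kernels(sigma)
  # x = columns, y = rows; separable compiled correlation, reflect boundary
  out <- list(
    Lxx = sep_conv2_reflect(image, k$g0, k$g2),
    Lyy = sep_conv2_reflect(image, k$g2, k$g0),
    Lxy = sep_conv2_reflect(image, k$g1, k$g1),
    sigma = sigma
  )
  class(out) <- "hessian_field"
  out
}

# 1-D Gaussian and its first/second derivative kernels, truncated at 4*sigma.
gauss_deriv_kernels <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g1 <- g1 / sum(-x * g1) # response to f(x) = x is exactly 1
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - g * sum(g2) # zero response to constants despite truncation
  g2 <- g2 * (2 / sum(x^2 * g2)) # response to f(x) = x^2 is exactly 2
  list(g0 = g, g1 = g1, g2 = g2, r = r)
}

# Reflect-pad a matrix by r rows/cols on each side (edge pixel not repeated
# when the matrix is large enough; degenerates gracefully for tiny inputs).
reflect_pad <- function(m, r) {
  n <- nrow(m); p <- ncol(m)
  ref_idx <- function(len) {
    i <- c(rev(seq_len(min(r, len))), seq_len(len),
           rev(seq_len(len))[seq_len(min(r, len))])
    # if len < r, cycle the reflection
    while (length(i) < len + 2L * r) i <- c(i[1L], i, i[length(i)])
    i
  }
  m[ref_idx(n), ref_idx(p), drop = FALSE]
}

#' Eigenvalues of a Hessian field
#'
#' Pointwise eigenvalues of the 2x2 Hessian, ordered `K1 >= K2`:
#' \deqn{K_{1,2} = \frac{L_{xx}+L_{yy} \pm \sqrt{(L_{xx}-L_{yy})^2 + 4L_{xy}^2}}{2}}
#'
#' @param field a `hessian_field` from [hessian_response()], or a list with
#'   matrices `Lxx`, `Lxy`, `Lyy`.
#' @return list with matrices `K1`, `K2` (`K1 >= K2` everywhere).
#' @export
hessian_eigenvalues <- function(field) {
  tr <- field$Lxx + field$Lyy
  disc <- sqrt((field$Lxx - field$Lyy)^2 + 4 * field$Lxy^2)
  list(K1 = (tr + disc) / 2, K2 = (tr - disc) / 2)
}

#' Shape index from Hessian eigenvalues
#'
#' Maps local second-order intensity geometry to a single value in
#' \eqn{[-1, 1]}: \eqn{s = (2/\pi)\,\arctan\!\big((K_2+K_1)/(K_2-K_1)\big)}
#' with \eqn{K_1 \ge K_2}. Umbilic points (`K1 == K2 != 0`) take the
#' directional limit `-sign(K1)` (a dark local minimum, both curvatures
#' positive, maps to -1); flat points (`K1 == K2 == 0`) are undefined and
#' returned as `NA`.
#'
#' @param K1,K2 eigenvalue matrices with `K1 >= K2` pointwise.
#' @return matrix of shape-index values in `[-1, 1]`, `NA` where undefined.
#' @export
shape_index <- function(K1, K2) {
  if (any(K1 < K2, na.rm = TRUE)) stop("'K1' must be >= 'K2' pointwise")
  s <- matrix(NA_real_, nrow(K1), ncol(K1))
  nz <- (K1 - K2) > 0
  s[nz] <- (2 / pi) * atan((K2[nz] + K1[nz]) / (K2[nz] - K1[nz]))
  umb <- !nz & (K1 != 0)
  s[umb] <- -sign(K1[umb])
  s
}

#' Shape-index category table
#'
#' The nine Koenderink surface-type categories partitioning \eqn{[-1, 1]}.
#' Intervals are closed on the left and open on the right, except the last
#' which is closed on both sides.
#'
#' @return data.frame with columns `category`, `lo`, `hi`.
#' @export
shape_category_table <- function() {
  data.frame(
    category = c("spherical cup", "trough", "rut", "saddle rut", "saddle",
                 "saddle ridge", "ridge", "dome", "spherical cap"),
    lo = c(-8, -7, -5, -3, -1, 1, 3, 5, 7) / 8,
    hi = c(-7, -5, -3, -1, 1, 3, 5, 7, 8) / 8,
    stringsAsFactors = FALSE
  )
}

#' Classify shape-index values into the nine curvature categories
#'
#' @param s matrix (or vector) of shape-index values in `[-1, 1]`; `NA`
#'   (undefined) stays `NA`.
#' @return factor (same shape as a vector, or a matrix-backed factor) with
#'   levels given by [shape_category_table()]. For a matrix input a
#'   character matrix is returned to preserve the shape.
#' @export
classify_shape_category <- function(s) {
  tab <- shape_category_table()
  v <- as.vector(s)
  if (any(v < -1 - 1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    stop("shape-index values must lie in [-1, 1]")
  idx <- findInterval(pmin(pmax(v, -1), 1), tab$lo, rightmost.closed = TRUE)
  out <- tab$category[idx]
  out[is.na(v)] <- NA_character_
  if (is.matrix(s)) matrix(out, nrow(s), ncol(s)) else
    factor(out, levels = tab$category)
}

#' Full shape-index map of an image at one scale
#'
#' Convenience composition of [hessian_response()], [hessian_eigenvalues()],
#' [shape_index()] and [classify_shape_category()].
#'
#' @inheritParams hessian_response
#' @return object of class `shape_index_map`: list with `s`, `K1`, `K2`,
#'   `category` (character matrix), `sigma`.
#' @export
shape_index_map <- function(image, sigma) {
  H <- hessian_response(image, sigma)
  ev <- hessian_eigenvalues(H)
  s <- shape_index(ev$K1, ev$K2)
  out <- list(s = s, K1 = ev$K1, K2 = ev$K2,
              category = classify_shape_category(s),
              Lxx = H$Lxx, Lxy = H$Lxy, Lyy = H$Lyy, sigma = sigma)
  class(out) <- "shape_index_map"
  out
}
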