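# Shared low-level image primitives.
#
# Convention used throughout the package: images are numeric matrices with
# row = y (increasing downward) and column = x (increasing rightward);
# intensities are normalized to [0, 1]; pixel coordinates are 1-based with
# the center of pixel (r, c) at (x = c, y = r); angles are in degrees,
# measured from the +x axis toward +y.

#' Bilinear sampling of an image at fractional coordinates
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of sample coordinates (x = column, y = row).
#' @param fill value returned for samples outside the image.
#' @return numeric vector of sampled values, same length as `x`.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  inside <- x >= 1 & x <= w & y >= 1 & y <= h
  x0 <- pmin.int(pmax.int(floor(x), 1), w)
  y0 <- pmin.int(pmax.int(floor(y), 1), h)
  x1 <- pmin.int(x0 + 1, w)
  y1 <- pmin.int(y0 + 1, h)
  fx <- pmin.int(pmax.int(x - x0, 0), 1)
  fy <- pmin.int(pmax.int(y - y0, 0), 1)
  v <- (1 - fx) * (1 - fy) * img[cbind(y0, x0)] +
    fx * (1 - fy) * img[cbind(y0, x1)] +
    (1 - fx) * fy * img[cbind(y1, x0)] +
    fx * fy * img[cbind(y1, x1)]
  v[!inside] <- fill
  v
}

#' Rigid warp (rotation + translation) with bilinear interpolation
#'
#' Applies the forward map `p' = R(p - center) + center + translation` to the
#' image content, i.e. content at `p` moves to `p'`. Out-of-frame samples are
#' set to `fill`. When `angle_deg` and `translation` are both zero the input
#' is returned unchanged (exact, no resampling).
#'
#' @param img numeric matrix.
#' @param angle_deg rotation angle in degrees (+x toward +y).
#' @param translation length-2 numeric `(tx, ty)` in pixels.
#' @param center length-2 numeric `(cx, cy)` rotation center; defaults to the
#'   image center.
#' @param fill border fill value.
#' @return warped matrix of the same dimensions.
#' @export
warp_rigid <- function(img, angle_deg = 0, translation = c(0, 0),
                       center = NULL, fill = 0) {
  stopifnot(is.matrix(img), length(translation) == 2)
  if (angle_deg == 0 && all(translation == 0)) {
    return(img)
  }
  h <- nrow(img)
  w <- ncol(img)
  if (is.null(center)) center <- c((w + 1) / 2, (h + 1) / 2)
  a <- angle_deg * pi / 180
  xo <- rep(seq_len(w), each = h)
  yo <- rep.int(seq_len(h), w)
  # invert the forward map: p = R^T (p' - center - t) + center
  dx <- xo - center[1] - translation[1]
  dy <- yo - center[2] - translation[2]
  xs <- cos(a) * dx + sin(a) * dy + center[1]
  ys <- -sin(a) * dx + cos(a) * dy + center[2]
  matrix(bilinear_sample(img, xs, ys, fill = fill), h, w)
}

#' Label connected components with 8-connectivity
#'
#' `EBImage::bwlabel()` labels 4-connected components; this wrapper merges
#' labels that touch diagonally so that the result is 8-connected.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) {
    return(lab)
  }
  h <- nrow(lab)
  w <- ncol(lab)
  # label pairs adjacent along the two diagonals
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) == 0L) {
    return(lab)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1])
    rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' 2x2 median filter
#'
#' Sliding 2x2 window anchored at the top-left pixel; the median of four
#' values is the mean of the two middle order statistics. The last row and
#' column are handled by edge replication, so output dimensions equal input
#' dimensions. Idempotent on constant images and never widens the value
#' range.
#'
#' @param m numeric matrix.
#' @return filtered matrix, same dimensions.
#' @export
median_filter_2x2 <- function(m) {
  stopifnot(is.matrix(m))
  h <- nrow(m)
  w <- ncol(m)
  mp <- m[c(seq_len(h), h), , drop = FALSE][, c(seq_len(w), w), drop = FALSE]
  a <- mp[1:h, 1:w, drop = FALSE]
  b <- mp[1:h + 1, 1:w, drop = FALSE]
  d <- mp[1:h, 1:w + 1, drop = FALSE]
  e <- mp[1:h + 1, 1:w + 1, drop = FALSE]
  # median of 4 = (sum - min - max) / 2
  (a + b + d + e - pmin(a, b, d, e) - pmax(a, b, d, e)) / 2
}

#' Local variance in a square window
#'
#' @param img numeric matrix.
#' @param size odd window side length.
#' @return matrix of per-pixel variances (replicated borders).
#' @keywords internal
local_variance <- function(img, size = 5) {
  stopifnot(size %% 2 == 1)
  k <- matrix(1 / size^2, size, size)
  mu <- EBImage::filter2(img, k, boundary = "replicate")
  mu2 <- EBImage::filter2(img^2, k, boundary = "replicate")
  pmax(mu2 - mu^2, 0)
}
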