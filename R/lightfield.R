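# Light-field decoding, shift-and-add refocusing, depth-index mapping, and
# lateral/axial spatial-temporal maps for volumetric imaging.

#' Encode a 4D light field into a raw lenslet mosaic
#'
#' Each lenslet occupies a `pitch x pitch` block of the mosaic holding its
#' angular samples.
#'
#' @param lf 4D array `[u, v, y, x]`.
#' @param grid a [lenslet_grid()].
#' @return raw mosaic matrix of size `(ny * pitch) x (nx * pitch)`.
#' @export
encode_lightfield <- function(lf, grid) {
  p <- grid$pitch
  ny <- grid$n_lenslets[1]
  nx <- grid$n_lenslets[2]
  stopifnot(identical(dim(lf), as.integer(c(p, p, ny, nx))))
  raw <- matrix(0, ny * p, nx * p)
  for (ui in seq_len(p)) {
    for (vi in seq_len(p)) {
      raw[seq.int(ui, ny * p, by = p), seq.int(vi, nx * p, by = p)] <-
        lf[ui, vi, , ]
    }
  }
  raw
}

#' Decode a raw lenslet mosaic into sub-aperture images
#'
#' @param raw mosaic matrix whose dimensions are multiples of the grid
#'   pitch.
#' @param grid a [lenslet_grid()].
#' @return object of class `light_field`: list with `lf` (4D array
#'   `[u, v, y, x]`) and `grid`.
#' @export
decode_lightfield <- function(raw, grid) {
  p <- grid$pitch
  if (nrow(raw) %% p != 0 || ncol(raw) %% p != 0) {
    stop(sprintf(
      "raw size %dx%d not divisible by pitch %d (measured pitch ~ %.2f)",
      nrow(raw), ncol(raw), p, nrow(raw) / round(nrow(raw) / p)))
  }
  ny <- nrow(raw) %/% p
  nx <- ncol(raw) %/% p
  if (!all(grid$n_lenslets == c(ny, nx))) {
    grid$n_lenslets <- as.integer(c(ny, nx))
  }
  lf <- array(0, dim = c(p, p, ny, nx))
  for (ui in seq_len(p)) {
    for (vi in seq_len(p)) {
      lf[ui, vi, , ] <- raw[seq.int(ui, ny * p, by = p),
                            seq.int(vi, nx * p, by = p)]
    }
  }
  structure(list(lf = lf, grid = grid), class = "light_field")
}

as_lf_array <- function(lf) {
  if (inherits(lf, "light_field")) lf$lf else lf
}

#' Shift-and-add refocusing at one slope
#'
#' Each sub-aperture image is shifted by `-slope * (du, dv)` lenslets
#' (subpixel bilinear interpolation) and the shifted images are averaged.
#' At slope 0 this is exactly the plain sub-aperture mean.
#'
#' @param lf a `light_field` or 4D array `[u, v, y, x]`.
#' @param slope refocusing slope, lenslets of shift per angular index.
#' @return refocused matrix (`ny x nx`).
#' @export
refocus <- function(lf, slope) {
  grid_dims <- dim(as_lf_array(lf))
  a <- as_lf_array(lf)
  p <- grid_dims[1]
  ny <- grid_dims[3]
  nx <- grid_dims[4]
  half <- (p - 1) / 2
  if (abs(slope) * half >= max(ny, nx)) {
    stop("slope shifts exceed the lenslet grid size")
  }
  acc <- matrix(0, ny, nx)
  for (ui in seq_len(p)) {
    for (vi in seq_len(p)) {
      du <- ui - 1 - half
      dv <- vi - 1 - half
      sub <- a[ui, vi, , ]
      dim(sub) <- c(ny, nx)
      acc <- acc + warp_rigid(sub, angle_deg = 0,
                              translation = c(-slope * du, -slope * dv),
                              fill = 0)
    }
  }
  acc / p^2
}

#' Refocus a light field over a set of depths
#'
#' Depths are converted to slopes through the grid's `slope_per_mm`
#' calibration.
#'
#' @param lf a `light_field` or 4D array.
#' @param depths strictly monotonic numeric vector, mm.
#' @param grid a [lenslet_grid()] (taken from `lf` if absent).
#' @return object of class `focal_stack`: 3D array `[y, x, depth]` with
#'   attributes `depths` (mm) and `slopes`.
#' @export
focal_stack <- function(lf, depths, grid = NULL) {
  if (inherits(lf, "light_field")) grid <- grid %||% lf$grid
  if (is.null(grid)) stop("a lenslet_grid is required")
  stopifnot(length(depths) >= 1)
  if (length(depths) > 1 && !(all(diff(depths) > 0) ||
                              all(diff(depths) < 0))) {
    stop("depths must be strictly monotonic")
  }
  slopes <- depths * grid$slope_per_mm
  a <- as_lf_array(lf)
  slices <- array(0, dim = c(dim(a)[3], dim(a)[4], length(depths)))
  for (i in seq_along(depths)) {
    slices[, , i] <- refocus(a, slopes[i])
  }
  structure(slices, depths = depths, slopes = slopes,
            class = c("focal_stack", "array"))
}

#' Per-pixel best-focus depth from a focal stack
#'
#' The per-slice sharpness functional is the local variance of absorbance
#' in a 5x5 window; each pixel gets the depth of the slice maximizing it.
#' Confidence is the peak-to-mean sharpness ratio across slices; pixels
#' below `min_confidence` are masked (`NA`).
#'
#' @param stack a [focal_stack()] with >= 2 slices (a single slice returns
#'   a constant, degenerate-flagged map).
#' @param window sharpness window side (odd).
#' @param min_confidence mask threshold on peak/mean sharpness.
#' @return object of class `depth_index_map`: list with `depth` (matrix,
#'   mm, `NA` where masked), `confidence` (matrix), `degenerate` flag.
#' @export
depth_index_map <- function(stack, window = 5, min_confidence = 2) {
  depths <- attr(stack, "depths")
  nz <- dim(stack)[3]
  if (nz < 2) {
    return(structure(list(
      depth = matrix(depths[1], dim(stack)[1], dim(stack)[2]),
      confidence = matrix(0, dim(stack)[1], dim(stack)[2]),
      degenerate = TRUE), class = "depth_index_map"))
  }
  sharp <- array(0, dim = dim(stack))
  for (i in seq_len(nz)) {
    sharp[, , i] <- local_variance(stack[, , i], size = window)
  }
  best <- apply(sharp, c(1, 2), which.max)
  peak <- apply(sharp, c(1, 2), max)
  avg <- apply(sharp, c(1, 2), mean)
  conf <- ifelse(avg > 0, peak / avg, 0)
  conf[peak < 1e-10] <- 0     # structure-free: numerically zero sharpness
  depth <- matrix(depths[best], nrow(best), ncol(best))
  depth[conf < min_confidence] <- NA_real_
  structure(list(depth = depth, confidence = conf, degenerate = FALSE),
            class = "depth_index_map")
}

#' Lateral and axial spatial-temporal maps from a focal-stack sequence
#'
#' The lateral map runs the standard kymograph reduction on the best-focus
#' slice (determined from the first stack's depth index at the curve);
#' the axial map samples each centerline point's profile along the depth
#' axis instead of along the in-plane normal, with the identical
#' Otsu-threshold-and-average reduction.
#'
#' @param stacks list of [focal_stack()]s, one per time point, sharing
#'   depth axes.
#' @param curve a [resample_curve_with_normals()] result on the reference
#'   slice (coordinates in lenslet units).
#' @param frame_rate time-point rate, Hz.
#' @param min_confidence required depth-index confidence at the curve.
#' @param ... passed to [build_st_map()].
#' @return list with `lateral` and `axial` `st_map`s and `reference_depth`
#'   (mm).
#' @export
axial_st_map <- function(stacks, curve, frame_rate, min_confidence = 1.2,
                         ...) {
  stopifnot(length(stacks) >= 1, inherits(curve, "centerline_curve"))
  depths <- attr(stacks[[1]], "depths")
  dmap <- depth_index_map(stacks[[1]], min_confidence = 0)
  pts <- round(curve$points)
  conf <- dmap$confidence[cbind(pts[, 2], pts[, 1])]
  if (stats::median(conf) < min_confidence) {
    stop("curve lies off any best-focus slice (low depth confidence)")
  }
  zref <- stats::median(dmap$depth[cbind(pts[, 2], pts[, 1])], na.rm = TRUE)
  zi <- which.min(abs(depths - zref))
  nt <- length(stacks)
  L <- curve$normal_length
  offsets <- seq(-L / 2, L / 2, by = 1)
  m <- nrow(curve$points)
  xs <- outer(curve$points[, 1], rep(1, length(offsets))) +
    outer(curve$normals[, 1], offsets)
  ys <- outer(curve$points[, 2], rep(1, length(offsets))) +
    outer(curve$normals[, 2], offsets)
  P_lat <- array(0, dim = c(m, length(offsets), nt))
  nz <- length(depths)
  P_ax <- array(0, dim = c(m, nz, nt))
  for (k in seq_len(nt)) {
    sl <- stacks[[k]][, , zi]
    dim(sl) <- dim(stacks[[k]])[1:2]
    P_lat[, , k] <- bilinear_sample(sl, as.vector(xs), as.vector(ys))
    for (z in seq_len(nz)) {
      slz <- stacks[[k]][, , z]
      dim(slz) <- dim(stacks[[k]])[1:2]
      P_ax[, z, k] <- bilinear_sample(slz, curve$points[, 1],
                                      curve$points[, 2])
    }
  }
  attr(P_lat, "frame_rate") <- frame_rate
  attr(P_ax, "frame_rate") <- frame_rate
  list(lateral = build_st_map(P_lat, ...),
       axial = build_st_map(P_ax, ...),
       reference_depth = depths[zi])
}
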