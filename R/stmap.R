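# Spatial-temporal (kymograph) mapping along a curved intestine centerline.

#' Contrast-limited adaptive histogram equalization of all frames
#'
#' @param video a [video_stack()] (registered).
#' @param nx,ny CLAHE tile grid (default 8 x 8).
#' @param limit CLAHE clip limit in `EBImage::clahe()`'s multiplicative
#'   convention.
#' @param bins histogram bins.
#' @return enhanced [video_stack()], values clipped to [0, 1].
#' @export
enhance_frames <- function(video, nx = 8, ny = 8, limit = 2, bins = 256) {
  nt <- n_frames(video)
  out <- array(0, dim = dim(video))
  for (i in seq_len(nt)) {
    f <- get_frame(video, i)
    rng <- range(f)
    if (rng[2] - rng[1] < 1e-12) {
      out[, , i] <- f          # constant frame: nothing to equalize
    } else {
      e <- EBImage::clahe(f, nx = nx, ny = ny, bins = bins, limit = limit)
      out[, , i] <- pmin(pmax(as.matrix(e), 0), 1)
    }
  }
  video_stack(out, frame_rate = attr(video, "frame_rate"),
              pixel_pitch = attr(video, "pixel_pitch"),
              timestamps = attr(video, "timestamps"))
}

#' Minimal amplitude projection (MAP)
#'
#' Per-pixel minimum across the stack's third dimension: across frames for a
#' video (temporal MAP) or across depth slices for a focal stack (axial
#' MAP).
#'
#' @param stack a [video_stack()] or any 3D array.
#' @return numeric matrix of per-pixel minima.
#' @export
minimal_amplitude_projection <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  out <- stack[, , 1]
  dim(out) <- dim(stack)[1:2]
  n <- dim(stack)[3]
  if (n > 1) {
    for (i in 2:n) {
      f <- stack[, , i]
      dim(f) <- dim(out)
      out <- pmin(out, f)
    }
  }
  out
}

#' Resample a drawn centerline and attach unit normals
#'
#' The raw curve is resampled to ~1 px arc-length spacing; tangents come
#' from central differences and each normal is the tangent rotated +90
#' degrees. All normals share the same length `normal_length`, which must
#' fully cover the intestine cross-section.
#'
#' @param raw_points `n x 2` matrix of (x, y) px, `n >= 2`.
#' @param normal_length profile length L in px.
#' @param spacing resample spacing in px.
#' @return object of class `centerline_curve`: list with `points` (m x 2),
#'   `normals` (m x 2, unit), `normal_length`, `spacing`, `arclength_px`.
#' @export
resample_curve_with_normals <- function(raw_points, normal_length,
                                        spacing = 1) {
  stopifnot(is.matrix(raw_points) || is.data.frame(raw_points))
  raw_points <- as.matrix(raw_points)[, 1:2, drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(raw_points))) > 1e-12)
  raw_points <- raw_points[keep, , drop = FALSE]
  if (nrow(raw_points) < 2) {
    stop("centerline needs at least 2 distinct points")
  }
  stopifnot(normal_length > 0, spacing > 0)
  seg <- sqrt(rowSums(diff(raw_points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  si <- seq(0, total, by = spacing)
  if (si[length(si)] < total) si <- c(si, total)
  px <- stats::approx(s, raw_points[, 1], xout = si)$y
  py <- stats::approx(s, raw_points[, 2], xout = si)$y
  m <- length(si)
  tx <- c(px[2] - px[1], (px[-(1:2)] - px[seq_len(m - 2)]) / 2,
          px[m] - px[m - 1])
  ty <- c(py[2] - py[1], (py[-(1:2)] - py[seq_len(m - 2)]) / 2,
          py[m] - py[m - 1])
  nrm <- sqrt(tx^2 + ty^2)
  tx <- tx / nrm
  ty <- ty / nrm
  structure(list(points = cbind(x = px, y = py),
                 normals = cbind(x = -ty, y = tx),
                 normal_length = normal_length,
                 spacing = spacing,
                 arclength_px = si),
            class = "centerline_curve")
}

#' Extract cross-sectional profiles along the centerline normals
#'
#' At each centerline point, every frame is sampled bilinearly along the
#' normal at unit spacing over `[-L/2, +L/2]` (L + 1 samples). Samples that
#' fall outside the frame are 0 and the event is flagged in the result's
#' `clipped` attribute.
#'
#' @param video a [video_stack()] (registered, typically CLAHE-enhanced).
#' @param curve a [resample_curve_with_normals()] result.
#' @return numeric array `P[position, offset, time]` with attributes
#'   `frame_rate`, `pixel_pitch`, `offsets`, `clipped`.
#' @export
extract_profiles <- function(video, curve) {
  stopifnot(inherits(curve, "centerline_curve"))
  L <- curve$normal_length
  offsets <- seq(-L / 2, L / 2, by = 1)
  m <- nrow(curve$points)
  xs <- outer(curve$points[, 1], rep(1, length(offsets))) +
    outer(curve$normals[, 1], offsets)
  ys <- outer(curve$points[, 2], rep(1, length(offsets))) +
    outer(curve$normals[, 2], offsets)
  h <- dim(video)[1]
  w <- dim(video)[2]
  clipped <- any(xs < 1 | xs > w | ys < 1 | ys > h)
  if (clipped) {
    warning("some profile samples fall outside the frame; set to 0")
  }
  nt <- n_frames(video)
  P <- array(0, dim = c(m, length(offsets), nt))
  xv <- as.vector(xs)
  yv <- as.vector(ys)
  for (k in seq_len(nt)) {
    P[, , k] <- bilinear_sample(get_frame(video, k), xv, yv, fill = 0)
  }
  structure(P, frame_rate = attr(video, "frame_rate"),
            pixel_pitch = attr(video, "pixel_pitch"),
            offsets = offsets, clipped = clipped)
}

#' Build the spatial-temporal map from a profile stack
#'
#' For each centerline position, the offset x time profile map is
#' thresholded at its Otsu level (values below go to 0) to remove
#' low-amplitude signal, then averaged over offsets to one value per time
#' point. Stacking positions gives the map (rows = intestine positions,
#' columns = time points), which is finally smoothed with a 2x2 median
#' filter. With `invert = TRUE` (default) the profile stack is converted to
#' contrast-agent absorbance (`1 - intensity`) first, so contractions (less
#' absorber in the cross-section) are low values and relaxations high.
#'
#' @param P profile array from [extract_profiles()].
#' @param invert convert intensity to absorbance before thresholding.
#' @param otsu_scope `"per_position"` (threshold each position's offset x
#'   time map, the default) or `"global"` (one threshold for the whole
#'   stack).
#' @return object of class `st_map`: the matrix `S[position, time]` with
#'   attributes `frame_rate`, `pixel_pitch`, `position_spacing_px`,
#'   `otsu_thresholds`, `inverted`.
#' @export
build_st_map <- function(P, invert = TRUE,
                         otsu_scope = c("per_position", "global")) {
  otsu_scope <- match.arg(otsu_scope)
  stopifnot(length(dim(P)) == 3)
  A <- if (invert) 1 - P else P
  A <- pmin(pmax(A, 0), 1)
  m <- dim(P)[1]
  nt <- dim(P)[3]
  S <- matrix(0, m, nt)
  if (all(A == 0)) {
    warning("all-zero profile stack: returning all-zero map")
    th <- rep(NA_real_, m)
  } else if (otsu_scope == "global") {
    tg <- EBImage::otsu(matrix(A, nrow = dim(P)[2]), range = c(0, 1))
    th <- rep(tg, m)
    for (i in seq_len(m)) {
      Mi <- A[i, , , drop = TRUE]
      dim(Mi) <- dim(P)[2:3]
      Mi[Mi < tg] <- 0
      S[i, ] <- colMeans(Mi)
    }
  } else {
    th <- numeric(m)
    for (i in seq_len(m)) {
      Mi <- A[i, , , drop = TRUE]
      dim(Mi) <- dim(P)[2:3]
      if (max(Mi) - min(Mi) < 1e-12) {
        th[i] <- NA_real_      # flat map: nothing to threshold
      } else {
        th[i] <- EBImage::otsu(Mi, range = c(0, 1))
        Mi[Mi < th[i]] <- 0
      }
      S[i, ] <- colMeans(Mi)
    }
  }
  S <- median_filter_2x2(S)
  structure(S, frame_rate = attr(P, "frame_rate"),
            pixel_pitch = attr(P, "pixel_pitch"),
            position_spacing_px = 1,
            otsu_thresholds = th, inverted = invert,
            class = c("st_map", "matrix", "array"))
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("<st_map> %d positions x %d time points @ %.3g Hz%s\n",
              nrow(x), ncol(x), attr(x, "frame_rate"),
              if (isTRUE(attr(x, "inverted"))) " (absorbance)" else ""))
  invisible(x)
}

#' Full registered-video to ST-map pipeline
#'
#' Convenience wrapper: CLAHE enhancement, curve resampling, profile
#' extraction, and map construction.
#'
#' @param video registered [video_stack()].
#' @param raw_curve `n x 2` matrix of centerline points (x, y) px.
#' @param normal_length profile length in px.
#' @param enhance apply CLAHE first.
#' @param ... passed to [build_st_map()].
#' @return an `st_map`.
#' @export
st_map_from_video <- function(video, raw_curve, normal_length,
                              enhance = TRUE, ...) {
  if (enhance) video <- enhance_frames(video)
  curve <- resample_curve_with_normals(raw_curve, normal_length)
  P <- extract_profiles(video, curve)
  build_st_map(P, ...)
}

#' Classify the motor pattern of an ST map by autocorrelation peak drift
#'
#' Estimates the dominant temporal period from the row-averaged temporal
#' autocorrelation, then tracks the position lag of the 2D autocorrelation
#' peak over small time lags (below a quarter period, where a stationary
#' rhythm is still positively correlated in place). A propagating
#' (peristaltic) wave drifts the peak off the time axis at its band slope;
#' a stationary (segmentation) rhythm keeps it on the axis. The decision
#' statistic is the extrapolated drift over one period.
#'
#' @param S an `st_map`.
#' @param min_period_frames smallest time lag considered a period.
#' @param max_position_lag largest |position lag| searched, px.
#' @param drift_threshold_px |peak drift per period| above which the pattern
#'   is called peristalsis, px.
#' @return list with `pattern` (`"peristalsis"` or `"segmentation"`),
#'   `period_frames`, `period_s`, `slope_px_per_frame`,
#'   `drift_per_period_px`, and the tracked peak offsets (`drift` data
#'   frame).
#' @export
classify_motor_pattern <- function(S, min_period_frames = 3,
                                   max_position_lag = 25,
                                   drift_threshold_px = 4) {
  stopifnot(nrow(S) > 1, ncol(S) > 2 * min_period_frames)
  S0 <- S - mean(S)
  nt <- ncol(S)
  m <- nrow(S)
  max_lag <- floor(nt / 2)
  # temporal period: first local maximum of the mean row-wise
  # autocorrelation after its first local minimum (the global small-lag
  # maximum is just the zero-lag peak's shoulder)
  ac_t <- vapply(seq_len(max_lag), function(l) {
    a <- S0[, seq_len(nt - l), drop = FALSE]
    b <- S0[, seq_len(nt - l) + l, drop = FALSE]
    mean(a * b)
  }, numeric(1))
  i0 <- which(diff(ac_t) > 0)[1]      # first local minimum
  if (is.na(i0)) i0 <- max_lag %/% 2
  win <- seq.int(i0, min(3 * i0, max_lag))
  period <- max(win[which.max(ac_t[win])], min_period_frames)
  # track the correlation peak over small time lags (< period / 4, where a
  # stationary rhythm is still in phase with itself)
  dts <- seq_len(max(2, floor(period / 5)))
  K <- min(max_position_lag, m - 1)
  lags <- -K:K
  xc <- function(ds, dt) {
    if (ds >= 0) {
      a <- S0[seq_len(m - ds), seq_len(nt - dt), drop = FALSE]
      b <- S0[seq_len(m - ds) + ds, seq_len(nt - dt) + dt, drop = FALSE]
    } else {
      a <- S0[seq_len(m + ds) - ds, seq_len(nt - dt), drop = FALSE]
      b <- S0[seq_len(m + ds), seq_len(nt - dt) + dt, drop = FALSE]
    }
    mean(a * b)
  }
  peak_ds <- vapply(dts, function(dt) {
    cc <- vapply(lags, xc, numeric(1), dt = dt)
    i <- which.max(cc)
    ds <- lags[i]
    if (i > 1 && i < length(lags)) {   # parabolic subpixel refinement
      denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
      if (denom < 0) ds <- ds + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
    }
    ds
  }, numeric(1))
  slope <- sum(dts * peak_ds) / sum(dts^2)   # through-origin fit
  drift <- slope * period
  list(pattern = if (abs(drift) >= drift_threshold_px)
         "peristalsis" else "segmentation",
       period_frames = period,
       period_s = period / attr(S, "frame_rate"),
       slope_px_per_frame = slope,
       drift_per_period_px = drift,
       drift = data.frame(dt = dts, peak_position_lag = peak_ds))
}
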