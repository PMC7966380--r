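# Silhouette extraction and image-moment rigid registration.
#
# The mouse body silhouette is found by iterative thresholding of the
# complemented frame; its convex hull's second-order central moments give
# the body orientation (major-axis angle theta) and centroid. Every frame is
# rotated by (90 - theta) so the body is upright, then translated so its
# centroid lands on the first frame's (anchor) centroid.

#' Extract the mouse-body silhouette from a frame
#'
#' Starting from a threshold of 1, the frame is binarized (`pixel >= tau`),
#' complemented, and labeled into connected components (8-connectivity). The
#' largest dark component is the poorly illuminated background; the
#' second-largest is the mouse. The threshold is lowered by `threshold_step`
#' until the mouse component covers at least `area_fraction` of the full
#' field of view.
#'
#' @param frame numeric matrix with intensities in [0, 1].
#' @param area_fraction stop when second-largest dark component / frame area
#'   reaches this ratio (default 5% of the camera field of view).
#' @param threshold_step threshold decrement per iteration.
#' @param denoise_sigma Gaussian pre-smoothing in px applied before
#'   thresholding; suppresses per-pixel sensor noise that would otherwise
#'   speckle the binarized image. 0 disables.
#' @param clean_radius radius of the morphological opening (box structuring
#'   element of side `2 * clean_radius + 1`) applied to the complemented
#'   binary image before labeling; removes residual speckle and thin noise
#'   bridges. 0 disables.
#' @return object of class `silhouette_mask`: list with `mask` (logical
#'   matrix), `area_px`, `threshold` (the terminating tau), and `ratio`.
#' @export
extract_silhouette <- function(frame, area_fraction = 0.05,
                               threshold_step = 0.005, denoise_sigma = 1,
                               clean_radius = 1) {
  stopifnot(is.matrix(frame), area_fraction > 0, threshold_step > 0)
  if (denoise_sigma > 0) {
    frame <- EBImage::gblur(frame, sigma = denoise_sigma)
  }
  brush <- if (clean_radius > 0) {
    EBImage::makeBrush(2 * clean_radius + 1, shape = "box")
  }
  total <- length(frame)
  tau <- 1
  best_ratio <- 0
  while (tau > 0) {
    comp <- frame < tau                # complement of (frame >= tau)
    if (!is.null(brush) && any(comp)) {
      comp <- EBImage::opening(comp * 1, brush) > 0.5
    }
    if (any(comp)) {
      lab <- label_components(comp)
      n <- max(lab)
      if (n >= 2) {
        areas <- tabulate(lab[lab > 0L], nbins = n)
        ord <- order(areas, decreasing = TRUE)
        second <- ord[2]
        ratio <- areas[second] / total
        best_ratio <- max(best_ratio, ratio)
        if (ratio >= area_fraction) {
          return(structure(list(mask = lab == second,
                                area_px = areas[second],
                                threshold = tau,
                                ratio = ratio),
                           class = "silhouette_mask"))
        }
      }
    }
    tau <- tau - threshold_step
  }
  stop(sprintf(
    "no silhouette: threshold reached 0 with best area ratio %.4f < %.4f",
    best_ratio, area_fraction))
}

#' Fill the convex hull of a binary mask
#'
#' The hull generalizes the animal shape before moment analysis. Vertices
#' come from [grDevices::chull()] on the set pixel centers; the polygon is
#' filled by scanline rasterization. The result is a superset of the input.
#'
#' @param mask a `silhouette_mask` or logical matrix.
#' @return object of class `silhouette_mask` containing the filled hull.
#' @export
convex_hull_mask <- function(mask) {
  m <- if (inherits(mask, "silhouette_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no convex hull")
  out <- matrix(FALSE, nrow(m), ncol(m))
  xs <- idx[, 2]
  ys <- idx[, 1]
  if (nrow(idx) <= 2) {
    out[idx] <- TRUE
  } else {
    hull <- grDevices::chull(xs, ys)
    hx <- xs[hull]
    hy <- ys[hull]
    nh <- length(hull)
    if (nh < 3) {
      out[idx] <- TRUE
    } else {
      for (r in seq.int(min(hy), max(hy))) {
        cross <- numeric(0)
        for (e in seq_len(nh)) {
          y1 <- hy[e]; y2 <- hy[if (e == nh) 1 else e + 1]
          x1 <- hx[e]; x2 <- hx[if (e == nh) 1 else e + 1]
          if ((y1 <= r && y2 >= r) || (y2 <= r && y1 >= r)) {
            if (y1 == y2) {
              cross <- c(cross, x1, x2)
            } else {
              cross <- c(cross, x1 + (r - y1) * (x2 - x1) / (y2 - y1))
            }
          }
        }
        if (length(cross) > 0) {
          lo <- ceiling(min(cross) - 1e-9)
          hi <- floor(max(cross) + 1e-9)
          if (hi >= lo) out[r, lo:hi] <- TRUE
        }
      }
    }
  }
  structure(list(mask = out, area_px = sum(out),
                 threshold = if (inherits(mask, "silhouette_mask"))
                   mask$threshold else NA_real_,
                 ratio = sum(out) / length(out)),
            class = "silhouette_mask")
}

#' Second-order central image moments of a binary mask
#'
#' For a binary mask the intensity function is identically 1 inside the
#' region, so the moments reduce to statistics of the set pixel coordinates:
#' centroid `(xbar, ybar)` and per-pixel normalized central moments
#' `mu_xx = sum((x - xbar)^2)/N`, `mu_yy`, `mu_xy`, assembled into the 2x2
#' covariance matrix.
#'
#' @param mask a `silhouette_mask` or logical matrix with `N >= 1` pixels.
#' @return object of class `moment_set`: list with `n`, `centroid`,
#'   `mu_xx`, `mu_yy`, `mu_xy`, `cov`.
#' @export
compute_moments <- function(mask) {
  m <- if (inherits(mask, "silhouette_mask")) mask$mask else mask
  idx <- which(m != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) stop("cannot compute moments of an empty mask")
  x <- idx[, 2]
  y <- idx[, 1]
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  mu_xx <- sum((x - xbar)^2) / n
  mu_yy <- sum((y - ybar)^2) / n
  mu_xy <- sum((x - xbar) * (y - ybar)) / n
  structure(list(n = n, centroid = c(xbar, ybar),
                 mu_xx = mu_xx, mu_yy = mu_yy, mu_xy = mu_xy,
                 cov = matrix(c(mu_xx, mu_xy, mu_xy, mu_yy), 2, 2)),
            class = "moment_set")
}

#' Body pose (major-axis angle and centroid) from image moments
#'
#' The eigenvector of the covariance matrix with the larger eigenvalue is
#' the major axis; theta is its angle against the horizontal axis, mapped to
#' [0, 180). An isotropic covariance (equal eigenvalues) is flagged
#' degenerate with theta = 0 by convention.
#'
#' @param m a `moment_set`.
#' @return object of class `rigid_pose`: list with `theta` (deg in
#'   [0, 180)), `centroid` (px), `eigenvalues`, `eccentricity`, `degenerate`.
#' @export
pose_from_moments <- function(m) {
  stopifnot(inherits(m, "moment_set"))
  e <- eigen(m$cov, symmetric = TRUE)
  lam <- e$values
  degenerate <- (lam[1] - lam[2]) <= 1e-12 * max(lam[1], 1)
  if (degenerate) {
    theta <- 0
  } else {
    v <- e$vectors[, 1]
    theta <- atan2(v[2], v[1]) * 180 / pi
    theta <- theta %% 180
  }
  ecc <- if (lam[1] > 0) sqrt(1 - lam[2] / lam[1]) else 0
  structure(list(theta = theta, centroid = m$centroid,
                 eigenvalues = lam, eccentricity = ecc,
                 degenerate = degenerate),
            class = "rigid_pose")
}

# convenience: frame -> pose (+ hull mask), used by register_video
frame_pose <- function(frame, area_fraction = 0.05, threshold_step = 0.005) {
  sil <- extract_silhouette(frame, area_fraction, threshold_step)
  hull <- convex_hull_mask(sil)
  pose <- pose_from_moments(compute_moments(hull))
  list(pose = pose, hull = hull, silhouette = sil)
}

#' Register a frame to the anchor pose
#'
#' Rotates the frame by `(90 - theta)` degrees about the image center
#' (bilinear interpolation, zero fill), then translates so the rotated
#' centroid coincides with the anchor centroid; the body ends up upright and
#' anchored. A degenerate pose returns the frame untransformed with a
#' warning flag.
#'
#' @param frame numeric matrix.
#' @param pose the frame's own `rigid_pose`.
#' @param anchor the anchor (first-frame) `rigid_pose`.
#' @param flip if `TRUE`, rotate by an extra 180 degrees (resolves the
#'   major-axis head/tail ambiguity).
#' @return list with `frame` (registered matrix) and `transform` (class
#'   `rigid_transform`: `theta`, `angle_applied`, `rotation` 2x2 matrix,
#'   `translation`, `degenerate`).
#' @export
register_frame <- function(frame, pose, anchor, flip = FALSE) {
  stopifnot(inherits(pose, "rigid_pose"), inherits(anchor, "rigid_pose"))
  h <- nrow(frame)
  w <- ncol(frame)
  ctr <- c((w + 1) / 2, (h + 1) / 2)
  if (pose$degenerate) {
    warning("degenerate pose: frame returned untransformed")
    return(list(frame = frame,
                transform = structure(
                  list(theta = pose$theta, angle_applied = 0,
                       rotation = diag(2), translation = c(0, 0),
                       center = ctr, degenerate = TRUE),
                  class = "rigid_transform")))
  }
  beta <- (90 - pose$theta) + if (flip) 180 else 0
  a <- beta * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  c_rot <- as.vector(rot %*% (pose$centroid - ctr)) + ctr
  trans <- anchor$centroid - c_rot
  reg <- warp_rigid(frame, angle_deg = beta, translation = trans,
                    center = ctr, fill = 0)
  list(frame = reg,
       transform = structure(
         list(theta = pose$theta, angle_applied = beta, rotation = rot,
              translation = trans, center = ctr, degenerate = FALSE),
         class = "rigid_transform"))
}

#' Apply a rigid transform to 2D points
#'
#' @param transform a `rigid_transform` from [register_frame()].
#' @param points `n x 2` matrix of (x, y) pixel coordinates.
#' @return transformed `n x 2` matrix.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  p <- t(transform$rotation %*% (t(points) - transform$center)) +
    rep(transform$center + transform$translation, each = nrow(points))
  colnames(p) <- c("x", "y")
  p
}

#' Apply a scene pose (rotation about a center plus centroid placement) to
#' points
#'
#' Maps canonical-scene coordinates into the posed frame: rotation by
#' `angle` about `center` followed by moving `center` to `centroid`.
#'
#' @param points `n x 2` (x, y) px in the canonical frame.
#' @param angle degrees.
#' @param centroid length-2 target of the canonical center.
#' @param center length-2 rotation center (canonical mouse centroid).
#' @return posed `n x 2` matrix.
#' @export
apply_pose <- function(points, angle, centroid, center) {
  a <- angle * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  p <- t(rot %*% (t(points) - center)) + rep(centroid, each = nrow(points))
  colnames(p) <- c("x", "y")
  p
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Register a whole video to its first frame
#'
#' The first frame's convex-hull centroid is the anchor. Each frame's pose
#' is estimated from its own silhouette; the 180-degree major-axis ambiguity
#' is resolved by whichever flip maximizes silhouette overlap (Jaccard) with
#' the registered anchor. Frames whose hull eccentricity falls below
#' `min_eccentricity` (severely bent body) are flagged for similarity-based
#' fallback analysis. Frames without a silhouette reuse the previous pose
#' (flagged) or abort, per `on_missing`.
#'
#' @param video a [video_stack()] with at least 2 frames.
#' @param area_fraction,threshold_step passed to [extract_silhouette()].
#' @param roi optional `c(x, y, w, h)` crop applied uniformly after
#'   registration.
#' @param min_eccentricity hull eccentricity below which a frame is flagged.
#' @param on_missing `"interpolate"` (reuse previous pose) or `"abort"`.
#' @return list with `video` (registered, cropped [video_stack()]),
#'   `transforms` (list of `rigid_transform`), `poses` (data frame: frame,
#'   theta, cx, cy, flip, eccentricity, flagged), `anchor`, `roi`.
#' @export
register_video <- function(video, area_fraction = 0.05,
                           threshold_step = 0.005, roi = NULL,
                           min_eccentricity = 0.6,
                           on_missing = c("interpolate", "abort")) {
  on_missing <- match.arg(on_missing)
  nt <- n_frames(video)
  if (nt < 2) stop("registration needs at least 2 frames")
  h <- dim(video)[1]
  w <- dim(video)[2]

  fp1 <- frame_pose(get_frame(video, 1), area_fraction, threshold_step)
  anchor <- fp1$pose
  reg1 <- register_frame(get_frame(video, 1), anchor, anchor)
  anchor_mask <- warp_rigid(fp1$hull$mask * 1,
                            angle_deg = reg1$transform$angle_applied,
                            translation = reg1$transform$translation,
                            center = reg1$transform$center, fill = 0) > 0.5

  frames <- array(0, dim = c(h, w, nt))
  frames[, , 1] <- reg1$frame
  transforms <- vector("list", nt)
  transforms[[1]] <- reg1$transform
  poses <- data.frame(frame = seq_len(nt), theta = NA_real_,
                      cx = NA_real_, cy = NA_real_, flip = FALSE,
                      eccentricity = NA_real_, flagged = FALSE,
                      missing_silhouette = FALSE)
  poses[1, c("theta", "cx", "cy")] <-
    c(anchor$theta, anchor$centroid)
  poses$eccentricity[1] <- anchor$eccentricity
  prev <- fp1

  for (i in 2:nt) {
    fr <- get_frame(video, i)
    fp <- tryCatch(frame_pose(fr, area_fraction, threshold_step),
                   error = function(e) NULL)
    if (is.null(fp)) {
      if (on_missing == "abort") {
        stop("frame ", i, " yielded no silhouette")
      }
      fp <- prev
      poses$missing_silhouette[i] <- TRUE
    }
    # resolve the 180-degree ambiguity by anchor-overlap
    cand <- lapply(c(FALSE, TRUE), function(fl) {
      rf <- register_frame(fp$hull$mask * 1, fp$pose, anchor, flip = fl)
      list(flip = fl, j = jaccard(rf$frame > 0.5, anchor_mask))
    })
    flip <- cand[[which.max(vapply(cand, `[[`, numeric(1), "j"))]]$flip
    reg <- register_frame(fr, fp$pose, anchor, flip = flip)
    frames[, , i] <- reg$frame
    transforms[[i]] <- reg$transform
    poses$theta[i] <- fp$pose$theta
    poses$cx[i] <- fp$pose$centroid[1]
    poses$cy[i] <- fp$pose$centroid[2]
    poses$flip[i] <- flip
    poses$eccentricity[i] <- fp$pose$eccentricity
    poses$flagged[i] <- fp$pose$eccentricity < min_eccentricity
    prev <- fp
  }
  poses$flagged[1] <- anchor$eccentricity < min_eccentricity

  out <- video_stack(frames, frame_rate = attr(video, "frame_rate"),
                     pixel_pitch = attr(video, "pixel_pitch"),
                     timestamps = attr(video, "timestamps"))
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4)
    rows <- roi[2]:(roi[2] + roi[4] - 1)
    cols <- roi[1]:(roi[1] + roi[3] - 1)
    out <- video_stack(out[rows, cols, , drop = FALSE],
                       frame_rate = attr(video, "frame_rate"),
                       pixel_pitch = attr(video, "pixel_pitch"),
                       timestamps = attr(video, "timestamps"))
  }
  list(video = out, transforms = transforms, poses = poses,
       anchor = anchor, roi = roi)
}
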