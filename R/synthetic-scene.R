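# Synthetic transillumination scenes with known ground truth.
#
# The generator emulates the imaging geometry of trans-abdominal
# transillumination of a freely moving mouse: a bright illumination disk on a
# dark background, a mouse-body silhouette of intermediate transmission
# covering a few percent of the field of view, and a dark absorber-filled
# intestine whose local diameter follows a programmed motor pattern.
# Attenuation through the intestine follows Beer-Lambert along the chord of a
# circular cross-section; frames get a scattering blur and additive Gaussian
# sensor noise.

#' Scene configuration for the synthetic generator
#'
#' @param image_size `(H, W)` in pixels.
#' @param pixel_pitch mm per pixel. Default 0.2 mm/px so a 4 mm intestine
#'   spans 20 px.
#' @param frame_rate acquisition rate in Hz (15 Hz single-color by default).
#' @param duration recording length in seconds.
#' @param illumination_center `(x, y)` px of the illumination disk; defaults
#'   to the image center.
#' @param illumination_radius disk radius in px.
#' @param background_level,mouse_level,illum_level normalized intensities,
#'   `0 <= background < mouse < illum <= 1`.
#' @param illumination_falloff fractional quadratic dimming of the
#'   illumination disk from center to rim (diffuse trans-tissue
#'   illumination is never flat); intensity at radius r is
#'   `illum_level * (1 - falloff * (r/R)^2)`.
#' @param mouse_axes `(a, b)` semi-axes of the elliptical mouse silhouette in
#'   px; defaults cover ~6% of a 256x256 field of view.
#' @param scatter_sigma_px Gaussian scattering blur applied to each frame,
#'   in px.
#' @param noise_sigma additive Gaussian sensor noise (normalized intensity).
#' @param rng_seed integer seed making the render bit-reproducible.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(256, 256),
                         pixel_pitch = 0.2,
                         frame_rate = 15,
                         duration = 60,
                         illumination_center = NULL,
                         illumination_radius = 100,
                         illumination_falloff = 0.06,
                         background_level = 0.05,
                         mouse_level = 0.5,
                         illum_level = 0.9,
                         mouse_axes = c(50, 25),
                         scatter_sigma_px = 1.5,
                         noise_sigma = 0.02,
                         rng_seed = 1L) {
  if (!(background_level >= 0 && background_level < mouse_level &&
        mouse_level < illum_level && illum_level <= 1)) {
    stop("need 0 <= background_level < mouse_level < illum_level <= 1")
  }
  stopifnot(frame_rate > 0, noise_sigma >= 0, duration > 0,
            length(image_size) == 2, all(image_size >= 16),
            illumination_radius > 0, all(mouse_axes > 0))
  if (is.null(illumination_center)) {
    illumination_center <- c((image_size[2] + 1) / 2, (image_size[1] + 1) / 2)
  }
  structure(list(image_size = as.integer(image_size),
                 pixel_pitch = pixel_pitch,
                 frame_rate = frame_rate,
                 duration = duration,
                 illumination_center = illumination_center,
                 illumination_radius = illumination_radius,
                 illumination_falloff = illumination_falloff,
                 background_level = background_level,
                 mouse_level = mouse_level,
                 illum_level = illum_level,
                 mouse_axes = mouse_axes,
                 scatter_sigma_px = scatter_sigma_px,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Motor-pattern configuration
#'
#' Diameters are in mm. The resting diameter (4 mm) and the contracted
#' fraction (25% of resting, i.e. a 75% diameter change) are the
#' physiological values for the mouse small intestine.
#'
#' @param resting_diameter resting intestinal diameter, mm.
#' @param contracted_fraction fully contracted diameter as a fraction of
#'   resting, in (0, 1).
#' @param pattern `"segmentation"` (stationary alternating contractions),
#'   `"peristalsis"` (traveling wave), or `"mixed"`.
#' @param contraction_frequency cycle frequency in Hz. Default 0.772 Hz, the
#'   segmentation rate of an awake, freely moving mouse.
#' @param wave_speed peristaltic wave speed, mm/s.
#' @param site_spacing distance between segmentation contraction sites, mm.
#' @param bump_width width of the raised-cosine contraction bump, mm.
#' @param centerline_points optional `n x 2` matrix of (x, y) centerline
#'   coordinates in mm, in the canonical (mouse-centered, axis-horizontal)
#'   frame; `NULL` uses a gentle sinusoidal arc along the mouse's major axis.
#' @return object of class `motility_config`.
#' @export
motility_config <- function(resting_diameter = 4,
                            contracted_fraction = 0.25,
                            pattern = c("segmentation", "peristalsis",
                                        "mixed"),
                            contraction_frequency = 0.772,
                            wave_speed = 2,
                            site_spacing = 3,
                            bump_width = 2,
                            centerline_points = NULL) {
  pattern <- match.arg(pattern)
  if (contraction_frequency <= 0) {
    stop("contraction_frequency must be positive (Hz)")
  }
  stopifnot(resting_diameter > 0,
            contracted_fraction > 0, contracted_fraction < 1,
            wave_speed > 0, site_spacing > 0, bump_width > 0)
  structure(list(resting_diameter = resting_diameter,
                 contracted_fraction = contracted_fraction,
                 pattern = pattern,
                 contraction_frequency = contraction_frequency,
                 wave_speed = wave_speed,
                 site_spacing = site_spacing,
                 bump_width = bump_width,
                 centerline_points = centerline_points),
            class = "motility_config")
}

#' Rigid-motion schedule for the synthetic mouse
#'
#' @param pose_schedule data frame with columns `time` (s, strictly
#'   increasing), `angle` (deg), `cx`, `cy` (px centroid). `NULL` means the
#'   identity pose (centered, angle 0) for the whole recording.
#' @param interpolation `"linear"` (smooth motion between key poses) or
#'   `"hold"` (piecewise-constant poses, abrupt switches).
#' @return object of class `motion_config`.
#' @export
motion_config <- function(pose_schedule = NULL,
                          interpolation = c("linear", "hold")) {
  interpolation <- match.arg(interpolation)
  if (!is.null(pose_schedule)) {
    stopifnot(is.data.frame(pose_schedule),
              all(c("time", "angle", "cx", "cy") %in% names(pose_schedule)))
    if (any(diff(pose_schedule$time) <= 0)) {
      stop("pose_schedule times must be strictly increasing")
    }
    if (any(!is.finite(as.matrix(
      pose_schedule[c("time", "angle", "cx", "cy")])))) {
      stop("pose_schedule entries must be finite")
    }
  }
  structure(list(pose_schedule = pose_schedule,
                 interpolation = interpolation),
            class = "motion_config")
}

# Beer-Lambert absorption coefficient (1/mm), chosen so a resting 4 mm
# intestine transmits ~20% at its center (~80% attenuation).
tip_mu <- function() log(5) / 4

# raised-cosine contraction bump, unit height, support width w (mm)
contraction_bump <- function(x, w) {
  ifelse(abs(x) <= w / 2, cos(pi * x / w)^2, 0)
}

# default canonical centerline: sinusoidal arc along the major axis, mm
default_centerline_mm <- function(scene) {
  half <- 0.72 * scene$mouse_axes[1] * scene$pixel_pitch
  x <- seq(-half, half, length.out = 200)
  amp <- min(1, 0.15 * scene$mouse_axes[2] * scene$pixel_pitch)
  cbind(x = x, y = amp * sin(pi * x / half))
}

# contraction activation field a(s, t) in [0, 1]; s in mm along the curve
activation_field <- function(s, t, motility, total_len) {
  f <- motility$contraction_frequency
  w <- motility$bump_width
  switch(motility$pattern,
    peristalsis = {
      lam <- motility$wave_speed / f      # spatial period of the wave train
      x <- (s - motility$wave_speed * t) %% max(lam, total_len * 1e-9)
      x <- pmin(x, lam - x)               # distance to nearest wave crest
      contraction_bump(x, w)
    },
    segmentation = {
      sites <- segmentation_sites(total_len, motility$site_spacing)
      a <- numeric(length(s))
      for (k in seq_along(sites)) {
        phase <- if (k %% 2 == 1) 0 else 0.5   # flanking pair vs in-between
        amp <- cos(pi * (f * t - phase))^2
        a <- a + amp * contraction_bump(s - sites[k], w)
      }
      pmin(a, 1)
    },
    mixed = {
      per <- activation_field(s, t,
                              modifyList(motility, list(pattern = "peristalsis")),
                              total_len)
      seg <- activation_field(s, t,
                              modifyList(motility, list(pattern = "segmentation")),
                              total_len)
      pmin(per + seg, 1)
    })
}

# contraction-site arclength positions (mm) for the segmentation pattern
segmentation_sites <- function(total_len, spacing) {
  margin <- spacing / 2
  if (total_len <= 2 * margin) {
    return(total_len / 2)
  }
  seq(margin, total_len - margin, by = spacing)
}

# local diameter d(s, t) in mm
diameter_field <- function(s, t, motility, total_len) {
  d0 <- motility$resting_diameter
  dc <- d0 * motility$contracted_fraction
  a <- activation_field(s, t, motility, total_len)
  pmin(pmax(d0 - (d0 - dc) * a, dc), d0)
}

# interpolate the pose schedule at time t -> list(angle, centroid)
pose_at <- function(motion, t, scene) {
  ctr <- c((scene$image_size[2] + 1) / 2, (scene$image_size[1] + 1) / 2)
  sched <- motion$pose_schedule
  if (is.null(sched)) {
    return(list(angle = 0, centroid = ctr))
  }
  interp <- function(v) {
    if (motion$interpolation == "hold") {
      idx <- findInterval(t, sched$time, rightmost.closed = FALSE)
      v[pmax(idx, 1)]
    } else {
      stats::approx(sched$time, v, xout = t, rule = 2)$y
    }
  }
  list(angle = interp(sched$angle),
       centroid = c(interp(sched$cx), interp(sched$cy)))
}

# distance (mm) and arclength (mm) maps from every pixel to the centerline
centerline_distance_maps <- function(curve_px, scene) {
  h <- scene$image_size[1]
  w <- scene$image_size[2]
  px <- rep(seq_len(w), each = h)
  py <- rep.int(seq_len(h), w)
  seg_len_px <- sqrt(diff(curve_px[, 1])^2 + diff(curve_px[, 2])^2)
  s_at_vertex <- c(0, cumsum(seg_len_px)) * scene$pixel_pitch
  best_d2 <- rep(Inf, h * w)
  best_s <- rep(0, h * w)
  for (i in seq_len(nrow(curve_px) - 1)) {
    ax <- curve_px[i, 1]; ay <- curve_px[i, 2]
    bx <- curve_px[i + 1, 1]; by <- curve_px[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    tt <- if (len2 == 0) rep(0, h * w) else
      pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
    d2 <- (px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_s[better] <- s_at_vertex[i] + tt[better] * seg_len_px[i] *
      scene$pixel_pitch
  }
  list(r_mm = matrix(sqrt(best_d2) * scene$pixel_pitch, h, w),
       s_mm = matrix(best_s, h, w),
       total_len = s_at_vertex[length(s_at_vertex)])
}

#' Render a synthetic motility video with ground truth
#'
#' Each frame is composed as: illumination disk on dark background; inside
#' the disk the elliptical mouse silhouette transmits `mouse_level`; the
#' intestinal tube attenuates by `exp(-mu * chord(r, d(s, t)))` where the
#' chord is the path length through a circular absorber of local diameter
#' `d(s, t)` following the configured motor pattern. The canonical scene is
#' then rigidly posed per frame, blurred, and corrupted with clipped
#' Gaussian noise.
#'
#' @param scene a [scene_config()].
#' @param motility a [motility_config()].
#' @param motion a [motion_config()] or `NULL` for identity motion.
#' @return list with elements `video` (a [video_stack()]) and `truth`
#'   (per-frame pose, diameter field `d[s, t]` in mm, canonical centerline in
#'   px and mm arclength, segmentation-site positions, pattern and
#'   frequency).
#' @export
render_motility_video <- function(scene, motility, motion = NULL) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(motility, "motility_config"))
  if (is.null(motion)) motion <- motion_config()
  nt <- round(scene$duration * scene$frame_rate)
  if (nt < 2) stop("duration * frame_rate must give at least 2 frames")
  h <- scene$image_size[1]
  w <- scene$image_size[2]
  ctr <- c((w + 1) / 2, (h + 1) / 2)

  cl_mm <- motility$centerline_points %||% default_centerline_mm(scene)
  curve_px <- cbind(ctr[1] + cl_mm[, 1] / scene$pixel_pitch,
                    ctr[2] + cl_mm[, 2] / scene$pixel_pitch)
  if (any(curve_px[, 1] < 1 | curve_px[, 1] > w |
          curve_px[, 2] < 1 | curve_px[, 2] > h)) {
    stop("centerline falls outside the frame; shrink it or enlarge the image")
  }
  rdisk <- sqrt((curve_px[, 1] - scene$illumination_center[1])^2 +
                (curve_px[, 2] - scene$illumination_center[2])^2)
  if (any(rdisk > scene$illumination_radius)) {
    stop("centerline must lie inside the illumination disk")
  }

  maps <- centerline_distance_maps(curve_px, scene)
  total_len <- maps$total_len
  d0 <- motility$resting_diameter
  tube_idx <- which(maps$r_mm <= d0 / 2 + 0.5)
  r_tube <- maps$r_mm[tube_idx]
  s_tube <- maps$s_mm[tube_idx]

  # mouse silhouette (canonical frame: centered, major axis horizontal)
  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep.int(seq_len(h), w), h, w)
  mouse <- ((xg - ctr[1]) / scene$mouse_axes[1])^2 +
    ((yg - ctr[2]) / scene$mouse_axes[2])^2 <= 1
  r2 <- (xg - scene$illumination_center[1])^2 +
    (yg - scene$illumination_center[2])^2
  disk <- r2 <= scene$illumination_radius^2
  illum <- scene$illum_level *
    (1 - scene$illumination_falloff * r2 / scene$illumination_radius^2)

  mu <- tip_mu()
  base_factor <- matrix(1, h, w)
  base_factor[mouse] <- scene$mouse_level / scene$illum_level

  set.seed(scene$rng_seed)
  times <- (seq_len(nt) - 1) / scene$frame_rate
  s_curve <- c(0, cumsum(sqrt(diff(curve_px[, 1])^2 +
                              diff(curve_px[, 2])^2))) * scene$pixel_pitch
  frames <- array(0, dim = c(h, w, nt))
  pose_df <- data.frame(time = times, angle = 0, cx = 0, cy = 0)
  d_truth <- matrix(0, nrow(curve_px), nt)

  for (k in seq_len(nt)) {
    t <- times[k]
    dvec <- diameter_field(s_tube, t, motility, total_len)
    chord <- 2 * sqrt(pmax((dvec / 2)^2 - r_tube^2, 0))
    fac <- base_factor
    fac[tube_idx] <- fac[tube_idx] * exp(-mu * chord)
    pose <- pose_at(motion, t, scene)
    pose_df$angle[k] <- pose$angle
    pose_df$cx[k] <- pose$centroid[1]
    pose_df$cy[k] <- pose$centroid[2]
    facw <- warp_rigid(fac, angle_deg = pose$angle,
                       translation = pose$centroid - ctr,
                       center = ctr, fill = 1)
    frame <- matrix(scene$background_level, h, w)
    frame[disk] <- illum[disk] * facw[disk]
    if (scene$scatter_sigma_px > 0) {
      frame <- EBImage::gblur(frame, sigma = scene$scatter_sigma_px)
    }
    if (scene$noise_sigma > 0) {
      frame <- frame + stats::rnorm(h * w, 0, scene$noise_sigma)
    }
    frames[, , k] <- pmin(pmax(frame, 0), 1)
    d_truth[, k] <- diameter_field(s_curve, t, motility, total_len)
  }

  truth <- list(
    pose = pose_df,
    diameter = d_truth,
    centerline_px = curve_px,
    arclength_mm = s_curve,
    sites_mm = if (motility$pattern %in% c("segmentation", "mixed"))
      segmentation_sites(total_len, motility$site_spacing) else NULL,
    contraction_frequency = motility$contraction_frequency,
    pattern = motility$pattern,
    wave_speed = if (motility$pattern != "segmentation")
      motility$wave_speed else NULL,
    diameter_range = c(motility$resting_diameter * motility$contracted_fraction,
                       motility$resting_diameter))

  list(video = video_stack(frames, frame_rate = scene$frame_rate,
                           pixel_pitch = scene$pixel_pitch),
       truth = truth)
}

#' Render a straight-tube agar phantom image
#'
#' Emulates the depth-validation phantom: a contrast-filled tube embedded in
#' scattering agar, imaged in transillumination. Scattering between the tube
#' and the camera (`depth_below`) blurs the tube shadow; agar on the
#' illumination side (`depth_above`) only attenuates globally. `fixed_t1`
#' sweeps hold the illumination-side thickness fixed and vary `depth_below`;
#' `fixed_t2` sweeps hold the camera-side thickness fixed and vary
#' `depth_above`.
#'
#' @param tube_diameter inner diameter, mm.
#' @param depth_above agar thickness on the illumination side, mm.
#' @param depth_below agar thickness on the camera side, mm.
#' @param mode `"fixed_t1"` or `"fixed_t2"` (recorded in the output).
#' @param image_size `(H, W)` px.
#' @param pixel_pitch mm/px.
#' @param illum_level background (no-tube) intensity before depth
#'   attenuation.
#' @param blur_per_mm Gaussian blur sigma added per mm of camera-side agar,
#'   mm of sigma per mm of depth.
#' @param attenuation_per_mm global intensity attenuation coefficient of the
#'   agar, 1/mm.
#' @return list with `image` (blurred 2D phantom), `profile` (one noiseless
#'   blurred cross-section row), `profile_ideal` (unblurred cross-section),
#'   and `truth` (parameters incl. tube width in px).
#' @export
render_tube_phantom <- function(tube_diameter, depth_above = 0,
                                depth_below = 0,
                                mode = c("fixed_t1", "fixed_t2"),
                                image_size = c(96, 96), pixel_pitch = 0.2,
                                illum_level = 0.9, blur_per_mm = 0.25,
                                attenuation_per_mm = 0.05) {
  mode <- match.arg(mode)
  stopifnot(tube_diameter > 0, depth_above >= 0, depth_below >= 0)
  h <- image_size[1]
  w <- image_size[2]
  mu <- tip_mu()
  xc <- (w + 1) / 2
  x_mm <- (seq_len(w) - xc) * pixel_pitch
  R <- tube_diameter / 2
  chord <- 2 * sqrt(pmax(R^2 - x_mm^2, 0))
  level <- illum_level * exp(-attenuation_per_mm * (depth_above + depth_below))
  profile_ideal <- level * exp(-mu * chord)
  img <- matrix(rep(profile_ideal, each = h), h, w)
  sigma_px <- blur_per_mm * depth_below / pixel_pitch
  if (sigma_px > 0) img <- EBImage::gblur(img, sigma = sigma_px)
  list(image = img,
       profile = img[round(h / 2), ],
       profile_ideal = profile_ideal,
       truth = list(tube_diameter = tube_diameter,
                    tube_width_px = tube_diameter / pixel_pitch,
                    depth_above = depth_above, depth_below = depth_below,
                    mode = mode, pixel_pitch = pixel_pitch,
                    blur_sigma_px = sigma_px, level = level))
}

#' Lenslet grid geometry for light-field capture
#'
#' @param pitch pixels per lenslet along each axis (odd, >= 3); also the
#'   number of angular samples per axis.
#' @param n_lenslets `(ny, nx)` lenslet count.
#' @param slope_per_mm refocusing calibration: lateral shift (in lenslets)
#'   per unit angular index per mm of depth.
#' @return object of class `lenslet_grid`.
#' @export
lenslet_grid <- function(pitch = 5, n_lenslets = c(41, 41),
                         slope_per_mm = 0.3) {
  stopifnot(pitch >= 3, pitch %% 2 == 1, all(n_lenslets >= 3),
            slope_per_mm > 0)
  structure(list(pitch = as.integer(pitch),
                 n_lenslets = as.integer(n_lenslets),
                 slope_per_mm = slope_per_mm),
            class = "lenslet_grid")
}

#' Render a synthetic light field of point or tube sources
#'
#' Pinhole-array forward model: a source at depth `z` contributes to the
#' angular sample `(u, v)` of the lenslet displaced laterally by
#' `z * slope_per_mm * (u, v)` lenslets from the source position, so an
#' in-focus source (z = 0) illuminates a single lenslet while an off-focus
#' source spreads over several.
#'
#' @param sources data frame with columns `x`, `y` (lenslet-grid coordinates,
#'   1-based), `depth` (mm), `type` (`"point"` or `"tube"`; tubes run
#'   vertically through the whole grid at column `x`), and optionally
#'   `intensity`.
#' @param grid a [lenslet_grid()].
#' @return list with `lf` (4D array `[u, v, y, x]` of sub-aperture images),
#'   `raw` (encoded lenslet mosaic), `grid`, and `truth` (the source table).
#' @export
render_lightfield <- function(sources, grid = lenslet_grid()) {
  stopifnot(is.data.frame(sources),
            all(c("x", "y", "depth", "type") %in% names(sources)))
  ny <- grid$n_lenslets[1]
  nx <- grid$n_lenslets[2]
  p <- grid$pitch
  half <- (p - 1) / 2
  if (is.null(sources$intensity)) sources$intensity <- 1
  lf <- array(0, dim = c(p, p, ny, nx))
  splat <- function(mat, x, y, val) {
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    for (q in 1:4) {
      xi <- x0 + (q - 1) %% 2
      yi <- y0 + (q - 1) %/% 2
      wq <- (if (q %% 2 == 1) 1 - fx else fx) *
        (if (q <= 2) 1 - fy else fy)
      if (xi >= 1 && xi <= ncol(mat) && yi >= 1 && yi <= nrow(mat) && wq > 0) {
        mat[yi, xi] <- mat[yi, xi] + val * wq
      }
    }
    mat
  }
  for (i in seq_len(nrow(sources))) {
    src <- sources[i, ]
    shift <- src$depth * grid$slope_per_mm
    ys <- if (src$type == "tube") seq_len(ny) else src$y
    for (ui in seq_len(p)) {
      for (vi in seq_len(p)) {
        du <- ui - 1 - half
        dv <- vi - 1 - half
        sub <- lf[ui, vi, , ]
        dim(sub) <- c(ny, nx)
        for (y0 in ys) {
          sub <- splat(sub, src$x + shift * du,
                       y0 + if (src$type == "tube") 0 else shift * dv,
                       src$intensity)
        }
        lf[ui, vi, , ] <- sub
      }
    }
  }
  list(lf = lf, raw = encode_lightfield(lf, grid), grid = grid,
       truth = sources)
}
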