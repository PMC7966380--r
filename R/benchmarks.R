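# Canonical validation scenarios: synthetic recordings pinned to the
# published physiological conditions, run through the full pipeline.

#' Free-moving segmentation benchmark
#'
#' Renders a 60 s, 15 Hz synthetic segmentation recording at the
#' free-moving segmentation rate (0.772 Hz) with moderate sensor noise and
#' a scripted rigid walk, then recovers the rate with the full pipeline:
#' registration, kymograph mapping along the ground-truth centerline
#' (mapped through the estimated anchor transform), and spectral peak
#' estimation over 0.1-2.0 Hz at the first contraction site.
#'
#' @param seed RNG seed for the scene.
#' @param duration recording length, s.
#' @param frequency generator contraction frequency, Hz.
#' @return list with `recovered_hz`, `truth_hz`, `bin_width_hz`, `n_frames`,
#'   `st_map`, `registration`.
#' @export
benchmark_freemoving <- function(seed = 42, duration = 60,
                                 frequency = 0.772) {
  sc <- scene_config(duration = duration, rng_seed = seed,
                     noise_sigma = 0.02)
  mo <- motility_config(pattern = "segmentation",
                        contraction_frequency = frequency)
  ctr <- 128.5
  sched <- data.frame(
    time = seq(0, duration, length.out = 5),
    angle = c(0, 18, -12, 8, 0),
    cx = ctr + c(0, 7.5, -5.5, 2.5, 0),
    cy = ctr + c(0, -5.5, 3.5, -2.5, 0))
  sim <- render_motility_video(sc, mo, motion_config(sched))
  reg <- register_video(sim$video)
  curve <- registered_truth_curve(sim, reg)
  S <- st_map_from_video(reg$video, curve, normal_length = 40)
  f <- site_peak_frequency(S, sim)
  list(recovered_hz = f$peak_frequency, truth_hz = frequency,
       bin_width_hz = f$bin_width, n_frames = n_frames(sim$video),
       st_map = S, registration = reg, truth = sim$truth)
}

#' Anesthetized (motion-free) segmentation benchmark
#'
#' As [benchmark_freemoving()] but with identity motion and the
#' anesthetized segmentation rate (0.380 Hz); no registration is needed so
#' the kymograph is computed directly on the rendered stack.
#'
#' @inheritParams benchmark_freemoving
#' @return list with `recovered_hz`, `truth_hz`, `bin_width_hz`,
#'   `n_frames`, `st_map`.
#' @export
benchmark_anesthetized <- function(seed = 43, duration = 60,
                                   frequency = 0.380) {
  sc <- scene_config(duration = duration, rng_seed = seed,
                     noise_sigma = 0.02)
  mo <- motility_config(pattern = "segmentation",
                        contraction_frequency = frequency)
  sim <- render_motility_video(sc, mo)
  S <- st_map_from_video(sim$video, sim$truth$centerline_px,
                         normal_length = 40)
  f <- site_peak_frequency(S, sim)
  list(recovered_hz = f$peak_frequency, truth_hz = frequency,
       bin_width_hz = f$bin_width, n_frames = n_frames(sim$video),
       st_map = S, truth = sim$truth)
}

#' Resting-vs-contracted diameter benchmark
#'
#' Renders noiseless straight-tube phantoms at the resting (4 mm) and
#' fully contracted (25% of resting) diameters at 0.2 mm/px under mild
#' camera-side blur, and measures the FWHM-based diameter ratio.
#'
#' @param resting_diameter mm.
#' @param contracted_fraction fraction of resting.
#' @param depth_below camera-side agar thickness (mild blur), mm.
#' @return list from [diameter_change()] plus `ratio_percent`.
#' @export
benchmark_diameter_ratio <- function(resting_diameter = 4,
                                     contracted_fraction = 0.25,
                                     depth_below = 1) {
  rest <- render_tube_phantom(resting_diameter, depth_above = 4,
                              depth_below = depth_below)
  cont <- render_tube_phantom(resting_diameter * contracted_fraction,
                              depth_above = 4, depth_below = depth_below)
  dc <- diameter_change(rest$profile, cont$profile, pixel_pitch = 0.2)
  dc$ratio_percent <- 100 * dc$ratio
  dc
}

# map the generator's canonical centerline into registered-video
# coordinates via the true first-frame pose and the estimated anchor
# transform
registered_truth_curve <- function(sim, reg) {
  video <- reg$video
  ctr <- c((dim(video)[2] + 1) / 2, (dim(video)[1] + 1) / 2)
  pose1 <- sim$truth$pose[1, ]
  posed <- apply_pose(sim$truth$centerline_px, pose1$angle,
                      c(pose1$cx, pose1$cy), ctr)
  apply_transform(reg$transforms[[1]], posed)
}

# cross-section rows around a ground-truth contraction site -> peak
site_peak_frequency <- function(S, sim, halfwidth_rows = 3,
                                band = c(0.1, 2.0)) {
  pp <- attr(S, "pixel_pitch")
  sites <- sim$truth$sites_mm
  site <- sites[min(2, length(sites))]
  r0 <- round(site / pp)
  rows <- max(1, r0 - halfwidth_rows):min(nrow(S), r0 + halfwidth_rows)
  peak_frequency(cross_section_series(S, rows), band = band)
}
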