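test_that("CLAHE enhancement keeps range and stretches low-contrast input", {
  konst <- video_stack(array(0.4, c(64, 64, 2)), frame_rate = 1)
  out <- enhance_frames(konst)
  expect_equal(as.vector(out), as.vector(konst))   # nothing to equalize

  x <- matrix(rep(1:64, each = 64), 64, 64)
  grating <- 0.5 + 0.04 * sin(x / 3)
  v <- video_stack(array(grating, c(64, 64, 1)), frame_rate = 1)
  e <- enhance_frames(v)
  expect_gte(diff(range(e)), diff(range(v)))       # histogram spread grows
  set.seed(2)
  rnd <- video_stack(array(runif(64 * 64), c(64, 64, 1)), frame_rate = 1)
  er <- enhance_frames(rnd)
  expect_gte(min(er), 0)
  expect_lte(max(er), 1)
})

test_that("minimal amplitude projection is the per-pixel minimum", {
  f1 <- matrix(c(1, 0, 2, 3), 2, 2)
  f2 <- matrix(c(0, 2, 4, 1), 2, 2)
  v <- video_stack(array(c(f1, f2), c(2, 2, 2)), frame_rate = 1)
  expect_equal(minimal_amplitude_projection(v),
               matrix(c(0, 0, 2, 1), 2, 2))
  single <- video_stack(array(f1, c(2, 2, 1)), frame_rate = 1)
  expect_equal(minimal_amplitude_projection(single), f1)
  expect_true(all(minimal_amplitude_projection(v) <= f1) &&
                all(minimal_amplitude_projection(v) <= f2))
})

test_that("curve resampling yields unit normals orthogonal to the tangent", {
  seg <- cbind(seq(5, 25, by = 2), 10)
  cv <- resample_curve_with_normals(seg, normal_length = 8)
  expect_true(all(abs(cv$normals[, 1]) < 1e-9))
  expect_true(all(abs(abs(cv$normals[, 2]) - 1) < 1e-9))
  expect_true(all(diff(cv$arclength_px) <= 1.5))

  th <- seq(0, 2 * pi, length.out = 200)
  circ <- cbind(50 + 30 * cos(th), 50 + 30 * sin(th))
  cvc <- resample_curve_with_normals(circ, normal_length = 10)
  radial <- cbind(cvc$points[, 1] - 50, cvc$points[, 2] - 50)
  radial <- radial / sqrt(rowSums(radial^2))
  cosang <- abs(rowSums(radial * cvc$normals))
  expect_true(all(acos(pmin(cosang, 1)) * 180 / pi < 2))
  # unit length, orthogonal to tangent
  expect_true(all(abs(sqrt(rowSums(cvc$normals^2)) - 1) < 1e-9))

  expect_error(resample_curve_with_normals(rbind(c(1, 1), c(1, 1)), 5),
               "distinct")
})

test_that("profiles sample the cross-section with L+1 points and locate the tube", {
  ph <- render_tube_phantom(3, 0, 1, pixel_pitch = 0.2)
  v <- video_stack(array(ph$image, c(dim(ph$image), 1)), frame_rate = 1,
                   pixel_pitch = 0.2)
  curve <- resample_curve_with_normals(
    cbind((ncol(ph$image) + 1) / 2, seq(20, 76, by = 2)), normal_length = 30)
  P <- extract_profiles(v, curve)
  expect_equal(dim(P)[2], 31)
  expect_equal(dim(P)[1], nrow(curve$points))
  mins <- apply(P[, , 1], 1, which.min)
  expect_true(all(abs(mins - 16) <= 1))          # dip at the center offset
  flat <- video_stack(array(0.7, c(50, 50, 2)), frame_rate = 1)
  cf <- resample_curve_with_normals(cbind(10:40, 25), normal_length = 10)
  Pf <- extract_profiles(flat, cf)
  expect_true(all(abs(Pf - 0.7) < 1e-12))
})

test_that("ST map has the contracted shape and the Otsu/median conventions", {
  sc <- tiny_scene(duration = 4, seed = 3, noise_sigma = 0.01)
  sim <- render_motility_video(sc, motility_config())
  S <- st_map_from_video(sim$video, sim$truth$centerline_px, 40)
  curve <- resample_curve_with_normals(sim$truth$centerline_px, 40)
  expect_identical(dim(unclass(S)),
                   c(nrow(curve$points), n_frames(sim$video)))
  expect_true(all(S >= 0))

  konst <- video_stack(array(0.6, c(60, 60, 5)), frame_rate = 1)
  ck <- resample_curve_with_normals(cbind(15:45, 30), normal_length = 10)
  Pk <- extract_profiles(konst, ck)
  Sk <- build_st_map(Pk)
  expect_true(all(abs(Sk - Sk[1, 1]) < 1e-12))   # constant in, constant out
})

test_that("Otsu threshold separates a two-level histogram between the modes", {
  set.seed(4)
  x <- matrix(sample(c(0.2, 0.8), 400, replace = TRUE), 20, 20)
  thr <- EBImage::otsu(x, range = c(0, 1))
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
  # equals the exhaustive inter-class-variance scan
  oracle <- otsu_oracle(x)
  expect_equal(interclass_variance(x, thr), oracle$variance,
               tolerance = 1e-12)
})

test_that("segmentation and peristalsis maps are discriminated by peak drift", {
  sc <- tiny_scene(duration = 12, seed = 6)
  seg <- render_motility_video(sc, motility_config(pattern = "segmentation"))
  per <- render_motility_video(sc, motility_config(pattern = "peristalsis"))
  Ss <- st_map_from_video(seg$video, seg$truth$centerline_px, 40)
  Sp <- st_map_from_video(per$video, per$truth$centerline_px, 40)
  cs <- classify_motor_pattern(Ss)
  cp <- classify_motor_pattern(Sp)
  expect_equal(cs$pattern, "segmentation")
  expect_equal(cp$pattern, "peristalsis")
  # peristaltic drift per period approximates wave speed x period
  fr <- attr(per$video, "frame_rate")
  pp <- attr(per$video, "pixel_pitch")
  v_est <- abs(cp$slope_px_per_frame) * pp * fr
  expect_equal(v_est, 2, tolerance = 0.4)
})
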