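test_that("frame similarity is 1 for identical frames and -1 for anti-correlated ones", {
  f <- matrix(runif(64 * 64), 64, 64)
  v_same <- video_stack(array(rep(f, 5), c(64, 64, 5)), frame_rate = 1)
  tr <- frame_similarity(v_same)
  expect_equal(tr$values, rep(1, 5))

  v_anti <- video_stack(array(c(f, 1 - f), c(64, 64, 2)), frame_rate = 1)
  tr2 <- frame_similarity(v_anti)
  expect_equal(tr2$values[2], -1)

  v_flat <- video_stack(array(c(f, matrix(0.5, 64, 64)), c(64, 64, 2)),
                        frame_rate = 1)
  tr3 <- frame_similarity(v_flat)
  expect_equal(tr3$values[2], 0)
  expect_true(tr3$zero_variance[2])
})

test_that("a pose switch drops the similarity and splits exactly two epochs", {
  sc <- tiny_scene(duration = 4, seed = 17, frame_rate = 5)
  sched <- data.frame(time = c(0, 2), angle = c(0, 50),
                      cx = c(96.5, 110), cy = c(96.5, 85))
  sim <- render_motility_video(sc, motility_config(),
                               motion_config(sched, interpolation = "hold"))
  k <- which(sim$truth$pose$angle > 0)[1]       # switch frame
  tr <- frame_similarity(sim$video, roi = c(49, 49, 96, 96))
  expect_gt(tr$values[k - 1] - tr$values[k], 0.2)
  ep <- segment_behaviors(tr, min_epoch_frames = 3)
  expect_equal(nrow(ep), 2)
  expect_lte(abs(ep$start[2] - k), 1)
})

test_that("epoch segmentation merges short epochs and handles constants", {
  konst <- structure(list(values = rep(1, 20), resets = integer(0),
                          drop_threshold = 0.8,
                          zero_variance = logical(20)),
                     class = "similarity_trace")
  expect_equal(nrow(segment_behaviors(konst)), 1)

  noisy <- structure(list(values = rep(0.5, 100), resets = integer(0),
                          drop_threshold = 0.8,
                          zero_variance = logical(100)),
                     class = "similarity_trace")
  ep <- segment_behaviors(noisy, min_epoch_frames = 10)
  expect_true(all(ep$end - ep$start + 1 >= 10))
  expect_equal(sum(ep$end - ep$start + 1), 100)
})

test_that("stitching concatenates epochs and keeps single maps unchanged", {
  mk <- function(nc, val) {
    structure(matrix(val, 8, nc), frame_rate = 15, pixel_pitch = 0.2,
              position_spacing_px = 1, inverted = TRUE,
              class = c("st_map", "matrix", "array"))
  }
  st <- stitch_st_maps(list(mk(100, 1), mk(100, 2)))
  expect_equal(dim(unclass(st)), c(8L, 200L))
  expect_equal(attr(st, "epoch_boundaries"), c(100, 200))
  expect_equal(unclass(st)[1, 101], 2)

  single <- stitch_st_maps(list(mk(40, 3)))
  plain <- unclass(single)
  attr(plain, "epoch_boundaries") <- NULL
  expect_equal(plain, unclass(mk(40, 3)))

  bad <- structure(matrix(0, 5, 10), frame_rate = 15,
                   class = c("st_map", "matrix", "array"))
  expect_error(stitch_st_maps(list(mk(10, 1), bad)), "row mismatch")
  fixed <- stitch_st_maps(list(mk(10, 1), bad), resample_rows = TRUE)
  expect_equal(nrow(fixed), 8)
})

test_that("a motion-free recording is one epoch whose stitched map equals the plain map", {
  sc <- tiny_scene(duration = 6, seed = 23)
  sim <- render_motility_video(sc, motility_config())
  tr <- frame_similarity(sim$video)
  ep <- segment_behaviors(tr, min_epoch_frames = 5)
  expect_equal(nrow(ep), 1)
  S <- st_map_from_video(sim$video, sim$truth$centerline_px, 40)
  stitched <- stitch_st_maps(list(S))
  plain <- unclass(stitched)
  attr(plain, "epoch_boundaries") <- NULL
  expect_identical(plain, unclass(S))
  # total stitched columns = sum of epoch frame counts
  expect_equal(ncol(stitched), sum(ep$end - ep$start + 1))
})

test_that("per-epoch maps recover the generator frequency after stitching", {
  sc <- tiny_scene(duration = 16, seed = 29)
  sched <- data.frame(time = c(0, 8), angle = c(0, 35),
                      cx = c(96.5, 96.5), cy = c(96.5, 96.5))
  mo <- motility_config(contraction_frequency = 0.772)
  sim <- render_motility_video(sc, mo, motion_config(sched, "hold"))
  tr <- frame_similarity(sim$video, roi = c(49, 49, 96, 96))
  ep <- segment_behaviors(tr, min_epoch_frames = 10)
  expect_equal(nrow(ep), 2)
  fr <- attr(sim$video, "frame_rate")
  maps <- lapply(seq_len(nrow(ep)), function(i) {
    idx <- ep$start[i]:ep$end[i]
    sub <- video_stack(sim$video[, , idx, drop = FALSE], frame_rate = fr,
                       pixel_pitch = attr(sim$video, "pixel_pitch"))
    reg <- register_video(sub)
    pose1 <- sim$truth$pose[idx[1], ]
    ctr <- c((dim(sub)[2] + 1) / 2, (dim(sub)[1] + 1) / 2)
    posed <- apply_pose(sim$truth$centerline_px, pose1$angle,
                        c(pose1$cx, pose1$cy), ctr)
    curve <- apply_transform(reg$transforms[[1]], posed)
    st_map_from_video(reg$video, curve, 40)
  })
  long <- stitch_st_maps(maps)
  expect_equal(ncol(long), n_frames(sim$video))
  site <- sim$truth$sites_mm[2]
  rows <- round(site / attr(sim$video, "pixel_pitch")) + (-3:3)
  for (i in 1:2) {
    cols <- if (i == 1) 1:attr(long, "epoch_boundaries")[1] else
      (attr(long, "epoch_boundaries")[1] + 1):ncol(long)
    sub <- unclass(long)[, cols]
    series <- colMeans(sub[rows, ])
    f <- peak_frequency(series, band = c(0.3, 1.5), frame_rate = fr)
    expect_lte(abs(f$peak_frequency - 0.772), 2 * f$bin_width)
  }
})
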