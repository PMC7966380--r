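test_that("silhouette extraction finds the second-largest dark component", {
  fx <- disk_blob_frame()
  sil <- extract_silhouette(fx$frame, denoise_sigma = 0, clean_radius = 0)
  # oracle: at the terminating threshold, label the complement directly and
  # take its second-largest component
  lab <- tipr:::label_components(fx$frame < sil$threshold)
  areas <- tabulate(lab[lab > 0])
  second <- order(areas, decreasing = TRUE)[2]
  expect_identical(sil$mask, lab == second)
  # the blob is the second-largest dark region
  expect_gt(jaccard_masks(sil$mask, fx$blob), 0.99)
  expect_gte(sil$ratio, 0.05)
})

test_that("silhouette extraction fails cleanly on structureless frames", {
  expect_error(extract_silhouette(matrix(1, 50, 50), denoise_sigma = 0),
               "no silhouette")
})

test_that("convex hull mask is idempotent on convex shapes and fills concave ones", {
  fx <- disk_blob_frame()
  disk_mask <- fx$blob
  hull <- convex_hull_mask(disk_mask)
  expect_gte(jaccard_masks(hull$mask, disk_mask), 0.99)
  expect_true(all(hull$mask[disk_mask]))      # superset

  # L-shape: hull must fill the notch; compare to a half-plane oracle on the
  # vertex set
  L <- matrix(FALSE, 40, 40)
  L[10:30, 10:15] <- TRUE
  L[25:30, 10:30] <- TRUE
  hl <- convex_hull_mask(L)
  expect_true(all(hl$mask[L]))
  expect_gt(sum(hl$mask), sum(L))
  idx <- which(L, arr.ind = TRUE)
  ch <- grDevices::chull(idx[, 2], idx[, 1])
  vx <- idx[ch, 2]
  vy <- idx[ch, 1]
  inside_oracle <- function(px, py) {
    nh <- length(vx)
    for (e in seq_len(nh)) {
      x1 <- vx[e]; y1 <- vy[e]
      x2 <- vx[e %% nh + 1]; y2 <- vy[e %% nh + 1]
      if ((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1) > 1e-9) return(FALSE)
    }
    TRUE
  }
  set.seed(5)
  for (k in 1:50) {
    px <- sample(8:32, 1)
    py <- sample(8:32, 1)
    expect_equal(unname(hl$mask[py, px]), inside_oracle(px, py))
  }

  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  expect_identical(convex_hull_mask(single)$mask, single)
  expect_error(convex_hull_mask(matrix(FALSE, 3, 3)), "empty")
})

test_that("second-order central moments match closed forms and the coordinate oracle", {
  sq <- matrix(TRUE, 3, 3)
  m <- compute_moments(sq)
  expect_equal(m$mu_xx, 2 / 3)
  expect_equal(m$mu_yy, 2 / 3)
  expect_equal(m$mu_xy, 0)

  row5 <- matrix(FALSE, 5, 7)
  row5[3, 2:6] <- TRUE
  m2 <- compute_moments(row5)
  expect_equal(m2$mu_xx, 2)
  expect_equal(m2$mu_yy, 0)
  expect_equal(m2$mu_xy, 0)

  set.seed(8)
  blob <- matrix(runif(30 * 30) < 0.3, 30, 30)
  blob[1, 1] <- TRUE
  m3 <- compute_moments(blob)
  oracle <- moments_oracle(blob)
  expect_equal(m3$centroid, unname(oracle$centroid), tolerance = 1e-9)
  expect_equal(unname(m3$cov), unname(oracle$cov), tolerance = 1e-9)
  # covariance invariants
  expect_equal(m3$cov[1, 2], m3$cov[2, 1])
  expect_true(all(eigen(m3$cov)$values >= -1e-12))
  expect_lte(m3$mu_xy^2, m3$mu_xx * m3$mu_yy + 1e-12)
  expect_error(compute_moments(matrix(FALSE, 3, 3)), "empty")
})

test_that("pose angles follow the major axis", {
  row5 <- matrix(FALSE, 5, 7)
  row5[3, 2:6] <- TRUE
  expect_equal(pose_from_moments(compute_moments(row5))$theta, 0)

  col5 <- matrix(FALSE, 7, 5)
  col5[2:6, 3] <- TRUE
  expect_equal(pose_from_moments(compute_moments(col5))$theta, 90)

  # rotated ellipse: theta within 1 degree of truth and of the closed form
  x <- matrix(rep(1:201, each = 201), 201, 201)
  y <- t(x)
  a <- 30 * pi / 180
  xr <- cos(a) * (x - 101) + sin(a) * (y - 101)
  yr <- -sin(a) * (x - 101) + cos(a) * (y - 101)
  ell <- (xr / 60)^2 + (yr / 25)^2 <= 1
  m <- compute_moments(ell)
  p <- pose_from_moments(m)
  expect_lt(theta_err(p$theta, 30), 1)
  expect_lt(theta_err(p$theta, theta_closed_form(m)), 1e-6)

  # isotropic mask is degenerate
  iso <- pose_from_moments(compute_moments(matrix(TRUE, 9, 9)))
  expect_true(iso$degenerate)
  expect_equal(iso$theta, 0)
})

test_that("moment covariance is rotation-equivariant and translation-invariant", {
  x <- matrix(rep(1:121, each = 121), 121, 121)
  y <- t(x)
  base <- ((x - 61) / 35)^2 + ((y - 61) / 14)^2 <= 1
  m0 <- compute_moments(base)
  for (ang in c(20, 55, 110)) {
    rot <- warp_rigid(base * 1, ang) > 0.5
    p <- pose_from_moments(compute_moments(rot))
    expect_lt(theta_err(p$theta, ang), 1)
  }
  shifted <- matrix(FALSE, 121, 121)
  shifted[which(base, arr.ind = TRUE) + 5] <- TRUE   # translate by (5, 5)
  expect_equal(eigen(compute_moments(shifted)$cov)$values,
               eigen(m0$cov)$values, tolerance = 1e-12)
})

test_that("register_frame with matching pose is the identity", {
  set.seed(1)
  img <- matrix(runif(60 * 60), 60, 60)
  pose <- structure(list(theta = 90, centroid = c(30.5, 30.5),
                         eigenvalues = c(2, 1), eccentricity = 0.7,
                         degenerate = FALSE), class = "rigid_pose")
  out <- register_frame(img, pose, pose)
  expect_lt(max(abs(out$frame - img)), 1e-6)
  expect_equal(out$transform$angle_applied, 0)
})

test_that("registration recovers scripted poses on noise-free scenes", {
  sc <- tiny_scene(duration = 3, seed = 21, noise_sigma = 0, frame_rate = 5)
  mo <- motility_config()
  sched <- data.frame(time = c(0, 3), angle = c(10, 32),
                      cx = c(96.5, 103), cy = c(96.5, 91))
  sim <- render_motility_video(sc, mo, motion_config(sched))
  reg <- register_video(sim$video)
  terr <- theta_err(reg$poses$theta, sim$truth$pose$angle)
  cerr <- sqrt((reg$poses$cx - sim$truth$pose$cx)^2 +
                 (reg$poses$cy - sim$truth$pose$cy)^2)
  expect_lt(max(terr), 1)
  expect_lt(max(cerr), 1)
  # registered silhouettes overlap the first registered frame
  masks <- lapply(seq_len(n_frames(reg$video)), function(i) {
    extract_silhouette(get_frame(reg$video, i))$mask
  })
  js <- vapply(2:length(masks), function(i) {
    jaccard_masks(masks[[1]], masks[[i]])
  }, numeric(1))
  expect_gte(min(js), 0.97)
  # transforms map the frame centroid onto the anchor centroid
  for (i in seq_along(reg$transforms)) {
    tr <- reg$transforms[[i]]
    p <- apply_transform(tr, matrix(c(reg$poses$cx[i], reg$poses$cy[i]),
                                    1, 2))
    expect_lt(sqrt(sum((p - reg$anchor$centroid)^2)), 0.5)
  }
})

test_that("registration is idempotent within interpolation tolerance", {
  sc <- tiny_scene(duration = 1, seed = 13, noise_sigma = 0, frame_rate = 3)
  sched <- data.frame(time = c(0, 1), angle = c(25, 25),
                      cx = c(100, 100), cy = c(92, 92))
  sim <- render_motility_video(sc, motility_config(), motion_config(sched))
  reg1 <- register_video(sim$video)
  reg2 <- register_video(reg1$video)
  expect_lt(abs(reg2$transforms[[2]]$angle_applied) %% 180, 1.5)
  d <- abs(get_frame(reg2$video, 2) - get_frame(reg1$video, 2))
  expect_lt(mean(d), 0.01)
})

test_that("degenerate inputs are rejected or flagged", {
  one_frame <- video_stack(array(0.5, c(20, 20, 1)), frame_rate = 1)
  expect_error(register_video(one_frame), "at least 2")
})
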