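# shared fixture: three vertical tubes at the hair-experiment depths
lf_three_tubes <- function() {
  g <- lenslet_grid(pitch = 5, n_lenslets = c(41, 41), slope_per_mm = 0.3)
  src <- data.frame(x = c(10, 21, 32), y = 21, depth = c(-2, 1, 5),
                    type = "tube")
  list(grid = g, src = src, lf = render_lightfield(src, g))
}

test_that("decode is the exact inverse of encode", {
  fx <- lf_three_tubes()
  dec <- decode_lightfield(fx$lf$raw, fx$grid)
  expect_identical(dec$lf, fx$lf$lf)
  bad <- matrix(0, 17, 20)
  expect_error(decode_lightfield(bad, fx$grid), "divisible")
  # uniform mosaic decodes to uniform sub-aperture images
  g2 <- lenslet_grid(pitch = 3, n_lenslets = c(4, 4))
  u <- decode_lightfield(matrix(0.4, 12, 12), g2)
  expect_true(all(u$lf == 0.4))
})

test_that("refocusing at slope 0 is the sub-aperture mean; uniform fields stay uniform", {
  fx <- lf_three_tubes()
  r0 <- refocus(fx$lf$lf, 0)
  mean_sub <- apply(fx$lf$lf, c(3, 4), mean)
  expect_lt(max(abs(r0 - mean_sub)), 1e-14)

  g2 <- lenslet_grid(pitch = 3, n_lenslets = c(8, 8))
  unif <- array(0.25, dim = c(3, 3, 8, 8))
  for (s in c(-0.5, 0, 0.8)) {
    ri <- refocus(unif, s)
    interior <- ri[3:6, 3:6]
    expect_true(all(abs(interior - 0.25) < 1e-12))
  }
  expect_error(refocus(unif, 20), "exceed")
})

test_that("a point is sharpest when refocused at its own depth", {
  g <- lenslet_grid(pitch = 5, n_lenslets = c(31, 31), slope_per_mm = 0.3)
  for (z in c(-2, 0, 3)) {
    lf <- render_lightfield(data.frame(x = 16, y = 16, depth = z,
                                       type = "point"), g)
    st <- focal_stack(lf$lf, depths = seq(-4, 4, by = 1), grid = g)
    sharp <- vapply(seq_len(dim(st)[3]), function(i) max(st[, , i]),
                    numeric(1))
    expect_equal(attr(st, "depths")[which.max(sharp)], z)
  }
})

test_that("focal stacks conserve interior mean intensity within 1%", {
  fx <- lf_three_tubes()
  st <- focal_stack(fx$lf$lf, depths = seq(-3, 3, by = 1.5), grid = fx$grid)
  # trim rows near the tube ends (content shifted past the border is lost
  # there) but keep all columns, where content only redistributes
  raw_mean <- mean(apply(fx$lf$lf, c(3, 4), mean)[6:36, ])
  for (i in seq_len(dim(st)[3])) {
    expect_equal(mean(st[6:36, , i]), raw_mean, tolerance = 0.01)
  }
  expect_error(focal_stack(fx$lf$lf, c(0, 1, 0.5), grid = fx$grid),
               "monotonic")
})

test_that("depth-index map assigns each tube its true stack plane", {
  fx <- lf_three_tubes()
  st <- focal_stack(fx$lf$lf, depths = seq(-4, 6, by = 1), grid = fx$grid)
  dm <- depth_index_map(st)
  for (i in 1:3) {
    cols <- fx$src$x[i] + (-1:1)
    med <- stats::median(dm$depth[, cols], na.rm = TRUE)
    expect_equal(med, fx$src$depth[i])
  }
  # structure-free background is masked as low confidence (columns far
  # enough from every tube that no refocused spill reaches the window)
  bg_cols <- c(1, 41)
  expect_true(mean(is.na(dm$depth[, bg_cols])) > 0.9)

  single <- focal_stack(fx$lf$lf, depths = 0, grid = fx$grid)
  dms <- depth_index_map(single)
  expect_true(dms$degenerate)
  expect_true(all(dms$depth == 0))
})

test_that("axial MAP over the depth axis bounds every slice", {
  fx <- lf_three_tubes()
  st <- focal_stack(fx$lf$lf, depths = seq(-2, 2, by = 1), grid = fx$grid)
  m <- minimal_amplitude_projection(st)
  for (i in seq_len(dim(st)[3])) {
    expect_true(all(m <= st[, , i] + 1e-12))
  }
})

test_that("lateral vs axial ST maps expose contraction anisotropy", {
  # synthetic focal-stack sequence: a vertical tube at x0 whose absorbance
  # is a separable Gaussian in (x, z); lateral width sigma_x(t), axial
  # sigma_z(t)
  mk_stacks <- function(sig_x, sig_z, nt = 60, nx = 41, nz = 21) {
    depths <- seq(-5, 5, by = 0.5)
    x0 <- 21
    z0 <- 0
    lapply(seq_len(nt), function(k) {
      sx <- sig_x(k)
      sz <- sig_z(k)
      a <- array(0, dim = c(nx, nx, nz))
      for (zi in seq_len(nz)) {
        prof <- exp(-((seq_len(nx) - x0)^2) / (2 * sx^2)) *
          exp(-((depths[zi] - z0)^2) / (2 * sz^2))
        a[, , zi] <- 1 - 0.8 * matrix(rep(prof, each = nx), nx, nx)
      }
      structure(a, depths = depths, class = c("focal_stack", "array"))
    })
  }
  curve <- resample_curve_with_normals(cbind(21, seq(8, 34, by = 2)),
                                       normal_length = 20)
  osc <- function(k) 3 + 1.5 * sin(2 * pi * k / 20)
  fixed <- function(k) 3

  iso <- axial_st_map(mk_stacks(osc, function(k) 0.5 * osc(k)), curve,
                      frame_rate = 5)
  amp <- function(S) mean(apply(unclass(S), 1, function(r) diff(range(r))))
  # isotropic contraction modulates both maps comparably
  expect_gt(amp(iso$axial), 0.3 * amp(iso$lateral))

  aniso <- axial_st_map(mk_stacks(osc, fixed), curve, frame_rate = 5)
  expect_gt(amp(aniso$lateral), 2 * amp(aniso$axial))

  static <- axial_st_map(mk_stacks(fixed, fixed), curve, frame_rate = 5)
  expect_lt(amp(static$lateral), 1e-9)
  expect_lt(amp(static$axial), 1e-9)
})
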