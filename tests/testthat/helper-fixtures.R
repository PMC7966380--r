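# Shared fixtures and independent oracles, built in code at test time.

# small, fast scene for pipeline-level tests
tiny_scene <- function(duration = 8, seed = 1, noise_sigma = 0.02,
                       frame_rate = 15) {
  scene_config(image_size = c(192, 192), illumination_radius = 80,
               duration = duration, rng_seed = seed,
               noise_sigma = noise_sigma, frame_rate = frame_rate)
}

# a hand-built frame matching the silhouette-extraction geometry: bright
# disk on dark background with an intermediate blob inside it
disk_blob_frame <- function(h = 100, w = 100, disk_level = 0.9,
                            blob_level = 0.5, bg_level = 0.1,
                            disk_radius = 25, blob_center = c(50, 50),
                            blob_radius = 14) {
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep.int(seq_len(h), w), h, w)
  f <- matrix(bg_level, h, w)
  disk <- (x - (w + 1) / 2)^2 + (y - (h + 1) / 2)^2 <= disk_radius^2
  f[disk] <- disk_level
  blob <- (x - blob_center[1])^2 + (y - blob_center[2])^2 <= blob_radius^2
  f[blob] <- blob_level
  list(frame = f, disk = disk, blob = blob)
}

# exhaustive inter-class-variance scan over a 256-bin histogram in [0, 1]
otsu_oracle <- function(x, levels = 256) {
  b <- seq(0, 1, length.out = levels + 1)
  h <- hist(as.vector(x), breaks = b, plot = FALSE)$counts
  centers <- (b[-1] + b[-(levels + 1)]) / 2
  n <- sum(h)
  best_var <- -1
  best_t <- centers[1]
  for (k in seq_len(levels - 1)) {
    w0 <- sum(h[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * centers[1:k]) / sum(h[1:k])
    mu1 <- sum(h[(k + 1):levels] * centers[(k + 1):levels]) /
      sum(h[(k + 1):levels])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_var) {
      best_var <- v
      best_t <- centers[k]
    }
  }
  list(threshold = best_t, variance = best_var)
}

# inter-class variance of a given threshold on the same 256-bin histogram
interclass_variance <- function(x, thr, levels = 256) {
  b <- seq(0, 1, length.out = levels + 1)
  h <- hist(as.vector(x), breaks = b, plot = FALSE)$counts
  centers <- (b[-1] + b[-(levels + 1)]) / 2
  n <- sum(h)
  lo <- centers <= thr
  w0 <- sum(h[lo]) / n
  w1 <- 1 - w0
  if (w0 == 0 || w1 == 0) return(0)
  mu0 <- sum(h[lo] * centers[lo]) / sum(h[lo])
  mu1 <- sum(h[!lo] * centers[!lo]) / sum(h[!lo])
  w0 * w1 * (mu0 - mu1)^2
}

# sort-based 2x2 median oracle (mean of the two middle order statistics),
# edge replication
median2x2_oracle <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      i2 <- min(i + 1, h)
      j2 <- min(j + 1, w)
      v <- sort(c(m[i, j], m[i2, j], m[i, j2], m[i2, j2]))
      out[i, j] <- (v[2] + v[3]) / 2
    }
  }
  out
}

# brute-force two-sided rank-sum p by enumerating all C(n+m, n) assignments
wilcoxon_oracle <- function(a, b) {
  r <- rank(c(a, b))
  n <- length(a)
  w <- sum(r[seq_len(n)])
  sums <- utils::combn(length(r), n, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}

# direct coordinate-covariance oracle (population normalization)
moments_oracle <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  co <- cbind(x = idx[, 2], y = idx[, 1])
  n <- nrow(co)
  list(centroid = colMeans(co),
       cov = stats::cov(co) * (n - 1) / n)
}

# closed-form principal-axis angle from central moments, degrees in [0, 180)
theta_closed_form <- function(m) {
  (atan2(2 * m$mu_xy, m$mu_xx - m$mu_yy) / 2 * 180 / pi) %% 180
}

jaccard_masks <- function(a, b) sum(a & b) / sum(a | b)

# angular difference folded to [0, 90] (major axis is orientation mod 180)
theta_err <- function(a, b) abs(((a - b + 90) %% 180) - 90)
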