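# Motor-pattern quantification: cross-section series, spectral peak
# frequency, exact rank-sum group comparison, phantom contrast and FWHM,
# and diameter-change estimation.

#' Average cross-section time series from an ST map
#'
#' @param S an `st_map`.
#' @param rows integer vector of map rows (intestine positions) to average.
#' @return object of class `cross_section_series`: list with `values`,
#'   `frame_rate`, `rows`.
#' @export
cross_section_series <- function(S, rows) {
  stopifnot(length(rows) >= 1)
  if (any(rows < 1 | rows > nrow(S))) {
    stop("row range outside the map")
  }
  structure(list(values = colMeans(S[rows, , drop = FALSE]),
                 frame_rate = attr(S, "frame_rate"),
                 rows = rows),
            class = "cross_section_series")
}

#' Peak frequency of a cross-section series
#'
#' The series is detrended (mean and linear trend removed), Hann-windowed,
#' and Fourier-transformed; the peak is the largest magnitude within the
#' analysis band. The default band 0.1-2.0 Hz brackets murine segmentation
#' rates.
#'
#' @param series a [cross_section_series()], or a numeric vector (then
#'   `frame_rate` must be given).
#' @param band `(f_lo, f_hi)` Hz.
#' @param frame_rate sampling rate in Hz when `series` is a plain vector.
#' @return object of class `frequency_result`: list with `peak_frequency`
#'   (Hz), `bin_width` (Hz), `spectrum` (data frame: frequency, amplitude,
#'   restricted to the band), `band`.
#' @export
peak_frequency <- function(series, band = c(0.1, 2.0), frame_rate = NULL) {
  if (inherits(series, "cross_section_series")) {
    v <- series$values
    fs <- series$frame_rate
  } else {
    v <- as.numeric(series)
    fs <- frame_rate
    if (is.null(fs)) stop("frame_rate required for a plain numeric series")
  }
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  n <- length(v)
  if (fs <= 2 * band[2]) {
    stop(sprintf(
      "Nyquist violated: band up to %.3g Hz requires frame rate > %.3g Hz",
      band[2], 2 * band[2]))
  }
  if (n / fs < 2 / band[1]) {
    stop(sprintf("series too short: need at least %.3g s for f_lo = %.3g Hz",
                 2 / band[1], band[1]))
  }
  tt <- seq_len(n)
  v <- stats::residuals(stats::lm(v ~ tt))
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  spec <- Mod(stats::fft(v * hann))
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  freqs <- freqs[half]
  spec <- spec[half]
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("no spectral bins inside the band")
  if (max(spec[in_band]) < n * 1e-12) {
    stop("zero-amplitude series: no spectral peak in band")
  }
  idx <- which(in_band)[which.max(spec[in_band])]
  structure(list(peak_frequency = freqs[idx],
                 bin_width = fs / n,
                 spectrum = data.frame(frequency = freqs[in_band],
                                       amplitude = spec[in_band]),
                 band = band),
            class = "frequency_result")
}

#' Two-sided Wilcoxon rank-sum comparison of two frequency groups
#'
#' Exact two-sided p value by full enumeration of rank assignments when
#' `min(n, m) <= max_exact` (ties are mid-ranked and enumeration runs on the
#' tied ranks); the large-sample normal approximation with tie correction is
#' used above that. The two-sided p is `min(1, 2 * min(P(W <= w),
#' P(W >= w)))`.
#'
#' @param group_a,group_b numeric vectors (e.g. per-mouse peak frequencies).
#' @param max_exact largest `min(n, m)` for which enumeration is used.
#' @return list with `p_value`, `statistic` (rank sum of `group_a`),
#'   `method`.
#' @export
compare_frequencies <- function(group_a, group_b, max_exact = 8) {
  n <- length(group_a)
  m <- length(group_b)
  if (n < 1 || m < 1) stop("both groups must be non-empty")
  r <- rank(c(group_a, group_b))
  w <- sum(r[seq_len(n)])
  if (min(n, m) <= max_exact) {
    sums <- utils::combn(n + m, n, function(ix) sum(r[ix]))
    eps <- 1e-9
    p_le <- mean(sums <= w + eps)
    p_ge <- mean(sums >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    N <- n + m
    ties <- table(r)
    mu <- n * (N + 1) / 2
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = w, method = method)
}

#' Transillumination contrast parameter
#'
#' `Contrast = (A_b - A_t) / A_t`: a darker tube and brighter background
#' give a larger contrast.
#'
#' @param A_b mean background amplitude.
#' @param A_t mean tube amplitude (> 0).
#' @return dimensionless contrast.
#' @export
contrast_parameter <- function(A_b, A_t) {
  if (any(A_t <= 0)) stop("A_t must be positive")
  (A_b - A_t) / A_t
}

#' Full width at half maximum of a tube cross-section profile
#'
#' The baseline is the median of the outer 20% of samples; the dominant
#' extremum (a dip for transillumination tubes, inverted internally) defines
#' the depth; the width is measured between the two half-depth crossings
#' with linear interpolation.
#'
#' @param profile numeric vector (one cross-section).
#' @return width in samples (px).
#' @export
profile_fwhm <- function(profile) {
  v <- as.numeric(profile)
  n <- length(v)
  if (n < 5) stop("profile too short")
  k <- max(1, floor(0.1 * n))
  baseline <- stats::median(c(v[seq_len(k)], v[n - seq_len(k) + 1]))
  dip <- baseline - min(v)
  peak <- max(v) - baseline
  y <- if (dip >= peak) baseline - v else v - baseline   # extremum now a max
  i0 <- which.max(y)
  depth <- y[i0]
  if (depth <= 0) stop("no extremum against the baseline")
  half <- depth / 2
  il <- i0
  while (il > 1 && y[il] > half) il <- il - 1
  if (y[il] > half) stop("no half-maximum crossing on the left")
  xl <- il + (half - y[il]) / (y[il + 1] - y[il])
  ir <- i0
  while (ir < n && y[ir] > half) ir <- ir + 1
  if (y[ir] > half) stop("no half-maximum crossing on the right")
  xr <- ir - 1 + (y[ir - 1] - half) / (y[ir - 1] - y[ir])
  xr - xl
}

#' Phantom contrast and width metrics from a cross-section profile
#'
#' @param profile numeric cross-section (tube dip on bright background).
#' @param tube_width_px true tube width in px; if given, `A_t` is the mean
#'   over the central `tube_width_px` samples, otherwise over the FWHM
#'   support.
#' @return object of class `phantom_metrics`: list with `A_b`, `A_t`,
#'   `contrast`, `fwhm` (px).
#' @export
phantom_metrics <- function(profile, tube_width_px = NULL) {
  v <- as.numeric(profile)
  n <- length(v)
  k <- max(1, floor(0.1 * n))
  A_b <- mean(c(v[seq_len(k)], v[n - seq_len(k) + 1]))
  fw <- profile_fwhm(v)
  ctr <- which.min(v)
  halfw <- (tube_width_px %||% fw) / 2
  sel <- seq.int(max(1, ceiling(ctr - halfw)), min(n, floor(ctr + halfw)))
  A_t <- mean(v[sel])
  structure(list(A_b = A_b, A_t = A_t,
                 contrast = contrast_parameter(A_b, A_t), fwhm = fw),
            class = "phantom_metrics")
}

#' Diameter change between resting and contracted cross-sections
#'
#' @param resting_profile,contracted_profile cross-section profiles suitable
#'   for [profile_fwhm()].
#' @param pixel_pitch mm/px for mm-unit reporting (optional).
#' @return list with `ratio` (contracted/resting FWHM), `change`
#'   (`1 - ratio`), `fwhm_resting`, `fwhm_contracted` (px), and mm versions
#'   when `pixel_pitch` is given.
#' @export
diameter_change <- function(resting_profile, contracted_profile,
                            pixel_pitch = NULL) {
  fr <- profile_fwhm(resting_profile)
  fc <- profile_fwhm(contracted_profile)
  out <- list(ratio = fc / fr, change = 1 - fc / fr,
              fwhm_resting = fr, fwhm_contracted = fc)
  if (!is.null(pixel_pitch)) {
    out$fwhm_resting_mm <- fr * pixel_pitch
    out$fwhm_contracted_mm <- fc * pixel_pitch
  }
  out
}

#' Contrast/FWHM sweep over phantom depths
#'
#' Runs [render_tube_phantom()] over a vector of depths in one of the two
#' phantom modes and collects [phantom_metrics()] per depth. In `fixed_t1`
#' the illumination-side thickness is fixed and the camera-side depth
#' varies; in `fixed_t2` the converse.
#'
#' @param depths numeric vector of varied depths, mm.
#' @param mode `"fixed_t1"` or `"fixed_t2"`.
#' @param fixed_depth the non-varied thickness, mm.
#' @param tube_diameter mm.
#' @param ... passed to [render_tube_phantom()].
#' @return data frame with columns depth, contrast, fwhm_px, A_b, A_t.
#' @export
phantom_depth_sweep <- function(depths, mode = c("fixed_t1", "fixed_t2"),
                                fixed_depth = 4, tube_diameter = 2, ...) {
  mode <- match.arg(mode)
  rows <- lapply(depths, function(d) {
    ph <- if (mode == "fixed_t1") {
      render_tube_phantom(tube_diameter, depth_above = fixed_depth,
                          depth_below = d, mode = mode, ...)
    } else {
      render_tube_phantom(tube_diameter, depth_above = d,
                          depth_below = fixed_depth, mode = mode, ...)
    }
    pm <- phantom_metrics(ph$profile, tube_width_px = ph$truth$tube_width_px)
    data.frame(depth = d, contrast = pm$contrast, fwhm_px = pm$fwhm,
               A_b = pm$A_b, A_t = pm$A_t)
  })
  do.call(rbind, rows)
}
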