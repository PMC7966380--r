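# Dual-wavelength acquisition: demultiplexing alternating-illumination
# stacks into per-agent channels and color-overlay composition.

#' Acquisition schedule of per-frame wavelength labels
#'
#' @param labels vector of wavelength labels, one per frame, drawn from
#'   exactly two values (e.g. 808 and 980).
#' @param frame_rate acquisition rate in Hz (2 Hz for dual-color capture by
#'   default).
#' @param require_alternating enforce strict alternation.
#' @return object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(labels, frame_rate = 2,
                                 require_alternating = TRUE) {
  u <- unique(labels)
  if (length(u) != 2) stop("schedule must contain exactly 2 distinct labels")
  if (require_alternating && any(labels[-1] == labels[-length(labels)])) {
    stop("schedule is not strictly alternating")
  }
  structure(list(labels = labels, wavelengths = u,
                 frame_rate = frame_rate),
            class = "acquisition_schedule")
}

#' Alternating schedule helper
#' @param n_frames total frame count.
#' @param wavelengths two labels, first one first.
#' @param frame_rate acquisition rate Hz.
#' @return an [acquisition_schedule()].
#' @export
alternating_schedule <- function(n_frames, wavelengths = c(808, 980),
                                 frame_rate = 2) {
  acquisition_schedule(rep_len(wavelengths, n_frames),
                       frame_rate = frame_rate)
}

#' Demultiplex an alternating-wavelength video into two channels
#'
#' Frames are routed by schedule label; each channel's effective frame rate
#' is the acquisition rate times its frame fraction, and original
#' acquisition timestamps are preserved per channel.
#'
#' @param video a [video_stack()].
#' @param schedule an [acquisition_schedule()] of the same length.
#' @return named list of two [video_stack()]s (names = wavelength labels),
#'   with attribute `empty_channels` naming any label with zero frames.
#' @export
demultiplex <- function(video, schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  nt <- n_frames(video)
  if (length(schedule$labels) != nt) {
    stop(sprintf("schedule length (%d) does not match frame count (%d)",
                 length(schedule$labels), nt))
  }
  ts <- attr(video, "timestamps")
  out <- lapply(schedule$wavelengths, function(wl) {
    idx <- which(schedule$labels == wl)
    if (length(idx) == 0) {
      return(NULL)
    }
    video_stack(video[, , idx, drop = FALSE],
                frame_rate = schedule$frame_rate * length(idx) / nt,
                pixel_pitch = attr(video, "pixel_pitch"),
                timestamps = ts[idx])
  })
  names(out) <- as.character(schedule$wavelengths)
  empty <- names(out)[vapply(out, is.null, logical(1))]
  if (length(empty) > 0) {
    warning("empty channel(s): ", paste(empty, collapse = ", "))
  }
  attr(out, "empty_channels") <- empty
  out
}

#' Re-interleave two demultiplexed channels
#'
#' Inverse of [demultiplex()]: routes each channel's frames back to their
#' original positions in the acquisition order.
#'
#' @param channels named list from [demultiplex()].
#' @param schedule the [acquisition_schedule()] used to split.
#' @return the reconstructed [video_stack()].
#' @export
interleave_channels <- function(channels, schedule) {
  nt <- length(schedule$labels)
  dims <- dim(channels[[which(!vapply(channels, is.null, logical(1)))[1]]])
  frames <- array(0, dim = c(dims[1], dims[2], nt))
  for (wl in as.character(schedule$wavelengths)) {
    ch <- channels[[wl]]
    if (is.null(ch)) next
    idx <- which(schedule$labels == wl)
    frames[, , idx] <- ch
  }
  video_stack(frames, frame_rate = schedule$frame_rate)
}

#' Two-channel color overlay of per-agent absorbance
#'
#' Each channel's absorbance (`1 - intensity`) is normalized to its own
#' maximum and mapped to a distinct color plane (channel 1 to red, channel
#' 2 to green by default); overlap regions carry both colors.
#'
#' @param ch1_frame,ch2_frame equally sized matrices, or `NULL` for an
#'   absent channel.
#' @param planes length-2 integer: RGB plane (1-3) per channel.
#' @return `H x W x 3` RGB array with attribute `channel_planes`.
#' @export
overlay_channels <- function(ch1_frame, ch2_frame, planes = c(1L, 2L)) {
  ref <- ch1_frame %||% ch2_frame
  if (is.null(ref)) stop("both channels empty")
  if (!is.null(ch1_frame) && !is.null(ch2_frame) &&
      !identical(dim(ch1_frame), dim(ch2_frame))) {
    stop("channel frames must have identical dimensions")
  }
  absb <- function(f) {
    if (is.null(f)) return(matrix(0, nrow(ref), ncol(ref)))
    a <- pmax(1 - f, 0)
    mx <- max(a)
    if (mx > 0) a / mx else a
  }
  rgb <- array(0, dim = c(nrow(ref), ncol(ref), 3))
  rgb[, , planes[1]] <- absb(ch1_frame)
  rgb[, , planes[2]] <- absb(ch2_frame)
  attr(rgb, "channel_planes") <- planes
  rgb
}

#' Pair frames of two channels by nearest acquisition time
#'
#' @param ch1,ch2 [video_stack()]s with `timestamps` attributes.
#' @return integer vector: for each ch1 frame, the index of the nearest ch2
#'   frame in time.
#' @export
pair_nearest_frames <- function(ch1, ch2) {
  t1 <- attr(ch1, "timestamps")
  t2 <- attr(ch2, "timestamps")
  vapply(t1, function(t) which.min(abs(t2 - t)), integer(1))
}
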