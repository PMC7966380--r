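# Video stack container and TIFF/CSV/JSON I/O.

#' Ordered grayscale video stack
#'
#' The pipeline's universal currency: an `H x W x T` numeric array of frames
#' normalized to [0, 1], with acquisition frame rate and (optionally) the
#' physical pixel pitch attached.
#'
#' @param frames `H x W x T` numeric array, or a list of equally sized
#'   matrices.
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param pixel_pitch physical pixel size in mm/px, or `NA` if unknown.
#' @param timestamps optional per-frame acquisition times in seconds
#'   (defaults to `(0:(T-1)) / frame_rate`).
#' @return an object of class `video_stack`.
#' @export
video_stack <- function(frames, frame_rate, pixel_pitch = NA_real_,
                        timestamps = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) {
      stop("all frames must have identical dimensions")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    stop("frame_rate must be a single positive number (Hz)")
  }
  nt <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- (seq_len(nt) - 1) / frame_rate
  stopifnot(length(timestamps) == nt)
  structure(frames,
            frame_rate = frame_rate,
            pixel_pitch = pixel_pitch,
            timestamps = timestamps,
            class = c("video_stack", "array"))
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<video_stack> %d x %d px, %d frames @ %.3g Hz (%.3g s), pitch %s mm/px\n",
    d[1], d[2], d[3], attr(x, "frame_rate"), d[3] / attr(x, "frame_rate"),
    format(attr(x, "pixel_pitch"))))
  invisible(x)
}

#' Number of frames in a video stack
#' @param video a `video_stack` or 3D array.
#' @return integer frame count.
#' @export
n_frames <- function(video) dim(video)[3]

#' Extract a single frame as a plain matrix
#' @param video a `video_stack` or 3D array.
#' @param i frame index.
#' @return numeric matrix.
#' @export
get_frame <- function(video, i) {
  f <- video[, , i]
  dim(f) <- dim(video)[1:2]
  f
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a grayscale video from a multi-page TIFF
#'
#' Pixel data are normalized to [0, 1] by the file's bit depth (so 8-bit and
#' 16-bit encodings of proportional data read back identically). The frame
#' rate is taken from a JSON sidecar (`<path>.json`, written by
#' [write_video()]) or from the `frame_rate` argument; it is an error to
#' provide neither.
#'
#' @param path multi-page TIFF file.
#' @param frame_rate acquisition rate in Hz; overrides the sidecar if given.
#' @param pixel_pitch mm/px; overrides the sidecar if given.
#' @return a [video_stack()].
#' @export
read_video <- function(path, frame_rate = NULL, pixel_pitch = NULL) {
  if (!file.exists(path)) stop("video file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  ref <- dims[[1]]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], ref)) {
      stop(sprintf("page %d has dimensions %s; expected %s", i,
                   paste(dims[[i]], collapse = "x"),
                   paste(ref, collapse = "x")))
    }
  }
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  fr <- frame_rate %||% meta$frame_rate
  if (is.null(fr)) {
    stop("frame rate unknown: no sidecar metadata found and no ",
         "`frame_rate` given for ", path)
  }
  pp <- pixel_pitch %||% meta$pixel_pitch %||% NA_real_
  video_stack(pages, frame_rate = fr, pixel_pitch = pp)
}

#' Write a video stack as a multi-page TIFF plus JSON sidecar
#'
#' @param video a [video_stack()] (values in [0, 1]).
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, bits_per_sample = 16) {
  frames <- lapply(seq_len(n_frames(video)), function(i) {
    f <- get_frame(video, i)
    pmin(pmax(f, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  meta <- list(frame_rate = attr(video, "frame_rate"),
               pixel_pitch = attr(video, "pixel_pitch"),
               n_frames = n_frames(video))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an intestine centerline from CSV
#'
#' @param path CSV with columns `x_px`, `y_px` (ordered along the intestine).
#' @return two-column numeric matrix `(x, y)` in pixels.
#' @export
read_centerline <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(df))) {
    stop("centerline CSV must have columns x_px and y_px")
  }
  cbind(x = df$x_px, y = df$y_px)
}

#' Write an intestine centerline to CSV
#' @param points two-column matrix `(x, y)` in pixels.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(points, path) {
  utils::write.csv(data.frame(x_px = points[, 1], y_px = points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
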