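# Behavior-aware analysis of long recordings: frame similarity, epoch
# segmentation, and ST-map stitching.

#' Frame-similarity trace against running epoch references
#'
#' Each frame's Pearson correlation with the current epoch's reference
#' frame (the first frame of the epoch), computed on block-downsampled
#' frames. When the similarity drops below `drop_threshold` the reference
#' resets to the current frame (a new behavior epoch begins).
#'
#' @param video a [video_stack()] (registered) with >= 2 frames.
#' @param downsample block size for mean-downsampling before correlation.
#' @param drop_threshold similarity below which the reference resets.
#' @param roi optional `c(x, y, w, h)` crop to the region of interest
#'   before comparison; restricting to the animal region keeps static
#'   background (the illumination field) from diluting the correlation.
#' @return object of class `similarity_trace`: list with `values` (length
#'   `n_frames`, in [-1, 1]), `resets` (frame indices where the reference
#'   changed), `drop_threshold`, `zero_variance` (flagged frames).
#' @export
frame_similarity <- function(video, downsample = 4, drop_threshold = 0.8,
                             roi = NULL) {
  nt <- n_frames(video)
  if (nt < 2) stop("similarity needs at least 2 frames")
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4)
    video <- video_stack(video[roi[2]:(roi[2] + roi[4] - 1),
                               roi[1]:(roi[1] + roi[3] - 1), ,
                               drop = FALSE],
                         frame_rate = attr(video, "frame_rate"))
  }
  down <- function(f) {
    h <- nrow(f) %/% downsample * downsample
    w <- ncol(f) %/% downsample * downsample
    f <- f[seq_len(h), seq_len(w), drop = FALSE]
    blk <- array(f, dim = c(downsample, h %/% downsample,
                            downsample, w %/% downsample))
    apply(blk, c(2, 4), mean)
  }
  vals <- numeric(nt)
  zerovar <- logical(nt)
  resets <- integer(0)
  ref <- down(get_frame(video, 1))
  vals[1] <- 1
  for (i in 2:nt) {
    f <- down(get_frame(video, i))
    if (stats::sd(f) < 1e-12 || stats::sd(ref) < 1e-12) {
      vals[i] <- 0
      zerovar[i] <- TRUE
    } else {
      vals[i] <- stats::cor(as.vector(ref), as.vector(f))
    }
    if (vals[i] < drop_threshold) {
      ref <- f
      resets <- c(resets, i)
    }
  }
  structure(list(values = vals, resets = resets,
                 drop_threshold = drop_threshold,
                 zero_variance = zerovar),
            class = "similarity_trace")
}

#' Segment a similarity trace into behavior epochs
#'
#' A new epoch starts wherever the similarity falls below `drop_threshold`;
#' epochs shorter than `min_epoch_frames` are merged forward into the next
#' epoch (the final epoch merges backward if short).
#'
#' @param trace a [frame_similarity()] result.
#' @param drop_threshold override of the trace's threshold.
#' @param min_epoch_frames minimum epoch length in frames.
#' @return data frame with columns `start`, `end` (inclusive frame indices).
#' @export
segment_behaviors <- function(trace, drop_threshold = NULL,
                              min_epoch_frames = 1) {
  stopifnot(inherits(trace, "similarity_trace"))
  thr <- drop_threshold %||% trace$drop_threshold
  n <- length(trace$values)
  starts <- c(1L, which(trace$values < thr))
  starts <- sort(unique(starts))
  ends <- c(starts[-1] - 1L, n)
  keep_start <- starts
  keep_end <- ends
  # merge short epochs forward
  i <- 1
  while (i <= length(keep_start)) {
    len <- keep_end[i] - keep_start[i] + 1
    if (len < min_epoch_frames && length(keep_start) > 1) {
      if (i < length(keep_start)) {
        keep_start <- keep_start[-(i + 1)]
        keep_end <- keep_end[-i]
      } else {
        keep_end <- keep_end[-(i - 1)]
        keep_start <- keep_start[-i]
        i <- i - 1
      }
    } else {
      i <- i + 1
    }
  }
  data.frame(start = keep_start, end = keep_end)
}

#' Stitch per-epoch ST maps into one long-duration map
#'
#' Column-wise concatenation in epoch order. Epochs must share the intestine
#' length (row count); alternatively rows are linearly resampled to the
#' first map's count.
#'
#' @param per_epoch_maps list of `st_map` objects.
#' @param resample_rows allow row-count mismatch via linear resampling.
#' @return an `st_map` with attribute `epoch_boundaries` (last column index
#'   of each epoch).
#' @export
stitch_st_maps <- function(per_epoch_maps, resample_rows = FALSE) {
  stopifnot(length(per_epoch_maps) >= 1)
  if (length(per_epoch_maps) == 1) {
    out <- per_epoch_maps[[1]]
    attr(out, "epoch_boundaries") <- ncol(out)
    return(out)
  }
  m0 <- nrow(per_epoch_maps[[1]])
  mats <- lapply(per_epoch_maps, function(S) {
    if (nrow(S) == m0) return(unclass(S))
    if (!resample_rows) {
      stop(sprintf("row mismatch (%d vs %d) with resampling disabled",
                   nrow(S), m0))
    }
    apply(unclass(S), 2, function(col) {
      stats::approx(seq_along(col), col, n = m0)$y
    })
  })
  out <- do.call(cbind, mats)
  a1 <- per_epoch_maps[[1]]
  structure(out,
            frame_rate = attr(a1, "frame_rate"),
            pixel_pitch = attr(a1, "pixel_pitch"),
            position_spacing_px = attr(a1, "position_spacing_px"),
            inverted = attr(a1, "inverted"),
            epoch_boundaries = cumsum(vapply(mats, ncol, integer(1))),
            class = c("st_map", "matrix", "array"))
}
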