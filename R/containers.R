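#' Image time series
#'
#' A grayscale 2D+time stack stored as an `H x W x T` array (row = y,
#' column = x) together with its acquisition metadata.
#'
#' @param frames Numeric `H x W x T` array of finite, non-negative
#'   intensities with `T >= 2`.
#' @param frame_period Frame period, seconds.
#' @param pixel_size Pixel size, um/pixel.
#'
#' @return An object of class `image_time_series`.
#' @export
image_time_series <- function(frames, frame_period, pixel_size) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be an H x W x T array", call. = FALSE)
  }
  if (dim(frames)[3] < 2L) {
    stop("an image time series needs at least 2 frames", call. = FALSE)
  }
  if (!all(is.finite(frames))) stop("intensities must be finite", call. = FALSE)
  if (min(frames) < 0) stop("intensities must be non-negative", call. = FALSE)
  stopifnot(frame_period > 0, pixel_size > 0)
  structure(list(frames = frames, frame_period = frame_period,
                 pixel_size = pixel_size),
            class = "image_time_series")
}

#' @export
print.image_time_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_time_series> %d x %d px, %d frames, %.3f s/frame, %.3f um/px\n",
              d[1], d[2], d[3], x$frame_period, x$pixel_size))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An [image_time_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Stallogram: capillaries x frames stall matrix
#'
#' A boolean matrix marking, for each analyzed capillary (row) and each
#' frame (column), whether the capillary was stalled. Every run of `TRUE`
#' must span at least 2 frames: a stall is defined as the same RBC shadows
#' stationary across two or more consecutive frames, so a single-frame
#' "stall" is not observable.
#'
#' @param mat Logical (or 0/1) matrix, capillaries x frames.
#' @param capillary_ids Character or integer vector of row identifiers;
#'   defaults to rownames or `1:nrow`.
#' @param frame_period Frame period, seconds.
#' @param check_runs Validate the minimum-2-frame run invariant
#'   (default `TRUE`).
#'
#' @return An object of class `stallogram` with fields `matrix`,
#'   `capillary_ids`, `frame_period`.
#' @export
stallogram <- function(mat, capillary_ids = NULL, frame_period = 1 / 0.57,
                       check_runs = TRUE) {
  if (!is.matrix(mat)) stop("`mat` must be a matrix", call. = FALSE)
  storage.mode(mat) <- "logical"
  if (anyNA(mat)) stop("stallogram entries must be TRUE/FALSE", call. = FALSE)
  if (is.null(capillary_ids)) {
    capillary_ids <- rownames(mat)
    if (is.null(capillary_ids)) capillary_ids <- as.character(seq_len(nrow(mat)))
  }
  capillary_ids <- as.character(capillary_ids)
  if (length(capillary_ids) != nrow(mat)) {
    stop("`capillary_ids` must match the number of rows", call. = FALSE)
  }
  if (anyDuplicated(capillary_ids)) {
    stop("`capillary_ids` must be unique", call. = FALSE)
  }
  stopifnot(frame_period > 0)
  if (check_runs && nrow(mat) > 0) {
    lens <- unlist(lapply(seq_len(nrow(mat)), function(i) {
      r <- rle(mat[i, ])
      r$lengths[r$values]
    }))
    if (length(lens) && any(lens < 2)) {
      stop("stallogram invariant violated: a stall run of a single frame was found",
           call. = FALSE)
    }
  }
  rownames(mat) <- capillary_ids
  structure(list(matrix = mat, capillary_ids = capillary_ids,
                 frame_period = frame_period),
            class = "stallogram")
}

#' @export
print.stallogram <- function(x, ...) {
  cat(sprintf("<stallogram> %d capillaries x %d frames; %d stalled entries\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Capillary centerline
#'
#' An ordered path of (x, y) pixel coordinates along one capillary.
#' Coordinates are 1-based with x = column and y = row; subpixel values are
#' allowed.
#'
#' @param points Numeric n x 2 matrix with columns x, y.
#' @param capillary_id Identifier.
#' @return An object of class `centerline` with fields `capillary_id`,
#'   `points`, `length_px`.
#' @export
centerline <- function(points, capillary_id = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L || !all(is.finite(points))) {
    stop("`points` must be a finite n x 2 matrix", call. = FALSE)
  }
  colnames(points) <- c("x", "y")
  structure(list(capillary_id = as.character(capillary_id), points = points,
                 length_px = nrow(points)),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> id=%s, %d points\n", x$capillary_id, x$length_px))
  invisible(x)
}

# canonical empty stall-event table (frames 1-based, inclusive)
empty_events <- function() {
  data.frame(capillary_id = character(0), start_frame = integer(0),
             end_frame = integer(0), duration_frames = integer(0),
             duration_s = numeric(0), stringsAsFactors = FALSE)
}

make_events <- function(capillary_id, start_frame, end_frame, frame_period) {
  if (length(start_frame) == 0L) return(empty_events())
  dur <- as.integer(end_frame) - as.integer(start_frame) + 1L
  data.frame(capillary_id = as.character(capillary_id),
             start_frame = as.integer(start_frame),
             end_frame = as.integer(end_frame),
             duration_frames = dur,
             duration_s = dur * frame_period,
             stringsAsFactors = FALSE)
}
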