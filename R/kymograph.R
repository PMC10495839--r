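# Motion stabilization and length-time (kymograph) extraction.

# bilinear sampling of matrix M at arbitrary (x, y); coordinates clamped
# to the image, returning also how many samples were clamped
sample_bilinear <- function(M, x, y) {
  H <- nrow(M); W <- ncol(M)
  xc <- pmin(pmax(x, 1), W); yc <- pmin(pmax(y, 1), H)
  n_clamped <- sum(xc != x | yc != y)
  x0 <- pmin(floor(xc), W - 1L); x1 <- x0 + 1L; fx <- xc - x0
  y0 <- pmin(floor(yc), H - 1L); y1 <- y0 + 1L; fy <- yc - y0
  v <- M[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    M[cbind(y0, x1)] * fx * (1 - fy) +
    M[cbind(y1, x0)] * (1 - fx) * fy +
    M[cbind(y1, x1)] * fx * fy
  attr(v, "n_clamped") <- n_clamped
  v
}

# FFT cross-correlation surface between two equally sized matrices;
# returns the shift (dx, dy) of `img` relative to `ref` (img(x) ~
# ref(x - d)), with quadratic subpixel interpolation around the peak
cc_shift <- function(ref, img, max_shift) {
  n1 <- nrow(ref); n2 <- ncol(ref)
  Fr <- fft(ref); Fi <- fft(img)
  cc <- Re(fft(Fi * Conj(Fr), inverse = TRUE)) / (n1 * n2)
  # cc[1 + dy mod n1, 1 + dx mod n2] = sum_x ref(x) img(x + d)... the
  # peak row/col encode the displacement of img content relative to ref
  sy <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1))
  sx <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1))
  allowed <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift)
  cc_a <- cc
  cc_a[!allowed] <- -Inf
  pk <- arrayInd(which.max(cc_a), dim(cc_a))
  py <- pk[1]; px <- pk[2]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  qfit <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (cm - cp) / den
    max(min(d, 0.5), -0.5)
  }
  dy <- sy[py] + qfit(cc[wrap(py - 1, n1), px], cc[py, px], cc[wrap(py + 1, n1), px])
  dx <- sx[px] + qfit(cc[py, wrap(px - 1, n2)], cc[py, px], cc[py, wrap(px + 1, n2)])
  c(dx, dy)
}

#' Locally register a cropped region around a centerline across time
#'
#' Crops the stack around the centerline's bounding box (plus
#' `margin_px`), and estimates a per-frame rigid translation by maximizing
#' the cross-correlation of each frame's zero-mean crop against a
#' reference crop, with quadratic subpixel peak interpolation.
#' Translation-only: the crops are small, so rotation is negligible.
#'
#' @param stack An [image_time_series()].
#' @param cl A [centerline()].
#' @param margin_px Margin around the centerline bounding box (default 10).
#' @param reference `"mean"` (default) registers against the temporal mean
#'   crop, which is robust to the per-frame shadow pattern; alternatively a
#'   frame index, whose own offset is then exactly `(0, 0)`.
#' @param max_shift Largest search shift in pixels (default `margin_px`).
#' @param smooth_window Odd window (frames) for a running-median smoothing
#'   of the offset trajectory; tissue motion is slow while the moving RBC
#'   shadows add white per-frame localization noise (they drag the
#'   correlation peak along the vessel axis), so smoothing suppresses the
#'   jitter without distorting the drift. Use 1 to disable (e.g. for
#'   stacks with frame-rate jumps).
#' @return `T x 2` matrix of offsets (dx, dy): the vessel at reference
#'   position `p` lies at `p + offset[t, ]` in frame `t`.
#' @export
register_local <- function(stack, cl, margin_px = 10, reference = "mean",
                           max_shift = margin_px, smooth_window = 5) {
  stopifnot(inherits(stack, "image_time_series"), inherits(cl, "centerline"))
  d <- dim(stack$frames); H <- d[1]; W <- d[2]; T <- d[3]
  xs <- max(1L, floor(min(cl$points[, 1])) - margin_px):
    min(W, ceiling(max(cl$points[, 1])) + margin_px)
  ys <- max(1L, floor(min(cl$points[, 2])) - margin_px):
    min(H, ceiling(max(cl$points[, 2])) + margin_px)
  if (length(xs) < 8L || length(ys) < 8L) {
    stop("registration crop is smaller than 8 x 8 px; widen the margin",
         call. = FALSE)
  }
  crops <- stack$frames[ys, xs, , drop = FALSE]
  register_to <- function(ref) {
    ref <- ref - mean(ref)
    offs <- matrix(0, T, 2, dimnames = list(NULL, c("dx", "dy")))
    for (t in seq_len(T)) {
      a <- crops[, , t]
      offs[t, ] <- cc_shift(ref, a - mean(a), max_shift)
    }
    offs
  }
  if (identical(reference, "mean")) {
    # two passes: the raw temporal mean is blurred by the motion itself,
    # so re-average the motion-compensated crops and register again
    offs <- register_to(rowMeans(crops, dims = 2))
    aligned <- 0
    for (t in seq_len(T)) {
      aligned <- aligned + bilinear_shift(crops[, , t], -offs[t, 1],
                                          -offs[t, 2])
    }
    offs <- register_to(aligned / T)
  } else {
    offs <- register_to(crops[, , as.integer(reference)])
    offs <- offs - matrix(offs[as.integer(reference), ], T, 2, byrow = TRUE)
  }
  if (smooth_window > 1 && T >= smooth_window) {
    k <- smooth_window + (smooth_window %% 2 == 0)  # force odd
    offs[, 1] <- runmed(offs[, 1], k, endrule = "median")
    offs[, 2] <- runmed(offs[, 2], k, endrule = "median")
  }
  offs
}

#' Apply per-frame offsets to a centerline
#'
#' @param cl A [centerline()].
#' @param offsets `T x 2` matrix of (dx, dy) offsets.
#' @return List of `T` point matrices: frame `t`'s points are
#'   `cl$points + offsets[t, ]`.
#' @export
apply_offsets <- function(cl, offsets) {
  stopifnot(inherits(cl, "centerline"), is.matrix(offsets), ncol(offsets) == 2L)
  lapply(seq_len(nrow(offsets)), function(t) {
    sweep(cl$points, 2L, offsets[t, ], `+`)
  })
}

#' Extract a length-time (LT) image along a centerline
#'
#' Samples each frame by bilinear interpolation at the (per-frame shifted)
#' centerline points, producing the `T x L` kymograph matrix: row = frame,
#' column = position along the capillary. Sample points falling outside
#' the image take the nearest edge value; their count is recorded in
#' `n_clamped`.
#'
#' @param stack An [image_time_series()].
#' @param cl A [centerline()].
#' @param offsets Optional `T x 2` per-frame offsets (e.g. from
#'   [register_local()]); `NULL` means no motion correction.
#' @return An object of class `lt_image`: list with `capillary_id`,
#'   `values` (`T x L`), `offsets`, `frame_period`, `n_clamped`.
#' @export
extract_lt <- function(stack, cl, offsets = NULL) {
  stopifnot(inherits(stack, "image_time_series"), inherits(cl, "centerline"))
  T <- n_frames(stack)
  if (is.null(offsets)) offsets <- matrix(0, T, 2)
  stopifnot(nrow(offsets) == T)
  L <- cl$length_px
  values <- matrix(NA_real_, T, L)
  n_clamped <- 0L
  for (t in seq_len(T)) {
    v <- sample_bilinear(stack$frames[, , t],
                         cl$points[, 1] + offsets[t, 1],
                         cl$points[, 2] + offsets[t, 2])
    n_clamped <- n_clamped + attr(v, "n_clamped")
    values[t, ] <- v
  }
  structure(list(capillary_id = cl$capillary_id, values = values,
                 offsets = offsets, frame_period = stack$frame_period,
                 n_clamped = n_clamped),
            class = "lt_image")
}

#' @export
print.lt_image <- function(x, ...) {
  cat(sprintf("<lt_image> id=%s, %d frames x %d px\n", x$capillary_id,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
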