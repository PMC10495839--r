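# Arteriole diameter (FWHM), dF/F, isolated dilation events, and
# dilation-triggered averaging of stall point prevalence.

#' Vessel diameter by full width at half maximum
#'
#' Draws `n_lines` intensity profiles perpendicular to the vessel axis,
#' spaced `spacing_um` apart and centered on `axis_point`, averages them,
#' min-max normalizes the averaged profile, and returns the distance
#' between the two half-maximum crossings (linear interpolation between
#' samples).
#'
#' @param frame Numeric matrix (one image frame).
#' @param axis_point `c(x, y)` point on the vessel axis (1-based px).
#' @param axis_direction `c(dx, dy)` direction of the vessel axis (any
#'   nonzero vector).
#' @param pixel_size um/pixel.
#' @param n_lines Number of averaged profiles (default 20).
#' @param spacing_um Spacing between profile lines along the axis, um
#'   (default 2).
#' @param profile_halfwidth_um Half-length of each profile, um; must be
#'   generous (at least ~1.5x the expected diameter).
#' @param sample_step_um Profile sampling step, um (default 0.5).
#' @return Diameter in um.
#' @export
diameter_fwhm <- function(frame, axis_point, axis_direction, pixel_size,
                          n_lines = 20, spacing_um = 2,
                          profile_halfwidth_um = 40, sample_step_um = 0.5) {
  stopifnot(is.matrix(frame), length(axis_point) == 2L,
            length(axis_direction) == 2L, pixel_size > 0, n_lines >= 1)
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm == 0) stop("`axis_direction` must be nonzero", call. = FALSE)
  ax <- axis_direction / nrm
  perp <- c(-ax[2], ax[1])
  sp_px <- spacing_um / pixel_size
  centers_k <- (seq_len(n_lines) - (n_lines + 1) / 2) * sp_px
  u_um <- seq(-profile_halfwidth_um, profile_halfwidth_um, by = sample_step_um)
  u_px <- u_um / pixel_size
  cx <- axis_point[1] + centers_k * ax[1]
  cy <- axis_point[2] + centers_k * ax[2]
  X <- outer(cx, u_px * perp[1], `+`)
  Y <- outer(cy, u_px * perp[2], `+`)
  if (min(X) < 1 || max(X) > ncol(frame) || min(Y) < 1 || max(Y) > nrow(frame)) {
    stop("profile lines extend beyond the image; shorten profile_halfwidth_um",
         call. = FALSE)
  }
  v <- sample_bilinear(frame, as.numeric(X), as.numeric(Y))
  prof <- colMeans(matrix(v, n_lines, length(u_um)))
  rng <- range(prof)
  if (diff(rng) <= 0) stop("flat profile: FWHM undefined", call. = FALSE)
  p <- (prof - rng[1]) / diff(rng)
  ipk <- which.max(p)
  cross <- function(side) {
    idx <- if (side < 0) rev(seq_len(ipk)) else ipk:length(p)
    below <- which(p[idx] < 0.5)
    if (!length(below)) {
      stop("intensity profile never crosses half-maximum on one side (unbracketed FWHM)",
           call. = FALSE)
    }
    j <- below[1]                       # first sample below half-max
    a <- idx[j - 1]; b <- idx[j]        # bracket: p[a] >= 0.5 > p[b]
    u_um[a] + (u_um[b] - u_um[a]) * (0.5 - p[a]) / (p[b] - p[a])
  }
  abs(cross(+1) - cross(-1))
}

#' Per-frame diameter trace of a stack
#'
#' Applies [diameter_fwhm()] to every frame; frames where the FWHM is not
#' bracketed yield `NA` and are counted in the `n_failed` attribute.
#'
#' @inheritParams diameter_fwhm
#' @param stack An [image_time_series()].
#' @param ... Passed to [diameter_fwhm()].
#' @return Numeric length-`T` vector of diameters (um), with attribute
#'   `n_failed`.
#' @export
diameter_trace <- function(stack, axis_point, axis_direction,
                           pixel_size = stack$pixel_size, ...) {
  stopifnot(inherits(stack, "image_time_series"))
  T <- n_frames(stack)
  out <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    out[t] <- tryCatch(diameter_fwhm(stack$frames[, , t], axis_point,
                                     axis_direction, pixel_size, ...),
                       error = function(e) NA_real_)
  }
  attr(out, "n_failed") <- sum(is.na(out))
  out
}

#' Fractional fluorescence change (dF/F) in a rectangular ROI
#'
#' `F_t` is the mean intensity in the ROI; the baseline `F0` is the 10th
#' percentile of the `F_t` trace (robust to dilation transients), and
#' `dF/F_t = (F_t - F0) / F0`.
#'
#' @param stack An [image_time_series()].
#' @param roi Rectangle `c(xmin, xmax, ymin, ymax)`, 1-based inclusive px.
#' @param baseline_quantile Baseline quantile of the ROI-mean trace
#'   (default 0.1).
#' @return Numeric length-`T` dF/F trace with attribute `F0`.
#' @export
dff <- function(stack, roi, baseline_quantile = 0.1) {
  stopifnot(inherits(stack, "image_time_series"), length(roi) == 4L)
  d <- dim(stack$frames)
  if (roi[1] < 1 || roi[2] > d[2] || roi[3] < 1 || roi[4] > d[1] ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("ROI out of image bounds", call. = FALSE)
  }
  f <- apply(stack$frames[roi[3]:roi[4], roi[1]:roi[2], , drop = FALSE],
             3L, mean)
  f0 <- as.numeric(quantile(f, baseline_quantile))
  if (f0 <= 0) stop("degenerate baseline: F0 <= 0", call. = FALSE)
  out <- (f - f0) / f0
  attr(out, "F0") <- f0
  out
}

#' Detect large isolated dilation events
#'
#' A qualifying peak is a strict local maximum of the fractional diameter
#' increase over a rolling-median baseline, reaching at least
#' `amplitude_frac_min`. To avoid confounds from successive dilations,
#' any qualifying peak with another qualifying peak within
#' `isolation_frames` frames is excluded (both drop).
#'
#' @param diameter Numeric diameter trace (um); `NA`s not allowed.
#' @param amplitude_frac_min Minimum fractional increase (default 0.1).
#' @param isolation_frames Isolation window in frames (default 10).
#' @param baseline_window Rolling-median window in frames (odd; default
#'   31), tolerant to slow drift.
#' @return Data frame with `peak_frame` and `amplitude_frac` (possibly
#'   zero rows).
#' @export
detect_dilations <- function(diameter, amplitude_frac_min = 0.1,
                             isolation_frames = 10L, baseline_window = 31L) {
  stopifnot(is.numeric(diameter), !anyNA(diameter),
            amplitude_frac_min > 0, isolation_frames >= 0)
  T <- length(diameter)
  if (T <= 2 * isolation_frames) {
    stop("trace too short for the isolation window", call. = FALSE)
  }
  k <- min(baseline_window, T)
  if (k %% 2 == 0) k <- k - 1L
  base <- if (k >= 3) runmed(diameter, k, endrule = "median") else diameter
  frac <- (diameter - base) / base
  i <- 2:(T - 1)
  peaks <- i[frac[i] > frac[i - 1] & frac[i] > frac[i + 1] &
               frac[i] >= amplitude_frac_min]
  if (length(peaks) > 1L) {
    iso <- vapply(seq_along(peaks), function(j) {
      all(abs(peaks[-j] - peaks[j]) > isolation_frames)
    }, logical(1))
    peaks <- peaks[iso]
  }
  data.frame(peak_frame = as.integer(peaks), amplitude_frac = frac[peaks])
}

#' Dilation-triggered average of stall point prevalence
#'
#' Averages a per-frame point-prevalence trace in windows of
#' `+/- window` frames around each dilation peak (lag 0 = peak diameter).
#' Events whose window does not fit inside the record are dropped and
#' counted.
#'
#' @param prevalence Numeric per-frame point prevalence trace (percent),
#'   e.g. from [point_prevalence_trace()].
#' @param events Dilation events from [detect_dilations()] (or any data
#'   frame with `peak_frame`).
#' @param window Half-width of the lag window, frames (default 10).
#' @return List of class `triggered_average`: `lags` (frames, 0 = peak),
#'   `mean`, `sem` (standard error across events; 0 when `n_events = 1`),
#'   `n_events`, `n_dropped`.
#' @export
triggered_average <- function(prevalence, events, window = 10L) {
  stopifnot(is.numeric(prevalence), window >= 1)
  T <- length(prevalence)
  pk <- events$peak_frame
  usable <- pk - window >= 1 & pk + window <= T
  n_dropped <- sum(!usable)
  pk <- pk[usable]
  if (length(pk) == 0L) {
    stop("no usable dilation events (all windows clipped or none supplied)",
         call. = FALSE)
  }
  lags <- -window:window
  m <- vapply(pk, function(p) prevalence[p + lags], numeric(length(lags)))
  m <- matrix(m, nrow = length(lags))
  mu <- rowMeans(m)
  n <- length(pk)
  sem <- if (n > 1) apply(m, 1L, sd) / sqrt(n) else rep(0, length(lags))
  structure(list(lags = lags, mean = mu, sem = sem, n_events = n,
                 n_dropped = n_dropped),
            class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("<triggered_average> %d events (%d dropped), lags %d..%d\n",
              x$n_events, x$n_dropped, min(x$lags), max(x$lags)))
  invisible(x)
}
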