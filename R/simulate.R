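# Synthetic angiogram generator.
#
# Phenomenology emulated: bright curvilinear capillaries on a dim
# background; dark RBC shadows along each lumen that are redrawn
# independently every frame while flowing (at ~mm/s speeds and ~0.57 Hz
# sampling a shadow traverses many capillary lengths per frame, so
# consecutive flowing frames are uncorrelated) and frozen in place during
# stall intervals; rigid whole-field motion; additive Gaussian noise;
# optionally a penetrating arteriole whose diameter fluctuations modulate
# its fluorescence intensity.

# multiplicative shadow attenuation along arclength (um)
shadow_factor <- function(s_um, positions_um, sigma_um, depth) {
  if (length(positions_um) == 0L) return(rep(1, length(s_um)))
  e <- exp(-outer(s_um, positions_um, "-")^2 / (2 * sigma_um^2))
  f <- exp(rowSums(log(pmax(1 - depth * e, 1e-6))))
  pmax(f, 0)
}

draw_shadow_positions <- function(length_um, density_per_100um) {
  n <- rpois(1L, density_per_100um * length_um / 100)
  if (n == 0L) numeric(0) else runif(n, 0, length_um)
}

# Discrete-frame alternating renewal process for one capillary:
# flow sojourn ~ 1 + Geom(p_onset) frames, stall ~ dur_min + Geom(dur_prob)
# frames. A terminal event truncated below 2 frames is unobservable as a
# stall and is dropped.
sample_stall_row <- function(n_frames, p_onset, dur_prob, dur_min) {
  row <- logical(n_frames)
  starts <- integer(0); ends <- integer(0)
  t <- 1L
  repeat {
    t <- t + 1L + rgeom(1L, p_onset)
    if (t > n_frames) break
    d <- dur_min + rgeom(1L, dur_prob)
    e <- min(t + d - 1L, n_frames)
    if (e - t + 1L >= 2L) {
      row[t:e] <- TRUE
      starts <- c(starts, t); ends <- c(ends, e)
    }
    t <- e + 1L
  }
  list(row = row, starts = starts, ends = ends)
}

cap_ids <- function(n) {
  if (n == 0L) character(0) else paste0("cap", seq_len(n))
}

# stall process for all capillaries; uses the current RNG stream
sample_stall_process <- function(cfg, capillary_ids) {
  n <- length(capillary_ids)
  mat <- matrix(FALSE, n, cfg$n_frames)
  ev <- list()
  if (n > 0 && cfg$stall_onset_rate > 0 && cfg$stalling_fraction > 0) {
    eligible <- runif(n) < cfg$stalling_fraction
    p_onset <- 1 - exp(-cfg$stall_onset_rate * cfg$frame_period / 60)
    dd <- cfg$stall_duration_dist
    for (i in which(eligible)) {
      r <- sample_stall_row(cfg$n_frames, p_onset, dd$prob,
                            as.integer(dd$min_frames))
      mat[i, ] <- r$row
      if (length(r$starts)) {
        ev[[length(ev) + 1L]] <- make_events(capillary_ids[i], r$starts,
                                             r$ends, cfg$frame_period)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  list(stallogram = stallogram(mat, capillary_ids, cfg$frame_period),
       events = events)
}

#' Simulate ground-truth stallograms without rendering images
#'
#' Runs only the two-state (flow/stall) renewal process of the simulator:
#' for each eligible capillary, flowing sojourns last `1 + Geom(p)` frames
#' with per-frame onset probability `p = 1 - exp(-rate * frame_period / 60)`,
#' and stalls last `min_frames + Geom(prob)` frames. Useful for testing
#' stallogram statistics at scale.
#'
#' @param config A [simulation_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with `stallogram` (a [stallogram()]) and `events` (a
#'   stall-event data frame with 1-based inclusive frame indices).
#' @export
simulate_stallogram <- function(config, seed = config$seed) {
  config <- validate_sim_config(config)
  set.seed(seed)
  ids <- cap_ids(config$n_capillaries)
  sample_stall_process(config, ids)
}

# --- capillary geometry ------------------------------------------------

disk_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

stamp_occupancy <- function(occ, path, sep_px) {
  H <- nrow(occ); W <- ncol(occ)
  d <- disk_offsets(ceiling(sep_px))
  ii <- seq(1L, nrow(path), by = 2L)
  px <- rep(round(path[ii, 1]), each = nrow(d)) + d$dx
  py <- rep(round(path[ii, 2]), each = nrow(d)) + d$dy
  keep <- px >= 1 & px <= W & py >= 1 & py <= H
  occ[cbind(py[keep], px[keep])] <- TRUE
  occ
}

# grow one smooth random curve at 1 px steps; stops at field margin,
# occupancy, or self-proximity
grow_path <- function(H, W, occ, sep_px, target_len, margin = 6) {
  x <- runif(1, margin + 1, W - margin)
  y <- runif(1, margin + 1, H - margin)
  theta <- runif(1, 0, 2 * pi)
  kappa <- 0
  pts <- matrix(NA_real_, target_len, 2)
  pts[1, ] <- c(x, y)
  n <- 1L
  while (n < target_len) {
    kappa <- 0.8 * kappa + rnorm(1, 0, 0.025)
    kappa <- max(min(kappa, 0.12), -0.12)
    theta <- theta + kappa
    nx <- x + cos(theta); ny <- y + sin(theta)
    if (nx < margin + 1 || nx > W - margin || ny < margin + 1 || ny > H - margin) break
    if (occ[round(ny), round(nx)]) break
    n_old <- n - ceiling(2 * sep_px)
    if (n_old >= 1) {
      old <- pts[seq_len(n_old), , drop = FALSE]
      if (min((old[, 1] - nx)^2 + (old[, 2] - ny)^2) < sep_px^2) break
    }
    n <- n + 1L
    x <- nx; y <- ny
    pts[n, ] <- c(x, y)
  }
  pts[seq_len(n), , drop = FALSE]
}

# place n non-crossing capillary centerlines with separation >= 3 widths
sim_capillary_paths <- function(cfg, occ_init = NULL) {
  H <- cfg$height_px; W <- cfg$width_px
  sep_px <- 3 * cfg$capillary_width / cfg$pixel_size
  min_len <- max(30, ceiling(40 / cfg$pixel_size))
  occ <- if (is.null(occ_init)) matrix(FALSE, H, W) else occ_init
  paths <- vector("list", cfg$n_capillaries)
  for (i in seq_len(cfg$n_capillaries)) {
    placed <- FALSE
    for (attempt in 1:500) {
      target <- round(runif(1, min_len, max(min_len + 1, 130 / cfg$pixel_size)))
      p <- grow_path(H, W, occ, sep_px, target)
      if (nrow(p) >= min_len) {
        paths[[i]] <- p
        occ <- stamp_occupancy(occ, p, sep_px)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", cfg$n_capillaries, " capillaries with ",
           "separation ", round(sep_px, 1), " px in a ", H, "x", W,
           " field; reduce n_capillaries or capillary_width", call. = FALSE)
    }
  }
  paths
}

# --- rendering ---------------------------------------------------------

# per-capillary static render info: affected pixels, tube weight, nearest
# arclength index
cap_render_info <- function(path, sigma_w_px, H, W) {
  rmax <- ceiling(3 * sigma_w_px)
  off <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  n <- nrow(path)
  npx <- nrow(off)
  px <- rep(round(path[, 1]), each = npx) + off$dx
  py <- rep(round(path[, 2]), each = npx) + off$dy
  sx <- rep(path[, 1], each = npx)
  sy <- rep(path[, 2], each = npx)
  si <- rep(seq_len(n), each = npx)
  keep <- px >= 1 & px <= W & py >= 1 & py <= H
  px <- px[keep]; py <- py[keep]
  d2 <- (px - sx[keep])^2 + (py - sy[keep])^2
  si <- si[keep]
  keep2 <- d2 <= rmax^2
  idx <- (px[keep2] - 1L) * H + py[keep2]
  d2 <- d2[keep2]; si <- si[keep2]
  o <- order(idx, d2)
  idx <- idx[o]; d2 <- d2[o]; si <- si[o]
  first <- !duplicated(idx)
  list(idx = idx[first],
       w = exp(-d2[first] / (2 * sigma_w_px^2)),
       s = si[first])
}

bilinear_shift <- function(M, dx, dy) {
  H <- nrow(M); W <- ncol(M)
  xs <- pmin(pmax(seq_len(W) - dx, 1), W)
  ys <- pmin(pmax(seq_len(H) - dy, 1), H)
  x0 <- floor(xs); x1 <- pmin(x0 + 1L, W); fx <- xs - x0
  y0 <- floor(ys); y1 <- pmin(y0 + 1L, H); fy <- ys - y0
  outer(1 - fy, 1 - fx) * M[y0, x0] + outer(1 - fy, fx) * M[y0, x1] +
    outer(fy, 1 - fx) * M[y1, x0] + outer(fy, fx) * M[y1, x1]
}

# smooth bounded rigid-motion trajectory with peak excursion `amp` px
sim_motion_offsets <- function(n_frames, amp) {
  if (amp <= 0 || n_frames < 2) return(matrix(0, n_frames, 2))
  k <- exp(-((-6:6)^2) / (2 * 2.5^2)); k <- k / sum(k)
  sm <- function() {
    raw <- rnorm(n_frames + 12)
    as.numeric(stats::filter(raw, k, sides = 2))[7:(n_frames + 6)]
  }
  m <- cbind(sm(), sm())
  m <- m - rep(colMeans(m), each = n_frames)
  mx <- max(abs(m))
  if (mx > 0) m <- m * (amp / mx)
  m
}

# arteriole diameter trace: baseline plus isolated smooth dilation bumps
sim_artery_dynamics <- function(cfg) {
  T <- cfg$n_frames
  d0 <- cfg$artery_diameter_baseline
  peaks <- integer(0)
  if (cfg$dilation_amplitude_frac > 0) {
    n_target <- max(3L, round(T / 60))
    min_gap <- 25L
    for (k in seq_len(200L)) {
      cand <- sample(15:(T - 15), 1L)
      if (all(abs(cand - peaks) > min_gap)) peaks <- c(peaks, cand)
      if (length(peaks) >= n_target) break
    }
    peaks <- sort(peaks)
  }
  d <- rep(d0, T)
  tt <- seq_len(T)
  for (p in peaks) {
    a <- cfg$dilation_amplitude_frac * d0 * runif(1, 0.9, 1.2)
    d <- d + a * exp(-(tt - p)^2 / (2 * 1.5^2))
  }
  dff_true <- cfg$coupling_gain * (d - d0) / d0
  list(diameter_um = d, dff_true = dff_true, peak_frames = peaks)
}

# logistic-edged arteriole cross profile: half-max crossings at +/- w/2
artery_profile <- function(x_px, center_px, width_px, edge_px = 0.7) {
  1 / (1 + exp((abs(x_px - center_px) - width_px / 2) / edge_px))
}

#' Simulate a capillary angiogram time series with ground truth
#'
#' Renders `config$n_capillaries` bright capillaries (Gaussian tube cross
#' sections of FWHM `capillary_width`) carrying dark RBC shadows, on a dim
#' background. While a capillary flows, shadow positions are redrawn
#' independently each frame; during each ground-truth stall interval its
#' shadow pattern is frozen, so only noise varies. Smooth rigid whole-field
#' motion with peak excursion `motion_amplitude` is applied, Gaussian noise
#' is added, and frames are clipped to `[0, 1]` and quantized to the 16-bit
#' grid (so TIFF round trips are bit-identical). Deterministic given
#' `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @return A list with:
#'   \describe{
#'     \item{stack}{[image_time_series()] of rendered frames.}
#'     \item{truth}{ground truth: `centerlines` (list of [centerline()],
#'       subpixel), `stallogram` ([stallogram()]), `stall_events` (data
#'       frame, 1-based inclusive frames), `motion_offsets` (`T x 2`
#'       content displacement in px; the vessel at reference position `p`
#'       appears at `p + offset[t, ]` in frame `t`), and if
#'       `config$include_artery`, `artery` with `diameter_um`, `dff_true`,
#'       `peak_frames`, `center_x_px`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_angiogram <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  H <- cfg$height_px; W <- cfg$width_px; T <- cfg$n_frames
  ids <- cap_ids(cfg$n_capillaries)

  occ <- matrix(FALSE, H, W)
  artery <- NULL
  artery_x <- NA_real_
  if (cfg$include_artery) {
    artery <- sim_artery_dynamics(cfg)
    artery_x <- 10 + cfg$artery_diameter_baseline / cfg$pixel_size
    block <- ceiling(artery_x + cfg$artery_diameter_baseline / cfg$pixel_size + 6)
    occ[, seq_len(min(block, W))] <- TRUE
    artery$center_x_px <- artery_x
  }

  paths <- sim_capillary_paths(cfg, occ)
  sp <- sample_stall_process(cfg, ids)
  stall_mat <- sp$stallogram$matrix

  sigma_w_px <- cfg$capillary_width / cfg$pixel_size / (2 * sqrt(2 * log(2)))
  info <- lapply(paths, cap_render_info, sigma_w_px = sigma_w_px, H = H, W = W)
  offs <- sim_motion_offsets(T, cfg$motion_amplitude)

  n_caps <- cfg$n_capillaries
  frozen <- vector("list", n_caps)  # frozen shadow positions during a stall
  frames <- array(0, dim = c(H, W, T))
  base <- matrix(cfg$background_intensity, H, W)
  if (cfg$include_artery) {
    amp_t <- cfg$tube_intensity * (1 + artery$dff_true)
    width_px_t <- artery$diameter_um / cfg$pixel_size
    xg <- seq_len(W)
  }

  for (t in seq_len(T)) {
    fr <- base
    if (cfg$include_artery) {
      prof <- amp_t[t] * artery_profile(xg, artery_x, width_px_t[t])
      fr <- fr + matrix(prof, H, W, byrow = TRUE)
    }
    for (i in seq_len(n_caps)) {
      L_um <- nrow(paths[[i]]) * cfg$pixel_size
      if (stall_mat[i, t]) {
        if (is.null(frozen[[i]])) {
          frozen[[i]] <- draw_shadow_positions(L_um, cfg$shadow_density)
        }
        pos <- frozen[[i]]
      } else {
        frozen[i] <- list(NULL)
        pos <- draw_shadow_positions(L_um, cfg$shadow_density)
      }
      f_arc <- shadow_factor(seq_len(nrow(paths[[i]])) * cfg$pixel_size,
                             pos, cfg$shadow_sigma, cfg$shadow_depth)
      ri <- info[[i]]
      fr[ri$idx] <- fr[ri$idx] + cfg$tube_intensity * ri$w * f_arc[ri$s]
    }
    if (cfg$motion_amplitude > 0) {
      fr <- bilinear_shift(fr, offs[t, 1], offs[t, 2])
    }
    if (cfg$noise_sd > 0) {
      fr <- fr + rnorm(H * W, 0, cfg$noise_sd)
    }
    frames[, , t] <- floor(pmin(pmax(fr, 0), 1) * 65535) / 65535
  }

  truth <- list(centerlines = lapply(seq_len(n_caps), function(i) {
                  centerline(paths[[i]], ids[i])
                }),
                stallogram = sp$stallogram,
                stall_events = sp$events,
                motion_offsets = offs,
                artery = artery)
  list(stack = image_time_series(frames, cfg$frame_period, cfg$pixel_size),
       truth = truth, config = cfg)
}

#' Simulate a length-time (kymograph) image directly
#'
#' Generates the 1D shadow-attenuation profile along a capillary of
#' `length_px` pixels for each of `n_frames` frames, without rendering any
#' 2D images. Rows inside a stall interval repeat the shadow profile frozen
#' at the interval's first frame (plus noise); rows outside are freshly
#' sampled, mutually independent profiles.
#'
#' @param length_px Centerline length in pixels.
#' @param n_frames Number of frames (rows).
#' @param stall_intervals List of inclusive 1-based frame ranges
#'   `c(start, end)`, each spanning at least 2 frames, non-overlapping.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @param pixel_size um/pixel.
#' @param shadow_density Shadows per 100 um.
#' @param shadow_sigma,shadow_depth Shadow shape parameters (um, fraction).
#' @param baseline Lumen intensity before attenuation.
#' @return A list with `values` (`n_frames x length_px` matrix) and
#'   `stall` (logical length-`n_frames` trace, `TRUE` inside intervals).
#' @export
simulate_kymograph <- function(length_px, n_frames, stall_intervals = list(),
                               noise_sd = 0.02, seed = 1L,
                               pixel_size = 713 / 512, shadow_density = 8,
                               shadow_sigma = 3, shadow_depth = 0.55,
                               baseline = 0.75) {
  stopifnot(length_px >= 2, n_frames >= 2)
  for (iv in stall_intervals) {
    if (length(iv) != 2L || iv[1] < 1 || iv[2] > n_frames || iv[2] < iv[1]) {
      stop("stall interval out of range [1, n_frames]", call. = FALSE)
    }
    if (iv[2] - iv[1] + 1 < 2) {
      stop("a stall interval must span at least 2 frames", call. = FALSE)
    }
  }
  set.seed(seed)
  s_um <- seq_len(length_px) * pixel_size
  L_um <- length_px * pixel_size
  stall <- logical(n_frames)
  for (iv in stall_intervals) stall[iv[1]:iv[2]] <- TRUE
  values <- matrix(0, n_frames, length_px)
  frozen <- NULL
  for (t in seq_len(n_frames)) {
    if (stall[t]) {
      if (is.null(frozen)) {
        frozen <- baseline *
          shadow_factor(s_um, draw_shadow_positions(L_um, shadow_density),
                        shadow_sigma, shadow_depth)
      }
      prof <- frozen
    } else {
      frozen <- NULL
      prof <- baseline *
        shadow_factor(s_um, draw_shadow_positions(L_um, shadow_density),
                      shadow_sigma, shadow_depth)
    }
    values[t, ] <- prof
  }
  if (noise_sd > 0) {
    values <- values + matrix(rnorm(n_frames * length_px, 0, noise_sd),
                              n_frames, length_px)
  }
  list(values = values, stall = stall)
}

#' Simulate an arteriole with coupled diameter and fluorescence dynamics
#'
#' Renders a straight vertical arteriole whose width follows a diameter
#' trace containing isolated dilation events, and whose fluorescence
#' amplitude is linearly coupled to fractional diameter change
#' (`dF/F = coupling_gain * (d - d0) / d0`). The cross profile has logistic
#' edges whose half-maximum crossings sit exactly at the nominal diameter,
#' so FWHM estimation recovers the trace.
#'
#' @param config A [simulation_config()] with `include_artery = TRUE`.
#' @param dff_noise_sd Gaussian noise sd added to the returned dF/F trace.
#' @param height_px Canvas height (vessel axis length), pixels.
#' @return A list with `diameter_um`, `dff` (noisy), `dff_true`,
#'   `peak_frames`, `frames` (canvas `H x W x T` [image_time_series()]),
#'   `center_x_px`.
#' @export
simulate_artery <- function(config, dff_noise_sd = 0) {
  cfg <- validate_sim_config(config)
  if (!cfg$include_artery) {
    stop("simulate_artery requires include_artery = TRUE", call. = FALSE)
  }
  set.seed(cfg$seed)
  dyn <- sim_artery_dynamics(cfg)
  T <- cfg$n_frames
  W <- ceiling(4 * cfg$artery_diameter_baseline / cfg$pixel_size)
  H <- max(64L, min(128L, cfg$height_px))
  cx <- (W + 1) / 2
  xg <- seq_len(W)
  frames <- array(0, dim = c(H, W, T))
  amp_t <- cfg$tube_intensity * (1 + dyn$dff_true)
  for (t in seq_len(T)) {
    prof <- cfg$background_intensity +
      amp_t[t] * artery_profile(xg, cx, dyn$diameter_um[t] / cfg$pixel_size)
    fr <- matrix(prof, H, W, byrow = TRUE)
    if (cfg$noise_sd > 0) fr <- fr + rnorm(H * W, 0, cfg$noise_sd)
    frames[, , t] <- pmin(pmax(fr, 0), 1)
  }
  dff <- dyn$dff_true
  if (dff_noise_sd > 0) dff <- dff + rnorm(T, 0, dff_noise_sd)
  list(diameter_um = dyn$diameter_um, dff = dff, dff_true = dyn$dff_true,
       peak_frames = dyn$peak_frames,
       frames = image_time_series(frames, cfg$frame_period, cfg$pixel_size),
       center_x_px = cx)
}
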