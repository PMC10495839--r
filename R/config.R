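#' Simulation configuration
#'
#' Parameters for the synthetic angiogram generator. Defaults mirror a
#' Bessel-beam two-photon acquisition: 512x512 pixels spanning 713x713 um
#' (1.393 um/px), 350 frames at 0.57 Hz (frame period 1.754 s). Rate-type
#' defaults (shadow density, stall onset rate, stall durations, stalling
#' fraction) are chosen to produce stall statistics of the same order as
#' in-vivo cortical measurements; see the package vignette.
#'
#' @param height_px,width_px Field size in pixels.
#' @param pixel_size Pixel size, um/pixel.
#' @param n_frames Number of frames.
#' @param frame_period Frame period, seconds.
#' @param n_capillaries Number of capillaries to place.
#' @param capillary_width Capillary tube FWHM, um.
#' @param shadow_density Expected RBC shadows per 100 um of capillary.
#' @param shadow_sigma Gaussian half-width (sd) of one RBC shadow, um.
#' @param shadow_depth Fractional intensity dip at a shadow center (0-1).
#' @param shadow_speed Flowing shadow speed, um/s. At the default frame
#'   period shadows traverse many capillary lengths per frame, so flowing
#'   frames are rendered as independent redraws of shadow positions; the
#'   speed is retained for documentation and future advection models.
#' @param stall_onset_rate Stall events per capillary per minute (hazard
#'   while flowing), for eligible capillaries.
#' @param stall_duration_dist Stall duration distribution: a list with
#'   `family` (currently `"geometric"`), `prob`, and `min_frames` (>= 2).
#'   Durations are `min_frames + rgeom(prob)` frames.
#' @param stalling_fraction Fraction of capillaries eligible to stall.
#' @param noise_sd Additive Gaussian noise sd, intensity units (frames are
#'   on a 0-1 scale).
#' @param motion_amplitude Peak rigid-motion excursion, pixels.
#' @param background_intensity,tube_intensity Background level and tube
#'   amplitude above background, 0-1 intensity units.
#' @param include_artery Render a penetrating arteriole along the left edge
#'   and return its ground-truth dynamics.
#' @param artery_diameter_baseline Arteriole baseline diameter, um.
#' @param dilation_amplitude_frac Peak fractional diameter increase of a
#'   dilation event.
#' @param coupling_gain dF/F per unit fractional diameter change.
#' @param seed Integer seed; all simulator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_angiogram()], [simulate_kymograph()],
#'   [simulate_artery()]
#' @export
simulation_config <- function(height_px = 512L,
                              width_px = 512L,
                              pixel_size = 713 / 512,
                              n_frames = 350L,
                              frame_period = 1 / 0.57,
                              n_capillaries = 50L,
                              capillary_width = 6,
                              shadow_density = 8,
                              shadow_sigma = 3,
                              shadow_depth = 0.55,
                              shadow_speed = 1000,
                              stall_onset_rate = 0.8,
                              stall_duration_dist = list(family = "geometric",
                                                         prob = 0.25,
                                                         min_frames = 2L),
                              stalling_fraction = 0.3,
                              noise_sd = 0.05,
                              motion_amplitude = 2,
                              background_intensity = 0.15,
                              tube_intensity = 0.6,
                              include_artery = FALSE,
                              artery_diameter_baseline = 25,
                              dilation_amplitude_frac = 0.15,
                              coupling_gain = 1,
                              seed = 1L) {
  cfg <- list(height_px = as.integer(height_px),
              width_px = as.integer(width_px),
              pixel_size = pixel_size,
              n_frames = as.integer(n_frames),
              frame_period = frame_period,
              n_capillaries = as.integer(n_capillaries),
              capillary_width = capillary_width,
              shadow_density = shadow_density,
              shadow_sigma = shadow_sigma,
              shadow_depth = shadow_depth,
              shadow_speed = shadow_speed,
              stall_onset_rate = stall_onset_rate,
              stall_duration_dist = stall_duration_dist,
              stalling_fraction = stalling_fraction,
              noise_sd = noise_sd,
              motion_amplitude = motion_amplitude,
              background_intensity = background_intensity,
              tube_intensity = tube_intensity,
              include_artery = isTRUE(include_artery),
              artery_diameter_baseline = artery_diameter_baseline,
              dilation_amplitude_frac = dilation_amplitude_frac,
              coupling_gain = coupling_gain,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos <- c("height_px", "width_px", "pixel_size", "n_frames", "frame_period",
           "capillary_width", "shadow_sigma", "frame_period")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("sim_config: `", f, "` must be a positive finite scalar",
           call. = FALSE)
    }
  }
  nonneg <- c("n_capillaries", "shadow_density", "shadow_depth",
              "stall_onset_rate", "noise_sd", "motion_amplitude",
              "coupling_gain", "dilation_amplitude_frac")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] < 0) {
      stop("sim_config: `", f, "` must be a non-negative finite scalar",
           call. = FALSE)
    }
  }
  if (cfg$stalling_fraction < 0 || cfg$stalling_fraction > 1) {
    stop("sim_config: `stalling_fraction` must lie in [0, 1]", call. = FALSE)
  }
  dd <- cfg$stall_duration_dist
  if (!is.list(dd) || !identical(dd$family, "geometric") ||
      !is.numeric(dd$prob) || dd$prob <= 0 || dd$prob > 1) {
    stop("sim_config: `stall_duration_dist` must be list(family = \"geometric\", prob in (0,1], min_frames >= 2)",
         call. = FALSE)
  }
  if (is.null(dd$min_frames) || dd$min_frames < 2) {
    stop("sim_config: stall durations must span at least 2 frames",
         call. = FALSE)
  }
  if (cfg$n_frames < 2) stop("sim_config: need at least 2 frames", call. = FALSE)
  cfg
}

#' Analysis configuration
#'
#' Tunable parameters for the detection pipeline. Defaults reproduce the
#' reference acquisition (frame period 1/0.57 = 1.754 s, pixel size
#' 713/512 = 1.393 um) and the deliberately low correlation threshold of
#' 0.4 that trades specificity for sensitivity.
#'
#' @param frame_period_s Frame period, seconds.
#' @param pixel_size_um Pixel size, um/pixel.
#' @param correlation_threshold Frame-pair Pearson correlation at or above
#'   which the pair is flagged as stalled.
#' @param min_stall_frames Minimum event duration (frames) retained by
#'   duration filtering in downstream statistics; 2 keeps all stalls.
#' @param review_min_frames Minimum event duration (frames) required by the
#'   automated review step that stands in for human confirmation of flagged
#'   events in the fully automatic pipeline (see [review_events()]).
#' @param review_pair_threshold Minimum pairwise row correlation within a
#'   `review_min_frames` window for an event to be confirmed by the
#'   automated review.
#' @param vesselness_scales Gaussian scales (pixels) for vessel enhancement.
#' @param segmentation_threshold Fraction of the vesselness range used to
#'   segment vessels, or `NULL` for automatic (Otsu) selection.
#' @param max_click_distance_px Maximum distance from a click to the nearest
#'   centerline before the click is rejected.
#' @param registration_margin_px Margin added around a centerline bounding
#'   box when cropping for local registration.
#' @param dilation_amplitude_min Minimum fractional diameter increase for a
#'   "large" dilation event.
#' @param dilation_isolation_frames Isolation window: qualifying peaks with
#'   another qualifying peak within this many frames are excluded.
#' @param seed Integer seed for any stochastic steps.
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(frame_period_s = 1 / 0.57,
                            pixel_size_um = 713 / 512,
                            correlation_threshold = 0.4,
                            min_stall_frames = 2L,
                            review_min_frames = 4L,
                            review_pair_threshold = 0.5,
                            vesselness_scales = c(1, 2, 3, 4),
                            segmentation_threshold = NULL,
                            max_click_distance_px = 20,
                            registration_margin_px = 10,
                            dilation_amplitude_min = 0.1,
                            dilation_isolation_frames = 10L,
                            seed = 1L) {
  stopifnot(frame_period_s > 0, pixel_size_um > 0,
            correlation_threshold > -1, correlation_threshold < 1,
            min_stall_frames >= 2, review_min_frames >= 2,
            review_pair_threshold > -1, review_pair_threshold < 1,
            length(vesselness_scales) >= 1, all(vesselness_scales > 0),
            max_click_distance_px > 0, registration_margin_px >= 0,
            dilation_amplitude_min > 0, dilation_isolation_frames >= 0)
  if (!is.null(segmentation_threshold)) {
    stopifnot(segmentation_threshold > 0, segmentation_threshold < 1)
  }
  structure(list(frame_period_s = frame_period_s,
                 pixel_size_um = pixel_size_um,
                 correlation_threshold = correlation_threshold,
                 min_stall_frames = as.integer(min_stall_frames),
                 review_min_frames = as.integer(review_min_frames),
                 review_pair_threshold = review_pair_threshold,
                 vesselness_scales = vesselness_scales,
                 segmentation_threshold = segmentation_threshold,
                 max_click_distance_px = max_click_distance_px,
                 registration_margin_px = registration_margin_px,
                 dilation_amplitude_min = dilation_amplitude_min,
                 dilation_isolation_frames = as.integer(dilation_isolation_frames),
                 seed = as.integer(seed)),
            class = "analysis_config")
}
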