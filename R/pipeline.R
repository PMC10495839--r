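# End-to-end driver: centerlines -> kymographs -> correlation detection ->
# stallogram -> statistics.

#' Extract click-selected centerlines from a stack
#'
#' Runs the centerline chain on the temporal-mean image (which maximizes
#' lumen SNR and washes out the moving RBC shadows): vessel enhancement at
#' `config$vesselness_scales`, segmentation (Otsu by default),
#' skeletonization, graph conversion, then nearest-edge selection for each
#' click. Clicks farther than `config$max_click_distance_px` from any
#' vessel are dropped and counted.
#'
#' @param stack An [image_time_series()].
#' @param clicks Data frame with `capillary_label` and 1-based `x`, `y`
#'   (see [read_clicks()]).
#' @param config An [analysis_config()].
#' @return List with `centerlines` (short ones already excluded), `graph`,
#'   `vesselness`, `mask`, `skeleton`, `n_failed_clicks`,
#'   `n_short_excluded`.
#' @export
extract_centerlines <- function(stack, clicks, config = analysis_config()) {
  stopifnot(inherits(stack, "image_time_series"))
  mean_img <- rowMeans(stack$frames, dims = 2)
  v <- enhance_vessels(mean_img, config$vesselness_scales, "bright")
  mask <- segment_vessels(v, config$segmentation_threshold)
  skel <- skeletonize_mask(mask)
  graph <- skeleton_to_graph(skel)
  cls <- list()
  n_failed <- 0L
  for (k in seq_len(nrow(clicks))) {
    cl <- tryCatch(
      select_centerline(graph, c(clicks$x[k], clicks$y[k]),
                        config$max_click_distance_px,
                        capillary_id = as.character(clicks$capillary_label[k])),
      error = function(e) NULL)
    if (is.null(cl)) n_failed <- n_failed + 1L else cls[[length(cls) + 1L]] <- cl
  }
  kept <- filter_short_centerlines(cls)
  list(centerlines = kept, graph = graph, vesselness = v, mask = mask,
       skeleton = skel, n_failed_clicks = n_failed,
       n_short_excluded = length(cls) - length(kept))
}

#' Run the full stall-detection pipeline
#'
#' For each centerline: local registration, LT extraction, frame-to-frame
#' correlation, and threshold flagging at
#' `config$correlation_threshold`. The threshold is deliberately low
#' (sensitivity over specificity), so in fully automatic operation an
#' automated review stands in for human confirmation of flagged events:
#' only events of at least `config$review_min_frames` frames (i.e. at
#' least `review_min_frames - 1` consecutive suprathreshold frame pairs)
#' are confirmed. Set `review_min_frames = 2` to keep every flagged event.
#'
#' @param stack An [image_time_series()].
#' @param centerlines List of [centerline()] objects (e.g. from
#'   [extract_centerlines()] or simulator ground truth).
#' @param config An [analysis_config()].
#' @param n_capillaries_total Denominator for statistics (default: number
#'   of centerlines).
#' @param detrend Remove each LT image's static along-length profile
#'   (see [detrend_lt()]) before correlating (default `TRUE`).
#' @return List of class `stall_pipeline`: `lt_images`, `traces`,
#'   `flagged_events` (all suprathreshold events), `events` (after
#'   review), `stallogram`, `statistics`, `config`.
#' @export
run_stall_pipeline <- function(stack, centerlines,
                               config = analysis_config(),
                               n_capillaries_total = length(centerlines),
                               detrend = TRUE) {
  stopifnot(inherits(stack, "image_time_series"), length(centerlines) > 0)
  ids <- vapply(centerlines, function(cl) cl$capillary_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate capillary ids", call. = FALSE)
  lts <- vector("list", length(centerlines))
  traces <- vector("list", length(centerlines))
  flagged <- list()
  confirmed <- list()
  for (i in seq_along(centerlines)) {
    offs <- register_local(stack, centerlines[[i]],
                           margin_px = config$registration_margin_px)
    lts[[i]] <- extract_lt(stack, centerlines[[i]], offs)
    lt_c <- if (detrend) detrend_lt(lts[[i]]) else lts[[i]]
    traces[[i]] <- frame_correlation(lt_c)
    ev <- threshold_correlation(traces[[i]], config$correlation_threshold,
                                stack$frame_period)
    if (nrow(ev)) {
      flagged[[length(flagged) + 1L]] <- ev
      cf <- review_events(lt_c, ev, config$review_min_frames,
                          config$review_pair_threshold)
      if (nrow(cf)) confirmed[[length(confirmed) + 1L]] <- cf
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else empty_events()
  events <- if (length(confirmed)) do.call(rbind, confirmed) else empty_events()
  sg <- events_to_stallogram(events, ids, n_frames(stack),
                             stack$frame_period)
  stats <- compute_statistics(sg, n_capillaries_total)
  structure(list(lt_images = lts, traces = traces, flagged_events = flagged,
                 events = events, stallogram = sg, statistics = stats,
                 config = config),
            class = "stall_pipeline")
}

#' @export
print.stall_pipeline <- function(x, ...) {
  cat(sprintf("<stall_pipeline> %d capillaries, %d confirmed events (%d flagged)\n",
              nrow(x$stallogram$matrix), nrow(x$events),
              nrow(x$flagged_events)))
  print(x$statistics)
  invisible(x)
}
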