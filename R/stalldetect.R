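# Frame-to-frame correlation stall detector.
#
# During flow, new RBC shadows appear at new positions every frame, so
# consecutive kymograph rows are decorrelated; during a stall the same
# shadow pattern repeats and consecutive rows correlate strongly. The
# correlation trace is thresholded (deliberately low, trading specificity
# for sensitivity) and suprathreshold frame pairs become stall events.

#' Remove the static along-length profile from an LT image
#'
#' Subtracts each column's temporal mean from the LT matrix. The static
#' intensity structure along a capillary (end tapers, brightness
#' variation along the lumen) correlates consecutive rows even during
#' flow and carries no evidence about stalling; detrending leaves only
#' the per-frame shadow fluctuation, so flowing rows decorrelate toward 0
#' while frozen (stalled) rows still match. A capillary stalled for most
#' of the record loses contrast against its own mean — see the vignette.
#'
#' @param lt An [extract_lt()] result.
#' @return The LT image with `values` detrended.
#' @export
detrend_lt <- function(lt) {
  lt$values <- sweep(lt$values, 2L, colMeans(lt$values))
  lt
}

#' Frame-to-frame intensity correlation of an LT image
#'
#' `r[t]` is the Pearson correlation between LT rows `t` and `t + 1`
#' (frames `t` and `t + 1`). If either row has zero variance the pair
#' carries no evidence of a frozen shadow pattern: `r[t]` is set to 0 and
#' flagged degenerate.
#'
#' @param lt An [extract_lt()] result (or any list with a `T x L` numeric
#'   `values` matrix, `T >= 2`, `L >= 6`).
#' @return An object of class `correlation_trace`: list with
#'   `capillary_id`, `r` (length `T - 1`), `degenerate` (logical), and
#'   `frame_period`.
#' @export
frame_correlation <- function(lt) {
  v <- lt$values
  if (!is.matrix(v) || nrow(v) < 2L) {
    stop("LT image needs at least 2 rows (frames)", call. = FALSE)
  }
  if (ncol(v) < 6L) {
    stop("LT image has fewer than 6 columns; centerlines of 5 px or less are excluded",
         call. = FALSE)
  }
  T <- nrow(v)
  ctr <- v - rowMeans(v)
  ss <- sqrt(rowSums(ctr^2))
  a <- ctr[-T, , drop = FALSE]; b <- ctr[-1, , drop = FALSE]
  num <- rowSums(a * b)
  den <- ss[-T] * ss[-1]
  degenerate <- den <= .Machine$double.eps * ncol(v)
  r <- ifelse(degenerate, 0, num / ifelse(degenerate, 1, den))
  r <- pmin(pmax(r, -1), 1)
  structure(list(capillary_id = lt$capillary_id, r = as.numeric(r),
                 degenerate = degenerate,
                 frame_period = if (!is.null(lt$frame_period)) lt$frame_period else NA_real_),
            class = "correlation_trace")
}

#' Threshold a correlation trace into stall events
#'
#' A correlation is a property of a frame pair: a suprathreshold `r[t]`
#' marks both frames `t` and `t + 1` as stalled. Maximal runs of stalled
#' frames become events, so a single suprathreshold value yields a 2-frame
#' event — the minimum detectable stall, spanning one frame interval.
#'
#' @param trace A [frame_correlation()] result.
#' @param threshold Correlation threshold in (-1, 1); `r >= threshold`
#'   flags the pair. Default 0.4, deliberately low.
#' @param frame_period Frame period (s); defaults to the trace's.
#' @return Stall-event data frame (`capillary_id`, `start_frame`,
#'   `end_frame` 1-based inclusive, `duration_frames`, `duration_s`).
#' @export
threshold_correlation <- function(trace, threshold = 0.4,
                                  frame_period = trace$frame_period) {
  stopifnot(inherits(trace, "correlation_trace"),
            threshold > -1, threshold < 1)
  supra <- trace$r >= threshold
  T <- length(trace$r) + 1L
  stalled <- logical(T)
  stalled[which(supra)] <- TRUE
  stalled[which(supra) + 1L] <- TRUE
  runs <- rle(stalled)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  make_events(rep(trace$capillary_id, sum(keep)), starts[keep], ends[keep],
              frame_period)
}

#' Build a stallogram from stall events
#'
#' Marks the event frames of each capillary; overlapping or adjacent
#' events on one capillary merge into a single run.
#'
#' @param events Stall-event data frame (1-based inclusive frames).
#' @param capillary_ids Row identifiers; every event's `capillary_id` must
#'   be among them.
#' @param n_frames Number of frames (columns).
#' @param frame_period Frame period, seconds.
#' @return A [stallogram()].
#' @export
events_to_stallogram <- function(events, capillary_ids, n_frames,
                                 frame_period = 1 / 0.57) {
  capillary_ids <- as.character(capillary_ids)
  mat <- matrix(FALSE, length(capillary_ids), n_frames)
  if (nrow(events)) {
    unknown <- setdiff(unique(events$capillary_id), capillary_ids)
    if (length(unknown)) {
      stop("events reference unknown capillary ids: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(events$start_frame < 1 | events$end_frame > n_frames |
            events$start_frame > events$end_frame)) {
      stop("event frames out of range [1, n_frames]", call. = FALSE)
    }
    ridx <- match(events$capillary_id, capillary_ids)
    for (k in seq_len(nrow(events))) {
      mat[ridx[k], events$start_frame[k]:events$end_frame[k]] <- TRUE
    }
  }
  stallogram(mat, capillary_ids, frame_period)
}

#' Capillary-level validation against a ground-truth stallogram
#'
#' A capillary is "positive" if it has at least one stall event. Compares
#' prediction and truth capillary by capillary, returning the confusion
#' counts and rates (sensitivity, specificity) in the layout of a
#' validation truth table; a frame-level confusion over all
#' (capillary, frame) entries is included as a secondary output.
#'
#' @param predicted,truth [stallogram()]s over the same capillaries and
#'   frames.
#' @return A list of class `confusion_table`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity` (percent), and `frame_level` (same
#'   fields computed per frame entry).
#' @export
compare_to_truth <- function(predicted, truth) {
  stopifnot(inherits(predicted, "stallogram"), inherits(truth, "stallogram"))
  if (!identical(dim(predicted$matrix), dim(truth$matrix)) ||
      !identical(predicted$capillary_ids, truth$capillary_ids)) {
    stop("predicted and truth stallograms must share capillaries and frames",
         call. = FALSE)
  }
  p <- rowSums(predicted$matrix) > 0
  g <- rowSums(truth$matrix) > 0
  cap <- confusion_rates(tp = sum(p & g), fp = sum(p & !g),
                         tn = sum(!p & !g), fn = sum(!p & g))
  frm <- confusion_rates(tp = sum(predicted$matrix & truth$matrix),
                         fp = sum(predicted$matrix & !truth$matrix),
                         tn = sum(!predicted$matrix & !truth$matrix),
                         fn = sum(!predicted$matrix & truth$matrix))
  cap$frame_level <- frm
  cap
}

#' Automated review of flagged stall events
#'
#' Stands in for human confirmation of detector-flagged events in fully
#' automatic operation. A flagged event is confirmed when (a) it lasts at
#' least `min_frames` frames and (b) some window of `min_frames`
#' consecutive frames within it has *all pairwise* row correlations at or
#' above `pair_threshold` — the direct transcription of the stall
#' definition: the same shadow pattern present throughout, not merely in
#' one lucky consecutive pair. Chance suprathreshold runs in flowing
#' capillaries almost never satisfy the all-pairs condition, while frozen
#' shadow patterns do.
#'
#' @param lt The (preferably detrended, see [detrend_lt()]) LT image the
#'   events were detected on.
#' @param events Flagged events for this capillary (from
#'   [threshold_correlation()]).
#' @param min_frames Minimum confirmed event duration (default 4).
#' @param pair_threshold Minimum pairwise row correlation within the
#'   confirming window (default 0.5).
#' @return The subset of `events` that is confirmed.
#' @export
review_events <- function(lt, events, min_frames = 4L, pair_threshold = 0.5) {
  if (!nrow(events)) return(events)
  v <- lt$values
  ok <- logical(nrow(events))
  for (j in seq_len(nrow(events))) {
    a <- events$start_frame[j]; b <- events$end_frame[j]
    if (b - a + 1L < min_frames) next
    for (st in a:(b - min_frames + 1L)) {
      rows <- v[st:(st + min_frames - 1L), , drop = FALSE]
      cc <- suppressWarnings(cor(t(rows)))
      cc[!is.finite(cc)] <- 0
      if (min(cc[lower.tri(cc)]) >= pair_threshold) {
        ok[j] <- TRUE
        break
      }
    }
  }
  events[ok, , drop = FALSE]
}

#' Export flagged stall candidates for external review
#'
#' Writes the detector's flagged (capillary, interval) candidates as a CSV
#' with 0-based inclusive frame indices, supporting manual review outside
#' the package.
#'
#' @param events Stall-event data frame (1-based internally).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_candidates <- function(events, path) {
  out <- data.frame(capillary_id = events$capillary_id,
                    start_frame = events$start_frame - 1L,
                    end_frame = events$end_frame - 1L,
                    duration_frames = events$duration_frames,
                    duration_s = events$duration_s)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
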