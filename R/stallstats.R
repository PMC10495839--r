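# Stallogram summary statistics, duration filtering, incidence accumulation
# and the exponential incidence model.

#' Extract stall events from a stallogram
#'
#' Run-length reading of each row: every maximal run of `TRUE` becomes one
#' event. A run of a single frame violates the stall definition (two or
#' more consecutive frames) and raises an integrity error.
#'
#' @param sg A [stallogram()].
#' @return Stall-event data frame (1-based inclusive frames).
#' @export
extract_events <- function(sg) {
  stopifnot(inherits(sg, "stallogram"))
  out <- list()
  for (i in seq_len(nrow(sg$matrix))) {
    r <- rle(sg$matrix[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(r$lengths[keep] < 2L)) {
      stop("stallogram integrity error: single-frame stall run in capillary ",
           sg$capillary_ids[i], call. = FALSE)
    }
    if (any(keep)) {
      out[[length(out) + 1L]] <- make_events(sg$capillary_ids[i],
                                             starts[keep], ends[keep],
                                             sg$frame_period)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_events()
}

#' Stall statistics: incidence, point prevalence, cumulative duration
#'
#' * incidence — percent of all counted capillaries with at least one
#'   stall during the record;
#' * point prevalence — time-averaged percent of capillaries actively
#'   stalled at a given frame;
#' * cumulative stall duration — mean, over stalling capillaries, of the
#'   percent of the record each spends stalled (0, flagged, if no
#'   capillary stalls).
#'
#' @param sg A [stallogram()] over the analyzed capillaries.
#' @param n_capillaries_total Denominator: all counted capillaries (can
#'   exceed the stallogram's rows when only flagged capillaries were
#'   analyzed). Defaults to the row count.
#' @return An object of class `stall_statistics`.
#' @export
compute_statistics <- function(sg, n_capillaries_total = nrow(sg$matrix)) {
  stopifnot(inherits(sg, "stallogram"))
  if (n_capillaries_total <= 0) {
    stop("`n_capillaries_total` must be positive", call. = FALSE)
  }
  stalled_rows <- rowSums(sg$matrix) > 0
  n_stalling <- sum(stalled_rows)
  if (n_capillaries_total < n_stalling) {
    stop("`n_capillaries_total` is smaller than the number of stalling capillaries",
         call. = FALSE)
  }
  T <- ncol(sg$matrix)
  incidence <- 100 * n_stalling / n_capillaries_total
  point_prev <- 100 * mean(colSums(sg$matrix) / n_capillaries_total)
  if (n_stalling > 0) {
    cum_dur <- 100 * mean(rowSums(sg$matrix[stalled_rows, , drop = FALSE]) / T)
    no_stalls <- FALSE
  } else {
    cum_dur <- 0
    no_stalls <- TRUE
  }
  structure(list(incidence = incidence, point_prevalence = point_prev,
                 cumulative_stall_duration = cum_dur,
                 n_capillaries_total = n_capillaries_total,
                 n_capillaries_stalling = n_stalling,
                 no_stalls = no_stalls),
            class = "stall_statistics")
}

#' @export
print.stall_statistics <- function(x, ...) {
  cat(sprintf(paste0("<stall_statistics> incidence %.2f%%, point prevalence %.3f%%, ",
                     "cumulative stall duration %.2f%% (%d/%d capillaries stalling)\n"),
              x$incidence, x$point_prevalence, x$cumulative_stall_duration,
              x$n_capillaries_stalling, x$n_capillaries_total))
  invisible(x)
}

#' Per-frame stall point prevalence trace
#'
#' @param sg A [stallogram()].
#' @param n_capillaries_total Denominator (default: row count).
#' @return Numeric length-`T` trace, percent.
#' @export
point_prevalence_trace <- function(sg, n_capillaries_total = nrow(sg$matrix)) {
  stopifnot(inherits(sg, "stallogram"), n_capillaries_total > 0)
  100 * colSums(sg$matrix) / n_capillaries_total
}

#' Remove stalls shorter than a minimum duration
#'
#' Recomputes the stallogram keeping only events of at least `min_frames`
#' frames. `min_frames = 2` keeps all stalls (every stall spans at least
#' two frames by definition).
#'
#' @param sg A [stallogram()].
#' @param min_frames Minimum duration in frames, `>= 2`.
#' @return A filtered [stallogram()].
#' @export
filter_min_duration <- function(sg, min_frames) {
  stopifnot(inherits(sg, "stallogram"))
  if (min_frames < 2) {
    stop("`min_frames` must be at least 2 (the minimum stall duration)",
         call. = FALSE)
  }
  if (min_frames == 2) return(sg)
  ev <- extract_events(sg)
  ev <- ev[ev$duration_frames >= min_frames, , drop = FALSE]
  events_to_stallogram(ev, sg$capillary_ids, ncol(sg$matrix), sg$frame_period)
}

#' Empirical CDF of stall event durations
#'
#' @param events Non-empty stall-event data frame.
#' @return List of class `duration_cdf` with `durations_s` (sorted unique
#'   durations) and `cdf` (cumulative fraction at each duration, ending
#'   at 1).
#' @export
duration_cdf <- function(events) {
  if (!nrow(events)) stop("no stall events: CDF undefined", call. = FALSE)
  d <- sort(unique(events$duration_s))
  cdf <- vapply(d, function(x) mean(events$duration_s <= x), numeric(1))
  structure(list(durations_s = d, cdf = cdf), class = "duration_cdf")
}

#' Stall incidence as a function of measurement time
#'
#' For each time `t` (minutes), the percent of capillaries with at least
#' one stalled frame within the first `floor(t * 60 / frame_period)`
#' frames. Non-decreasing in `t`.
#'
#' @param sg A [stallogram()].
#' @param t_grid_min Times in minutes, within the record duration.
#' @param n_capillaries_total Denominator (default: row count).
#' @return Data frame with `t_min` and `incidence` (percent).
#' @export
incidence_vs_time <- function(sg, t_grid_min,
                              n_capillaries_total = nrow(sg$matrix)) {
  stopifnot(inherits(sg, "stallogram"), n_capillaries_total > 0)
  if (any(t_grid_min < 0)) stop("times must be non-negative", call. = FALSE)
  T <- ncol(sg$matrix)
  record_min <- T * sg$frame_period / 60
  if (any(t_grid_min > record_min + 1e-9)) {
    stop("times exceed the record duration (", round(record_min, 2), " min)",
         call. = FALSE)
  }
  any_prefix <- t(apply(sg$matrix, 1L, cumsum)) > 0
  inc <- vapply(t_grid_min, function(t) {
    k <- min(T, floor(t * 60 / sg$frame_period))
    if (k < 1) 0 else 100 * sum(any_prefix[, k]) / n_capillaries_total
  }, numeric(1))
  data.frame(t_min = t_grid_min, incidence = inc)
}

#' Fit the exponential incidence-accumulation model
#'
#' Fits `I(t) = A * (1 - exp(-B * t)) + C` (t in minutes) by nonlinear
#' least squares (Levenberg-Marquardt), with multi-start initialization to
#' guard against local minima. The saturating form expresses that a
#' consistent subset of capillaries stalls repeatedly: observed incidence
#' accumulates quickly and plateaus near `A + C` rather than growing
#' without bound.
#'
#' @param t_min Times, minutes.
#' @param incidence Incidence values, percent.
#' @param init Initial `(A, B, C)` (default `c(1, 1, 0)`).
#' @param extra_starts Additional data-driven starts tried alongside
#'   `init` (default `TRUE`).
#' @return List of class `exponential_fit`: `A`, `B`, `C`,
#'   `residual_norm`, `converged`, `degenerate` (`TRUE` for a constant
#'   curve, where `B` is unidentifiable and `A = 0`, `C = mean`).
#' @export
fit_exponential <- function(t_min, incidence, init = c(1, 1, 0),
                            extra_starts = TRUE) {
  stopifnot(length(t_min) == length(incidence), length(t_min) >= 4)
  if (sd(incidence) < 1e-12) {
    return(structure(list(A = 0, B = NA_real_, C = mean(incidence),
                          residual_norm = 0, converged = TRUE,
                          degenerate = TRUE),
                     class = "exponential_fit"))
  }
  dat <- data.frame(t = t_min, y = incidence)
  starts <- list(c(A = init[1], B = init[2], C = init[3]))
  if (extra_starts) {
    rng <- diff(range(incidence))
    starts <- c(starts,
                list(c(A = rng, B = 1 / max(mean(t_min), 1e-6), C = min(incidence)),
                     c(A = rng, B = 5, C = min(incidence))))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * (1 - exp(-B * t)) + C, data = dat,
                        start = as.list(s),
                        lower = c(A = -Inf, B = 1e-9, C = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$residual_norm) {
      cf <- coef(fit)
      best <- list(A = unname(cf["A"]), B = unname(cf["B"]),
                   C = unname(cf["C"]), residual_norm = rn,
                   converged = TRUE, degenerate = FALSE)
    }
  }
  if (is.null(best)) {
    stop("exponential model fit failed to converge from all starts",
         call. = FALSE)
  }
  structure(best, class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<exponential_fit> degenerate (constant): A=0, C=%.4g; B unidentifiable\n",
                x$C))
  } else {
    cat(sprintf("<exponential_fit> A=%.4g%%, B=%.4g /min, C=%.4g%% (residual %.3g)\n",
                x$A, x$B, x$C, x$residual_norm))
  }
  invisible(x)
}

#' Validation truth-table rates from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative counts. Positive = the capillary (or
#'   frame) has at least one stall.
#' @return List of class `confusion_table`: the counts; `sensitivity` and
#'   `specificity` in percent (`NA` with `undefined_rates = TRUE` when a
#'   truth row is empty); and `rates` — the truth-table layout with row
#'   percentages (`positive_row` = percent of ground-truth positives
#'   missed/detected, `negative_row` = percent of ground-truth negatives
#'   correctly rejected/falsely flagged).
#' @export
confusion_rates <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  pos <- tp + fn; neg <- tn + fp
  sens <- if (pos > 0) 100 * tp / pos else NA_real_
  spec <- if (neg > 0) 100 * tn / neg else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 undefined_rates = pos == 0 || neg == 0,
                 rates = list(
                   positive_row = c(negative_pct = if (pos > 0) 100 * fn / pos else NA_real_,
                                    positive_pct = sens),
                   negative_row = c(negative_pct = spec,
                                    positive_pct = if (neg > 0) 100 * fp / neg else NA_real_))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>\n")
  cat(sprintf("  ground truth positive (%d): %5.1f%% negative (%d)  %5.1f%% positive (%d)\n",
              x$tp + x$fn, x$rates$positive_row["negative_pct"], x$fn,
              x$rates$positive_row["positive_pct"], x$tp))
  cat(sprintf("  ground truth negative (%d): %5.1f%% negative (%d)  %5.1f%% positive (%d)\n",
              x$tn + x$fp, x$rates$negative_row["negative_pct"], x$tn,
              x$rates$negative_row["positive_pct"], x$fp))
  invisible(x)
}
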