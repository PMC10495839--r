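# Shared fixtures and independent oracles, built in code.

# Independent per-frame state-machine simulation of the two-state
# flow/stall renewal process. Deliberately coded differently from the
# package's event-time sampler: it walks frame by frame, decrementing a
# sojourn counter. Never renders images.
oracle_renewal_row <- function(n_frames, p_onset, dur_prob, dur_min) {
  row <- logical(n_frames)
  state <- "flow"
  remaining <- 1L + rgeom(1L, p_onset)
  for (t in seq_len(n_frames)) {
    row[t] <- state == "stall"
    remaining <- remaining - 1L
    if (remaining == 0L) {
      if (state == "flow") {
        state <- "stall"
        remaining <- dur_min + rgeom(1L, dur_prob)
      } else {
        state <- "flow"
        remaining <- 1L + rgeom(1L, p_onset)
      }
    }
  }
  # truncated terminal stall of one observed frame is not a stall
  r <- rle(row)
  if (tail(r$values, 1) && tail(r$lengths, 1) < 2L) {
    row[n_frames] <- FALSE
  }
  row
}

oracle_renewal_prevalence <- function(n_caps, n_frames, rate_per_min,
                                      frame_period, dur_prob, dur_min,
                                      stalling_fraction) {
  p_onset <- 1 - exp(-rate_per_min * frame_period / 60)
  stalled <- 0
  for (i in seq_len(n_caps)) {
    if (runif(1) < stalling_fraction) {
      stalled <- stalled + sum(oracle_renewal_row(n_frames, p_onset,
                                                  dur_prob, dur_min))
    }
  }
  stalled / (n_caps * n_frames)
}

# brute-force per-entry counting of stallogram statistics
oracle_count_statistics <- function(mat, n_total) {
  T <- ncol(mat)
  stalling <- 0L
  col_counts <- integer(T)
  row_frac <- numeric(0)
  for (i in seq_len(nrow(mat))) {
    n_true <- 0L
    for (t in seq_len(T)) {
      if (mat[i, t]) {
        n_true <- n_true + 1L
        col_counts[t] <- col_counts[t] + 1L
      }
    }
    if (n_true > 0L) {
      stalling <- stalling + 1L
      row_frac <- c(row_frac, n_true / T)
    }
  }
  list(incidence = 100 * stalling / n_total,
       point_prevalence = 100 * mean(col_counts / n_total),
       cumulative_stall_duration = if (stalling > 0) 100 * mean(row_frac) else 0)
}

# random valid stallogram (all TRUE runs >= 2 frames)
random_stallogram <- function(n_caps, n_frames, frame_period = 1 / 0.57) {
  mat <- matrix(FALSE, n_caps, n_frames)
  for (i in seq_len(n_caps)) {
    t <- 1L
    while (t <= n_frames - 2L) {
      t <- t + sample(1:15, 1L)
      d <- sample(2:8, 1L)
      e <- min(t + d - 1L, n_frames)
      if (e <= n_frames && e - t + 1L >= 2L && t <= n_frames) mat[i, t:e] <- TRUE
      t <- e + 2L
    }
  }
  stallogram(mat, paste0("c", seq_len(n_caps)), frame_period)
}

# analytic straight-tube image: Gaussian cross profile of sd `sigma`,
# oriented along `theta`, centered on the image center
analytic_tube <- function(n, sigma, theta = 0, amp = 1) {
  c0 <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n), each = n), n, n)   # x = column
  yg <- matrix(rep(seq_len(n), times = n), n, n)  # y = row
  d_perp <- -(xg - c0) * sin(theta) + (yg - c0) * cos(theta)
  amp * exp(-d_perp^2 / (2 * sigma^2))
}

# midpoint clicks for ground-truth capillaries
truth_clicks <- function(truth) {
  do.call(rbind, lapply(truth$centerlines, function(cl) {
    p <- cl$points[round(cl$length_px / 2), ]
    data.frame(capillary_label = cl$capillary_id, x = p[1], y = p[2])
  }))
}

# mean distance from each point of `cl` to the nearest point of `ref`
mean_dist_to <- function(cl, ref) {
  mean(apply(cl$points, 1L, function(p) {
    sqrt(min((ref$points[, 1] - p[1])^2 + (ref$points[, 2] - p[2])^2))
  }))
}

# minimal lt_image-like wrapper for raw matrices
as_lt <- function(values, frame_period = 1 / 0.57, id = "cap") {
  structure(list(capillary_id = id, values = values,
                 offsets = matrix(0, nrow(values), 2),
                 frame_period = frame_period, n_clamped = 0L),
            class = "lt_image")
}
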