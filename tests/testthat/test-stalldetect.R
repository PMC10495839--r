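test_that("frame correlation handles exact, inverted and degenerate rows", {
  row <- sin(seq(0, 6, length.out = 20))
  lt <- as_lt(rbind(row, row))
  tr <- frame_correlation(lt)
  expect_equal(tr$r, 1)
  expect_false(any(tr$degenerate))

  neg <- as_lt(rbind(row, mean(row) - (row - mean(row))))
  expect_equal(frame_correlation(neg)$r, -1)

  const <- as_lt(rbind(rep(2, 20), row))
  trc <- frame_correlation(const)
  expect_equal(trc$r, 0)
  expect_true(trc$degenerate[1])

  expect_error(frame_correlation(as_lt(matrix(1, 1, 20))), "2 rows")
  expect_error(frame_correlation(as_lt(matrix(1, 5, 5))), "6 columns")
})

test_that("correlation of independent rows is centered on zero", {
  set.seed(12)
  lt <- as_lt(matrix(rnorm(10001 * 50), 10001, 50))
  r <- frame_correlation(lt)$r
  expect_identical(length(r), 10000L)
  expect_lt(abs(mean(r)), 0.03)
})

test_that("thresholding maps suprathreshold pairs to >=2-frame events", {
  tr <- structure(list(capillary_id = "a", r = c(0.1, 0.9, 0.9, 0.1),
                       degenerate = rep(FALSE, 4), frame_period = 1 / 0.57),
                  class = "correlation_trace")
  ev <- threshold_correlation(tr, 0.5)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$start_frame, 2L)
  expect_identical(ev$end_frame, 4L)
  expect_identical(ev$duration_frames, 3L)

  none <- threshold_correlation(
    structure(list(capillary_id = "a", r = rep(0.1, 6),
                   degenerate = rep(FALSE, 6), frame_period = 1),
              class = "correlation_trace"), 0.5)
  expect_identical(nrow(none), 0L)

  single <- threshold_correlation(
    structure(list(capillary_id = "a", r = c(0.1, 0.8, 0.1),
                   degenerate = rep(FALSE, 3), frame_period = 1 / 0.57),
              class = "correlation_trace"), 0.5)
  expect_identical(single$duration_frames, 2L)
  expect_equal(single$duration_s, 2 / 0.57)
})

test_that("predictions are nested in the threshold (monotonicity)", {
  set.seed(3)
  for (rep in 1:20) {
    tr <- structure(list(capillary_id = "a", r = runif(80, -1, 1),
                         degenerate = rep(FALSE, 80), frame_period = 1),
                    class = "correlation_trace")
    lo <- events_to_stallogram(threshold_correlation(tr, 0.3), "a", 81, 1)
    hi <- events_to_stallogram(threshold_correlation(tr, 0.6), "a", 81, 1)
    expect_true(all(lo$matrix[hi$matrix]))   # hi-threshold frames subset of lo
  }
})

test_that("events build stallograms with merging and validation", {
  sg0 <- events_to_stallogram(capstall:::empty_events(), c("a", "b"), 10, 1)
  expect_false(any(sg0$matrix))

  ev <- make_events_df <- data.frame(capillary_id = c("a", "a"),
                                     start_frame = c(1L, 2L),
                                     end_frame = c(2L, 4L),
                                     duration_frames = c(2L, 3L),
                                     duration_s = c(2, 3))
  sg <- events_to_stallogram(ev, c("a", "b"), 10, 1)
  expect_identical(which(sg$matrix["a", ]), 1:4)
  merged <- extract_events(sg)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$start_frame, 1L)
  expect_identical(merged$end_frame, 4L)

  expect_error(events_to_stallogram(ev, c("b"), 10, 1), "unknown capillary")
  bad <- ev; bad$end_frame[2] <- 11L
  expect_error(events_to_stallogram(bad, c("a"), 10, 1), "out of range")
})

test_that("capillary-level confusion against truth is correct", {
  m <- matrix(FALSE, 3, 8); m[1, 3:5] <- TRUE; m[2, 6:7] <- TRUE
  truth <- stallogram(m, c("a", "b", "c"), 1)
  perfect <- compare_to_truth(truth, truth)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  none <- stallogram(matrix(FALSE, 3, 8), c("a", "b", "c"), 1)
  miss <- compare_to_truth(none, truth)
  expect_equal(miss$sensitivity, 0)
  expect_equal(miss$specificity, 100)
  expect_identical(miss$fn, 2L)

  other <- stallogram(matrix(FALSE, 2, 8), c("a", "b"), 1)
  expect_error(compare_to_truth(other, truth), "share")
})

test_that("detrending removes static structure but keeps frozen patterns detectable", {
  set.seed(8)
  static <- seq(0, 1, length.out = 40)^2
  frozen <- rnorm(40, sd = 0.1)
  vals <- matrix(rep(static, each = 12), 12, 40)
  for (t in 1:12) {
    vals[t, ] <- vals[t, ] + (if (t %in% 5:8) frozen else rnorm(40, sd = 0.1))
  }
  lt <- as_lt(vals)
  ltd <- detrend_lt(lt)
  expect_equal(colMeans(ltd$values), rep(0, 40), tolerance = 1e-12)
  r_raw <- frame_correlation(lt)$r
  r_det <- frame_correlation(ltd)$r
  expect_gt(mean(r_raw[c(1:3, 9:11)]), 0.5)    # static structure dominates
  expect_lt(mean(abs(r_det[c(1:3, 9:11)])), 0.4)
  expect_gt(min(r_det[5:7]), 0.5)              # frozen pattern survives
})

test_that("automated review confirms frozen windows and rejects lucky pairs", {
  set.seed(4)
  L <- 40
  frozen <- rnorm(L)
  vals <- matrix(rnorm(12 * L), 12, L)
  for (t in 5:9) vals[t, ] <- frozen + rnorm(L, sd = 0.15)
  lt <- as_lt(vals)
  ev_true <- make_ev <- data.frame(capillary_id = "cap", start_frame = 5L,
                                   end_frame = 9L, duration_frames = 5L,
                                   duration_s = 5 * 1.754)
  expect_identical(nrow(review_events(lt, ev_true)), 1L)

  # a 4-frame candidate whose rows are mutually unrelated
  ev_fake <- data.frame(capillary_id = "cap", start_frame = 1L,
                        end_frame = 4L, duration_frames = 4L,
                        duration_s = 4 * 1.754)
  expect_identical(nrow(review_events(lt, ev_fake)), 0L)
  # too short to confirm
  ev_short <- data.frame(capillary_id = "cap", start_frame = 5L,
                         end_frame = 6L, duration_frames = 2L,
                         duration_s = 2 * 1.754)
  expect_identical(nrow(review_events(lt, ev_short)), 0L)
})

test_that("candidate export writes 0-based frames", {
  ev <- data.frame(capillary_id = "a", start_frame = 3L, end_frame = 5L,
                   duration_frames = 3L, duration_s = 3 * 1.754)
  f <- withr::local_tempfile(fileext = ".csv")
  export_candidates(ev, f)
  back <- read.csv(f)
  expect_identical(back$start_frame, 2L)
  expect_identical(back$end_frame, 4L)
})
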