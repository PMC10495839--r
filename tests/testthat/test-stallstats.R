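test_that("events are maximal runs with conservation of stalled frames", {
  m <- matrix(FALSE, 1, 7); m[1, c(2, 3, 5, 6, 7)] <- TRUE
  ev <- extract_events(stallogram(m, "a", 1))
  expect_identical(ev$duration_frames, c(2L, 3L))

  expect_identical(nrow(extract_events(stallogram(matrix(FALSE, 2, 5),
                                                  c("a", "b"), 1))), 0L)
  set.seed(2)
  for (rep in 1:10) {
    sg <- random_stallogram(8, 60)
    ev <- extract_events(sg)
    expect_identical(sum(ev$duration_frames), sum(sg$matrix))
  }
  bad <- matrix(FALSE, 1, 5); bad[1, 3] <- TRUE
  sg_bad <- stallogram(bad, "a", 1, check_runs = FALSE)
  expect_error(extract_events(sg_bad), "integrity")
})

test_that("incidence, prevalence and cumulative duration match hand counts", {
  m <- matrix(FALSE, 10, 350); m[1, ] <- TRUE
  st <- compute_statistics(stallogram(m, frame_period = 1))
  expect_equal(st$incidence, 10)
  expect_equal(st$point_prevalence, 10)
  expect_equal(st$cumulative_stall_duration, 100)

  m2 <- matrix(FALSE, 10, 350)
  m2[1, 1:35] <- TRUE; m2[2, 11:80] <- TRUE
  st2 <- compute_statistics(stallogram(m2, frame_period = 1))
  expect_equal(st2$incidence, 20)
  expect_equal(st2$cumulative_stall_duration, 15)   # mean(10%, 20%)

  expect_error(compute_statistics(stallogram(m2, frame_period = 1), 0),
               "positive")
  expect_error(compute_statistics(stallogram(m2, frame_period = 1), 1),
               "smaller")
  empty <- compute_statistics(stallogram(matrix(FALSE, 4, 10),
                                         frame_period = 1))
  expect_true(empty$no_stalls)
  expect_equal(empty$cumulative_stall_duration, 0)
})

test_that("statistics equal the brute-force counting oracle exactly", {
  set.seed(14)
  for (rep in 1:20) {
    sg <- random_stallogram(12, 80)
    st <- compute_statistics(sg)
    orc <- oracle_count_statistics(sg$matrix, 12)
    expect_identical(st$incidence, orc$incidence)
    expect_identical(st$point_prevalence, orc$point_prevalence)
    expect_identical(st$cumulative_stall_duration,
                     orc$cumulative_stall_duration)
    # conservation identity before percentage scaling
    expect_equal(st$point_prevalence / 100 * 12 * 80, sum(sg$matrix))
  }
})

test_that("duration filtering removes short stalls and is identity at 2", {
  m <- matrix(FALSE, 4, 30)
  m[1, 1:2] <- TRUE; m[2, 5:7] <- TRUE; m[3, 10:14] <- TRUE; m[4, 20:26] <- TRUE
  sg <- stallogram(m, frame_period = 1 / 0.57)
  expect_identical(filter_min_duration(sg, 2), sg)
  f5 <- filter_min_duration(sg, 5)
  expect_identical(nrow(extract_events(f5)), 2L)
  expect_error(filter_min_duration(sg, 1), "at least 2")
  # 5 frames at 1.754 s/frame keeps only stalls of at least ~8.8 s
  kept <- extract_events(f5)
  expect_true(all(kept$duration_s >= 5 / 0.57 - 1e-9))
})

test_that("statistics are monotone non-increasing in the duration filter", {
  set.seed(6)
  for (rep in 1:10) {
    sg <- random_stallogram(10, 100)
    prev_st <- compute_statistics(sg)
    prev_n <- nrow(extract_events(sg))
    for (mf in c(3, 4, 6, 8)) {
      f <- filter_min_duration(sg, mf)
      st <- compute_statistics(f, 10)
      n <- nrow(extract_events(f))
      expect_lte(st$incidence, prev_st$incidence)
      expect_lte(st$point_prevalence, prev_st$point_prevalence)
      expect_lte(n, prev_n)
      prev_st <- st; prev_n <- n
    }
  }
})

test_that("duration CDF is a proper empirical CDF", {
  fp <- 1 / 0.57
  ev <- make_events_helper <- data.frame(capillary_id = c("a", "a", "b"),
                                         start_frame = c(1L, 10L, 1L),
                                         end_frame = c(2L, 11L, 4L),
                                         duration_frames = c(2L, 2L, 4L),
                                         duration_s = c(2, 2, 4) * fp)
  cdf <- duration_cdf(ev)
  expect_equal(cdf$durations_s, c(2, 4) * fp)
  expect_equal(cdf$cdf, c(2 / 3, 1))
  expect_true(all(diff(cdf$cdf) >= 0))
  expect_equal(tail(cdf$cdf, 1), 1)
  single <- duration_cdf(ev[3, ])
  expect_equal(single$cdf, 1)
  expect_error(duration_cdf(ev[0, ]), "no stall events")
})

test_that("incidence accumulates with measurement time", {
  set.seed(10)
  sg <- random_stallogram(15, 120, frame_period = 1)
  full_min <- 120 / 60
  curve <- incidence_vs_time(sg, seq(0, full_min, length.out = 13))
  expect_equal(curve$incidence[1], 0)
  expect_equal(tail(curve$incidence, 1), compute_statistics(sg)$incidence)
  expect_true(all(diff(curve$incidence) >= 0))
  # brute-force prefix counting oracle
  for (k in c(3, 7, 11)) {
    t <- curve$t_min[k]
    nf <- floor(t * 60 / 1)
    expect_equal(curve$incidence[k],
                 100 * sum(apply(sg$matrix[, seq_len(nf), drop = FALSE], 1, any)) / 15)
  }
  expect_error(incidence_vs_time(sg, -1), "non-negative")
  expect_error(incidence_vs_time(sg, 10), "exceed")
})

test_that("exponential model round trips noiselessly and flags constants", {
  fp <- 1 / 0.57
  t_min <- (1:350) * fp / 60
  for (p in list(c(A = 8.4, B = 6.4, C = 1.15), c(A = 5.4, B = 6.5, C = 0.7))) {
    y <- p["A"] * (1 - exp(-p["B"] * t_min)) + p["C"]
    fit <- fit_exponential(t_min, y, init = c(1, 1, 0))
    expect_lt(abs(fit$A - p["A"]) / p["A"], 1e-6)
    expect_lt(abs(fit$B - p["B"]) / p["B"], 1e-6)
    expect_lt(abs(fit$C - p["C"]) / abs(p["C"]), 1e-6)
    expect_true(fit$converged)
  }
  const <- fit_exponential(t_min[1:20], rep(4.2, 20))
  expect_true(const$degenerate)
  expect_equal(const$A, 0)
  expect_equal(const$C, 4.2)
})

test_that("exponential fit recovers A under noise (Monte-Carlo)", {
  fp <- 1 / 0.57
  t_min <- (1:350) * fp / 60
  y0 <- 8.4 * (1 - exp(-6.4 * t_min)) + 1.15
  set.seed(20)
  rel_err <- vapply(1:200, function(s) {
    fit <- fit_exponential(t_min, y0 + rnorm(350, sd = 0.5),
                           init = c(1, 1, 0), extra_starts = FALSE)
    abs(fit$A - 8.4) / 8.4
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
})

test_that("confusion rates reproduce truth-table arithmetic", {
  manual <- confusion_rates(tp = 102, fp = 37, tn = 2074, fn = 245)
  expect_equal(round(manual$sensitivity, 1), 29.4)
  expect_equal(round(manual$specificity, 1), 98.2)
  expect_equal(round(manual$rates$positive_row[["negative_pct"]], 1), 70.6)

  corr <- confusion_rates(tp = 317, fp = 1150, tn = 961, fn = 30)
  expect_equal(round(corr$sensitivity, 1), 91.4)
  expect_equal(round(corr$specificity, 1), 45.5)
  expect_equal(round(corr$rates$positive_row[["negative_pct"]], 1), 8.6)

  z <- confusion_rates(0, 0, 5, 0)
  expect_true(z$undefined_rates)
  expect_true(is.na(z$sensitivity))
  expect_error(confusion_rates(-1, 0, 0, 0), "non-negative")
})
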