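test_that("vesselness is zero on structureless images and peaks on the tube axis", {
  expect_true(all(enhance_vessels(matrix(5, 40, 40), c(1, 2)) == 0))
  expect_error(enhance_vessels(matrix(0, 4, 4), numeric(0)), "scale")
  expect_error(enhance_vessels(matrix(NA_real_, 4, 4), 1), "finite")

  # bright tube of width ~3 px (sigma = 3/2.355)
  img <- analytic_tube(61, sigma = 3 / 2.355, theta = 0)
  v <- enhance_vessels(img, c(1, 2, 3))
  peak <- arrayInd(which.max(v), dim(v))
  expect_equal(peak[1], 31, tolerance = 1)        # on the horizontal axis row
  on_axis <- mean(v[31, 10:52])
  off_axis <- mean(v[31 + 9, 10:52])              # 3 tube widths away
  expect_gt(on_axis, 5 * off_axis)
})

test_that("vesselness is rotation covariant within discretization error", {
  v0 <- enhance_vessels(analytic_tube(81, 1.5, 0), c(1, 2, 3))
  v45 <- enhance_vessels(analytic_tube(81, 1.5, pi / 4), c(1, 2, 3))
  # mean response along the central third of each tube axis
  idx <- 30:52
  m0 <- mean(v0[41, idx])
  m45 <- mean(v45[cbind(idx, idx)])
  expect_lt(abs(m0 - m45) / m0, 0.10)
})

test_that("segmentation thresholds the vesselness map", {
  v <- matrix(c(0.2, 0.8), 4, 4)
  expect_identical(segment_vessels(v, 0.5), v == 0.8)
  expect_true(all(segment_vessels(v, 0)))
  expect_false(any(segment_vessels(v, 0.9)))
  expect_error(segment_vessels(v, 1.2), "\\[0, 1\\)")
  # automatic threshold separates a bimodal map
  v2 <- matrix(0.05, 32, 32); v2[10:20, 5:28] <- 0.9
  expect_identical(segment_vessels(v2), v2 == 0.9)
})

test_that("skeletonization thins to 1-px lines preserving topology", {
  expect_identical(skeletonize_mask(matrix(FALSE, 10, 10)),
                   matrix(FALSE, 10, 10))

  bar <- matrix(FALSE, 40, 40); bar[18:22, 5:35] <- TRUE
  s <- skeletonize_mask(bar)
  expect_true(all(s[bar == FALSE] == FALSE))              # subset of mask
  expect_identical(unique(which(s, arr.ind = TRUE)[, 1]), 20L)  # middle row
  no22 <- function(m) !any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
                             m[-nrow(m), -1] & m[-1, -1])
  expect_true(no22(s))

  # annulus keeps its single cycle (Euler number 0: one loop)
  n <- 41; c0 <- 21
  d <- sqrt(outer((1:n - c0)^2, (1:n - c0)^2, `+`))
  ring <- d >= 8 & d <= 14
  sk <- skeletonize_mask(ring)
  g <- skeleton_to_graph(sk)
  expect_identical(length(g$edges), 1L)
  e <- g$edges[[1]]
  expect_identical(e$node_a, e$node_b)                    # self-edge
  deg_census <- table(vapply(seq_len(sum(sk)), function(i) {
    idx <- which(sk)[i]
    y <- (idx - 1) %% n + 1; x <- (idx - 1) %/% n + 1
    nb <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      if ((dy != 0 || dx != 0) && y + dy >= 1 && y + dy <= n &&
          x + dx >= 1 && x + dx <= n && sk[y + dy, x + dx]) nb <- nb + 1L
    }
    nb
  }, integer(1)))
  expect_identical(names(deg_census), "2")                # pure cycle
})

test_that("component count is preserved by skeletonization", {
  set.seed(99)
  for (rep in 1:5) {
    m <- matrix(FALSE, 60, 60)
    for (b in 1:6) {
      cx <- sample(8:52, 1); cy <- sample(8:52, 1); r <- sample(2:5, 1)
      d <- sqrt(outer((1:60 - cy)^2, (1:60 - cx)^2, `+`))
      m <- m | d <= r
    }
    s <- skeletonize_mask(m)
    expect_identical(max(capstall:::label_components8(s)),
                     max(capstall:::label_components8(m)))
  }
})

test_that("skeleton-to-graph identifies endpoints, branches and loops", {
  line <- matrix(FALSE, 30, 30); line[15, 6:25] <- TRUE
  g <- skeleton_to_graph(line)
  expect_identical(nrow(g$nodes), 2L)
  expect_identical(length(g$edges), 1L)
  expect_identical(nrow(g$edges[[1]]$path), 20L)

  y <- matrix(FALSE, 30, 30)
  y[15, 5:15] <- TRUE                       # stem
  for (k in 1:8) { y[15 - k, 15 + k] <- TRUE; y[15 + k, 15 + k] <- TRUE }
  gy <- skeleton_to_graph(y)
  expect_identical(nrow(gy$nodes), 4L)      # 3 endpoints + 1 branch
  expect_identical(length(gy$edges), 3L)

  # closed octagonal loop of 24 px, every pixel of degree exactly 2
  loop <- matrix(FALSE, 30, 30)
  moves <- rbind(c(0, 1), c(0, 1), c(0, 1), c(1, 1), c(1, 1), c(1, 1),
                 c(1, 0), c(1, 0), c(1, 0), c(1, -1), c(1, -1), c(1, -1),
                 c(0, -1), c(0, -1), c(0, -1), c(-1, -1), c(-1, -1), c(-1, -1),
                 c(-1, 0), c(-1, 0), c(-1, 0), c(-1, 1), c(-1, 1), c(-1, 1))
  p <- c(8, 12)
  for (k in seq_len(24)) {
    loop[p[1], p[2]] <- TRUE
    p <- p + moves[k, ]
  }
  expect_identical(sum(loop), 24L)
  gl <- skeleton_to_graph(loop)
  expect_identical(length(gl$edges), 1L)
  el <- gl$edges[[1]]
  expect_identical(el$node_a, el$node_b)
  expect_identical(nrow(unique(el$path)), 24L)

  thick <- matrix(FALSE, 5, 5); thick[2:3, 2:3] <- TRUE
  expect_error(skeleton_to_graph(thick), "not 1 pixel wide")
})

test_that("every skeleton pixel is accounted for exactly once in the graph", {
  set.seed(7)
  for (rep in 1:4) {
    m <- matrix(FALSE, 70, 70)
    for (b in 1:4) {
      x0 <- sample(10:60, 1); y0 <- sample(10:60, 1)
      th <- runif(1, 0, pi); len <- sample(15:35, 1)
      xs <- round(x0 + cos(th) * (0:len)); ys <- round(y0 + sin(th) * (0:len))
      ok <- xs >= 3 & xs <= 68 & ys >= 3 & ys <= 68
      m[cbind(ys[ok], xs[ok])] <- TRUE
      m[cbind(pmin(ys[ok] + 1, 68), xs[ok])] <- TRUE
    }
    s <- skeletonize_mask(m)
    g <- skeleton_to_graph(s)
    # conservation: node pixels belong to nodes, path interiors to edges,
    # each exactly once
    interior_count <- sum(vapply(g$edges, function(e) {
      max(nrow(e$path) - 2L, 0L)
    }, integer(1)))
    expect_identical(nrow(g$nodes) + interior_count, sum(s))
    # coverage: union of edge paths and node pixels is the skeleton
    covered <- unique(rbind(do.call(rbind, lapply(g$edges, `[[`, "path")),
                            as.matrix(g$nodes[, c("x", "y")])))
    expect_identical(nrow(covered), sum(s))
  }
})

test_that("click selection picks the nearest edge with deterministic ties", {
  m <- matrix(FALSE, 30, 30)
  m[10, 5:25] <- TRUE   # edge 1 (row 10)
  m[20, 5:25] <- TRUE   # edge 2 (row 20)
  g <- skeleton_to_graph(m)
  expect_identical(length(g$edges), 2L)
  on_edge <- select_centerline(g, c(12, 10))
  expect_true(all(on_edge$points[, 2] == 10))
  equidist <- select_centerline(g, c(15, 15))   # 5 px from both
  expect_identical(equidist$points,
                   centerline(g$edges[[1]]$path)$points)
  expect_error(select_centerline(g, c(15, 200), max_click_distance = 20),
               "no vessel within")
})

test_that("short centerlines are excluded (5 px or less)", {
  make_cl <- function(n) centerline(cbind(seq_len(n), rep(1, n)), paste0("L", n))
  got <- filter_short_centerlines(lapply(c(3, 5, 6, 40), make_cl))
  expect_identical(vapply(got, `[[`, integer(1), "length_px"), c(6L, 40L))
  expect_identical(filter_short_centerlines(list()), list())
  long <- lapply(c(100, 100), make_cl)
  expect_identical(length(filter_short_centerlines(long)), 2L)
})
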