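test_that("snap_to_curve finds the nearest black pixel, with frame preference", {
  m <- matrix(0L, 20, 20)
  m[, 10] <- 1L
  expect_identical(snap_to_curve(c(5, 10), m), c(5L, 10L))
  expect_identical(snap_to_curve(c(7, 7), m), c(7L, 10L))
  # near the border with a connected on-frame pixel: snap onto the frame
  m2 <- frame_mask(20, 20)
  m2[10, 2:12] <- 1L  # curve reaching the left frame
  s <- snap_to_curve(c(10, 2), m2, border_margin = 2)
  expect_identical(s, c(10L, 1L))
  # farther along the curve there is no adjacent frame pixel to prefer
  expect_identical(snap_to_curve(c(10, 4), m2, border_margin = 2),
                   c(10L, 4L))
  expect_error(snap_to_curve(c(1, 1), matrix(0L, 5, 5)), "no boundary")
})

test_that("tracing along a straight line returns the sub-segment", {
  m <- matrix(0L, 20, 40)
  m[10, 5:35] <- 1L
  cv <- trace_curve(rbind(c(10, 8), c(10, 30)), m)
  expect_identical(cv$pieces[[1]]$steps, 22L)
  expect_identical(cv$pieces[[1]]$mode, "component")
  expect_identical(sum(cv$mask), 23L)
  expect_true(all(cv$mask <= m))  # path is a subset of the curve
})

test_that("tracing an L-shaped line walks both legs", {
  m <- matrix(0L, 30, 30)
  m[5:25, 5] <- 1L
  m[25, 5:25] <- 1L
  cv <- trace_curve(rbind(c(5, 5), c(25, 25)), m)
  expect_identical(cv$pieces[[1]]$steps, 40L)
  lab <- label_lines(m)
  oracle <- bfs_steps_oracle((lab == 1L) + 0L, c(5L, 5L), c(25L, 25L))
  expect_identical(cv$pieces[[1]]$steps, as.integer(oracle))
})

test_that("guide points in different components are joined by a straight segment", {
  m <- matrix(0L, 20, 40)
  m[5, 3:10] <- 1L
  m[15, 30:38] <- 1L
  cv <- trace_curve(rbind(c(5, 10), c(15, 30)), m)
  expect_identical(cv$pieces[[1]]$mode, "straight")
  expect_identical(unname(cv$endpoints[1, ]), c(5L, 10L))
  expect_identical(unname(cv$endpoints[2, ]), c(15L, 30L))
})

test_that("a diagonally-connected component without a 4-path raises a routing error", {
  m <- matrix(0L, 10, 10)
  m[3, 3] <- 1L
  m[4, 4] <- 1L  # 8-connected to (3,3), not 4-connected
  expect_error(trace_curve(rbind(c(3, 3), c(4, 4)), m), "routing error")
})

test_that("traced fewest-steps lengths equal an independent breadth-first oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(0L, 40, 40)
    # random orthogonal scribble forming one component
    r <- 20L; c <- 20L
    m[r, c] <- 1L
    for (i in 1:150) {
      d <- sample(list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)), 1)[[1]]
      r <- min(39L, max(2L, r + d[1])); c <- min(39L, max(2L, c + d[2]))
      m[r, c] <- 1L
    }
    px <- which(m == 1L, arr.ind = TRUE)
    a <- px[sample(nrow(px), 1), ]
    b <- px[sample(nrow(px), 1), ]
    cv <- trace_curve(rbind(a, b), m, snap = FALSE)
    oracle <- bfs_steps_oracle(m, a, b)
    expect_identical(cv$pieces[[1]]$steps, as.integer(oracle))
    expect_true(all(cv$mask <= m))
  }
})

test_that("overlay unions curves with the frame, order-independently", {
  m1 <- matrix(0L, 15, 15); m1[7, 3:12] <- 1L
  m2 <- matrix(0L, 15, 15); m2[3:12, 7] <- 1L
  o12 <- overlay_curves(list(m1, m2), 15, 15)
  o21 <- overlay_curves(list(m2, m1), 15, 15)
  expect_identical(o12, o21)
  of <- overlay_curves(list(), 15, 15)
  expect_identical(sum(of), 4L * 15L - 4L)  # just the frame
  d1 <- matrix(0L, 15, 15); d1[5, 5] <- 1L
  d2 <- matrix(0L, 15, 15); d2[9, 9] <- 1L
  od <- overlay_curves(list(d1, d2), 15, 15, frame = FALSE)
  expect_identical(sum(od), 2L)
  expect_error(overlay_curves(list(matrix(0L, 5, 5)), 15, 15),
               "do not match")
})

test_that("a diagram decomposed into traced curves reassembles to the same regions", {
  g <- generate_diagram(random_diagram_spec(21, n_bands = 3,
                                            isotherm = FALSE,
                                            resolution = c(101, 101)))
  lab0 <- label_regions(thin(g$mask))
  n0 <- attr(lab0, "n")
  # trace each interior boundary from guide points on the truth polylines
  lines <- label_lines(g$mask)
  curves <- list()
  for (k in seq_len(length(g$truth$polygons) - 1)) {
    p <- g$truth$polygons[[k]]
    # right edge of band k runs from vertex 2 (t_min) to vertex 3 (t_max)
    a <- data_to_pixel(p[2, ] + c(1, 0), g$truth$cal)
    b <- data_to_pixel(p[3, ] - c(1, 0), g$truth$cal)
    curves[[k]] <- trace_curve(rbind(a, b), g$mask, lines)
  }
  over <- overlay_curves(curves, g$truth$height, g$truth$width)
  labr <- label_regions(thin(over))
  expect_identical(attr(labr, "n"), n0)
})
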