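test_that("binarize thresholds normalized darkness", {
  expect_identical(binarize(matrix(1, 5, 5)), matrix(0L, 5, 5))
  expect_identical(binarize(matrix(0, 5, 5)), matrix(1L, 5, 5))
  # checkerboard at 40% darkness stays below a 0.5 threshold everywhere
  cb <- matrix(ifelse((outer(1:6, 1:6, "+") %% 2) == 0, 0.6, 1), 6, 6)
  expect_identical(binarize(cb, 0.5), matrix(0L, 6, 6))
  expect_identical(sum(binarize(cb, 0.3)), 18L)
  expect_error(binarize(array(0, c(3, 3, 3))), "2-D")
  expect_error(binarize(matrix(1, 5, 5), threshold = 0), "between 0 and 1")
})

test_that("find_plot_frame picks the largest closed contour", {
  m <- matrix(0L, 40, 60)
  m[5:35, 10:50] <- 0L
  m[5, 10:50] <- 1L; m[35, 10:50] <- 1L; m[5:35, 10] <- 1L; m[5:35, 50] <- 1L
  q <- find_plot_frame(m)
  expect_equal(unname(q[, 1]), c(5, 5, 35, 35))
  expect_equal(unname(q[, 2]), c(10, 50, 50, 10))
  # a small legend box must lose to the big frame
  m2 <- m
  m2[10:14, 15:22] <- 0L
  m2[10, 15:22] <- 1L; m2[14, 15:22] <- 1L
  m2[10:14, 15] <- 1L; m2[10:14, 22] <- 1L
  q2 <- find_plot_frame(m2)
  expect_equal(unname(q2), unname(q))
})

test_that("an open frame is rejected as not enclosed", {
  m <- matrix(0L, 30, 30)
  m[5, 5:25] <- 1L; m[5:25, 5] <- 1L; m[25, 5:25] <- 1L  # three sides
  expect_error(find_plot_frame(m), "not enclosed")
  expect_error(find_plot_frame(matrix(0L, 10, 10)), "not enclosed")
})

test_that("rectify is the identity on an axis-aligned full-frame quad", {
  m <- vsplit_mask(21, 31, 16)
  quad <- rbind(c(1, 1), c(1, 31), c(21, 31), c(21, 1))
  expect_identical(rectify(m, quad, 21, 31), m)
})

test_that("rectify maps sheared frame corners onto the output corners", {
  g <- generate_diagram(diagram_spec(
    list(list(state = "L1",
              polygon = rbind(c(0, 0), c(0, 100), c(100, 100), c(100, 0)))),
    resolution = c(80, 120), shear_deg = 5, seed = 3))
  q <- find_plot_frame(g$mask)
  expect_lte(max(abs(q - g$truth$quad)), 1)
  rect <- rectify(g$mask, q, 80, 120)
  # rectified frame edges are solid again (within a pixel of the border)
  expect_true(all(rowSums(rect[, 1:2]) >= 1))
  expect_true(all(rowSums(rect[, 119:120]) >= 1))
})

test_that("rectify rejects collinear corners", {
  expect_error(rectify(matrix(0L, 10, 10),
                       rbind(c(1, 1), c(1, 5), c(1, 10), c(10, 1))),
               "degenerate")
})

test_that("keep_largest retains the n largest components", {
  m <- matrix(0L, 30, 40)
  m[5:14, 5:14] <- 1L            # 100 px
  m[20:23, 20:29] <- 1L          # 40 px
  m[27, 35:37] <- 1L             # 3 px
  out <- keep_largest(m, 2)
  expect_identical(sum(out), 140L)
  expect_identical(sum(out[27, ]), 0L)
  expect_warning(out3 <- keep_largest(m, 5), "only 3")
  expect_identical(out3, m)
  expect_warning(empty <- keep_largest(matrix(0L, 5, 5), 1), "only 0")
  expect_identical(empty, matrix(0L, 5, 5))
})

test_that("keep_largest output pixels are a subset of the input", {
  for (seed in 1:10) {
    m <- random_structure_mask(25, 30, seed)
    out <- keep_largest(m, 1)
    expect_true(all(out <= m))
  }
})

test_that("thinning reduces a thick line to one pixel without changing regions", {
  m <- matrix(0L, 15, 25)
  m[7:9, ] <- 1L
  before <- attr(label_regions(m), "n")
  tm <- thin(m)
  expect_identical(attr(label_regions(tm), "n"), before)
  expect_identical(before, 2L)
  expect_true(all(colSums(tm) == 1L))
})

test_that("thinning leaves an already-thin ring unchanged", {
  m <- matrix(0L, 20, 20)
  m[5, 5:15] <- 1L; m[15, 5:15] <- 1L; m[5:15, 5] <- 1L; m[5:15, 15] <- 1L
  expect_identical(thin(m), m)
})

test_that("a solid disk erodes away but never splits a region", {
  m <- matrix(0L, 25, 25)
  px <- which(outer((1:25 - 13)^2, (1:25 - 13)^2, "+") <= 49,
              arr.ind = TRUE)
  m[px] <- 1L
  expect_identical(attr(label_regions(m), "n"), 1L)
  tm <- thin(m)
  expect_identical(attr(label_regions(tm), "n"), 1L)
})

test_that("thin preserves region counts and is idempotent on random masks", {
  for (seed in 1:25) {
    m <- random_structure_mask(22, 28, seed)
    tm <- thin(m)
    expect_identical(attr(label_regions(tm), "n"),
                     attr(label_regions(m), "n"))
    expect_identical(thin(tm), tm)
  }
})

test_that("label_regions numbers 4-connected regions with no gaps", {
  blank <- matrix(0L, 10, 10)
  lb <- label_regions(blank)
  expect_identical(attr(lb, "n"), 1L)
  expect_true(all(lb == 1L))
  ls <- label_regions(vsplit_mask(15, 20, 10))
  expect_identical(attr(ls, "n"), 2L)
  expect_identical(sort(unique(as.vector(ls))), 0:2)
  expect_error(label_regions(matrix(1L, 5, 5)), "no regions")
})

test_that("segmentation of a synthetic five-region diagram matches the generator", {
  spec <- random_diagram_spec(11, n_bands = 4, isotherm = TRUE,
                              resolution = c(151, 151))
  g <- generate_diagram(spec)
  lab <- label_regions(thin(g$mask))
  expect_identical(attr(lab, "n"), 5L)
  ids <- match_regions(lab, g$truth)
  expect_identical(sort(ids), 1:5)
  # region pixel areas track the polygon areas (boundary-pixel tolerance)
  px_area <- diff(range(g$truth$cal$temperature$data)) *
    diff(range(g$truth$cal$composition$data)) / (150 * 150)
  for (k in seq_along(ids)) {
    apix <- sum(lab == ids[k]) * px_area
    atruth <- phasedig:::polygon_area(g$truth$polygons[[k]])
    expect_lt(abs(apix - atruth) / atruth, 0.15)
  }
})

test_that("edit primitives draw segments, isotherms and extensions", {
  cal <- axis_calibration(c(1, 41), c(100, 0), c(1, 41), c(0, 100))
  m <- matrix(0L, 41, 41)
  # isotherm at T = 25 across the full width -> one full row of ones
  out <- apply_edits(m, list(list(kind = "isotherm", temperature = 25)),
                     cal)
  r <- data_to_pixel(c(25, 0), cal)[1]
  expect_identical(sum(out), 41L)
  expect_true(all(out[r, ] == 1L))
  # segment in data coordinates
  out2 <- apply_edits(m, list(list(kind = "segment", coords = "data",
                                   from = c(0, 20), to = c(100, 20))), cal)
  expect_identical(sum(out2[, data_to_pixel(c(50, 20), cal)[2]]), 41L)
  # erase wins over draw when applied later
  out3 <- apply_edits(out, list(list(kind = "segment", from = c(r, 1),
                                     to = c(r, 41), value = 0)))
  expect_identical(sum(out3), 0L)
  expect_error(apply_edits(m, list(list(kind = "isotherm",
                                        temperature = 25))),
               "calibration")
})

test_that("extend continues a line along its slope until frame or line", {
  m <- frame_mask(41, 41)
  m[20, 5:20] <- 1L  # horizontal half-line
  out <- apply_edits(m, list(list(kind = "extend", at = c(20, 20))))
  expect_true(all(out[20, 5:40] == 1L))
  # 45-degree stub: continues diagonally to the analytic frame intercept
  m2 <- frame_mask(41, 41)
  for (i in 0:9) m2[10 + i, 10 + i] <- 1L
  out2 <- apply_edits(m2, list(list(kind = "extend", at = c(19, 19))))
  hits <- which(out2 == 1L & frame_mask(41, 41) == 0L, arr.ind = TRUE)
  far <- hits[which.max(hits[, 1]), ]
  expect_lte(max(abs(far - c(40, 40))), 1)
  expect_error(apply_edits(m, list(list(kind = "extend", at = c(3, 3)))),
               "not on a boundary line")
})
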