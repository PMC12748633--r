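test_that("data_to_pixel rounds half toward the larger pixel index", {
  cal <- axis_calibration(c(1, 101), c(100, 0), c(1, 101), c(0, 100))
  expect_identical(data_to_pixel(c(50, 50), cal), c(row = 51L, col = 51L))
  # half-way composition rounds up in pixel index
  expect_identical(data_to_pixel(c(50, 49.5), cal)[["col"]], 51L)
  expect_identical(data_to_pixel(c(50, 48.5), cal)[["col"]], 50L)
  expect_error(data_to_pixel(c(101, 50), cal), "temperature outside")
  expect_error(data_to_pixel(c(50, 101), cal), "composition outside")
})

test_that("logarithmic axes interpolate in log space", {
  cal <- axis_calibration(c(1, 11), c(10, 0), c(1, 201), c(1, 100),
                          w_log = TRUE)
  expect_identical(data_to_pixel(c(5, 10), cal)[["col"]], 101L)
  expect_identical(data_to_pixel(c(5, 100), cal)[["col"]], 201L)
  back <- pixel_to_data(c(6, 101), cal)
  expect_equal(back[["composition"]], 10)
})

test_that("pixel mapping is invertible up to rounding", {
  cal <- axis_calibration(c(3, 120), c(80, -20), c(2, 250), c(0, 100))
  set.seed(4)
  pts <- cbind(runif(50, -20, 80), runif(50, 0, 100))
  px <- data_to_pixel(pts, cal)
  back <- pixel_to_data(px, cal)
  again <- data_to_pixel(back, cal)
  expect_identical(again, px)
})

test_that("phase distances are zero inside and one pixel across a boundary", {
  m <- vsplit_mask(21, 21, 11)
  lab <- label_regions(m)
  cal <- axis_calibration(c(1, 21), c(20, 0), c(1, 21), c(0, 20))
  d_in <- phase_distances(c(10, 5), lab, cal)
  expect_identical(d_in[[1]], 0)
  d_b <- phase_distances(c(10, 11), lab, cal)  # on the boundary, 1 px = 1 wt%
  expect_identical(d_b, c(1, 1))
  expect_error(phase_distances(c(0, 5), lab, cal), "outside")
})

test_that("fast distance maps equal the brute-force oracle bit for bit", {
  for (seed in 1:6) {
    m <- random_structure_mask(20, 24, seed)
    lab <- label_regions(thin(m))
    set.seed(seed + 100)
    st <- runif(1, 0.3, 2.5); sw <- runif(1, 0.3, 2.5)
    cal <- axis_calibration(c(1, 20), c(st * 19, 0), c(1, 24),
                            c(0, min(100, sw * 23)))
    sc <- phasedig:::axis_scales(cal)
    fast <- phase_distance_maps(lab, cal)
    brute <- brute_distance_maps(lab, sc[["t"]], sc[["w"]])
    for (i in seq_along(fast)) expect_identical(fast[[i]], brute[[i]])
  }
})

test_that("the kernel thresholds, normalizes and respects symmetry", {
  expect_identical(assign_probabilities(c(0, 20)), c(1, 0))
  expect_identical(assign_probabilities(c(1, 1)), c(0.5, 0.5))
  expect_equal(assign_probabilities(c(3, 3, 3)), rep(1 / 3, 3))
  # just beyond the cutoff distance the contribution is exactly zero
  dcut <- -2 * log(1e-3)
  p <- assign_probabilities(c(0, dcut + 1e-9))
  expect_identical(p, c(1, 0))
  # just inside the cutoff it is not
  p2 <- assign_probabilities(c(0, dcut - 1e-6))
  expect_gt(p2[2], 0)
  expect_error(assign_probabilities(c(30, 40)), "no assignable phase")
  expect_error(assign_probabilities(c(-1, 2)), "non-negative")
})

test_that("increasing one distance never increases its probability", {
  set.seed(9)
  for (i in 1:50) {
    d <- runif(4, 0, 12)
    p1 <- assign_probabilities(d)
    d2 <- d; d2[1] <- d2[1] + runif(1, 0, 5)
    p2 <- assign_probabilities(d2)
    expect_lte(p2[1], p1[1] + 1e-15)
  }
})

test_that("sampling a full 0-100 x 0-100 diagram at unit spacing gives 10201 rows", {
  m <- vsplit_mask(101, 101, 51)
  lab <- label_regions(m)
  cal <- axis_calibration(c(1, 101), c(100, 0), c(1, 101), c(0, 100))
  tab <- sample_grid(lab, cal, states = c("L1", "La"))
  expect_identical(nrow(tab), 10201L)
  expect_identical(names(tab), c("temperature", "composition", "L1", "La"))
  sums <- rowSums(tab[, c("L1", "La")])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a single-phase blank diagram gets probability one everywhere", {
  m <- frame_mask(51, 51)
  lab <- label_regions(thin(m))
  cal <- axis_calibration(c(1, 51), c(50, 0), c(1, 51), c(0, 50))
  tab <- sample_grid(lab, cal, states = "L1")
  expect_true(all(tab$L1 == 1))
  expect_identical(nrow(tab), 51L * 51L)
})

test_that("categorical assignment is the argmax with lowest-label tie-breaking", {
  m <- vsplit_mask(21, 21, 11)
  lab <- label_regions(m)
  cal <- axis_calibration(c(1, 21), c(20, 0), c(1, 21), c(0, 20))
  grid <- grid_spec(c(0, 20), c(0, 20))
  cat_tab <- categorical_grid(lab, cal, grid, states = c("left", "right"))
  soft <- sample_grid(lab, cal, grid, states = c("left", "right"))
  # interior points match their own phase
  expect_identical(cat_tab$state[cat_tab$composition == 3],
                   rep("left", 21))
  expect_identical(cat_tab$state[cat_tab$composition == 17],
                   rep("right", 21))
  # boundary column: exact tie resolved toward the lower label
  expect_identical(cat_tab$state[cat_tab$composition == 10],
                   rep("left", 21))
  # off ties, categorical equals the soft argmax
  pm <- as.matrix(soft[, c("left", "right")])
  untied <- abs(pm[, 1] - pm[, 2]) > 1e-12
  expect_identical(cat_tab$state[untied],
                   c("left", "right")[max.col(pm[untied, ])])
})
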