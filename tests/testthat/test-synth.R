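test_that("generation is deterministic for a fixed spec and seed", {
  s1 <- random_diagram_spec(42, n_bands = 3, n_blobs = 3, n_dashes = 2)
  s2 <- random_diagram_spec(42, n_bands = 3, n_blobs = 3, n_dashes = 2)
  g1 <- generate_diagram(s1)
  g2 <- generate_diagram(s2)
  expect_identical(g1$mask, g2$mask)
  expect_identical(g1$truth$states, g2$truth$states)
})

test_that("two half-plane regions rasterize to a two-region diagram", {
  spec <- diagram_spec(
    list(list(state = "L1",
              polygon = rbind(c(0, 0), c(0, 50), c(100, 50), c(100, 0))),
         list(state = "La",
              polygon = rbind(c(0, 50), c(0, 100), c(100, 100), c(100, 50)))),
    resolution = c(101, 101), seed = 1)
  g <- generate_diagram(spec)
  lab <- label_regions(thin(g$mask))
  expect_identical(attr(lab, "n"), 2L)
})

test_that("non-tiling or invalid region sets are rejected", {
  overlapping <- list(
    list(state = "L1",
         polygon = rbind(c(0, 0), c(0, 60), c(100, 60), c(100, 0))),
    list(state = "La",
         polygon = rbind(c(0, 40), c(0, 100), c(100, 100), c(100, 40))))
  expect_error(diagram_spec(overlapping), "overlap")
  expect_error(diagram_spec(list(list(state = "NotAState",
    polygon = rbind(c(0, 0), c(0, 100), c(100, 100), c(100, 0))))),
    "vocabulary-valid")
})

test_that("nuisance annotations are removed by keep_largest", {
  spec <- random_diagram_spec(5, n_bands = 2, isotherm = FALSE,
                              n_blobs = 5, n_dashes = 3, ticks = TRUE,
                              resolution = c(121, 121))
  g <- generate_diagram(spec)
  raw_n <- attr(label_regions(thin(g$mask)), "n")
  cleaned <- keep_largest(g$mask, 1)
  lab <- label_regions(thin(cleaned))
  expect_identical(attr(lab, "n"), 2L)
  expect_gte(raw_n, 2L)  # blobs may or may not enclose area
  expect_identical(sort(match_regions(lab, g$truth)), 1:2)
})

test_that("a sheared frame rectifies back to the true segmentation", {
  spec <- random_diagram_spec(13, n_bands = 3, isotherm = FALSE,
                              shear_deg = 5, resolution = c(121, 121))
  g <- generate_diagram(spec)
  q <- find_plot_frame(g$mask)
  rect <- rectify(g$mask, q, g$truth$height, g$truth$width)
  # re-close the crop boundary: the warped frame line sits within a
  # pixel of the border and may leave slivers
  rect <- overlay_curves(list(rect), nrow(rect), ncol(rect))
  lab <- label_regions(thin(keep_largest(rect, 1)))
  expect_identical(attr(lab, "n"), 3L)
})

test_that("pipeline probabilities track the vector oracle within corner-erosion limits", {
  # Along boundary edges the raster distance overshoots the vector
  # distance by at most ~1.5 px (half-pixel line placement plus the
  # one-pixel inset of region labels); where two one-pixel lines meet at
  # a right angle the region's corner pixel is crowded out and the
  # overshoot grows to ~1.5 * sqrt(2) px when viewed diagonally.  2.5 px
  # bounds both regimes with margin.
  kernel <- function(d, thr = 1e-3) {
    raw <- exp(-d / 2); raw[raw < thr] <- 0; raw
  }
  for (seed in c(4, 10, 17)) {
    g <- generate_diagram(random_diagram_spec(seed, resolution = c(201, 201)))
    lab <- label_regions(thin(g$mask))
    nr <- length(g$truth$polygons)
    ids <- match_regions(lab, g$truth)
    tab <- sample_grid(lab, g$truth$cal,
                       grid = grid_spec(c(0, 100), c(0, 100), 2, 2))
    pm <- as.matrix(tab[, paste0("phase_", ids), drop = FALSE])
    pts <- as.matrix(tab[, c("temperature", "composition")])
    dor <- vapply(seq_len(nr), function(k) {
      poly <- g$truth$polygons[[k]]
      vapply(seq_len(nrow(pts)), function(i)
        phasedig:::point_polygon_distance(pts[i, ], poly), 0)
    }, numeric(nrow(pts)))
    delta <- 2.5 * 0.5  # 2.5 px at 0.5 data units per pixel
    lo <- kernel(dor + delta); hi <- kernel(pmax(dor - delta, 0))
    for (k in seq_len(nr)) {
      p_hi <- hi[, k] / (hi[, k] + rowSums(lo[, -k, drop = FALSE]))
      p_lo <- lo[, k] / (lo[, k] + rowSums(hi[, -k, drop = FALSE]))
      p_lo[is.nan(p_lo)] <- 0
      expect_true(all(pm[, k] <= p_hi + 1e-12 & pm[, k] >= p_lo - 1e-12),
                  info = paste("seed", seed, "region", k))
    }
  }
})

test_that("the vector oracle reproduces hand-computed kernel values", {
  spec <- diagram_spec(
    list(list(state = "L1",
              polygon = rbind(c(0, 0), c(0, 50), c(100, 50), c(100, 0))),
         list(state = "La",
              polygon = rbind(c(0, 50), c(0, 100), c(100, 100), c(100, 50)))),
    resolution = c(101, 101), seed = 1)
  g <- generate_diagram(spec)
  # deep inside a region, more than the cutoff away from the other
  expect_identical(unname(oracle_probabilities(g$truth, c(50, 20))),
                   c(1, 0))
  # on the shared midline both phases touch the point
  expect_identical(unname(oracle_probabilities(g$truth, c(50, 50))),
                   c(0.5, 0.5))
  # two units into the left region: raw = (1, exp(-1))
  p <- oracle_probabilities(g$truth, c(50, 48))
  expect_equal(unname(p), c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(unname(p), 3), c(0.731, 0.269))
  expect_error(oracle_probabilities(g$truth, c(120, 50)), "outside")
})
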