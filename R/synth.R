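#' Specify a synthetic phase diagram
#'
#' A synthetic diagram is a set of labeled polygonal regions tiling the
#' `(temperature, composition)` rectangle, rasterized at a chosen
#' resolution with the region boundaries drawn as one-pixel black lines
#' inside a rectangular frame. Optional nuisance annotations (detached
#' dashed segments, text-like blobs, frame tick marks) and a frame shear
#' emulate the artifacts of scanned literature diagrams; horizontal
#' region edges play the role of inserted eutectic/peritectic isotherms.
#'
#' @param regions List of regions, each `list(state = <vocabulary state
#'   string>, polygon = <k x 2 matrix of (temperature, composition)
#'   vertices>)`. The polygons must tile the axis rectangle (shared
#'   edges only); this is checked through their total area.
#' @param t_range,w_range Axis ranges (degrees C, wt%).
#' @param resolution `c(height, width)` in pixels.
#' @param n_blobs Number of text-like nuisance blobs.
#' @param n_dashes Number of detached dashed nuisance segments.
#' @param ticks Draw tick marks on the frame.
#' @param shear_deg Shear angle of the plot frame in degrees (0 = none).
#' @param seed Integer seed making the rasterization reproducible.
#' @param vocab Vocabulary used to check the region states.
#' @return An object of class `phd_diagram_spec`.
#' @export
diagram_spec <- function(regions, t_range = c(0, 100),
                         w_range = c(0, 100), resolution = c(201, 201),
                         n_blobs = 0L, n_dashes = 0L, ticks = FALSE,
                         shear_deg = 0, seed = 1L,
                         vocab = phase_vocabulary()) {
  if (!length(regions)) stop("need at least one region")
  t_range <- sort(as.numeric(t_range)); w_range <- sort(as.numeric(w_range))
  area <- 0
  for (rg in regions) {
    if (is.null(rg$state) || is.null(rg$polygon))
      stop("each region needs a 'state' and a 'polygon'")
    if (!is_valid_state(rg$state, vocab))
      stop("region state is not vocabulary-valid: ", rg$state)
    p <- as.matrix(rg$polygon)
    if (nrow(p) < 3L) stop("polygons need at least 3 vertices")
    if (any(p[, 1] < t_range[1] - 1e-9) || any(p[, 1] > t_range[2] + 1e-9) ||
        any(p[, 2] < w_range[1] - 1e-9) || any(p[, 2] > w_range[2] + 1e-9))
      stop("polygon vertices outside the axis rectangle")
    area <- area + polygon_area(p)
  }
  rect_area <- diff(t_range) * diff(w_range)
  if (abs(area - rect_area) > 1e-6 * rect_area)
    stop("spec error: polygons overlap or do not tile the axis rectangle ",
         "(total area ", signif(area, 6), " vs ", signif(rect_area, 6), ")")
  structure(list(regions = regions, t_range = t_range, w_range = w_range,
                 resolution = as.integer(resolution),
                 n_blobs = as.integer(n_blobs),
                 n_dashes = as.integer(n_dashes), ticks = isTRUE(ticks),
                 shear_deg = shear_deg, seed = as.integer(seed)),
            class = "phd_diagram_spec")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i <- seq_len(nrow(p)); j <- c(2:nrow(p), 1L)
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

#' Random banded diagram specification
#'
#' Draws a diagram resembling a typical surfactant-water phase map: a
#' left-to-right sequence of 2-5 phase bands separated by slanted
#' straight boundaries, optionally with one band split by a horizontal
#' isotherm, each region tagged with a plausible vocabulary state.
#'
#' @param seed Integer seed.
#' @param n_bands Number of vertical bands (2-6).
#' @param isotherm Also split one band horizontally?
#' @param ... Passed on to [diagram_spec()] (resolution, nuisance, ...).
#' @return A `phd_diagram_spec`.
#' @export
random_diagram_spec <- function(seed, n_bands = sample(2:4, 1),
                                isotherm = TRUE, ...) {
  with_seed(seed, {
    n_bands <- max(2L, min(6L, as.integer(n_bands)))
    t_range <- c(0, 100); w_range <- c(0, 100)
    # boundary j runs from (t_min, bot[j]) to (t_max, top[j])
    base <- seq(0, 100, length.out = n_bands + 1)[2:n_bands]
    amp <- 100 / (3 * n_bands)  # keeps every band at least amp wide
    top <- sort(base + stats::runif(n_bands - 1, -amp, amp))
    bot <- sort(base + stats::runif(n_bands - 1, -amp, amp))
    topv <- c(w_range[1], top, w_range[2])
    botv <- c(w_range[1], bot, w_range[2])
    pool <- c("L1", "H1", "V1", "La", "L2", "Lb", "X1", "L1+W", "La+W",
              "L1+X1", "H1+La", "L1+La", "W+X1", "E+L1", "L1+L3")
    states <- sample(pool, n_bands + isotherm)
    regions <- vector("list", n_bands)
    for (j in seq_len(n_bands)) {
      # quadrilateral band: bottom edge at t_min, top edge at t_max
      regions[[j]] <- list(
        state = states[j],
        polygon = rbind(c(t_range[1], botv[j]), c(t_range[1], botv[j + 1]),
                        c(t_range[2], topv[j + 1]), c(t_range[2], topv[j]))
      )
    }
    if (isotherm) {
      j <- sample(n_bands, 1)
      tc <- stats::runif(1, 30, 70)
      p <- regions[[j]]$polygon
      f <- (tc - t_range[1]) / diff(t_range)
      wl <- p[1, 2] + f * (p[4, 2] - p[1, 2])
      wr <- p[2, 2] + f * (p[3, 2] - p[2, 2])
      lower <- rbind(p[1, ], p[2, ], c(tc, wr), c(tc, wl))
      upper <- rbind(c(tc, wl), c(tc, wr), p[3, ], p[4, ])
      regions[[j]]$polygon <- lower
      regions[[length(regions) + 1L]] <-
        list(state = states[n_bands + 1L], polygon = upper)
    }
    diagram_spec(regions, t_range = t_range, w_range = w_range,
                 seed = seed, ...)
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Rasterize a synthetic diagram
#'
#' Deterministic for a fixed spec (which includes the seed). Region
#' boundaries and the frame are drawn as 1-valued lines; nuisance
#' annotations are placed only where they stay detached from the
#' structural drawing (so [keep_largest()] can remove them); when
#' `shear_deg` is non-zero the whole frame is sheared and the true
#' corner quadrilateral recorded for [rectify()].
#'
#' @param spec A [diagram_spec()].
#' @return List with elements `mask` (binary 0/1 matrix), `image`
#'   (intensity matrix, 1 = white) and `truth`, the ground truth: the
#'   spec, calibration, region polygons (data coordinates), region
#'   states, per-region interior seed points, and the sheared frame
#'   quadrilateral (`NULL` when unsheared).
#' @export
generate_diagram <- function(spec) {
  stopifnot(inherits(spec, "phd_diagram_spec"))
  with_seed(spec$seed, {
    H <- spec$resolution[1]; W <- spec$resolution[2]
    cal <- axis_calibration(c(1, H), c(spec$t_range[2], spec$t_range[1]),
                            c(1, W), spec$w_range)
    mask <- matrix(0L, H, W)
    mask[c(1L, H), ] <- 1L
    mask[, c(1L, W)] <- 1L
    for (rg in spec$regions) {
      p <- as.matrix(rg$polygon)
      for (i in seq_len(nrow(p))) {
        a <- data_to_pixel(p[i, ], cal)
        b <- data_to_pixel(p[if (i == nrow(p)) 1L else i + 1L, ], cal)
        # canonical endpoint order: integer line rasterization is
        # asymmetric, and a shared edge drawn from both of its polygons
        # must produce the identical pixel set (else boundaries thicken)
        if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) { t <- a; a <- b; b <- t }
        mask[bresenham4(a, b)] <- 1L
      }
    }
    structural <- mask
    blocked <- dilate8(structural)  # nuisance must not touch structure
    mask <- add_nuisance(mask, blocked, spec)
    quad <- NULL
    if (spec$shear_deg != 0) {
      sh <- shear_image(mask, spec$shear_deg)
      mask <- sh$mask
      quad <- sh$quad
    }
    truth <- list(spec = spec, cal = cal,
                  polygons = lapply(spec$regions,
                                    function(r) as.matrix(r$polygon)),
                  states = vapply(spec$regions, function(r) r$state, ""),
                  seeds = t(vapply(spec$regions, function(r)
                    colMeans(as.matrix(r$polygon)), c(0, 0))),
                  quad = quad, height = H, width = W)
    list(mask = mask, image = 1 - mask, truth = truth)
  })
}

dilate8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(H, H + dr)
    rt <- max(1, 1 - dr):min(H, H - dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    ct <- max(1, 1 - dc):min(W, W - dc)
    out[rt, ct] <- pmax(out[rt, ct], mask[rs, cs])
  }
  out
}

add_nuisance <- function(mask, blocked, spec) {
  H <- nrow(mask); W <- ncol(mask)
  place_ok <- function(rows, cols) {
    all(rows >= 2) && all(rows <= H - 1) && all(cols >= 2) &&
      all(cols <= W - 1) && !any(blocked[rows, cols] == 1L)
  }
  for (i in seq_len(spec$n_blobs)) {
    for (try in 1:50) {
      h <- sample(2:4, 1); w <- sample(2:5, 1)
      r <- sample(seq_len(H - h), 1); c <- sample(seq_len(W - w), 1)
      if (place_ok(r:(r + h - 1), c:(c + w - 1))) {
        mask[r:(r + h - 1), c:(c + w - 1)] <- 1L
        break
      }
    }
  }
  for (i in seq_len(spec$n_dashes)) {
    for (try in 1:50) {
      len <- sample(8:16, 1)
      r <- sample(seq_len(H), 1); c <- sample(seq_len(W - len), 1)
      horiz <- stats::runif(1) < 0.5
      rows <- if (horiz) rep(r, len) else pmin(H, r + 0:(len - 1))
      cols <- if (horiz) c + 0:(len - 1) else rep(c, len)
      if (place_ok(rows, cols)) {
        on <- (seq_len(len) - 1L) %% 4L < 2L  # 2 px on, 2 px off
        mask[cbind(rows[on], cols[on])] <- 1L
        break
      }
    }
  }
  if (spec$ticks) {
    for (c in seq(10, W - 10, by = 25)) mask[2:3, c] <- 1L
    for (r in seq(10, H - 10, by = 25)) mask[r, 2:3] <- 1L
  }
  mask
}

shear_image <- function(mask, shear_deg) {
  H <- nrow(mask); W <- ncol(mask)
  t <- tan(shear_deg * pi / 180)
  extra <- ceiling(abs(t) * (H - 1))
  W2 <- W + extra
  out <- matrix(0L, H, W2)
  off <- function(r) if (t >= 0) t * (r - 1) else abs(t) * (H - r)
  for (r in seq_len(H)) {
    src <- seq_len(W2) - off(r)
    src <- floor(src + 0.5)
    ok <- src >= 1 & src <= W
    out[r, ok] <- mask[r, src[ok]]
  }
  quad <- rbind(tl = c(1, 1 + floor(off(1) + 0.5)),
                tr = c(1, W + floor(off(1) + 0.5)),
                br = c(H, W + floor(off(H) + 0.5)),
                bl = c(H, 1 + floor(off(H) + 0.5)))
  colnames(quad) <- c("row", "col")
  list(mask = out, quad = quad)
}

#' Exact point-to-polygon phase distances and oracle probabilities
#'
#' The oracle works in vector geometry, independently of the raster
#' pipeline: the distance from a test point to each region is zero when
#' the point lies inside (or on the boundary of) the region's polygon
#' and otherwise the exact Euclidean distance to the nearest polygon
#' edge, computed in data units with the 1 degree C = 1 wt% convention.
#' Probabilities then follow the same kernel, threshold and
#' normalization as [assign_probabilities()].
#'
#' @param truth Ground truth from [generate_diagram()].
#' @param point Numeric `c(temperature, composition)`.
#' @param threshold Kernel cutoff.
#' @return For `oracle_distances`, the numeric distance vector; for
#'   `oracle_probabilities`, the normalized probability vector (named by
#'   region state).
#' @export
oracle_distances <- function(truth, point) {
  if (point[1] < truth$spec$t_range[1] - 1e-9 ||
      point[1] > truth$spec$t_range[2] + 1e-9 ||
      point[2] < truth$spec$w_range[1] - 1e-9 ||
      point[2] > truth$spec$w_range[2] + 1e-9)
    stop("point outside the axis rectangle")
  vapply(truth$polygons, function(p) point_polygon_distance(point, p), 0)
}

#' @rdname oracle_distances
#' @export
oracle_probabilities <- function(truth, point, threshold = 1e-3) {
  d <- oracle_distances(truth, point)
  setNames(assign_probabilities(d, threshold), truth$states)
}

point_polygon_distance <- function(point, poly) {
  dmin <- min(point_segment_distance(point, poly,
                                     poly[c(2:nrow(poly), 1L), ]))
  if (dmin < 1e-12) return(0)
  if (point_in_polygon(point, poly)) 0 else dmin
}

point_segment_distance <- function(p, a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  abx <- b[, 1] - a[, 1]; aby <- b[, 2] - a[, 2]
  apx <- p[1] - a[, 1]; apy <- p[2] - a[, 2]
  len2 <- abx^2 + aby^2
  t <- ifelse(len2 > 0, pmin(1, pmax(0, (apx * abx + apy * aby) / len2)), 0)
  sqrt((apx - t * abx)^2 + (apy - t * aby)^2)
}

# 4-connected (supercover) line: like the 8-connected integer line but
# with an intermediate pixel inserted at every diagonal step, emulating
# the contiguous strokes of drawn or scanned diagrams. The 4-connected
# maze search used in curve tracing can traverse such lines.
bresenham4 <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  dr <- abs(b[1] - a[1]); dc <- abs(b[2] - a[2])
  sr <- sign(b[1] - a[1]); sc <- sign(b[2] - a[2])
  err <- dc - dr
  r <- a[1]; c <- a[2]
  pts <- matrix(NA_integer_, 2L * (dr + dc) + 2L, 2)
  i <- 1L
  pts[1L, ] <- c(r, c)
  while (!(r == b[1] && c == b[2])) {
    e2 <- 2L * err
    stepc <- e2 > -dr
    stepr <- e2 < dc
    if (stepc && stepr) {  # diagonal: insert the column step first
      i <- i + 1L; c <- c + sc; pts[i, ] <- c(r, c)
      err <- err - dr + dc
      i <- i + 1L; r <- r + sr; pts[i, ] <- c(r, c)
    } else if (stepc) {
      err <- err - dr
      i <- i + 1L; c <- c + sc; pts[i, ] <- c(r, c)
    } else {
      err <- err + dc
      i <- i + 1L; r <- r + sr; pts[i, ] <- c(r, c)
    }
  }
  pts[seq_len(i), , drop = FALSE]
}

# even-odd crossing test
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > p[2]) != (yj > p[2])) {
      xcross <- xi + (p[2] - yi) / (yj - yi) * (xj - xi)
      if (p[1] < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}
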