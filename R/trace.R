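#' Snap a guide point to the drawing
#'
#' Returns the nearest boundary (1) pixel by Euclidean distance, ties
#' broken by raster order. If that pixel lies within `border_margin`
#' pixels of the image edge and has an 8-connected boundary pixel on the
#' edge itself, the on-edge pixel is returned instead, so curves that run
#' into the frame snap onto it.
#'
#' @param point Numeric `c(row, col)` guide point.
#' @param mask Binary 0/1 matrix with at least one boundary pixel.
#' @param border_margin Pixel distance to the image edge below which the
#'   on-frame check applies.
#' @return Integer `c(row, col)` of the snapped pixel.
#' @export
snap_to_curve <- function(point, mask, border_margin = 2L) {
  mask <- check_mask(mask)
  px <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("cannot snap: mask has no boundary pixels")
  d2 <- (px[, 1] - point[1])^2 + (px[, 2] - point[2])^2
  # ties broken by raster (row-major, top-left first) order
  raster <- (px[, 1] - 1) * ncol(mask) + px[, 2]
  p <- px[order(d2, raster, method = "radix")[1], ]
  H <- nrow(mask); W <- ncol(mask)
  edge_dist <- min(p[1] - 1L, H - p[1], p[2] - 1L, W - p[2])
  if (edge_dist > 0 && edge_dist <= border_margin) {
    cand <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      q <- p + c(dr, dc)
      if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > W) next
      on_edge <- q[1] == 1L || q[1] == H || q[2] == 1L || q[2] == W
      if (on_edge && mask[q[1], q[2]] == 1L) cand <- rbind(cand, q)
    }
    if (!is.null(cand)) {
      # prefer the connected frame pixel closest to the guide point
      dd <- (cand[, 1] - point[1])^2 + (cand[, 2] - point[2])^2
      rs <- (cand[, 1] - 1) * W + cand[, 2]
      return(as.integer(unname(cand[order(dd, rs)[1], ])))
    }
  }
  as.integer(unname(p))
}

#' Label line components for curve tracing
#'
#' Convenience wrapper: 8-connected components of boundary pixels.
#'
#' @inheritParams snap_to_curve
#' @return Integer label matrix with attribute `n`.
#' @export
label_lines <- function(mask) {
  label_components(mask, target = 1L, connectivity = 8L)
}

#' Trace one boundary curve through user guide points
#'
#' Guide points are snapped to the drawing ([snap_to_curve()]), then each
#' consecutive pair is connected: when both pixels lie in the same line
#' component, by a fewest-steps 4-connected path that traverses only that
#' component's pixels (white pixels are walls, so the path is a subset of
#' the original curve); when they lie in different components, by a
#' straight rasterized segment. Among equal-length paths, the one found
#' by breadth-first expansion in the order up, down, left, right is kept
#' -- any fewest-steps path is acceptable for probabilistic sampling.
#'
#' @param points n x 2 matrix (or list) of ordered `(row, col)` guide
#'   points, n >= 2; order is preserved.
#' @param mask Binary 0/1 matrix of the cleaned drawing.
#' @param labeled_lines Optional precomputed [label_lines()] matrix.
#' @param snap Snap the guide points first (default); set to `FALSE` if
#'   they are already exact line pixels.
#' @param border_margin Passed to [snap_to_curve()].
#' @return An object of class `phd_curve`: list with `mask` (the curve's
#'   pixels only), `endpoints` (first and last snapped pixels), and
#'   `pieces` (per consecutive pair: the path pixels, its step count and
#'   whether it was routed through a component or drawn straight).
#' @export
trace_curve <- function(points, mask, labeled_lines = NULL, snap = TRUE,
                        border_margin = 2L) {
  mask <- check_mask(mask)
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, as.numeric))
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least two guide points")
  if (is.null(labeled_lines)) labeled_lines <- label_lines(mask)
  snapped <- t(apply(points, 1, function(p) {
    if (snap) snap_to_curve(p, mask, border_margin) else as.integer(p)
  }))
  out <- matrix(0L, nrow(mask), ncol(mask))
  pieces <- vector("list", nrow(snapped) - 1L)
  for (i in seq_len(nrow(snapped) - 1L)) {
    a <- snapped[i, ]; b <- snapped[i + 1L, ]
    la <- labeled_lines[a[1], a[2]]
    lb <- labeled_lines[b[1], b[2]]
    if (la > 0L && la == lb) {
      passable <- matrix(0L, nrow(mask), ncol(mask))
      passable[labeled_lines == la] <- 1L
      path <- .bfs_path_cpp(passable, a[1], a[2], b[1], b[2])
      if (is.null(path))
        stop("routing error: guide points ", i, " and ", i + 1L,
             " share a line component but no 4-connected path exists")
      mode <- "component"
    } else {
      path <- bresenham(a, b)
      mode <- "straight"
    }
    out[path] <- 1L
    pieces[[i]] <- list(path = path, steps = nrow(path) - 1L, mode = mode)
  }
  structure(list(mask = out,
                 endpoints = rbind(snapped[1, ], snapped[nrow(snapped), ]),
                 pieces = pieces),
            class = "phd_curve")
}

#' @export
print.phd_curve <- function(x, ...) {
  cat("Traced curve:", sum(x$mask), "pixels,", length(x$pieces),
      "piece(s)\n")
  invisible(x)
}

#' Overlay traced curves into a reconstructed diagram
#'
#' Pixelwise union of the curve masks plus the frame rectangle, giving a
#' boundary image ready for [thin()] and [label_regions()]. The union is
#' commutative, so curve order does not matter.
#'
#' @param curves List of `phd_curve` objects (or bare masks).
#' @param height,width Frame dimensions shared by all curves.
#' @param frame Draw the enclosing frame rectangle (default `TRUE`).
#' @return Binary 0/1 matrix.
#' @export
overlay_curves <- function(curves, height, width, frame = TRUE) {
  out <- matrix(0L, height, width)
  for (cv in curves) {
    m <- if (inherits(cv, "phd_curve")) cv$mask else check_mask(cv)
    if (nrow(m) != height || ncol(m) != width)
      stop("curve dimensions (", nrow(m), "x", ncol(m),
           ") do not match the frame (", height, "x", width, ")")
    out <- pmax(out, m)
  }
  if (frame) {
    out[c(1L, height), ] <- 1L
    out[, c(1L, width)] <- 1L
  }
  storage.mode(out) <- "integer"
  out
}
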