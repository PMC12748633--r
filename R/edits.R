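#' Edit primitives for diagram rectification
#'
#' Published diagrams often need manual repair before segmentation:
#' dashed transition lines replaced by solid ones, open regions closed,
#' and horizontal isotherms inserted below the surfactant freezing point
#' or at eutectic/peritectic temperatures to delineate two-phase regions
#' with different coexisting phases. Edits express those repairs as data:
#'
#' * `segment`: a straight one-pixel line between two endpoints, drawn
#'   (`value = 1`) or erased (`value = 0`). Endpoints are `(row, col)`
#'   pixels, or `(temperature, composition)` when `coords = "data"`.
#' * `isotherm`: a horizontal line at a given temperature spanning a
#'   composition interval (the full width by default); requires a
#'   calibration.
#' * `extend`: continue a boundary line from one of its pixels along its
#'   local slope (fitted to the nearest `k = 5` line pixels) until it
#'   meets another line or the image edge.
#'
#' Edits are applied in order. They can be supplied programmatically (a
#' list of lists) or loaded from a JSON array with [read_edits()].
#'
#' @param mask Binary 0/1 matrix.
#' @param edits List of edit descriptions (see details).
#' @param cal Optional [axis_calibration()]; required by `isotherm` edits
#'   and by `segment` edits in data coordinates.
#' @return The edited mask.
#' @examples
#' m <- matrix(0L, 21, 21)
#' cal <- axis_calibration(c(1, 21), c(100, 0), c(1, 21), c(0, 100))
#' m2 <- apply_edits(m, list(list(kind = "isotherm", temperature = 50)),
#'                   cal = cal)
#' sum(m2[11, ])
#' @export
apply_edits <- function(mask, edits, cal = NULL) {
  mask <- check_mask(mask)
  if (!length(edits)) return(mask)
  if (!is.null(edits$kind)) edits <- list(edits)
  for (e in edits) {
    kind <- e$kind %||% stop("edit without a 'kind' field")
    mask <- switch(kind,
      segment = edit_segment(mask, e, cal),
      isotherm = edit_isotherm(mask, e, cal),
      extend = edit_extend(mask, e),
      stop("unknown edit kind: ", kind)
    )
  }
  mask
}

#' @rdname apply_edits
#' @param path Path to a JSON file holding an array of edit objects.
#' @export
read_edits <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

edit_value <- function(e) {
  v <- e$value %||% 1L
  if (!v %in% c(0, 1)) stop("edit value must be 0 (erase) or 1 (draw)")
  as.integer(v)
}

edit_point_px <- function(p, mask, cal, coords) {
  p <- as.numeric(unlist(p))
  if (length(p) != 2L) stop("edit endpoints must have two coordinates")
  if (identical(coords, "data")) {
    if (is.null(cal)) stop("edits in data coordinates need a calibration")
    p <- data_to_pixel(p, cal)
  }
  p <- as.integer(round(p))
  if (p[1] < 1L || p[1] > nrow(mask) || p[2] < 1L || p[2] > ncol(mask))
    stop("edit endpoint lies outside the image")
  p
}

edit_segment <- function(mask, e, cal) {
  coords <- e$coords %||% "pixel"
  a <- edit_point_px(e$from, mask, cal, coords)
  b <- edit_point_px(e$to, mask, cal, coords)
  px <- bresenham(a, b)
  mask[px] <- edit_value(e)
  mask
}

edit_isotherm <- function(mask, e, cal) {
  if (is.null(cal)) stop("isotherm edits need a calibration")
  if (is.null(e$temperature)) stop("isotherm edit needs a 'temperature'")
  wr <- e$composition %||% sort(cal$composition$data)
  wr <- as.numeric(unlist(wr))
  if (length(wr) != 2L) stop("isotherm composition range must be length 2")
  a <- data_to_pixel(c(e$temperature, wr[1]), cal)
  b <- data_to_pixel(c(e$temperature, wr[2]), cal)
  cols <- seq(min(a[2], b[2]), max(a[2], b[2]))
  mask[a[1], cols] <- edit_value(e)
  mask
}

edit_extend <- function(mask, e, k = 5L) {
  at <- edit_point_px(e$at, mask, NULL, "pixel")
  if (mask[at[1], at[2]] != 1L)
    stop("extend edit: the given pixel is not on a boundary line")
  # walk the line from the endpoint to collect its last k pixels
  stub <- line_neighborhood(mask, at, k)
  if (nrow(stub) < 2L)
    stop("extend edit: not enough line pixels to estimate a slope")
  ctr <- colMeans(stub)
  sw <- sweep(stub, 2, ctr)
  dir <- eigen(crossprod(sw), symmetric = TRUE)$vectors[, 1]
  # orient away from the line body, toward the free end
  if (sum(dir * (at - ctr)) < 0) dir <- -dir
  dir <- dir / max(abs(dir))
  pos <- as.numeric(at)
  stub_idx <- stub[, 1] + nrow(mask) * (stub[, 2] - 1L)
  repeat {
    pos <- pos + dir / 2  # half-pixel steps so no cell is skipped
    p <- as.integer(floor(pos + 0.5))
    if (p[1] < 1L || p[1] > nrow(mask) || p[2] < 1L || p[2] > ncol(mask))
      break  # reached the image edge
    idx <- p[1] + nrow(mask) * (p[2] - 1L)
    if (idx %in% stub_idx) next
    if (mask[p[1], p[2]] == 1L) break  # met another line
    mask[p[1], p[2]] <- 1L
    stub_idx <- c(stub_idx, idx)  # freshly drawn pixels are not obstacles
  }
  mask
}

# Up to k line pixels nearest (in steps) to `at` within its 8-connected
# component: breadth-first from the endpoint.
line_neighborhood <- function(mask, at, k) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  seen[at[1], at[2]] <- TRUE
  out <- matrix(at, 1, 2)
  frontier <- out
  while (nrow(out) < k && nrow(frontier) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      p <- frontier[i, ]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        q <- p + c(dr, dc)
        if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > W) next
        if (mask[q[1], q[2]] == 1L && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          nxt <- rbind(nxt, q)
          out <- rbind(out, q)
          if (nrow(out) >= k) break
        }
      }
      if (nrow(out) >= k) break
    }
    frontier <- nxt
    if (is.null(frontier)) break
  }
  unname(out)
}

# Integer (8-connected) line rasterization between two (row, col) pixels.
bresenham <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  dr <- abs(b[1] - a[1]); dc <- abs(b[2] - a[2])
  sr <- sign(b[1] - a[1]); sc <- sign(b[2] - a[2])
  err <- dc - dr
  r <- a[1]; c <- a[2]
  pts <- matrix(NA_integer_, dr + dc + 1L, 2)
  i <- 0L
  repeat {
    i <- i + 1L
    pts[i, ] <- c(r, c)
    if (r == b[1] && c == b[2]) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  pts[seq_len(i), , drop = FALSE]
}
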