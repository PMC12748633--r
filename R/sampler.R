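#' Distance maps from every pixel to every phase region
#'
#' For each region label i, computes the minimum distance from each pixel
#' to the nearest pixel carrying label i. Row and column pixel offsets
#' are first converted to data units (degrees C and wt%) through the
#' calibration, and a 1 degree C step is treated as the same length as a
#' 1 wt% step, so the distance is the Euclidean
#' `sqrt(dT^2 + dw^2)` in those units and results are independent of the
#' scan resolution. Other axis weightings can be imposed through
#' `weights`.
#'
#' The transform is exact (not a chamfer approximation): it returns the
#' same value, bit for bit, as a brute-force scan over all labeled
#' pixels.
#'
#' @param labeled Label matrix from [label_regions()].
#' @param cal [axis_calibration()] for the image.
#' @param weights Length-2 multipliers applied to the (temperature,
#'   composition) data-unit scales; `c(1, 1)` is the equal-length
#'   convention.
#' @return List of `n` numeric matrices of distances in data units.
#' @export
phase_distance_maps <- function(labeled, cal, weights = c(1, 1)) {
  n <- attr(labeled, "n") %||% max(labeled)
  if (n < 1L) stop("labeled image has no regions")
  sc <- axis_scales(cal, weights)
  lab <- labeled
  storage.mode(lab) <- "integer"
  d2 <- .phase_d2_maps_cpp(lab, as.integer(n), sc[["t"]]^2, sc[["w"]]^2)
  lapply(d2, sqrt)
}

#' Distances from one test pixel to each phase
#'
#' @param test_pixel Integer `c(row, col)`.
#' @inheritParams phase_distance_maps
#' @param maps Optional precomputed [phase_distance_maps()] result.
#' @return Numeric vector `d` with `d[i]` the minimum distance in data
#'   units to phase i (0 when the pixel carries label i).
#' @export
phase_distances <- function(test_pixel, labeled, cal, weights = c(1, 1),
                            maps = NULL) {
  if (test_pixel[1] < 1 || test_pixel[1] > nrow(labeled) ||
      test_pixel[2] < 1 || test_pixel[2] > ncol(labeled))
    stop("test pixel lies outside the image")
  if (is.null(maps)) maps <- phase_distance_maps(labeled, cal, weights)
  vapply(maps, function(m) m[test_pixel[1], test_pixel[2]], 0)
}

#' Soft phase-state assignment from a distance vector
#'
#' Applies the exponential distance kernel `P_i = exp(-d_i / 2)` (d in
#' data units), zeroes every raw probability below `threshold` (default
#' `1e-3`, i.e. phases farther than `-2 log(1e-3) ~ 13.8` data units
#' contribute exactly zero), and normalizes the remainder to sum to one.
#' A pixel inside phase i has `d_i = 0`; a pixel on the boundary between
#' two phases is equidistant from both and receives equal probability.
#'
#' @param d Numeric vector of non-negative distances (data units).
#' @param threshold Raw-probability cutoff in (0, 1).
#' @return Numeric probability vector summing to 1.
#' @export
assign_probabilities <- function(d, threshold = 1e-3) {
  if (any(d < 0)) stop("distances must be non-negative")
  raw <- exp(-d / 2)
  raw[raw < threshold] <- 0
  s <- sum(raw)
  if (s == 0)
    stop("no assignable phase: every phase lies beyond the probability ",
         "threshold")
  raw / s
}

#' Sample a labeled diagram onto a probabilistic grid
#'
#' Lays a regular `(temperature, composition)` lattice over the
#' calibrated ranges (both endpoints inclusive; at the dataset convention
#' of 1 degree C x 1 wt% a full 0-100 x 0-100 diagram yields
#' 101 x 101 = 10201 rows), maps each lattice point to its test pixel
#' (rounding half up), and assigns each point the normalized kernel
#' probabilities over the n phases.
#'
#' @inheritParams phase_distance_maps
#' @param grid A [grid_spec()]; defaults to the calibrated data ranges at
#'   unit spacing.
#' @param states Optional character vector of phase-state names for
#'   regions 1..n (the curated region-to-state mapping); defaults to
#'   `"phase_1"`... placeholders.
#' @param threshold Kernel cutoff, see [assign_probabilities()].
#' @return A data frame of class `phd_table`: columns `temperature`,
#'   `composition`, then one probability column per state.
#' @export
sample_grid <- function(labeled, cal, grid = NULL, states = NULL,
                        threshold = 1e-3, weights = c(1, 1)) {
  n <- attr(labeled, "n") %||% max(labeled)
  if (is.null(grid))
    grid <- grid_spec(sort(cal$temperature$data),
                      sort(cal$composition$data))
  stopifnot(inherits(grid, "phd_grid"))
  states <- check_states_arg(states, n)
  pts <- grid_points(grid)
  px <- data_to_pixel(pts, cal)
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  maps <- phase_distance_maps(labeled, cal, weights)
  idx <- cbind(px[, 1], px[, 2])
  dmat <- vapply(maps, function(m) m[idx], numeric(nrow(idx)))
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1L)
  raw <- exp(-dmat / 2)
  raw[raw < threshold] <- 0
  s <- rowSums(raw)
  if (any(s == 0))
    stop("no assignable phase for ", sum(s == 0), " grid point(s): all ",
         "phases lie beyond the probability threshold")
  probs <- raw / s
  out <- data.frame(temperature = pts[, 1], composition = pts[, 2],
                    probs, check.names = FALSE)
  names(out)[-(1:2)] <- states
  structure(out, class = c("phd_table", "data.frame"),
            states = states, threshold = threshold)
}

#' Categorical (hard) assignment on a grid
#'
#' The simplified assignment used for cross-checking against manually
#' digitized grids: each lattice point takes the single phase of minimum
#' distance, ties broken by the lowest region label. Away from exact
#' ties this is the argmax of [sample_grid()].
#'
#' @inheritParams sample_grid
#' @return Data frame with columns `temperature`, `composition`, `state`.
#' @export
categorical_grid <- function(labeled, cal, grid = NULL, states = NULL,
                             weights = c(1, 1)) {
  n <- attr(labeled, "n") %||% max(labeled)
  if (is.null(grid))
    grid <- grid_spec(sort(cal$temperature$data),
                      sort(cal$composition$data))
  states <- check_states_arg(states, n)
  pts <- grid_points(grid)
  px <- data_to_pixel(pts, cal)
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  maps <- phase_distance_maps(labeled, cal, weights)
  idx <- cbind(px[, 1], px[, 2])
  dmat <- vapply(maps, function(m) m[idx], numeric(nrow(idx)))
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1L)
  best <- max.col(-dmat, ties.method = "first")
  data.frame(temperature = pts[, 1], composition = pts[, 2],
             state = states[best], stringsAsFactors = FALSE)
}

check_states_arg <- function(states, n) {
  if (is.null(states)) return(paste0("phase_", seq_len(n)))
  if (length(states) != n)
    stop("need one state name per region: expected ", n, ", got ",
         length(states))
  as.character(states)
}
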