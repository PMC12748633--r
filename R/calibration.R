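#' Axis calibration between pixel and data coordinates
#'
#' Binds image rows to temperature and image columns to composition.
#' Each axis maps a pixel range onto a data range, linearly or through
#' `log10` for logarithmic axes; the mapping is invertible up to pixel
#' rounding. Composition is bounded to `[0, 100]` wt% (0 wt% is pure
#' solvent, 100 wt% pure surfactant).
#'
#' @param t_px Length-2 pixel rows corresponding to `t_data`; typically
#'   `c(1, nrow(image))`.
#' @param t_data Length-2 temperatures (degrees C) at those rows; row 1
#'   is usually the top of the plot, i.e. the higher temperature.
#' @param w_px Length-2 pixel columns corresponding to `w_data`.
#' @param w_data Length-2 compositions (wt%) at those columns.
#' @param t_log,w_log Logical: is the axis logarithmic?
#' @return An object of class `phd_calibration`.
#' @examples
#' cal <- axis_calibration(c(1, 101), c(100, 0), c(1, 101), c(0, 100))
#' data_to_pixel(c(50, 50), cal)
#' @export
axis_calibration <- function(t_px, t_data, w_px, w_data,
                             t_log = FALSE, w_log = FALSE) {
  axis <- function(px, data, log, name, lo = -Inf, hi = Inf) {
    px <- as.numeric(px); data <- as.numeric(data)
    if (length(px) != 2L || length(data) != 2L)
      stop(name, " axis needs length-2 pixel and data ranges")
    if (px[1] == px[2] || data[1] == data[2])
      stop(name, " axis calibration is degenerate")
    if (any(data < lo) || any(data > hi))
      stop(name, " axis data range must lie in [", lo, ", ", hi, "]")
    if (log && any(data <= 0))
      stop(name, " axis: log scale requires positive data values")
    list(px = px, data = data, log = isTRUE(log))
  }
  structure(
    list(temperature = axis(t_px, t_data, t_log, "temperature"),
         composition = axis(w_px, w_data, w_log, "composition",
                            lo = 0, hi = 100)),
    class = "phd_calibration"
  )
}

#' @export
print.phd_calibration <- function(x, ...) {
  fmt <- function(a, unit)
    sprintf("px [%g, %g] -> [%g, %g] %s%s", a$px[1], a$px[2],
            a$data[1], a$data[2], unit, if (a$log) " (log)" else "")
  cat("Axis calibration\n  rows (temperature): ",
      fmt(x$temperature, "degC"), "\n  cols (composition): ",
      fmt(x$composition, "wt%"), "\n", sep = "")
  invisible(x)
}

axis_forward <- function(a, value) {
  tr <- if (a$log) log10 else identity
  f <- (tr(value) - tr(a$data[1])) / (tr(a$data[2]) - tr(a$data[1]))
  a$px[1] + f * (a$px[2] - a$px[1])
}

axis_backward <- function(a, px) {
  f <- (px - a$px[1]) / (a$px[2] - a$px[1])
  tr <- if (a$log) log10 else identity
  v <- tr(a$data[1]) + f * (tr(a$data[2]) - tr(a$data[1]))
  if (a$log) 10^v else v
}

in_range <- function(x, r) {
  x >= min(r) - sqrt(.Machine$double.eps) &
    x <= max(r) + sqrt(.Machine$double.eps)
}

#' Map data coordinates to the nearest pixel
#'
#' Half-way values round toward the larger pixel index.
#'
#' @param point Numeric `c(temperature, composition)`, or an n x 2 matrix
#'   of such points.
#' @param cal A [axis_calibration()] object.
#' @return Integer `c(row, col)` (or n x 2 matrix).
#' @export
data_to_pixel <- function(point, cal) {
  stopifnot(inherits(cal, "phd_calibration"))
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  if (!all(in_range(point[, 1], cal$temperature$data)))
    stop("temperature outside the calibrated range")
  if (!all(in_range(point[, 2], cal$composition$data)))
    stop("composition outside the calibrated range")
  r <- floor(axis_forward(cal$temperature, point[, 1]) + 0.5)
  c <- floor(axis_forward(cal$composition, point[, 2]) + 0.5)
  out <- cbind(row = as.integer(r), col = as.integer(c))
  if (nrow(out) == 1L) out[1, ] else out
}

#' Map pixel coordinates back to data coordinates
#'
#' @param pixel Numeric `c(row, col)` or an n x 2 matrix.
#' @inheritParams data_to_pixel
#' @return Numeric `c(temperature, composition)` (or n x 2 matrix).
#' @export
pixel_to_data <- function(pixel, cal) {
  stopifnot(inherits(cal, "phd_calibration"))
  if (is.null(dim(pixel))) pixel <- matrix(pixel, ncol = 2)
  out <- cbind(temperature = axis_backward(cal$temperature, pixel[, 1]),
               composition = axis_backward(cal$composition, pixel[, 2]))
  if (nrow(out) == 1L) out[1, ] else out
}

# Data units spanned by one pixel step along each axis (temperature per
# row, composition per column). For log axes this is the mean rate over
# the calibrated span; distances on log axes are approximate and can be
# re-weighted through the `weights` argument of the samplers.
axis_scales <- function(cal, weights = c(1, 1)) {
  sc <- function(a) abs(diff(a$data)) / abs(diff(a$px))
  c(t = sc(cal$temperature) * weights[1],
    w = sc(cal$composition) * weights[2])
}

#' Sampling grid specification
#'
#' @param t_range,w_range Length-2 inclusive data ranges (degrees C, wt%).
#' @param dt,dw Grid spacings; the dataset convention is 1 degree C by
#'   1 wt%.
#' @return An object of class `phd_grid`.
#' @export
grid_spec <- function(t_range, w_range, dt = 1, dw = 1) {
  if (dt <= 0 || dw <= 0) stop("grid spacings must be positive")
  t_range <- sort(as.numeric(t_range))
  w_range <- sort(as.numeric(w_range))
  if (any(w_range < 0) || any(w_range > 100))
    stop("composition range must lie in [0, 100] wt%")
  structure(list(t_range = t_range, w_range = w_range, dt = dt, dw = dw),
            class = "phd_grid")
}

grid_points <- function(grid) {
  tt <- seq(grid$t_range[1], grid$t_range[2], by = grid$dt)
  ww <- seq(grid$w_range[1], grid$w_range[2], by = grid$dw)
  # temperature-major ordering, matching the published record layout
  cbind(temperature = rep(tt, each = length(ww)),
        composition = rep(ww, times = length(tt)))
}
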