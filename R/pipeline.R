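#' Binarize a raster image
#'
#' A pixel becomes boundary (1, "black") when its darkness `1 - intensity`
#' is at least `threshold`. Intensities above 1 are assumed to be 8-bit
#' and are rescaled. The default threshold of 0.5 suits clean screen
#' captures; faded scans may need a lower value.
#'
#' @param image Intensity matrix (1 = white), as from [read_diagram()].
#' @param threshold Darkness fraction in (0, 1).
#' @return Integer 0/1 matrix: 1 = boundary line, 0 = region interior.
#' @export
binarize <- function(image, threshold = 0.5) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie strictly between 0 and 1")
  if (max(image) > 1) image <- image / 255
  mask <- matrix(as.integer((1 - image) >= threshold),
                 nrow(image), ncol(image))
  mask
}

check_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a 2-D matrix")
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  storage.mode(mask) <- "integer"
  mask
}

#' Label connected components of a mask
#'
#' Boundary lines are treated as 8-connected and region interiors as
#' 4-connected, so a region cannot leak diagonally through a line.
#' Components are numbered 1..n by raster-scan order of their first pixel.
#'
#' @param mask Binary 0/1 matrix.
#' @param target Pixel value to label: 1 for lines, 0 for regions.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 outside the target set), with
#'   attribute `n` = number of components.
#' @export
label_components <- function(mask, target = 1L,
                             connectivity = if (target == 1L) 8L else 4L) {
  mask <- check_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- .cc_label_cpp(mask, as.integer(connectivity), as.integer(target))
  structure(lab, n = max(lab))
}

#' Identify the plot frame as the largest closed contour
#'
#' Line components are ranked by their filled area (own pixels plus
#' enclosed interior); the winner must actually enclose something,
#' otherwise the diagram is not closed on all four sides and digitization
#' cannot proceed. Corner points are the extremes of `row + col` and
#' `row - col` over the winning component, i.e. a four-corner convex hull
#' suited to axis-aligned and moderately sheared frames.
#'
#' @param mask Binary 0/1 matrix.
#' @return A quadrilateral: 4x2 matrix of (row, col) corners in the order
#'   top-left, top-right, bottom-right, bottom-left, with attribute
#'   `component` (the frame's component id in [label_components()] terms).
#' @export
find_plot_frame <- function(mask) {
  mask <- check_mask(mask)
  lab <- label_components(mask, target = 1L, connectivity = 8L)
  n <- attr(lab, "n")
  if (n == 0L) stop("diagram not enclosed: no boundary pixels found")
  areas <- .component_areas_cpp(lab, n)
  filled <- areas$size + areas$enclosed
  best <- which.max(filled)
  if (areas$enclosed[best] == 0L)
    stop("diagram not enclosed: the largest contour does not close on ",
         "all four sides")
  px <- which(lab == best, arr.ind = TRUE)
  s <- px[, 1] + px[, 2]
  d <- px[, 1] - px[, 2]
  corners <- rbind(px[which.min(s), ],  # top-left
                   px[which.min(d), ],  # top-right
                   px[which.max(s), ],  # bottom-right
                   px[which.max(d), ])  # bottom-left
  dimnames(corners) <- list(c("tl", "tr", "br", "bl"), c("row", "col"))
  if (anyDuplicated(corners))
    stop("degenerate plot frame: corner points coincide")
  structure(corners, component = best)
}

# Homography (projective transform) mapping the unit-indexed output
# rectangle corners onto `quad`. Returns the 3x3 matrix for
# (row, col, 1) output -> source homogeneous coordinates.
quad_homography <- function(quad, out_height, out_width) {
  src <- rbind(c(1, 1), c(1, out_width), c(out_height, out_width),
               c(out_height, 1))
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- quad[i, 1]; v <- quad[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * u, -y * u)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -x * v, -y * v)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b),
                error = function(e) stop("degenerate quadrilateral: ",
                                         "corners are collinear"))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Rectify a (possibly sheared) plot frame to a rectangle
#'
#' Applies the projective transform that carries the four frame corners
#' onto the corners of an `out_height` x `out_width` rectangle, cropping
#' everything outside the frame. Nearest-neighbor resampling keeps binary
#' images binary; an axis-aligned quadrilateral equal to the output
#' rectangle is the identity.
#'
#' @param image Intensity or binary matrix.
#' @param quad 4x2 corner matrix (tl, tr, br, bl), as from
#'   [find_plot_frame()].
#' @param out_height,out_width Output size; defaults to the quadrilateral
#'   bounding-box size.
#' @param fill Value for output pixels that map outside the source image.
#' @return Matrix of size `out_height` x `out_width`, same storage as the
#'   input.
#' @export
rectify <- function(image, quad,
                    out_height = max(quad[, 1]) - min(quad[, 1]) + 1,
                    out_width = max(quad[, 2]) - min(quad[, 2]) + 1,
                    fill = 0) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  quad <- as.matrix(quad)
  if (!all(dim(quad) == c(4, 2))) stop("quad must be a 4x2 corner matrix")
  if (out_height < 3 || out_width < 3)
    stop("output dimensions must be at least 3")
  cr <- quad[c(1, 2, 3, 4, 1), ]
  cross <- diff(cr[, 1])[-4] * diff(cr[, 2])[-1] -
           diff(cr[, 2])[-4] * diff(cr[, 1])[-1]
  if (any(abs(cross) < sqrt(.Machine$double.eps)))
    stop("degenerate quadrilateral: corners are collinear")
  Hm <- quad_homography(quad, out_height, out_width)
  binary <- all(image %in% c(0, 1))
  sample_nn <- function(dr, dc) {
    grid <- cbind(rep(seq_len(out_height), times = out_width) + dr,
                  rep(seq_len(out_width), each = out_height) + dc, 1)
    src <- grid %*% t(Hm)
    sr <- floor(src[, 1] / src[, 3] + 0.5)
    sc <- floor(src[, 2] / src[, 3] + 0.5)
    ok <- sr >= 1 & sr <= nrow(image) & sc >= 1 & sc <= ncol(image)
    out <- matrix(fill, out_height, out_width)
    out[ok] <- image[cbind(sr[ok], sc[ok])]
    out
  }
  if (binary) {
    # supersampled nearest neighbor: each output pixel takes the max of
    # four sub-pixel samples, so a one-pixel boundary line cannot drop
    # pixels (and break a region) under the inverse warp; the output
    # stays binary and the identity transform stays the identity
    out <- pmax(sample_nn(-0.25, -0.25), sample_nn(-0.25, 0.25),
                sample_nn(0.25, -0.25), sample_nn(0.25, 0.25))
  } else {
    out <- sample_nn(0, 0)
  }
  storage.mode(out) <- storage.mode(image)
  out
}

#' Keep only the n largest line components
#'
#' Connected components of boundary (1) pixels are ranked by pixel count,
#' ties broken by earliest raster-scan first pixel, and all but the `n`
#' largest are erased. This is the annotation sweeper: with the frame and
#' boundary lines forming one large connected structure, `n = 1` removes
#' text blobs, stray marks and detached dashes in one pass.
#'
#' @param mask Binary 0/1 matrix.
#' @param n Number of components to keep (>= 1).
#' @return The filtered mask. If `n` is at least the component count the
#'   mask is returned unchanged with a warning.
#' @export
keep_largest <- function(mask, n = 1L) {
  mask <- check_mask(mask)
  if (n < 1L) stop("n must be a positive integer")
  lab <- label_components(mask, target = 1L, connectivity = 8L)
  ncomp <- attr(lab, "n")
  if (ncomp <= n) {
    if (ncomp < n)
      warning("mask has only ", ncomp, " component(s); nothing removed")
    return(mask)
  }
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  # component ids are already in raster order of first pixel, so a stable
  # sort on size implements the raster tie-break
  keep <- order(-sizes)[seq_len(n)]
  out <- mask
  out[!(lab %in% keep) & mask == 1L] <- 0L
  out
}

#' Thin boundary lines to one-pixel width
#'
#' Pixels are removed sequentially in order of their adjacency to white
#' pixels (count of white 8-neighbors, descending; raster order among
#' ties); a pixel is only removed if doing so leaves the number of
#' regions unchanged, i.e. if all its white 4-neighbors already belong to
#' one region. The result has the same region count as the input and the
#' operation is idempotent. Structures that separate nothing (solid
#' blobs, stubs) are eroded away entirely.
#'
#' @param mask Binary 0/1 matrix (cleaned boundary image).
#' @return The thinned mask.
#' @export
thin <- function(mask) {
  mask <- check_mask(mask)
  .thin_cpp(mask)
}

#' Partition a thinned diagram into labeled phase regions
#'
#' Each 4-connected component of white (0) pixels becomes a region with a
#' distinct label 1..n (raster order); boundary pixels keep label 0. The
#' image edge acts as a closed wall, so outer regions are bounded even
#' where the frame line has been thinned away.
#'
#' @param mask Binary 0/1 matrix.
#' @return Integer label matrix with attribute `n`, the region count.
#' @export
label_regions <- function(mask) {
  mask <- check_mask(mask)
  if (!any(mask == 0L)) stop("no regions: mask has no white pixels")
  lab <- .cc_label_cpp(mask, 4L, 0L)
  structure(lab, n = max(lab))
}
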