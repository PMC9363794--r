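# Center extraction from class-labeled masks. The segmentation map gives a
# pixel region per structure; the geometric center used for angle
# measurement is the center of the minimum enclosing circle (default) or of
# the axis-aligned bounding rectangle of the largest connected component.
#
# Coordinate convention: x = column index, y = row index, both 1-based,
# with pixel centers at integer coordinates.

#' Largest 8-connected component of a label class
#'
#' Predicted masks can fragment into speckle; center fitting operates on the
#' single largest 8-connected component of the requested class. Ties between
#' equal-sized components are broken by raster-scan order.
#'
#' @param mask Integer matrix with values in `{0, 1, 2}`.
#' @param class_code The class to extract (1 = optic disc, 2 = virtual macula).
#' @return A two-column matrix `(x, y)` of the component's pixel
#'   coordinates; zero rows when the class is absent.
#' @export
largest_component <- function(mask, class_code) {
  stopifnot(is.matrix(mask), class_code %in% c(1L, 2L))
  bin <- matrix(as.integer(mask == class_code), nrow(mask), ncol(mask))
  lab <- cc_label8(bin)
  k <- max(lab)
  if (k == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(lab == which.max(sizes), arr.ind = TRUE)
  cbind(x = keep[, 2], y = keep[, 1])
}

#' Minimum enclosing circle of a point set
#'
#' Smallest circle containing every input point, computed with a randomized
#' incremental (Welzl-style) algorithm, expected linear time. The circle
#' center is the geometric center used for DFA measurement.
#'
#' @param points Two-column matrix of `(x, y)` coordinates.
#' @return A list with `center` (named numeric `(x, y)`) and `radius`.
#' @examples
#' min_enclosing_circle(cbind(c(0, 4, 2), c(0, 0, 2)))  # center (2,0), r = 2
#' @export
min_enclosing_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0)
    stop_dfameter("empty_points", "cannot fit a circle to an empty point set")
  stopifnot(ncol(points) == 2, all(is.finite(points)))
  fit <- mec_welzl(as.numeric(points[, 1]), as.numeric(points[, 2]))
  list(center = c(x = fit[1], y = fit[2]), radius = fit[3])
}

#' Disc and macula centers from a segmentation mask
#'
#' Extracts the optic-disc and virtual-macula centers from a three-class
#' mask: the largest 8-connected component of each class is reduced to a
#' point either by the minimum enclosing circle (`method = "circle"`) or by
#' the center of its axis-aligned bounding rectangle
#' (`method = "rectangle"`). For the near-circular regions produced by
#' fundus segmentation the two agree closely.
#'
#' @param mask Integer matrix with values in `{0, 1, 2}`.
#' @param method Center definition, `"circle"` (default) or `"rectangle"`.
#' @return A list with numeric `(x, y)` elements `disc` and `macula`, plus
#'   the `method` used. Coordinates are continuous (sub-pixel).
#' @export
extract_centers <- function(mask, method = c("circle", "rectangle")) {
  method <- match.arg(method)
  center_of <- function(class_code, name) {
    pts <- largest_component(mask, class_code)
    if (nrow(pts) == 0)
      stop_dfameter("missing_class",
                    sprintf("no %s (class %d) pixels in mask; image is unmeasurable",
                            name, class_code),
                    which = name)
    if (method == "circle") {
      min_enclosing_circle(pts)$center
    } else {
      c(x = (min(pts[, 1]) + max(pts[, 1])) / 2,
        y = (min(pts[, 2]) + max(pts[, 2])) / 2)
    }
  }
  list(disc = center_of(1L, "disc"),
       macula = center_of(2L, "macula"),
       method = method)
}
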