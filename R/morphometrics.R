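#' Polygon area, perimeter and circularity of a frond outline
#'
#' Size is measured on the *pre-normalized* outline reference points (pixel
#' units), converted to absolute units with the mm-per-pixel calibration.
#' `polygon_area()` is the shoelace formula (absolute value, so point
#' orientation does not matter) scaled by `calibration^2`;
#' `polygon_perimeter()` sums consecutive point distances including the
#' closing edge, scaled by `calibration`. `circularity()` is
#' `4 * pi * area / perimeter^2`, which is 1 for a perfect circle and
#' approaches 0 for highly convoluted outlines; it is independent of the
#' calibration.
#'
#' @param outline Data frame with `x`, `y` columns (pixel units), at least 3
#'   rows.
#' @param calibration mm per pixel (default 1: results in pixel units).
#' @return `polygon_area()`: area in mm^2; `polygon_perimeter()`: perimeter in
#'   mm; `circularity()`: dimensionless value in (0, 1] for simple polygons.
#' @examples
#' square <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' polygon_area(square)        # 1
#' polygon_perimeter(square)   # 4
#' circularity(polygon_area(square), polygon_perimeter(square))  # pi / 4
#' @export
polygon_area <- function(outline, calibration = 1) {
  stopifnot(nrow(outline) >= 3L, calibration > 0)
  x <- outline$x; y <- outline$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 * calibration^2
}

#' @rdname polygon_area
#' @export
polygon_perimeter <- function(outline, calibration = 1) {
  stopifnot(nrow(outline) >= 3L, calibration > 0)
  x <- outline$x; y <- outline$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2)) * calibration
}

#' @rdname polygon_area
#' @param area Area (any units).
#' @param perimeter Perimeter (matching length units).
#' @export
circularity <- function(area, perimeter) {
  stopifnot(area > 0)
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  4 * pi * area / perimeter^2
}

# TRUE if any two non-adjacent polygon edges cross (used to flag outlines
# whose shoelace area is unreliable)
polygon_self_intersects <- function(outline) {
  x <- outline$x; y <- outline$y
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (a in seq_len(n - 2L)) {
    bs <- (a + 2L):n
    bs <- bs[!(a == 1L & bs == n)]    # skip adjacent (wrapping) edge
    if (!length(bs)) next
    d1 <- orient(x[a], y[a], x2[a], y2[a], x[bs], y[bs])
    d2 <- orient(x[a], y[a], x2[a], y2[a], x2[bs], y2[bs])
    d3 <- orient(x[bs], y[bs], x2[bs], y2[bs], x[a], y[a])
    d4 <- orient(x[bs], y[bs], x2[bs], y2[bs], x2[a], y2[a])
    if (any(d1 != d2 & d3 != d4 & d1 != 0 & d2 != 0 & d3 != 0 & d4 != 0)) {
      return(TRUE)
    }
  }
  FALSE
}

#' All size and shape measures of one outline
#'
#' Convenience wrapper computing area, perimeter, circularity, CSM and
#' CSM_forced of a single outline in one call.
#'
#' @inheritParams polygon_area
#' @return One-row tibble with columns `area_mm2`, `perimeter_mm`,
#'   `circularity`, `csm`, `csm_forced`, `axis_angle`,
#'   `self_intersecting` (logical warning flag).
#' @export
measure_outline <- function(outline, calibration = 1) {
  a <- polygon_area(outline, calibration)
  p <- polygon_perimeter(outline, calibration)
  cs <- csm(outline)
  csf <- csm_forced(outline)
  tibble::tibble(
    area_mm2 = a,
    perimeter_mm = p,
    circularity = circularity(a, p),
    csm = cs$csm,
    csm_forced = csf$csm,
    axis_angle = cs$axis$angle,
    self_intersecting = polygon_self_intersects(outline))
}
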