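#' Closed planar contour
#'
#' Constructs a closed 2D contour from an ordered point sequence, the basic
#' currency of the lumen-extraction and calcification stages. Coordinates are
#' in millimetres unless stated otherwise. Duplicate consecutive points are
#' merged and the vertex order is normalised to counter-clockwise, so the
#' signed (shoelace) area of a valid contour is always positive.
#'
#' @param xy two-column matrix (or data frame) of x/y coordinates. The closing
#'   edge is implicit; a repeated first point is dropped.
#' @param dedup_tol distance below which consecutive points are considered
#'   duplicates and merged.
#' @return an object of class `contour2d`: a list with `xy` (n x 2 matrix,
#'   counter-clockwise, open representation) and `is_closed = TRUE`.
#' @examples
#' sq <- contour2d(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygon_area(sq)
#' @export
contour2d <- function(xy, dedup_tol = 1e-9) {
  xy <- as.matrix(xy)
  if (!is.numeric(xy) || ncol(xy) != 2L) {
    stop("contour2d: 'xy' must be a numeric two-column matrix", call. = FALSE)
  }
  if (any(!is.finite(xy))) {
    stop("contour2d: non-finite coordinates", call. = FALSE)
  }
  n <- nrow(xy)
  if (n >= 2L && sqrt(sum((xy[1L, ] - xy[n, ])^2)) <= dedup_tol) {
    xy <- xy[-n, , drop = FALSE]
    n <- nrow(xy)
  }
  if (n >= 2L) {
    d <- sqrt(rowSums((xy - xy[c(2:n, 1L), , drop = FALSE])^2))
    keep <- d > dedup_tol
    # keep[i] guards the edge i -> i+1; dropping the *next* point merges dups
    if (!all(keep)) xy <- xy[c(TRUE, keep[-n]), , drop = FALSE]
    n <- nrow(xy)
  }
  if (n < 3L) {
    stop("contour2d: a closed contour needs at least 3 distinct points",
         call. = FALSE)
  }
  if (shoelace_area(xy) < 0) xy <- xy[n:1L, , drop = FALSE]
  dimnames(xy) <- list(NULL, c("x", "y"))
  structure(list(xy = xy, is_closed = TRUE), class = "contour2d")
}

is_contour2d <- function(x) inherits(x, "contour2d")

as_contour2d <- function(x) {
  if (is_contour2d(x)) x else contour2d(x)
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("<contour2d> %d points, area %.4f, perimeter %.4f\n",
              nrow(x$xy), polygon_area(x), polygon_perimeter(x)))
  invisible(x)
}

# signed shoelace area of an open-representation polygon matrix
shoelace_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L]) / 2
}

#' Enclosed area of a closed contour
#'
#' Shoelace area of the polygon. Contours are stored counter-clockwise, so the
#' result is strictly positive for any valid contour.
#'
#' @param contour a [contour2d] object (or coercible point matrix).
#' @return area in mm^2.
#' @export
polygon_area <- function(contour) {
  contour <- as_contour2d(contour)
  shoelace_area(contour$xy)
}

#' Perimeter of a closed contour
#'
#' Sum of consecutive edge lengths including the closing edge.
#'
#' @inheritParams polygon_area
#' @return length in mm.
#' @export
polygon_perimeter <- function(contour) {
  contour <- as_contour2d(contour)
  xy <- contour$xy
  n <- nrow(xy)
  sum(sqrt(rowSums((xy[c(2:n, 1L), , drop = FALSE] - xy)^2)))
}

#' Equal-area circle radius
#'
#' Radius of the circle whose area equals the given cross-sectional area,
#' `sqrt(area / pi)`. This is the "theoretical radius" used to summarise
#' calcification cross-sections.
#'
#' @param area area in mm^2 (vectorised, must be non-negative).
#' @return radius in mm.
#' @examples
#' theoretical_radius(pi)      # 1
#' theoretical_radius(1.46)    # ~0.68
#' @export
theoretical_radius <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area < 0)) {
    stop("theoretical_radius: 'area' must be non-negative and finite",
         call. = FALSE)
  }
  sqrt(area / pi)
}

#' Centroid of a closed contour
#'
#' Area-weighted centroid of the enclosed polygon.
#'
#' @inheritParams polygon_area
#' @return length-2 numeric (x, y) in mm.
#' @export
contour_centroid <- function(contour) {
  contour <- as_contour2d(contour)
  xy <- contour$xy
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L]
  a <- sum(cr) / 2
  c(x = sum((xy[, 1L] + xy[j, 1L]) * cr) / (6 * a),
    y = sum((xy[, 2L] + xy[j, 2L]) * cr) / (6 * a))
}

#' Resample a closed contour uniformly in arc length
#'
#' Places `n` points at equal arc-length steps along the polygon boundary
#' (linear interpolation along edges), starting at the first vertex. Used to
#' put contour pairs on a common sampling before overlap comparison.
#'
#' @inheritParams polygon_area
#' @param n number of output points (>= 8).
#' @return a [contour2d] with `n` points.
#' @export
resample_closed_contour <- function(contour, n) {
  contour <- as_contour2d(contour)
  if (!is.numeric(n) || length(n) != 1L || n < 8) {
    stop("resample_closed_contour: 'n' must be a single count >= 8",
         call. = FALSE)
  }
  n <- as.integer(n)
  xy <- contour$xy
  m <- nrow(xy)
  closed <- rbind(xy, xy[1L, ])
  seg <- sqrt(rowSums((closed[-1L, , drop = FALSE] -
                         closed[-(m + 1L), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[m + 1L]
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(s, closed[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(s, closed[, 2L], xout = target, ties = "ordered")$y
  contour2d(cbind(x, y))
}

#' Rotate a contour about the origin
#'
#' In-plane rigid rotation; positive angles are counter-clockwise.
#'
#' @inheritParams polygon_area
#' @param angle_deg rotation angle in degrees.
#' @param center rotation centre, default the origin (the catheter axis in
#'   frame coordinates).
#' @return rotated [contour2d].
#' @export
rotate_contour <- function(contour, angle_deg, center = c(0, 0)) {
  contour <- as_contour2d(contour)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  xy <- sweep(contour$xy, 2L, center)
  contour2d(sweep(xy %*% t(R), 2L, center, `+`))
}

#' Translate a contour
#'
#' @inheritParams polygon_area
#' @param offset length-2 numeric translation in mm.
#' @return translated [contour2d].
#' @export
translate_contour <- function(contour, offset) {
  contour <- as_contour2d(contour)
  contour2d(sweep(contour$xy, 2L, offset, `+`))
}

# polyclip representation: list(x=, y=)
contour_to_pc <- function(contour) {
  list(x = contour$xy[, 1L], y = contour$xy[, 2L])
}

pc_to_contour <- function(p) contour2d(cbind(p$x, p$y))

# total enclosed area of a polyclip result (list of rings)
pc_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  sum(vapply(rings, function(p) abs(shoelace_area(cbind(p$x, p$y))),
             numeric(1)))
}

#' Intersection area of two closed contours
#'
#' Exact polygon clipping (via the Clipper library) of the two closed
#' contours; the enclosed area of the intersection is returned. This is the
#' objective maximised by the catheter twist correction.
#'
#' @param a,b [contour2d] objects.
#' @return overlap area in mm^2 (0 when disjoint).
#' @export
contour_overlap_area <- function(a, b) {
  res <- polyclip::polyclip(contour_to_pc(as_contour2d(a)),
                            contour_to_pc(as_contour2d(b)),
                            op = "intersection")
  pc_area(res)
}
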