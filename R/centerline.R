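#' Vessel centerline
#'
#' An ordered 3D polyline with cumulative arc length and per-point orthonormal
#' transport frames (tangent, normal, binormal). Frames are built with the
#' rotation-minimizing double-reflection method, so a straight centerline
#' carries a constant frame and no artificial twist is introduced — a property
#' the registration stage depends on.
#'
#' @param points n x 3 matrix of (x, y, z) coordinates in mm.
#' @param dedup_tol consecutive points closer than this are merged (mm).
#' @return object of class `centerline`: list with `points`, `arclength`
#'   (cumulative, starting at 0) and `frames` (list of 3 n x 3 matrices:
#'   `tangent`, `normal`, `binormal`).
#' @export
centerline <- function(points, dedup_tol = 1e-6) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L) {
    stop("centerline: 'points' must be a numeric n x 3 matrix", call. = FALSE)
  }
  if (any(!is.finite(points))) {
    stop("centerline: non-finite coordinates", call. = FALSE)
  }
  n <- nrow(points)
  if (n >= 2L) {
    d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
    keep <- c(TRUE, d > dedup_tol)
    points <- points[keep, , drop = FALSE]
    n <- nrow(points)
  }
  if (n < 2L) {
    stop("centerline: need at least 2 distinct points", call. = FALSE)
  }
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  obj <- structure(list(points = unname(points),
                        arclength = c(0, cumsum(seg)),
                        frames = NULL),
                   class = "centerline")
  transport_frames(obj)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), centerline_length(x)))
  invisible(x)
}

#' Total arc length of a centerline
#' @param cl a [centerline].
#' @return length in mm.
#' @export
centerline_length <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  cl$arclength[length(cl$arclength)]
}

#' Read a centerline from a point-cloud text file
#'
#' Expects one whitespace-separated `x y z` triple per line in mm, the export
#' convention of CCTA centerline tools; `#` comment lines and blank lines are
#' ignored.
#'
#' @param path file path.
#' @return a [centerline].
#' @export
read_centerline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("read_centerline: no coordinate lines in ", path, call. = FALSE)
  }
  vals <- lapply(strsplit(lines, "[[:space:],]+"), as.numeric)
  if (any(lengths(vals) != 3L) || anyNA(unlist(vals))) {
    stop("read_centerline: every line must hold an 'x y z' triple",
         call. = FALSE)
  }
  centerline(do.call(rbind, vals))
}

#' Write a centerline as a point-cloud text file
#' @param cl a [centerline].
#' @param path output path.
#' @export
write_centerline <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  writeLines(sprintf("%.12g %.12g %.12g", cl$points[, 1L], cl$points[, 2L],
                     cl$points[, 3L]), path)
  invisible(path)
}

#' Resample a centerline at constant arc-length spacing
#'
#' Points are placed every `spacing` mm along the polyline starting at the
#' first point; the final point of the input is always kept, so the last
#' segment may be shorter than `spacing`. Used so that centerline spacing
#' matches the physical distance between OCT frames.
#'
#' @param cl a [centerline].
#' @param spacing arc-length step in mm (> 0, <= total length).
#' @return resampled [centerline] with fresh transport frames.
#' @export
resample_centerline <- function(cl, spacing) {
  stopifnot(inherits(cl, "centerline"))
  total <- centerline_length(cl)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0 ||
      spacing > total) {
    stop("resample_centerline: 'spacing' must be in (0, total length]",
         call. = FALSE)
  }
  s_new <- seq(0, total, by = spacing)
  if (total - s_new[length(s_new)] > 1e-9) s_new <- c(s_new, total)
  pts <- vapply(seq_len(3L), function(k) {
    stats::approx(cl$arclength, cl$points[, k], xout = s_new,
                  ties = "ordered")$y
  }, numeric(length(s_new)))
  centerline(pts)
}

normalize3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) stop("cannot normalise a zero vector",
                                     call. = FALSE)
  v / nv
}

# initial in-plane axis: projection of global x-axis, falling back to y when
# the tangent is (anti)parallel to x — deterministic, reproducible sections
reference_inplane_axis <- function(tangent) {
  for (axis in list(c(1, 0, 0), c(0, 1, 0))) {
    proj <- axis - sum(axis * tangent) * tangent
    if (sqrt(sum(proj^2)) > 1e-6) return(normalize3(proj))
  }
  stop("degenerate tangent", call. = FALSE)
}

#' Attach rotation-minimizing transport frames to a centerline
#'
#' Computes per-point tangents from local chords and propagates the in-plane
#' axes with the double-reflection method, which approximates the
#' rotation-minimizing frame to high order. Unlike Frenet frames this is
#' defined on straight segments and does not inject spurious twist, which
#' would corrupt the contour registration.
#'
#' @param cl a [centerline] (its `frames` field is replaced).
#' @return the centerline with `frames$tangent`, `frames$normal`,
#'   `frames$binormal` filled in (each n x 3, orthonormal rows).
#' @export
transport_frames <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  p <- cl$points
  n <- nrow(p)
  seg <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  if (any(rowSums(seg^2) == 0)) {
    stop("transport_frames: coincident consecutive points", call. = FALSE)
  }
  # chord-based tangents: central differences inside, one-sided at the ends
  tang <- matrix(0, n, 3L)
  tang[1L, ] <- normalize3(seg[1L, ])
  tang[n, ] <- normalize3(seg[n - 1L, ])
  if (n > 2L) {
    for (i in 2:(n - 1L)) tang[i, ] <- normalize3(normalize3(seg[i - 1L, ]) +
                                                    normalize3(seg[i, ]))
  }
  nor <- matrix(0, n, 3L)
  nor[1L, ] <- reference_inplane_axis(tang[1L, ])
  # double reflection (Wang et al. 2008)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      v1 <- p[i + 1L, ] - p[i, ]
      c1 <- sum(v1 * v1)
      rL <- nor[i, ] - (2 / c1) * sum(v1 * nor[i, ]) * v1
      tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
      v2 <- tang[i + 1L, ] - tL
      c2 <- sum(v2 * v2)
      nor[i + 1L, ] <- if (c2 < .Machine$double.eps) rL else
        rL - (2 / c2) * sum(v2 * rL) * v2
      # re-orthogonalise against accumulated rounding
      nor[i + 1L, ] <- normalize3(nor[i + 1L, ] -
                                    sum(nor[i + 1L, ] * tang[i + 1L, ]) *
                                      tang[i + 1L, ])
    }
  }
  bin <- cbind(tang[, 2L] * nor[, 3L] - tang[, 3L] * nor[, 2L],
               tang[, 3L] * nor[, 1L] - tang[, 1L] * nor[, 3L],
               tang[, 1L] * nor[, 2L] - tang[, 2L] * nor[, 1L])
  cl$frames <- list(tangent = tang, normal = nor, binormal = bin)
  cl
}

#' Index of the centerline point nearest to a 3D location
#' @param cl a [centerline].
#' @param point length-3 numeric.
#' @return list with `index` and `distance` (mm).
#' @export
nearest_centerline_point <- function(cl, point) {
  stopifnot(inherits(cl, "centerline"))
  d2 <- rowSums(sweep(cl$points, 2L, point)^2)
  i <- which.min(d2)
  list(index = i, distance = sqrt(d2[i]))
}
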