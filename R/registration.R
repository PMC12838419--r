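#' Twist-correction configuration
#'
#' Grid-search settings for the catheter twist correction: consecutive
#' contour pairs are rotated within `+/- angle_range_deg` (the clinical
#' window is 3 degrees) and the rotation maximising the overlap area is kept.
#'
#' @param angle_range_deg symmetric search bound in degrees (default 3).
#' @param angle_step_deg grid step in degrees (default 0.1).
#' @param resample_n common resampling of both contours before clipping.
#' @return object of class `twist_config`.
#' @export
twist_config <- function(angle_range_deg = 3, angle_step_deg = 0.1,
                         resample_n = 256L) {
  if (angle_range_deg <= 0 || angle_step_deg <= 0 ||
      angle_step_deg > angle_range_deg) {
    stop("twist_config: need 0 < step <= range", call. = FALSE)
  }
  structure(list(angle_range_deg = angle_range_deg,
                 angle_step_deg = angle_step_deg,
                 resample_n = as.integer(resample_n)),
            class = "twist_config")
}

#' Corrective rotation between two consecutive contours
#'
#' Grid search over rotations of `c_next` about the origin (the catheter
#' axis); the angle whose rotated contour has maximum intersection area with
#' `c_prev` is returned. Ties are broken toward the smallest magnitude and
#' then toward the negative angle, so rotationally symmetric contours report
#' zero twist. Positive angles are counter-clockwise.
#'
#' @param c_prev,c_next [contour2d] objects (mm, catheter at origin).
#' @param cfg a [twist_config].
#' @return best angle in degrees.
#' @export
pairwise_twist_angle <- function(c_prev, c_next, cfg = twist_config()) {
  c_prev <- resample_closed_contour(as_contour2d(c_prev), cfg$resample_n)
  c_next <- resample_closed_contour(as_contour2d(c_next), cfg$resample_n)
  angles <- seq(-cfg$angle_range_deg, cfg$angle_range_deg,
                by = cfg$angle_step_deg)
  ov <- vapply(angles, function(a)
    contour_overlap_area(c_prev, rotate_contour(c_next, a)), numeric(1))
  if (max(ov) <= 0) {
    stop("pairwise_twist_angle: contours do not overlap at any angle",
         call. = FALSE)
  }
  # ties: smallest |angle| first, then the negative one
  best <- which(ov >= max(ov) - 1e-12)
  best <- best[order(abs(angles[best]), angles[best])]
  angles[best[1L]]
}

#' Correct catheter twist along a pullback
#'
#' Walks the series once: each contour is compared against its
#' already-corrected predecessor, pre-rotated by the accumulated correction,
#' and the incremental angle found within the search window is added. The
#' cumulative angle per frame is stored in `twist_angles` and applied to the
#' contours; the first frame is the reference (angle 0). When the true
#' inter-frame twist exceeds the window the estimate clamps at the window
#' boundary and a message reports the saturated frame.
#'
#' @param series a [pullback_series].
#' @param cfg a [twist_config].
#' @return the series with rotated contours and `twist_angles` filled in.
#' @export
correct_twist <- function(series, cfg = twist_config()) {
  stopifnot(inherits(series, "pullback_series"))
  n <- length(series$contours)
  ang <- numeric(n)
  out <- series$contours
  for (k in 2:n) {
    inc <- tryCatch(
      pairwise_twist_angle(out[[k - 1L]],
                           rotate_contour(series$contours[[k]], ang[k - 1L]),
                           cfg),
      error = function(e) stop("correct_twist: frame ",
                               series$frame_indices[k], ": ",
                               conditionMessage(e), call. = FALSE))
    if (abs(abs(inc) - cfg$angle_range_deg) < 1e-9) {
      message(sprintf(
        "correct_twist: correction saturated at %+.1f deg at frame %d",
        inc, series$frame_indices[k]))
    }
    ang[k] <- ang[k - 1L] + inc
    out[[k]] <- rotate_contour(series$contours[[k]], ang[k])
  }
  series$contours <- out
  series$twist_angles <- ang
  series
}

#' Bifurcation landmark pair
#'
#' The registration landmark: the carina point picked on one OCT frame, and
#' the projection points picked on the main and side branch in the CCTA
#' volume.
#'
#' @param oct_frame_index index of the OCT frame showing the carina.
#' @param oct_carina_point (x, y) position of the carina in frame
#'   coordinates (mm, catheter at origin).
#' @param ccta_main_point,ccta_side_point (x, y, z) projection points in mm;
#'   must be distinct.
#' @return object of class `landmark_pair`.
#' @export
landmark_pair <- function(oct_frame_index, oct_carina_point,
                          ccta_main_point, ccta_side_point) {
  ccta_main_point <- as.numeric(ccta_main_point)
  ccta_side_point <- as.numeric(ccta_side_point)
  if (sqrt(sum((ccta_main_point - ccta_side_point)^2)) < 1e-9) {
    stop("landmark_pair: CCTA main and side points must be distinct",
         call. = FALSE)
  }
  structure(list(oct_frame_index = as.integer(oct_frame_index),
                 oct_carina_point = as.numeric(oct_carina_point),
                 ccta_main_point = ccta_main_point,
                 ccta_side_point = ccta_side_point),
            class = "landmark_pair")
}

#' CCTA-side registration point for a landmark
#'
#' The arithmetic midpoint of the main- and side-branch projection points,
#' snapped to the nearest centerline point. A landmark whose midpoint lies
#' farther than `gate_mm` from the centerline is rejected as a mismatch.
#'
#' @param lm a [landmark_pair].
#' @param cl the (resampled) [centerline].
#' @param gate_mm rejection distance in mm (default 5).
#' @return list with `point` (snapped, mm), `midpoint` (raw), `index`
#'   (centerline index).
#' @export
carina_registration_point <- function(lm, cl, gate_mm = 5) {
  stopifnot(inherits(lm, "landmark_pair"), inherits(cl, "centerline"))
  mid <- (lm$ccta_main_point + lm$ccta_side_point) / 2
  near <- nearest_centerline_point(cl, mid)
  if (near$distance > gate_mm) {
    stop(sprintf(
      "carina_registration_point: midpoint is %.2f mm from the centerline (gate %g mm)",
      near$distance, gate_mm), call. = FALSE)
  }
  list(point = cl$points[near$index, ], midpoint = mid, index = near$index)
}

#' Place a twist-corrected pullback onto the CCTA centerline
#'
#' The centerline is resampled so point spacing equals the physical distance
#' between OCT frames, the landmark frame is anchored at the carina
#' registration point (in-plane translation mapping the carina pixel point
#' onto the snapped midpoint, plus an in-plane rotation aligning the frame's
#' carina direction with the projected side-branch direction), and the
#' remaining frames are laid onto consecutive centerline points on both sides
#' of the landmark with the same in-plane transform, preserving their
#' relative orientation. Each contour lies in the plane orthogonal to the
#' local tangent; out-of-plane rotation is not modelled. Frames that would
#' fall off either centerline end are dropped with a warning.
#'
#' @param series a twist-corrected [pullback_series].
#' @param cl the CCTA [centerline].
#' @param lm a [landmark_pair] whose frame index is in the series.
#' @param gate_mm landmark gate passed to [carina_registration_point].
#' @param centroid_snap place each contour with its centroid on the
#'   centerline point instead of keeping the rigid catheter offset
#'   (default FALSE, honouring frame interlocking).
#' @return object of class `registered_stack`: list with `contours3d`
#'   (each a list with `points` n x 3, `centerline_index`, `normal`),
#'   `centerline` (resampled), `landmark_centerline_index`, `frame_indices`.
#' @export
register_pullback <- function(series, cl, lm, gate_mm = 5,
                              centroid_snap = FALSE) {
  stopifnot(inherits(series, "pullback_series"), inherits(cl, "centerline"),
            inherits(lm, "landmark_pair"))
  k0 <- match(lm$oct_frame_index, series$frame_indices)
  if (is.na(k0)) {
    stop("register_pullback: landmark frame index not in series",
         call. = FALSE)
  }
  spacing <- series$calibration$frame_spacing_mm
  clr <- resample_centerline(cl, spacing)
  reg <- carina_registration_point(lm, clr, gate_mm = gate_mm)
  i0 <- reg$index
  n_frames <- length(series$contours)
  n_cl <- nrow(clr$points)

  # in-plane rotation: align the frame's carina direction with the projected
  # side-branch direction at the registration point
  e1 <- clr$frames$normal[i0, ]; e2 <- clr$frames$binormal[i0, ]
  side_vec <- lm$ccta_side_point - reg$point
  side2d <- c(sum(side_vec * e1), sum(side_vec * e2))
  # the carina is picked on the raw frame; bring it into corrected series
  # coordinates by applying that frame's twist correction
  car2d <- lm$oct_carina_point
  if (length(series$twist_angles)) {
    a <- series$twist_angles[k0] * pi / 180
    car2d <- c(cos(a) * car2d[1L] - sin(a) * car2d[2L],
               sin(a) * car2d[1L] + cos(a) * car2d[2L])
  }
  # the carina direction is taken from the lumen centroid, not the catheter
  # origin, so an off-centre catheter does not bias the alignment
  car_dir <- car2d - contour_centroid(series$contours[[k0]])
  if (sqrt(sum(side2d^2)) < 1e-9 || sqrt(sum(car_dir^2)) < 1e-9) {
    stop("register_pullback: degenerate landmark directions", call. = FALSE)
  }
  phi <- atan2(side2d[2L], side2d[1L]) - atan2(car_dir[2L], car_dir[1L])
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  # in-plane translation: rotated carina point -> snapped midpoint (in the
  # plane coordinates of the landmark section)
  mid2d_vec <- reg$midpoint - reg$point
  mid2d <- c(sum(mid2d_vec * e1), sum(mid2d_vec * e2))
  tr <- mid2d - as.numeric(R %*% car2d)

  cl_idx <- i0 + (seq_len(n_frames) - k0)
  usable <- cl_idx >= 1L & cl_idx <= n_cl
  if (!any(usable)) {
    stop("register_pullback: no frame fits on the centerline", call. = FALSE)
  }
  if (!all(usable)) {
    warning(sprintf("register_pullback: %d frame(s) extend beyond the centerline and were dropped",
                    sum(!usable)), call. = FALSE)
  }
  contours3d <- vector("list", sum(usable))
  jj <- 0L
  for (k in which(usable)) {
    i <- cl_idx[k]
    uv <- sweep(series$contours[[k]]$xy %*% t(R), 2L, tr, `+`)
    if (centroid_snap) uv <- sweep(uv, 2L, colMeans(uv))
    p3 <- sweep(outer(uv[, 1L], clr$frames$normal[i, ]) +
                  outer(uv[, 2L], clr$frames$binormal[i, ]),
                2L, clr$points[i, ], `+`)
    jj <- jj + 1L
    contours3d[[jj]] <- list(points = p3, centerline_index = i,
                             normal = clr$frames$tangent[i, ])
  }
  structure(list(contours3d = contours3d, centerline = clr,
                 landmark_centerline_index = i0,
                 frame_indices = series$frame_indices[usable],
                 calibration = series$calibration),
            class = "registered_stack")
}

#' @export
print.registered_stack <- function(x, ...) {
  cat(sprintf(
    "<registered_stack> %d contours on %d centerline points (landmark at %d)\n",
    length(x$contours3d), nrow(x$centerline$points),
    x$landmark_centerline_index))
  invisible(x)
}

#' Export / import landmark annotations as JSON
#'
#' @param lm a [landmark_pair].
#' @param path JSON path.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_pair"))
  jsonlite::write_json(unclass(lm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @return `read_landmarks` returns a [landmark_pair].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_pair(obj$oct_frame_index, obj$oct_carina_point,
                obj$ccta_main_point, obj$ccta_side_point)
}
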