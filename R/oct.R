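#' OCT pullback calibration
#'
#' Physical calibration of a pullback recording. The default pixel pitch is
#' 103 px per mm on 1024 x 1024 frames; the physical distance between frames
#' is either given directly or derived as `pullback_speed / frame_rate` when
#' a frame rate is known.
#'
#' @param px_per_mm pixels per millimetre (default 103).
#' @param frame_spacing_mm physical distance between consecutive frames (mm).
#' @param pullback_speed catheter pullback speed in mm/s (default 40).
#' @param pullback_length pullback travel in mm (default 75).
#' @param frame_rate frames per second; when given it overrides
#'   `frame_spacing_mm`.
#' @return object of class `oct_calibration`.
#' @export
oct_calibration <- function(px_per_mm = 103, frame_spacing_mm = 0.2,
                            pullback_speed = 40, pullback_length = 75,
                            frame_rate = NULL) {
  if (!is.null(frame_rate)) {
    stopifnot(frame_rate > 0)
    frame_spacing_mm <- pullback_speed / frame_rate
  }
  vals <- c(px_per_mm, frame_spacing_mm, pullback_speed, pullback_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("oct_calibration: all calibration values must be positive",
         call. = FALSE)
  }
  structure(list(px_per_mm = px_per_mm, frame_spacing_mm = frame_spacing_mm,
                 pullback_speed = pullback_speed,
                 pullback_length = pullback_length),
            class = "oct_calibration")
}

#' Annotated OCT frame
#'
#' A square RGB frame whose lumen border has been pre-annotated in a known
#' colour by the upstream OCT console software.
#'
#' @param image H x W x 3 numeric array with values in `[0, 1]` (a plain
#'   matrix is treated as grayscale and expanded).
#' @param frame_index non-negative integer position in the pullback.
#' @param annotation_color RGB triple in `[0, 1]` marking the lumen border
#'   (default pure green).
#' @return object of class `annotated_frame`.
#' @export
annotated_frame <- function(image, frame_index,
                            annotation_color = c(0, 1, 0)) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    stop("annotated_frame: 'image' must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(image)[1L] != dim(image)[2L]) {
    stop("annotated_frame: frames must be square", call. = FALSE)
  }
  if (max(image) > 1 + 1e-9) image <- image / 255
  stopifnot(frame_index >= 0)
  structure(list(image = image[, , 1:3, drop = FALSE],
                 frame_index = as.integer(frame_index),
                 annotation_color = annotation_color),
            class = "annotated_frame")
}

#' Extract the binary annotation mask of a frame
#'
#' Isolates the annotated lumen border by colour thresholding, suppresses
#' speckle with a Gaussian kernel and re-thresholds the smoothed intensity,
#' mirroring the border-isolation step of the frame-processing chain.
#' Isolated same-colour speckles die in the smoothing; short dashed gaps in
#' the annotation (up to about `2 * sigma` px) are bridged.
#'
#' @param frame an [annotated_frame].
#' @param color_tol per-channel tolerance on the annotation colour (0-1
#'   scale; default 30/255).
#' @param sigma Gaussian kernel standard deviation in px.
#' @param threshold intensity threshold applied after smoothing.
#' @return logical H x W matrix.
#' @export
extract_annotation_mask <- function(frame, color_tol = 30 / 255, sigma = 2,
                                    threshold = 0.5) {
  stopifnot(inherits(frame, "annotated_frame"))
  img <- frame$image
  col <- frame$annotation_color
  raw <- abs(img[, , 1L] - col[1L]) <= color_tol &
    abs(img[, , 2L] - col[2L]) <= color_tol &
    abs(img[, , 3L] - col[3L]) <= color_tol
  if (!any(raw)) {
    stop(sprintf("extract_annotation_mask: no annotation pixels in frame %d",
                 frame$frame_index), call. = FALSE)
  }
  sm <- EBImage::gblur(raw * 1, sigma = sigma)
  mask <- sm > threshold
  # very thin (1 px) annotations blur below the absolute threshold; fall
  # back to a max-relative cut so they survive
  if (!any(mask)) mask <- sm > threshold * max(sm)
  if (!any(mask)) {
    stop(sprintf(
      "extract_annotation_mask: annotation vanished after smoothing (frame %d)",
      frame$frame_index), call. = FALSE)
  }
  mask
}

#' Fit a smooth closed contour around a binary mask
#'
#' Takes the convex hull of the mask foreground (the smallest convex polygon
#' enclosing all annotation pixels) and fits a closed periodic cubic spline
#' around it, sampled at `n_samples` points. Coordinates are returned in
#' pixel units with x = column, y = row.
#'
#' When the mask is an annular border (annotation band) rather than a
#' filled region, the hull rides the outer edge of the band; with
#' `border_compensation` the contour is pulled inward by half the band
#' thickness (estimated as mask area / hull perimeter), centring it on the
#' drawn border regardless of the export line width. Filled masks (mask
#' area comparable to hull area) are left untouched.
#'
#' @param mask logical matrix (rows x cols).
#' @param n_samples number of points sampled along the spline.
#' @param smoothing boundary smoothing window in px (0 = interpolating
#'   spline through the hull vertices).
#' @param border_compensation recentre border-band masks (default TRUE).
#' @return a [contour2d] in pixel units.
#' @export
hull_and_spline <- function(mask, n_samples = 256L, smoothing = 0,
                            border_compensation = TRUE) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) {
    stop("hull_and_spline: mask has fewer than 3 foreground pixels",
         call. = FALSE)
  }
  pts <- cbind(x = idx[, 2L], y = idx[, 1L])
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3L) {
    stop("hull_and_spline: degenerate (collinear) mask", call. = FALSE)
  }
  # chull returns clockwise in (col,row); orientation is normalised later.
  # densify the hull polygon first: a periodic cubic spline through sparse
  # corner vertices would overshoot badly on long edges
  hull <- hull[nrow(hull):1L, , drop = FALSE]
  dense <- resample_closed_contour(contour2d(hull),
                                   max(n_samples, 128L))$xy
  closed <- rbind(dense, dense[1L, ])
  s <- c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
  total <- s[length(s)]
  tout <- seq(0, total, length.out = n_samples + 1L)[-(n_samples + 1L)]
  sx <- stats::spline(s, closed[, 1L], method = "periodic", xout = tout)$y
  sy <- stats::spline(s, closed[, 2L], method = "periodic", xout = tout)$y
  out <- cbind(sx, sy)
  if (smoothing > 0) {
    # circular moving average with a window of `smoothing` px of arc length
    win <- max(1L, round(smoothing / (total / n_samples)))
    if (win > 1L) {
      kern <- rep(1 / (2 * win + 1), 2 * win + 1)
      pad <- function(v) c(utils::tail(v, win), v, utils::head(v, win))
      out <- cbind(stats::filter(pad(out[, 1L]), kern)[win + seq_len(n_samples)],
                   stats::filter(pad(out[, 2L]), kern)[win + seq_len(n_samples)])
    }
  }
  ct <- contour2d(out)
  if (border_compensation) {
    mask_area <- nrow(idx)
    hull_area <- polygon_area(ct)
    if (mask_area < 0.5 * hull_area) {
      band_px <- mask_area / polygon_perimeter(ct)
      # +0.5: the hull passes through the centres of the outermost pixels
      ct <- shrink_contour(ct, band_px / 2 + 0.5)
    }
  }
  ct
}

#' Convert a pixel-space contour to physical millimetres
#'
#' Divides by the pixel pitch, shifts the origin to the image centre (the
#' catheter axis) and flips the y axis so the result is right-handed with y
#' pointing up.
#'
#' @param contour_px [contour2d] in pixel units (x = column, y = row).
#' @param cal an [oct_calibration].
#' @param image_px frame edge length in pixels (default 1024).
#' @return [contour2d] in mm, catheter at the origin.
#' @export
pixels_to_mm <- function(contour_px, cal, image_px = 1024L) {
  stopifnot(inherits(cal, "oct_calibration"))
  ctr <- (image_px + 1) / 2
  xy <- as_contour2d(contour_px)$xy
  contour2d(cbind((xy[, 1L] - ctr) / cal$px_per_mm,
                  (ctr - xy[, 2L]) / cal$px_per_mm))
}

#' Ordered series of calibrated lumen contours
#'
#' @param contours list of [contour2d] in mm, frame order.
#' @param calibration an [oct_calibration].
#' @param frame_indices original frame indices (defaults to 0-based order).
#' @param twist_angles per-frame cumulative corrective rotations (degrees);
#'   empty until [correct_twist] has run.
#' @return object of class `pullback_series`.
#' @export
pullback_series <- function(contours, calibration,
                            frame_indices = seq_along(contours) - 1L,
                            twist_angles = numeric(0)) {
  stopifnot(inherits(calibration, "oct_calibration"))
  if (length(contours) < 2L) {
    stop("pullback_series: need at least 2 contours", call. = FALSE)
  }
  if (!all(vapply(contours, is_contour2d, logical(1)))) {
    stop("pullback_series: 'contours' must be contour2d objects",
         call. = FALSE)
  }
  if (length(twist_angles) != 0L &&
      length(twist_angles) != length(contours)) {
    stop("pullback_series: twist_angles length mismatch", call. = FALSE)
  }
  structure(list(contours = contours, calibration = calibration,
                 frame_indices = as.integer(frame_indices),
                 twist_angles = twist_angles),
            class = "pullback_series")
}

#' @export
print.pullback_series <- function(x, ...) {
  ar <- vapply(x$contours, polygon_area, numeric(1))
  cat(sprintf(
    "<pullback_series> %d frames, spacing %.3f mm, lumen area %.2f-%.2f mm^2%s\n",
    length(x$contours), x$calibration$frame_spacing_mm, min(ar), max(ar),
    if (length(x$twist_angles)) ", twist-corrected" else ""))
  invisible(x)
}

#' @export
summary.pullback_series <- function(object, ...) {
  ar <- vapply(object$contours, polygon_area, numeric(1))
  data.frame(frame_index = object$frame_indices,
             area_mm2 = ar,
             eq_radius_mm = theoretical_radius(ar),
             twist_deg = if (length(object$twist_angles))
               object$twist_angles else NA_real_)
}

#' Process an annotated pullback into calibrated lumen contours
#'
#' Runs the per-frame chain mask extraction -> convex hull + periodic spline
#' -> pixel-to-mm conversion over an ordered list of annotated frames.
#'
#' @param frames list of [annotated_frame], sorted by frame index.
#' @param cal an [oct_calibration].
#' @param skip_empty skip (with a warning) frames whose annotation is missing
#'   instead of failing.
#' @param n_samples,smoothing passed to [hull_and_spline].
#' @param color_tol,sigma,threshold passed to [extract_annotation_mask].
#' @return a [pullback_series]; skipped frames are absent but the remaining
#'   `frame_indices` keep their original values.
#' @export
process_pullback <- function(frames, cal, skip_empty = FALSE,
                             n_samples = 256L, smoothing = 0,
                             color_tol = 30 / 255, sigma = 2,
                             threshold = 0.5) {
  if (length(frames) < 2L) {
    stop("process_pullback: need at least 2 frames", call. = FALSE)
  }
  fidx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (is.unsorted(fidx)) {
    stop("process_pullback: frames must be sorted by frame_index",
         call. = FALSE)
  }
  contours <- list(); kept <- integer(0)
  img_px <- dim(frames[[1L]]$image)[1L]
  for (f in frames) {
    res <- tryCatch({
      mask <- extract_annotation_mask(f, color_tol = color_tol, sigma = sigma,
                                      threshold = threshold)
      pixels_to_mm(hull_and_spline(mask, n_samples = n_samples,
                                   smoothing = smoothing),
                   cal, image_px = img_px)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (skip_empty) {
        warning("skipping frame ", f$frame_index, ": ", conditionMessage(res),
                call. = FALSE)
        next
      }
      stop(res)
    }
    contours[[length(contours) + 1L]] <- res
    kept <- c(kept, f$frame_index)
  }
  if (length(contours) < 2L) {
    stop("process_pullback: fewer than 2 usable frames", call. = FALSE)
  }
  pullback_series(contours, cal, frame_indices = kept)
}

#' Process annotated frame files without holding the pullback in memory
#'
#' Streaming variant of [process_pullback]: frames are read from disk one at
#' a time (a directory of numbered TIFF/PNG files or a multi-page TIFF) and
#' only the extracted contours are kept, so arbitrarily long pullbacks fit
#' in memory.
#'
#' @param path frame directory or multi-page TIFF.
#' @inheritParams process_pullback
#' @param annotation_color RGB triple marking the lumen border.
#' @return a [pullback_series].
#' @export
process_pullback_path <- function(path, cal, skip_empty = FALSE,
                                  n_samples = 256L, smoothing = 0,
                                  color_tol = 30 / 255, sigma = 2,
                                  threshold = 0.5,
                                  annotation_color = c(0, 1, 0)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) {
      stop("process_pullback_path: need at least 2 frame files",
           call. = FALSE)
    }
    loader <- function(i) read_one_frame(files[i], i - 1L, annotation_color)
    n <- length(files)
  } else {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    loader <- function(i) annotated_frame(imgs[[i]], i - 1L,
                                          annotation_color)
    n <- length(imgs)
  }
  contours <- list(); kept <- integer(0)
  for (i in seq_len(n)) {
    f <- loader(i)
    res <- tryCatch({
      mask <- extract_annotation_mask(f, color_tol = color_tol,
                                      sigma = sigma, threshold = threshold)
      pixels_to_mm(hull_and_spline(mask, n_samples = n_samples,
                                   smoothing = smoothing),
                   cal, image_px = dim(f$image)[1L])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (skip_empty) {
        warning("skipping frame ", f$frame_index, ": ",
                conditionMessage(res), call. = FALSE)
        next
      }
      stop(res)
    }
    contours[[length(contours) + 1L]] <- res
    kept <- c(kept, f$frame_index)
  }
  if (length(contours) < 2L) {
    stop("process_pullback_path: fewer than 2 usable frames", call. = FALSE)
  }
  pullback_series(contours, cal, frame_indices = kept)
}

read_one_frame <- function(file, index, annotation_color) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is needed for PNG frames", call. = FALSE)
    }
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  annotated_frame(img, index, annotation_color)
}

#' Read annotated OCT frames from disk
#'
#' Accepts either a multi-page TIFF file or a directory of numbered
#' TIFF/PNG frames (sorted by name).
#'
#' @param path file or directory.
#' @param annotation_color RGB triple marking the lumen border.
#' @return list of [annotated_frame].
#' @export
read_oct_frames <- function(path, annotation_color = c(0, 1, 0)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      stop("read_oct_frames: no TIFF/PNG frames in ", path, call. = FALSE)
    }
    imgs <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE)) {
          stop("read_oct_frames: the 'png' package is needed for PNG frames",
               call. = FALSE)
        }
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
    })
  } else {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
  }
  lapply(seq_along(imgs), function(i)
    annotated_frame(imgs[[i]], frame_index = i - 1L,
                    annotation_color = annotation_color))
}

#' Write a pullback series to a JSON contour archive
#'
#' Schema (version 1): `{version, calibration{...}, frames:[{index,
#' twist_deg, points:[[x,y],...]}]}` with coordinates in mm.
#'
#' @param series a [pullback_series].
#' @param path output JSON path.
#' @export
write_contour_archive <- function(series, path) {
  stopifnot(inherits(series, "pullback_series"))
  tw <- if (length(series$twist_angles)) series$twist_angles else
    rep(NA_real_, length(series$contours))
  obj <- list(
    version = 1L,
    calibration = unclass(series$calibration),
    frames = lapply(seq_along(series$contours), function(i) list(
      index = series$frame_indices[i],
      twist_deg = tw[i],
      points = unname(series$contours[[i]]$xy))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pullback series from a JSON contour archive
#' @param path JSON path written by [write_contour_archive].
#' @return a [pullback_series].
#' @export
read_contour_archive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("read_contour_archive: unsupported archive version", call. = FALSE)
  }
  cal <- do.call(oct_calibration, obj$calibration[
    c("px_per_mm", "frame_spacing_mm", "pullback_speed", "pullback_length")])
  contours <- lapply(obj$frames$points, contour2d)
  tw <- obj$frames$twist_deg
  pullback_series(contours, cal, frame_indices = obj$frames$index,
                  twist_angles = if (all(is.na(tw))) numeric(0) else tw)
}
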