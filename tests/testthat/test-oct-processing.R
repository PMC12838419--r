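# a tiny synthetic frame: draw a circle of radius r_mm in the annotation
# colour over speckle, using the package renderer at reduced resolution
small_frame <- function(r_mm = 0.8, image_px = 256, px_per_mm = 103,
                        index = 0L, seed = 1) {
  set.seed(seed)
  cal <- oct_calibration(px_per_mm = px_per_mm)
  img <- corofuse:::render_frame_image(circle_contour(r_mm, 256), cal,
                                       image_px, c(0, 1, 0), 3L)
  annotated_frame(img, index)
}

test_that("colour thresholding isolates the annotation and kills speckle", {
  fr <- small_frame()
  mask <- extract_annotation_mask(fr)
  expect_true(any(mask))
  # add isolated single-pixel annotation speckles: smoothing removes them
  img <- fr$image
  set.seed(4)
  ij <- cbind(sample(10:60, 12), sample(10:60, 12))
  for (ch in 1:3) img[, , ch][ij] <- c(0, 1, 0)[ch]
  fr2 <- annotated_frame(img, 0L)
  mask2 <- extract_annotation_mask(fr2)
  expect_false(any(mask2[ij]))

  # a frame with no annotation errors, naming the frame
  blank <- annotated_frame(array(0.2, c(64, 64, 3)), 17L)
  expect_error(extract_annotation_mask(blank), "frame 17")
})

test_that("dashed annotation gaps within 2*sigma are bridged", {
  fr <- small_frame(0.6)
  img <- fr$image
  # punch 2-px radial gaps into the ring every 30 degrees
  ctr <- (256 + 1) / 2
  for (ang in seq(0, 2 * pi, by = pi / 6)) {
    cx <- round(ctr + 0.6 * 103 * cos(ang))
    cy <- round(ctr - 0.6 * 103 * sin(ang))
    rows <- pmax(1, cy - 1):pmin(256, cy)
    cols <- pmax(1, cx - 1):pmin(256, cx)
    for (ch in 1:3) img[rows, cols, ch] <- 0.1
  }
  mask <- extract_annotation_mask(annotated_frame(img, 0L))
  ct <- hull_and_spline(mask, 128)
  # the hull+spline still closes to a full circle of the right size
  expect_lt(abs(polygon_area(ct) / (pi * (0.6 * 103)^2) - 1), 0.05)
})

test_that("hull and periodic spline wrap masks as convex contours", {
  # filled square: area preserved within spline tolerance
  mask <- matrix(FALSE, 256, 256)
  mask[79:178, 79:178] <- TRUE
  ct <- hull_and_spline(mask, 256)
  expect_lt(abs(polygon_area(ct) / 99^2 - 1), 0.02)

  # crescent: the contour is the hull of the crescent, not the crescent
  idx <- which(mask, arr.ind = TRUE)
  cres <- matrix(FALSE, 256, 256)
  th <- seq(-pi / 2, pi / 2, length.out = 400)
  for (r in seq(60, 70, by = 1)) {
    cres[cbind(round(128 + r * sin(th)), round(128 + r * cos(th)))] <- TRUE
  }
  ct2 <- hull_and_spline(cres, 128, border_compensation = FALSE)
  hull_pts <- which(cres, arr.ind = TRUE)[, c(2, 1)]
  hull_area <- polygon_area(contour2d(
    hull_pts[grDevices::chull(hull_pts), ]))
  expect_lt(abs(polygon_area(ct2) / hull_area - 1), 0.05)
  expect_gt(polygon_area(ct2), 2 * sum(cres))  # much bigger than the band

  expect_error(hull_and_spline(matrix(FALSE, 8, 8)), "fewer than 3")
  collinear <- matrix(FALSE, 8, 8); collinear[3, 2:6] <- TRUE
  expect_error(hull_and_spline(collinear), "collinear|fewer")
})

test_that("pixel-to-mm conversion centres, scales and flips", {
  cal <- oct_calibration()
  ctr <- (1024 + 1) / 2
  px <- contour2d(rbind(c(ctr + 103, ctr), c(ctr, ctr + 103),
                        c(ctr - 103, ctr), c(ctr, ctr - 103)))
  mm <- pixels_to_mm(px, cal)
  d <- sqrt(rowSums(mm$xy^2))
  expect_equal(d, rep(1, 4), tolerance = 1e-12)
  # y axis flips: a point below the centre (larger row) has positive... the
  # point at row ctr+103 maps to y = -1
  expect_equal(sort(mm$xy[, 2]), c(-1, 0, 0, 1), tolerance = 1e-12)
  # full image width spans 1024/103 mm
  expect_equal(1024 / cal$px_per_mm, 9.9417, tolerance = 1e-4)
})

test_that("contour area scales as the inverse square of the pixel pitch", {
  fr <- small_frame()
  mask <- extract_annotation_mask(fr)
  ct_px <- hull_and_spline(mask)
  a1 <- polygon_area(pixels_to_mm(ct_px, oct_calibration(px_per_mm = 103),
                                  image_px = 256))
  a2 <- polygon_area(pixels_to_mm(ct_px, oct_calibration(px_per_mm = 206),
                                  image_px = 256))
  expect_equal(a1 / a2, 4, tolerance = 1e-9)
})

test_that("processing a pullback extracts calibrated contours per frame", {
  frames <- lapply(0:3, function(k) small_frame(0.5 + 0.1 * k, index = k,
                                                seed = k + 1))
  cal <- oct_calibration()
  series <- process_pullback(frames, cal)
  r_est <- theoretical_radius(vapply(series$contours, polygon_area, 0))
  expect_lt(max(abs(r_est - (0.5 + 0.1 * (0:3)))), 0.02)

  # skip_empty drops unusable frames but keeps original indices
  blank <- annotated_frame(array(0.2, c(256, 256, 3)), 2L)
  frames2 <- frames
  frames2[[3]] <- blank
  expect_error(process_pullback(frames2, cal), "frame 2")
  expect_warning(series2 <- process_pullback(frames2, cal, skip_empty = TRUE),
                 "skipping frame 2")
  expect_equal(series2$frame_indices, c(0L, 1L, 3L))

  allblank <- list(annotated_frame(array(0.2, c(64, 64, 3)), 0L),
                   annotated_frame(array(0.2, c(64, 64, 3)), 1L))
  expect_error(suppressWarnings(
    process_pullback(allblank, cal, skip_empty = TRUE)), "fewer than 2")
})

test_that("the extraction chain is idempotent under re-rendering", {
  cal <- oct_calibration()
  fr <- small_frame(0.8)
  ct1_px <- hull_and_spline(extract_annotation_mask(fr))
  ct1 <- pixels_to_mm(ct1_px, cal, image_px = 256)
  img2 <- corofuse:::render_frame_image(ct1, cal, 256L, c(0, 1, 0), 3L)
  ct2 <- pixels_to_mm(hull_and_spline(extract_annotation_mask(
    annotated_frame(img2, 1L))), cal, image_px = 256)
  # Hausdorff distance between the two passes below 2 px
  d12 <- RANN::nn2(ct1$xy, ct2$xy, k = 1)$nn.dists
  d21 <- RANN::nn2(ct2$xy, ct1$xy, k = 1)$nn.dists
  expect_lt(max(d12, d21), 2 / cal$px_per_mm)
})

test_that("contour archives round-trip through JSON", {
  series <- elliptical_series(c(0, 1, 2), spacing = 0.25)
  f <- withr::local_tempfile(fileext = ".json")
  write_contour_archive(series, f)
  s2 <- read_contour_archive(f)
  expect_equal(length(s2$contours), 3L)
  expect_equal(s2$calibration$frame_spacing_mm, 0.25)
  expect_equal(s2$contours[[2]]$xy, series$contours[[2]]$xy,
               tolerance = 1e-12)
})
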