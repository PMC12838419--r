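test_that("pairwise twist search finds the corrective rotation", {
  e <- ellipse_contour(2, 1)
  expect_equal(pairwise_twist_angle(e, e), 0)
  expect_equal(pairwise_twist_angle(e, rotate_contour(e, 2.0)), -2.0,
               tolerance = 1e-9)
  # rotationally symmetric contours tie at every angle: pick 0
  circ <- circle_contour(1, 128)
  expect_equal(pairwise_twist_angle(circ, circ), 0)
  # contours that never overlap fail loudly
  expect_error(pairwise_twist_angle(circ, translate_contour(circ, c(50, 0))),
               "do not overlap")
})

test_that("twist correction recovers a smooth injected profile", {
  inj <- smooth_twist(25, 1.2, seed = 21)
  series <- elliptical_series(inj)
  corrected <- correct_twist(series)
  # per-frame increments: estimated correction cancels the injected twist
  err <- abs(diff(corrected$twist_angles) + diff(inj))
  expect_lt(mean(err), 0.15)
  # the correction is rigid: areas and perimeters untouched
  a0 <- vapply(series$contours, polygon_area, 0)
  a1 <- vapply(corrected$contours, polygon_area, 0)
  p0 <- vapply(series$contours, polygon_perimeter, 0)
  p1 <- vapply(corrected$contours, polygon_perimeter, 0)
  expect_lt(max(abs(a1 / a0 - 1)), 1e-9)
  expect_lt(max(abs(p1 / p0 - 1)), 1e-9)
})

test_that("twist beyond the search window clamps at the boundary", {
  series <- elliptical_series(c(0, 5), offset = c(0, 0))
  expect_message(corrected <- correct_twist(series), "saturated")
  expect_equal(corrected$twist_angles[2], -3.0)
})

test_that("the carina registration point is the snapped projection midpoint", {
  cl <- centerline(cbind(1, 0, seq(0, 10, by = 0.5)))
  lm <- landmark_pair(0L, c(0.5, 0), c(0, 0, 5), c(2, 0, 5))
  reg <- carina_registration_point(lm, cl)
  expect_equal(reg$midpoint, c(1, 0, 5))
  expect_equal(reg$point, c(1, 0, 5))
  # a midpoint beyond the gate is a landmark mismatch
  lm2 <- landmark_pair(0L, c(0.5, 0), c(10, 0, 5), c(14, 0, 5))
  expect_error(carina_registration_point(lm2, cl), "gate")
  # identical projection points are rejected at construction
  expect_error(landmark_pair(0L, c(0, 0), c(1, 1, 1), c(1, 1, 1)),
               "distinct")
})

straight_stack_setup <- function(n_frames = 11, r = 1, spacing = 0.5) {
  cal <- oct_calibration(frame_spacing_mm = spacing)
  contours <- replicate(n_frames, circle_contour(r, 128), simplify = FALSE)
  series <- pullback_series(contours, cal)
  cl <- centerline(cbind(0, 0, seq(0, 30, by = 0.25)))
  k0 <- 5L
  z0 <- 10
  lm <- landmark_pair(k0, c(r, 0), c(0, 0, z0), c(2 * r, 0, z0))
  list(series = series, cl = cl, lm = lm, cal = cal, z0 = z0, k0 = k0)
}

test_that("a straight-centerline registration stacks parallel sections", {
  s <- straight_stack_setup()
  stack <- register_pullback(s$series, s$cl, s$lm)
  expect_length(stack$contours3d, 11L)
  zs <- vapply(stack$contours3d, function(ct) mean(ct$points[, 3]), 0)
  # exact frame spacing between consecutive sections
  expect_equal(diff(zs), rep(0.5, 10), tolerance = 1e-9)
  # landmark frame sits at the carina plane
  expect_equal(zs[s$k0 + 1], s$z0, tolerance = 1e-9)
  # each section orthogonal to the tangent and area preserved exactly
  for (ct in stack$contours3d) {
    spread <- max(ct$points[, 3]) - min(ct$points[, 3])
    expect_lt(spread, 1e-9)
    p2 <- contour2d(ct$points[, 1:2])
    expect_lt(abs(polygon_area(p2) / polygon_area(s$series$contours[[1]]) - 1),
              1e-9)
  }
  # round trip: centroids land on the centerline axis
  xy <- t(vapply(stack$contours3d, function(ct) colMeans(ct$points[, 1:2]), numeric(2)))
  expect_lt(max(abs(xy)), 1e-6)
})

test_that("frames that fall off the centerline are dropped with a warning", {
  s <- straight_stack_setup(n_frames = 61, spacing = 0.6)
  # 61 frames x 0.6 mm = 36 mm on a 30 mm centerline
  expect_warning(stack <- register_pullback(s$series, s$cl, s$lm),
                 "dropped")
  expect_lt(length(stack$contours3d), 61L)
  expect_error(register_pullback(s$series, s$cl,
                                 landmark_pair(99L, c(1, 0), c(0, 0, 10),
                                               c(2, 0, 10))),
               "not in series")
})

test_that("registration on a curved phantom lands centroids on the centerline", {
  spec <- phantom_spec(centerline_kind = "planar-arc", length_mm = 30,
                       base_radius_mm = 1.2, ellipticity = 1.25,
                       side_branches = list(c(12, 0.5, 70)),
                       noise_sd_mm = 0, twist_amplitude_deg = 0.3, seed = 9)
  ph <- build_phantom(spec)
  cal <- oct_calibration(frame_spacing_mm = 0.5)
  rp <- render_pullback(ph, cal, window = c(8, 18), image_px = 512,
                        catheter_offset_mm = c(0.2, 0.1))
  # analytic contours (skip the pixel chain here): raw view = truth + twist
  contours <- lapply(seq_along(rp$stations_mm), function(k)
    translate_contour(rotate_contour(phantom_section_contour(
      spec, rp$stations_mm[k]), rp$twist$cumulative_deg[k]), -c(0.2, 0.1)))
  series <- correct_twist(pullback_series(contours, cal))
  lm <- phantom_landmark(ph, rp, catheter_offset_mm = c(0.2, 0.1))
  stack <- register_pullback(series, ph$truth$centerline, lm)
  errs <- vapply(stack$contours3d, function(ct) {
    i <- ct$centerline_index
    sqrt(sum((colMeans(ct$points) - stack$centerline$points[i, ])^2))
  }, 0)
  expect_lt(max(errs), 0.2)
})

test_that("landmark files round-trip through JSON", {
  lm <- landmark_pair(7L, c(1.2, -0.3), c(1, 2, 3), c(4, 5, 6))
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm2, lm)
})
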