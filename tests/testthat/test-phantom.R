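test_that("phantom ground truth is analytic and consistent", {
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 30,
                       base_radius_mm = 1.5, stenoses = list(c(15, 0.5, 3)),
                       seed = 1)
  ph <- build_phantom(spec)
  expect_equal(ph$truth$true_pct_AS, 75)
  expect_equal(min(ph$truth$radii_mm), 0.75, tolerance = 1e-6)
  expect_true(is_watertight(ph$mesh))
  # no stenosis: zero severity
  ph0 <- build_phantom(phantom_spec(length_mm = 20, seed = 1))
  expect_equal(ph0$truth$true_pct_AS, 0)
  # branch bookkeeping mirrors the spec
  phb <- build_phantom(phantom_spec(length_mm = 60,
                                    side_branches = list(c(35, 0.6, 0),
                                                         c(51, 0.5, 120)),
                                    seed = 1))
  expect_equal(diff(phb$truth$branch_positions_mm), 16)
  expect_error(phantom_spec(side_branches = list(c(10, 0.5, 0),
                                                 c(10, 0.6, 90))),
               "overlapping")
  expect_error(phantom_spec(stenoses = list(c(10, 1.2, 3))), "depth")
})

test_that("the phantom mesh area profile matches the analytic radii", {
  spec <- phantom_spec(centerline_kind = "planar-arc", length_mm = 30,
                       base_radius_mm = 1.3, stenoses = list(c(14, 0.4, 3)),
                       ellipticity = 1.2, seed = 3)
  ph <- build_phantom(spec)
  cl <- resample_centerline(ph$truth$centerline, 1)
  prof <- lumen_area_profile(ph$mesh, cl)
  ok <- which(!is.na(prof$areas))
  ok <- ok[ok > 2 & ok < length(prof$areas) - 1]  # skip cap stations
  a_true <- pi * phantom_radius(spec, cl$arclength[ok])^2
  expect_lt(max(abs(prof$areas[ok] / a_true - 1)), 0.03)
})

test_that("rendered frames draw the border at the calibrated radius", {
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 10,
                       base_radius_mm = 1, ellipticity = 1,
                       noise_sd_mm = 0, twist_amplitude_deg = 0, seed = 6)
  ph <- build_phantom(spec)
  cal <- oct_calibration(frame_spacing_mm = 1)
  rp <- render_pullback(ph, cal, window = c(3, 7),
                        catheter_offset_mm = c(0, 0))
  fr <- rp$frames[[1]]
  mask <- extract_annotation_mask(fr)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- (1024 + 1) / 2
  rad <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
  expect_lt(abs(stats::median(rad) - 103), 2)
  # without twist or noise, consecutive frames of a constant section agree
  expect_equal(rp$frames[[1]]$image, rp$frames[[2]]$image, tolerance = 0.5)
  expect_identical(rp$twist$cumulative_deg, rep(0, 5))

  # a vessel wider than the field of view cannot be rendered
  big <- build_phantom(phantom_spec(length_mm = 10, base_radius_mm = 6,
                                    seed = 1))
  expect_error(render_pullback(big, cal, window = c(3, 7)),
               "field of view")
})

test_that("phantom datasets are deterministic under a fixed seed", {
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 10,
                       base_radius_mm = 0.8, ellipticity = 1.2, seed = 11)
  ph <- build_phantom(spec)
  cal <- oct_calibration(frame_spacing_mm = 1)
  r1 <- render_pullback(ph, cal, window = c(3, 6), image_px = 256,
                        catheter_offset_mm = c(0, 0))
  r2 <- render_pullback(ph, cal, window = c(3, 6), image_px = 256,
                        catheter_offset_mm = c(0, 0))
  expect_identical(r1$twist, r2$twist)
  expect_identical(r1$frames[[2]]$image, r2$frames[[2]]$image)
  c1 <- make_ccta_like_cloud(ph)
  c2 <- make_ccta_like_cloud(ph)
  expect_identical(c1$cloud$points, c2$cloud$points)
})

test_that("the CCTA-like cloud degrades the surface at the stated resolution", {
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 20,
                       base_radius_mm = 1.5, ellipticity = 1, seed = 8)
  ph <- build_phantom(spec)
  cc <- make_ccta_like_cloud(ph, resolution_mm = 0.4)
  pts <- cc$cloud$points
  mid <- pts[pts[, 3] > 3 & pts[, 3] < 17, , drop = FALSE]
  r_emp <- sqrt(mid[, 1]^2 + mid[, 2]^2)
  expect_lt(abs(mean(r_emp) - 1.5), 0.25)
  expect_true(all(cc$cloud$labels == "CCTA"))

  # resolution -> 0: the cloud converges to the surface
  dists <- vapply(c(0.4, 0.2, 0.1), function(res) {
    cl <- make_ccta_like_cloud(ph, resolution_mm = res)
    mean(abs(point_mesh_distance(cl$cloud$points, ph$mesh)))
  }, 0)
  expect_true(all(diff(dists) < 0))
})

test_that("synthetic blooming enlarges calcifications by the offset", {
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 20,
                       base_radius_mm = 1.5,
                       calcifications = list(c(10, 90, 0.6, 0.5)), seed = 12)
  ph <- build_phantom(spec)
  expect_length(ph$truth$calcifications, 1L)
  cm <- ph$truth$calcifications[[1]]
  expect_true(is_watertight(cm$mesh))
  cc <- make_ccta_like_cloud(ph)
  bl <- cc$bloomed_calcifications[[1]]
  # the bloomed surface sits ~0.5 mm outside the true calcification
  d <- point_mesh_distance(bl$mesh$vertices, cm$mesh, signed = TRUE)
  expect_equal(stats::median(d), 0.5, tolerance = 0.1)
  # and its section strictly contains the true section
  p <- plane(ph$truth$centerline$points[
    which.min(abs(ph$truth$centerline$arclength - 10)), ], c(0, 0, 1))
  a0 <- calc_cross_section(cm, p)$area
  a1 <- calc_cross_section(bl, p)$area
  expect_gt(a1, a0 + 0.5)
})

test_that("a full synthetic dataset lands on disk in open formats", {
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 12,
                       base_radius_mm = 1, ellipticity = 1.2,
                       side_branches = list(c(6, 0.45, 30)), seed = 14)
  dir <- withr::local_tempdir()
  ds <- write_phantom_dataset(spec, dir,
                              oct_calibration(frame_spacing_mm = 1))
  expect_true(file.exists(file.path(dir, "centerline.txt")))
  expect_true(file.exists(file.path(dir, "ccta_cloud.ply")))
  expect_true(file.exists(file.path(dir, "landmarks.json")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  frames <- list.files(file.path(dir, "frames"), pattern = "tif$")
  expect_gt(length(frames), 2L)
  # the written cloud reads back with normals for reconstruction
  cl <- read_point_cloud(file.path(dir, "ccta_cloud.ply"))
  expect_false(is.null(cl$normals))
})
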