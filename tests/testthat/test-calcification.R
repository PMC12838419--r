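test_that("inward contour offset erodes by the exact distance", {
  circ <- circle_contour(1.5, 360)
  s <- shrink_contour(circ, 0.5)
  expect_lt(abs(polygon_area(s) / pi - 1), 0.005)
  expect_equal(shrink_contour(circ, 0)$xy, circ$xy)

  # square side 2 eroded by 0.5 is the side-1 square (analytic, join-free)
  sq <- contour2d(cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)))
  expect_equal(polygon_area(shrink_contour(sq, 0.5)), 1, tolerance = 0.01)
  expect_equal(polygon_area(shrink_contour(sq, 0.5, join = "miter")), 1,
               tolerance = 0.01)

  expect_error(shrink_contour(circ, 1.6), "collapse")
})

test_that("erosion is anti-monotone and commutes with the radius for circles", {
  circ <- circle_contour(1.5, 360)
  areas <- vapply(c(0.1, 0.3, 0.5, 0.9), function(d)
    polygon_area(shrink_contour(circ, d)), 0)
  expect_true(all(diff(areas) < 0))
  for (d in c(0.2, 0.6)) {
    expect_lt(abs(theoretical_radius(polygon_area(shrink_contour(circ, d))) -
                    (1.5 - d)), 0.005)
  }
})

test_that("calcification cross-sections carry consistent metrics", {
  sp <- mesh_sphere(0.9, n_theta = 96, n_phi = 48)
  cm <- calcification_model(sp, bloom_offset_mm = 0.5)
  cs <- calc_cross_section(cm, plane(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(cs$theoretical_radius, 0.9, tolerance = 0.01)
  expect_equal(cs$area, pi * 0.81, tolerance = 0.02)
  # metrics recomputable from the stored contour
  expect_equal(cs$area, polygon_area(cs$contour), tolerance = 1e-9)
  expect_equal(cs$theoretical_radius, theoretical_radius(cs$area),
               tolerance = 1e-12)

  cs2 <- calc_cross_section(cm, plane(c(0, 0, 0), c(0, 0, 1)),
                            apply_bloom_correction = TRUE)
  expect_equal(cs2$theoretical_radius, 0.4, tolerance = 0.01)

  expect_error(calc_cross_section(cm, plane(c(0, 0, 5), c(0, 0, 1))),
               "does not intersect")
})

test_that("paired OCT/CCTA comparison reports CCTA-minus-OCT deltas", {
  # circles with the printed per-patient equal-area radii
  mk <- function(r) new_calc_cross_section(circle_contour(r, 720), "OCT")
  mkc <- function(r) new_calc_cross_section(circle_contour(r, 720), "CCTA")
  p7 <- compare_calc_contours(mk(0.68), mkc(0.86))
  expect_equal(p7$delta[p7$metric == "radius_mm"], 0.18, tolerance = 1e-3)
  p9 <- compare_calc_contours(mk(0.49), mkc(0.90))
  expect_equal(p9$delta[p9$metric == "radius_mm"], 0.41, tolerance = 1e-3)
  same <- compare_calc_contours(mk(0.7), mkc(0.7))
  expect_lt(max(abs(same$delta)), 1e-9)
})

test_that("blooming dilation then correction recovers the section area", {
  # smooth convex-ish blobs with curvature radius above the offset, so the
  # morphological closing is exact up to sampling
  for (seed in 1:5) {
    set.seed(seed)
    th <- seq(0, 2 * pi, length.out = 257)[-257]
    r0 <- runif(1, 0.8, 1.4)
    r <- r0 * (1 + 0.12 * sin(2 * th + runif(1, 0, 2 * pi)))
    blob <- contour2d(cbind(r * cos(th), r * sin(th)))
    bloomed <- grow_contour(blob, 0.5)
    recovered <- shrink_contour(bloomed, 0.5)
    expect_lt(abs(polygon_area(recovered) / polygon_area(blob) - 1), 0.05)
  }
})

test_that("3D inward offset inverts the synthetic blooming dilation", {
  sp <- mesh_sphere(0.4, n_theta = 64, n_phi = 32)
  bloomed <- offset_mesh(sp, 0.5, voxel_mm = 0.08)
  # bloomed section radius ~0.9 mirrors the clinical OCT/CCTA discrepancy
  cs <- calc_cross_section(calcification_model(bloomed, 0.5),
                           plane(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(cs$theoretical_radius, 0.9, tolerance = 0.03)
  corrected <- offset_mesh(bloomed, -0.5, voxel_mm = 0.08)
  expect_lt(abs(mesh_volume(corrected) / mesh_volume(sp) - 1), 0.1)
})

test_that("calcifications union into the wall solid", {
  cy <- mesh_cylinder(1.5, 10, n_theta = 48, n_axial = 21)
  wall <- add_wall(cy, fusion_config())
  # empty list: unchanged
  expect_identical(embed_calcifications(wall, list()), wall)

  calc <- calcification_model(mesh_sphere(0.8, center = c(2.0, 0, 5)),
                              bloom_offset_mm = 0)
  emb <- embed_calcifications(wall, list(calc), voxel_mm = 0.12,
                              correct_bloom = FALSE,
                              lumen_mesh = cy, wall_thickness_mm = 1)
  expect_true(is_watertight(emb))
  # Monte-Carlo union-volume oracle: wall solid = within 1 mm outside the
  # capped cylinder; sphere via its analytic equation
  set.seed(99)
  q <- cbind(runif(3e5, -3, 3), runif(3e5, -3, 3), runif(3e5, -1.5, 11.5))
  rxy <- sqrt(q[, 1]^2 + q[, 2]^2)
  # signed distance to the capped cylinder solid (r=1.5, z in [0,10])
  dr <- rxy - 1.5
  dz <- pmax(-q[, 3], q[, 3] - 10)
  outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
  d_solid <- ifelse(dr < 0 & dz < 0, pmax(dr, dz), outside)
  in_wall <- d_solid > 0 & d_solid <= 1
  in_sp <- (q[, 1] - 2)^2 + q[, 2]^2 + (q[, 3] - 5)^2 <= 0.8^2
  mc_vol <- mean(in_wall | in_sp) * 6 * 6 * 13
  expect_lt(abs(mesh_volume(emb) / mc_vol - 1), 0.03)

  # a calcification buried in the wall does not change the volume
  small <- calcification_model(mesh_sphere(0.3, center = c(2.0, 0, 5)),
                               bloom_offset_mm = 0)
  emb2 <- embed_calcifications(wall, list(small), voxel_mm = 0.12,
                               correct_bloom = FALSE,
                               lumen_mesh = cy, wall_thickness_mm = 1)
  mc_wall <- mean(in_wall) * 6 * 6 * 13
  expect_lt(abs(mesh_volume(emb2) / mc_wall - 1), 0.03)
})
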