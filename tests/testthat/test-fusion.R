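test_that("mesh sampling yields vertices plus area-proportional samples", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)),
                      rbind(c(1L, 2L, 3L)))  # area 1
  set.seed(5)
  pc <- mesh_to_point_cloud(tri, density = 100)
  expect_equal(nrow(pc$points), 3L + 100L)
  expect_true(all(pc$labels == "CCTA"))
  expect_lt(max(abs(pc$points[, 3])), 1e-12)  # samples lie on the face

  pc0 <- mesh_to_point_cloud(tri, density = 1e-4)
  expect_equal(nrow(pc0$points), 3L)

  cy <- mesh_cylinder(1, 5, n_theta = 48, n_axial = 10)
  pcc <- mesh_to_point_cloud(cy, density = 5)
  d <- abs(point_mesh_distance(pcc$points, cy))
  expect_lt(max(d), 1e-9)
  expect_error(mesh_to_point_cloud(surface_mesh(matrix(0, 1, 3),
                                                matrix(integer(0), 0, 3))),
               "empty mesh")
})

test_that("overlap removal matches the brute-force radius filter", {
  cfg <- fusion_config()
  for (seed in 1:3) {
    set.seed(seed)
    ccta <- labeled_point_cloud(matrix(runif(3 * 400, 0, 10), ncol = 3))
    oct <- labeled_point_cloud(matrix(runif(3 * 200, 0, 10), ncol = 3),
                               "OCT")
    got <- remove_overlapping_points(ccta, oct, cfg)
    # O(n*m) oracle
    dd <- as.matrix(stats::dist(rbind(ccta$points, oct$points)))
    dmin <- apply(dd[1:400, 401:600], 1L, min)
    keep <- dmin >= cfg$overlap_radius_mm
    expect_equal(got$points, ccta$points[keep, , drop = FALSE])
  }
})

test_that("overlap removal keeps a point exactly at the radius", {
  ccta <- labeled_point_cloud(rbind(c(0.35, 0, 0), c(0.3499, 0, 0),
                                    c(5, 5, 5)))
  oct <- labeled_point_cloud(rbind(c(0, 0, 0)), "OCT")
  got <- remove_overlapping_points(ccta, oct)
  expect_equal(nrow(got$points), 2L)
  expect_true(any(abs(got$points[, 1] - 0.35) < 1e-12))
  # empty OCT cloud: warning, CCTA unchanged
  expect_warning(
    same <- remove_overlapping_points(ccta, labeled_point_cloud(
      matrix(numeric(0), 0, 3), character(0))),
    "empty OCT")
  expect_equal(same$points, ccta$points)
})

test_that("overlap removal is monotone in the radius", {
  set.seed(8)
  ccta <- labeled_point_cloud(matrix(runif(900, 0, 5), ncol = 3))
  oct <- labeled_point_cloud(matrix(runif(300, 0, 5), ncol = 3), "OCT")
  prev <- NULL
  for (r in c(0.2, 0.35, 0.6, 1.0)) {
    res <- remove_overlapping_points(ccta, oct,
                                     fusion_config(overlap_radius_mm = r))
    if (!is.null(prev)) {
      # larger radius removes a superset: survivors are a subset
      key <- function(p) paste(p[, 1], p[, 2], p[, 3])
      expect_true(all(key(res$points) %in% key(prev$points)))
    }
    prev <- res
  }
})

test_that("region selection keeps or drops points exactly", {
  set.seed(10)
  pts <- matrix(runif(600, -3, 3), ncol = 3)
  cloud <- labeled_point_cloud(pts)
  inside <- sqrt(rowSums(pts^2)) <= 1
  dropped <- select_points_region(cloud, region_sphere(c(0, 0, 0), 1),
                                  keep = FALSE)
  expect_equal(dropped$points, pts[!inside, , drop = FALSE])
  kept <- select_points_region(cloud, region_box(c(-1, -1, -1), c(1, 1, 1)),
                               keep = TRUE)
  inb <- apply(abs(pts) <= 1, 1L, all)
  expect_equal(kept$points, pts[inb, , drop = FALSE])

  # tube region against a brute-force point-to-segment oracle
  cl <- centerline(cbind(0, 0, seq(-3, 3, by = 0.25)))
  tube <- select_points_region(cloud, region_tube(cl, c(10L, 20L), 1.5),
                               keep = FALSE)
  seg <- cl$points[10:20, ]
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(nrow(seg) - 1L), function(j) {
      a <- seg[j, ]; b <- seg[j + 1L, ]
      t <- max(0, min(1, sum((pts[i, ] - a) * (b - a)) / sum((b - a)^2)))
      sqrt(sum((pts[i, ] - (a + t * (b - a)))^2))
    }, 0))
  }, 0)
  expect_equal(tube$points, pts[oracle > 1.5, , drop = FALSE])

  expect_error(select_points_region(cloud, region_sphere(c(0, 0, 0), 100),
                                    keep = FALSE), "every point")
})

test_that("fusion concatenates clouds without moving points", {
  s <- local({
    cal <- oct_calibration(frame_spacing_mm = 0.5)
    contours <- replicate(5, circle_contour(1, 64), simplify = FALSE)
    series <- pullback_series(contours, cal)
    cl <- centerline(cbind(0, 0, seq(0, 10, by = 0.25)))
    lm <- landmark_pair(2L, c(1, 0), c(0, 0, 5), c(2, 0, 5))
    register_pullback(series, cl, lm)
  })
  ccta <- labeled_point_cloud(matrix(runif(300, -2, 2), ncol = 3))
  fused <- fuse_point_clouds(ccta, s)
  expect_equal(nrow(fused$points), 100L + 5L * 64L)
  expect_equal(sum(fused$labels == "OCT"), 5L * 64L)
  expect_equal(sum(fused$labels == "CCTA"), 100L)
  # no point moved: inputs appear verbatim
  expect_equal(fused$points[1:100, ], ccta$points)
  oct_pts <- do.call(rbind, lapply(s$contours3d, `[[`, "points"))
  expect_equal(fused$points[101:420, ], oct_pts)
})

test_that("implicit reconstruction recovers a cylinder from its cloud", {
  cy <- mesh_cylinder(1.5, 20, n_theta = 64, n_axial = 60)
  set.seed(12)
  pc <- mesh_to_point_cloud(cy, density = 30)
  m <- reconstruct_surface(pc, voxel_mm = 0.2)
  expect_true(is_watertight(m))
  a_true <- 2 * pi * 1.5 * 20 + 2 * pi * 1.5^2
  expect_lt(abs(mesh_area(m) / a_true - 1), 0.05)
  d <- point_mesh_distance(pc$points, m)
  expect_lt(mean(d), 0.1)
  # too few points is a precondition error
  expect_error(reconstruct_surface(labeled_point_cloud(
    matrix(runif(150), ncol = 3))), "at least 100")
})

test_that("reconstruction from contour stacks converges with the grid", {
  # rings of a circular tube, reconstructed at three grid refinements
  cl <- centerline(cbind(0, 0, seq(0, 10, by = 0.4)))
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  pts <- do.call(rbind, lapply(seq_len(nrow(cl$points)), function(i)
    cbind(1.5 * cos(th), 1.5 * sin(th), cl$points[i, 3])))
  nrm <- cbind(cos(th), sin(th), 0)[rep(1:96, nrow(cl$points)), ]
  cloud <- labeled_point_cloud(pts, "OCT", normals = nrm)
  errs <- vapply(c(0.8, 0.5, 0.3), function(h) {
    m <- reconstruct_surface(cloud, voxel_mm = h)
    prof <- lumen_area_profile(m, resample_centerline(cl, 1))
    r_est <- theoretical_radius(prof$areas[!is.na(prof$areas)])
    max(abs(r_est / 1.5 - 1))
  }, 0)
  # station radius within 2% at every refinement level; refining the grid
  # never makes it worse than the coarsest level (below ~0.5 mm the error
  # floor is the implicit-blend bias, not the grid)
  expect_true(all(errs < 0.02))
  expect_true(all(errs[-1] <= errs[1]))
})

test_that("the wall offset thickens a cylinder by the configured amount", {
  cy <- mesh_cylinder(1.5, 12, n_theta = 64, n_axial = 25)
  wall <- add_wall(cy, fusion_config(wall_thickness_mm = 1))
  sec <- plane_mesh_section(wall, plane(c(0, 0, 6), c(0, 0, 1)))
  areas <- sort(vapply(sec, polygon_area, 0))
  expect_length(sec, 2L)
  expect_lt(abs(theoretical_radius(areas[1]) / 1.5 - 1), 0.02)
  expect_lt(abs(theoretical_radius(areas[2]) / 2.5 - 1), 0.02)
  # the enclosed material volume equals the annulus volume (plus cap offset)
  expect_gt(mesh_volume(wall), pi * (2.5^2 - 1.5^2) * 12)
  expect_error(add_wall(mesh_tube(centerline(cbind(0, 0, c(0, 5))), 1,
                                  caps = FALSE)), "watertight")
})

test_that("labeled point clouds round-trip through PLY and text", {
  set.seed(13)
  cloud <- labeled_point_cloud(matrix(runif(60, -1, 1), ncol = 3),
                               rep(c("OCT", "CCTA"), 10),
                               normals = matrix(rep(c(1, 0, 0), 20),
                                                ncol = 3, byrow = TRUE))
  for (ext in c(".ply", ".txt")) {
    f <- withr::local_tempfile(fileext = ext)
    write_point_cloud(cloud, f)
    back <- read_point_cloud(f)
    expect_equal(back$points, cloud$points, tolerance = 1e-6)
    expect_equal(back$labels, cloud$labels)
  }
  # PLY carries normals
  f <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(cloud, f)
  expect_equal(read_point_cloud(f)$normals, cloud$normals,
               tolerance = 1e-6, ignore_attr = TRUE)
})
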