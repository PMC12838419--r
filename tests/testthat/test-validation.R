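test_that("percent area stenosis follows its definition exactly", {
  expect_equal(pct_area_stenosis(10, 2), 80)
  expect_equal(pct_area_stenosis(7, 7), 0)
  expect_error(pct_area_stenosis(5, 6), "exceeds")
  expect_error(pct_area_stenosis(0, 0), "positive")
  expect_error(pct_area_stenosis(5, -1), "non-negative")
  # scale invariance
  set.seed(31)
  for (rep in 1:10) {
    rva <- runif(1, 3, 12); mla <- runif(1, 0, rva); cc <- runif(1, 0.1, 50)
    expect_equal(pct_area_stenosis(rva, mla),
                 pct_area_stenosis(cc * rva, cc * mla), tolerance = 1e-12)
  }
})

test_that("MLA and the proximal reference are found in a profile", {
  prof <- area_profile(c(7, 7, 7, 2, 6, 7))
  st <- stenosis_from_profile(prof)
  expect_equal(st$MLA, 2)
  expect_equal(st$mla_index, 4L)
  expect_equal(st$RVA, 7)
  expect_equal(st$pct_AS, 5 / 7 * 100, tolerance = 1e-9)

  # MLA at the proximal end leaves no reference segment
  expect_error(stenosis_from_profile(area_profile(c(2, 3, 4, 5, 6, 7))),
               "proximal")
  # constant profile: zero stenosis
  expect_equal(stenosis_from_profile(area_profile(rep(5, 8)))$pct_AS, 0)
  expect_error(stenosis_from_profile(area_profile(c(1, 2, 3))), "at least 5")
})

test_that("z-scores are normalised and affine-invariant", {
  set.seed(33)
  a <- runif(40, 3, 9)
  pr <- area_profile(a)
  expect_lt(abs(mean(pr$zscores)), 1e-9)
  expect_lt(abs(sqrt(mean((pr$zscores - mean(pr$zscores))^2)) - 1), 1e-9)
  for (rep in 1:5) {
    shift <- runif(1, -2, 2); scale <- runif(1, 0.3, 3)
    pr2 <- area_profile(a * scale + shift)
    expect_lt(max(abs(pr2$zscores - pr$zscores)), 1e-9)
  }
})

test_that("lumen area profiles section the model perpendicular to the centerline", {
  cy <- mesh_cylinder(1, 20, n_theta = 96, n_axial = 40)
  cl <- resample_centerline(centerline(cbind(0, 0, c(1, 19))), 1)
  prof <- lumen_area_profile(cy, cl)
  expect_lt(max(abs(prof$areas / pi - 1)), 0.01)
  expect_lt(max(abs(prof$zscores), na.rm = TRUE), 3)  # no structure, noise only

  # a centerline extending past the mesh yields missing stations, not zeros
  cl2 <- resample_centerline(centerline(cbind(0, 0, c(1, 30))), 1)
  prof2 <- lumen_area_profile(cy, cl2)
  expect_true(anyNA(prof2$areas))
  expect_false(any(prof2$areas == 0, na.rm = TRUE))

  # stenosed phantom: area minimum lands at the throat
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 30,
                       base_radius_mm = 1.5, stenoses = list(c(15, 0.5, 3)),
                       ellipticity = 1, seed = 2)
  ph <- build_phantom(spec)
  clp <- resample_centerline(ph$truth$centerline, 0.5)
  prof3 <- lumen_area_profile(ph$mesh, clp)
  mla_i <- which.min(prof3$areas)
  expect_lt(abs(clp$arclength[mla_i] - 15), 0.5 + 1e-9)
})

test_that("vertex distances are point-to-surface with strict exclusion", {
  # sparse plane patch, translated along its normal by 0.20 mm
  g <- expand.grid(x = seq(0, 10, by = 1), y = seq(0, 10, by = 1))
  nv <- nrow(g)
  verts <- cbind(g$x, g$y, 0)
  ij <- matrix(seq_len(nv), 11, 11)
  f <- list()
  for (i in 1:10) for (j in 1:10) {
    f[[length(f) + 1L]] <- c(ij[i, j], ij[i + 1, j], ij[i + 1, j + 1])
    f[[length(f) + 1L]] <- c(ij[i, j], ij[i + 1, j + 1], ij[i, j + 1])
  }
  om <- surface_mesh(verts, do.call(rbind, f))
  dm <- om
  dm$vertices[, 3] <- 0.20
  vd <- vertex_distance_stats(dm, om)
  expect_equal(vd$median, 0.20, tolerance = 1e-6)
  expect_equal(vd$iqr, c(0.20, 0.20), tolerance = 1e-6)
  # raising the exclusion threshold never lowers the median
  meds <- vapply(c(0, 0.05, 0.1), function(ex)
    vertex_distance_stats(dm, om, validation_config(ex))$median, 0)
  expect_true(all(diff(meds) >= 0))
  # identical meshes: everything excluded, flagged degenerate
  vd0 <- vertex_distance_stats(om, om)
  expect_true(vd0$degenerate)
  expect_true(is.na(vd0$median))
})

test_that("vertex distances capture a radial cylinder offset", {
  om <- mesh_cylinder(1.5, 10, n_theta = 64, n_axial = 20, caps = FALSE)
  om <- fill_holes(om)
  dm <- mesh_cylinder(1.6, 10, n_theta = 64, n_axial = 20, caps = FALSE)
  dm <- fill_holes(dm)
  vd <- vertex_distance_stats(dm, om)
  expect_equal(vd$median, 0.1, tolerance = 0.01)
  # invariance under a joint rigid motion
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  vd2 <- vertex_distance_stats(transform_mesh(dm, R, c(3, -2, 7)),
                               transform_mesh(om, R, c(3, -2, 7)))
  expect_equal(vd2$median, vd$median, tolerance = 1e-9)
})

test_that("area differences and z-comparison behave under affine changes", {
  set.seed(35)
  a <- runif(30, 4, 9)
  om <- area_profile(a)
  dm_same <- area_profile(a)
  s0 <- area_difference_stats(om, dm_same)
  expect_equal(s0$ad_median, 0)
  expect_equal(s0$zdiff_mean, 0)

  dm_shift <- area_profile(a + 0.5)
  s1 <- area_difference_stats(om, dm_shift)
  expect_equal(s1$ad_median, 0.5, tolerance = 1e-12)
  expect_lt(s1$zdiff_mean, 1e-9)

  dm_scale <- area_profile(a * 1.2)
  s2 <- area_difference_stats(om, dm_scale)
  expect_lt(s2$zdiff_mean, 1e-9)

  expect_error(area_difference_stats(om, area_profile(c(1, 2, 3))),
               "shared")
})

test_that("regression summary matches the normal equations", {
  r <- regression_slope_r2(1:10, 1:10)
  expect_equal(r$slope, 1); expect_equal(r$r_squared, 1)
  r2 <- regression_slope_r2(1:10, 2 * (1:10) + 1)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)

  set.seed(37)
  x <- runif(10); y <- 0.8 * x + rnorm(10, sd = 0.1)
  got <- regression_slope_r2(x, y)
  # closed-form normal equations oracle
  sl <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  ic <- mean(y) - sl * mean(x)
  expect_equal(got$slope, sl, tolerance = 1e-12)
  expect_equal(got$intercept, ic, tolerance = 1e-12)
  expect_error(regression_slope_r2(rep(1, 5), 1:5), "constant")
})

test_that("side-branch separations follow frame spacing", {
  series <- elliptical_series(rep(0, 100), spacing = 0.2)
  expect_equal(side_branch_distance(series, 10, 80), 14)
  expect_error(side_branch_distance(series, 10, 10), "differ")
  expect_error(side_branch_distance(series, 10, 500), "out of range")
})

test_that("model-versus-model validation assembles a coherent report", {
  spec <- phantom_spec(centerline_kind = "straight", length_mm = 20,
                       base_radius_mm = 1.4, stenoses = list(c(10, 0.4, 2.5)),
                       ellipticity = 1, seed = 4)
  ph <- build_phantom(spec)
  om <- ph$mesh
  dm <- om
  dm$vertices <- dm$vertices * 1.02  # 2% printing-style scale error
  rep <- validate_models(om, dm, ph$truth$centerline, spacing_mm = 1)
  expect_false(rep$vd_degenerate)
  expect_gt(rep$vd_median, 0)
  expect_gt(rep$r_squared, 0.98)  # same profile shape up to scale
  expect_lt(abs(rep$stenosis_om$pct_AS - rep$stenosis_dm$pct_AS), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(rep, f)
  got <- utils::read.csv(f)
  expect_equal(got$vd_median_mm, rep$vd_median, tolerance = 1e-9)

  f2 <- withr::local_tempfile(fileext = ".ply")
  write_distance_heatmap(dm, rep$per_vertex_distances, f2)
  expect_true(any(grepl("quality", readLines(f2, n = 12))))
})
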