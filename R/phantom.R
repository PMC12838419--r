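#' Synthetic coronary phantom specification
#'
#' Fully parametric vessel used to exercise every pipeline stage with known
#' ground truth: a centerline of chosen shape, a Gaussian-stenosis radius
#' profile, optional side branches and wall calcifications, an injected
#' per-frame catheter twist and contour noise. Everything is deterministic
#' under `seed`.
#'
#' The lumen radius along arc length s is
#' `r(s) = base_radius * (1 - sum(depth_i * exp(-(s - pos_i)^2 / (2 w_i^2))))`
#' so the true stenosis severity is analytic:
#' `%AS = (1 - (r_throat / base_radius)^2) * 100`.
#'
#' @param centerline_kind one of `"straight"`, `"planar-arc"`, `"helix"`,
#'   `"spline-through-points"`.
#' @param length_mm vessel length (default 75, a typical pullback travel).
#' @param base_radius_mm healthy lumen radius.
#' @param stenoses list of `c(position_mm, depth_fraction, width_mm)`
#'   Gaussian narrowings (depth in `[0, 1)`).
#' @param ellipticity cross-section axis ratio (area-preserving; 1 =
#'   circular). Twist recovery needs some ellipticity to grip on.
#' @param side_branches list of `c(position_mm, radius_mm, angle_deg)`.
#' @param calcifications list of `c(position_mm, extent_deg, thickness_mm,
#'   bloom_mm)` wall calcifications.
#' @param twist_amplitude_deg bound on the per-frame injected twist
#'   increment (degrees/frame); the profile itself is a smooth seeded
#'   sinusoid generated at render time.
#' @param noise_sd_mm radial contour noise at render time.
#' @param curvature_radius_mm bend radius for `"planar-arc"` / `"helix"`.
#' @param waypoints optional k x 3 matrix for
#'   `"spline-through-points"`.
#' @param seed integer seed controlling every random element.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(centerline_kind = c("straight", "planar-arc",
                                             "helix",
                                             "spline-through-points"),
                         length_mm = 75, base_radius_mm = 1.5,
                         stenoses = list(), ellipticity = 1.25,
                         side_branches = list(), calcifications = list(),
                         twist_amplitude_deg = 0.5, noise_sd_mm = 0.01,
                         curvature_radius_mm = 60, waypoints = NULL,
                         seed = 1L) {
  centerline_kind <- match.arg(centerline_kind)
  stopifnot(length_mm > 0, base_radius_mm > 0, ellipticity >= 1,
            twist_amplitude_deg >= 0, noise_sd_mm >= 0)
  for (st in stenoses) {
    if (length(st) != 3L || st[2L] < 0 || st[2L] >= 1 || st[3L] <= 0) {
      stop("phantom_spec: each stenosis is c(position, depth in [0,1), width)",
           call. = FALSE)
    }
  }
  if (length(side_branches) > 1L) {
    pos <- vapply(side_branches, `[`, numeric(1), 1L)
    if (any(duplicated(pos))) {
      stop("phantom_spec: overlapping side branches at the same position",
           call. = FALSE)
    }
  }
  for (br in side_branches) {
    if (length(br) != 3L || br[2L] <= 0) {
      stop("phantom_spec: each branch is c(position, radius, angle)",
           call. = FALSE)
    }
  }
  structure(list(centerline_kind = centerline_kind, length_mm = length_mm,
                 base_radius_mm = base_radius_mm, stenoses = stenoses,
                 ellipticity = ellipticity, side_branches = side_branches,
                 calcifications = calcifications,
                 twist_amplitude_deg = twist_amplitude_deg,
                 noise_sd_mm = noise_sd_mm,
                 curvature_radius_mm = curvature_radius_mm,
                 waypoints = waypoints, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Shipped phantom presets
#'
#' Two headline scenarios: `"patient12-like"` (severe 89 %AS stenosis, no
#' calcification) and `"patient7-like"` (80 %AS with a calcified plaque).
#' The labels mirror clinical scenario archetypes, not any reproduction of
#' patient geometry. Both carry two side branches 16 mm apart.
#'
#' @param preset preset name.
#' @param seed seed forwarded to [phantom_spec].
#' @return a [phantom_spec].
#' @export
phantom_preset <- function(preset = c("patient12-like", "patient7-like"),
                           seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "patient12-like" = phantom_spec(
      centerline_kind = "planar-arc", length_mm = 70, base_radius_mm = 1.7,
      stenoses = list(c(35, 1 - sqrt(0.11), 3.5)),
      ellipticity = 1.3,
      side_branches = list(c(27, 0.7, 40), c(43, 0.6, 150)),
      seed = seed),
    "patient7-like" = phantom_spec(
      centerline_kind = "planar-arc", length_mm = 65, base_radius_mm = 1.6,
      stenoses = list(c(32, 1 - sqrt(0.2), 4)),
      ellipticity = 1.25,
      side_branches = list(c(24, 0.65, 60), c(40, 0.6, 200)),
      calcifications = list(c(32, 100, 0.8, 0.5)),
      seed = seed))
}

# centerline point at arc length s for each kind (vectorised over s)
phantom_centerline_points <- function(spec, s) {
  switch(spec$centerline_kind,
    straight = cbind(0, 0, s),
    "planar-arc" = {
      R <- spec$curvature_radius_mm
      th <- s / R
      cbind(R * (1 - cos(th)), 0, R * sin(th))
    },
    helix = {
      R <- spec$curvature_radius_mm
      pitch <- spec$length_mm / 3
      c1 <- sqrt(1 / (1 + (pitch / (2 * pi * R))^2))
      th <- s * c1 / R
      cbind(R * (1 - cos(th)), pitch * th / (2 * pi), R * sin(th))
    },
    "spline-through-points" = {
      wp <- spec$waypoints
      if (is.null(wp)) stop("phantom: waypoints required", call. = FALSE)
      # chord-length parameterised natural splines through the waypoints,
      # then arc-length reparameterised numerically
      tt <- c(0, cumsum(sqrt(rowSums(diff(wp)^2))))
      dense <- seq(0, max(tt), length.out = 2000L)
      dp <- vapply(1:3, function(k)
        stats::spline(tt, wp[, k], xout = dense)$y, numeric(2000L))
      sl <- c(0, cumsum(sqrt(rowSums(diff(dp)^2))))
      vapply(1:3, function(k)
        stats::approx(sl, dp[, k], xout = pmin(s, max(sl)))$y,
        numeric(length(s)))
    })
}

#' True lumen radius profile of a phantom
#'
#' @param spec a [phantom_spec].
#' @param s arc-length positions (mm).
#' @return equal-area lumen radius at each position (mm).
#' @export
phantom_radius <- function(spec, s) {
  r <- rep(spec$base_radius_mm, length(s))
  shrink <- 0
  for (st in spec$stenoses) {
    shrink <- shrink + st[2L] * exp(-(s - st[1L])^2 / (2 * st[3L]^2))
  }
  spec$base_radius_mm * (1 - shrink)
}

#' Build a synthetic phantom lumen mesh with ground truth
#'
#' Lofts elliptical cross-sections along the spec's centerline with the
#' analytic radius profile, attaches side-branch tubes and calcification
#' slabs, and returns the mesh together with a `phantom_truth` record
#' (centerline, analytic area profile, true stenosis severity, branch
#' positions, calcification models).
#'
#' @param spec a [phantom_spec].
#' @param section_spacing_mm loft sampling along the vessel.
#' @param n_theta circumferential mesh resolution.
#' @return list with `mesh` ([surface_mesh]) and `truth` (class
#'   `phantom_truth`).
#' @export
build_phantom <- function(spec, section_spacing_mm = 0.25, n_theta = 64L) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- seq(0, spec$length_mm, by = section_spacing_mm)
  cl <- centerline(phantom_centerline_points(spec, s))
  radii <- phantom_radius(spec, cl$arclength)
  main <- mesh_tube(cl, radii, n_theta = n_theta,
                    ellipticity = spec$ellipticity)
  parts <- list(main)
  branch_pos <- numeric(0)
  for (br in spec$side_branches) {
    bp <- branch_geometry(spec, cl, br)
    parts[[length(parts) + 1L]] <- bp$mesh
    branch_pos <- c(branch_pos, br[1L])
  }
  calcs <- list()
  for (ca in spec$calcifications) {
    calcs[[length(calcs) + 1L]] <- calcification_model(
      phantom_calc_mesh(spec, cl, ca), bloom_offset_mm = ca[4L])
  }
  mesh <- if (length(parts) > 1L) merge_meshes(parts) else main
  a_true <- pi * radii^2
  throat <- min(radii)
  truth <- structure(list(
    centerline = cl,
    area_profile = area_profile(a_true, seq_along(a_true)),
    stations_mm = cl$arclength,
    radii_mm = radii,
    true_pct_AS = (1 - (throat / spec$base_radius_mm)^2) * 100,
    branch_positions_mm = branch_pos,
    calcifications = calcs,
    spec = spec), class = "phantom_truth")
  list(mesh = mesh, truth = truth)
}

# side-branch tube mesh and direction at its ostium
branch_geometry <- function(spec, cl, br, length_mm = 6, n_theta = 32L) {
  i <- which.min(abs(cl$arclength - br[1L]))
  ang <- br[3L] * pi / 180
  e1 <- cl$frames$normal[i, ]; e2 <- cl$frames$binormal[i, ]
  tang <- cl$frames$tangent[i, ]
  # mostly radial take-off, tilted 35 degrees distally
  dir <- normalize3(cos(ang) * e1 + sin(ang) * e2 + tan(35 * pi / 180) * tang)
  s_b <- seq(0, length_mm, by = 0.5)
  pts <- sweep(outer(s_b, dir), 2L, cl$points[i, ], `+`)
  bcl <- centerline(pts)
  list(mesh = mesh_tube(bcl, br[2L], n_theta = n_theta), direction = dir,
       ostium_index = i)
}

# curved calcification slab embedded in the wall just outside the lumen
phantom_calc_mesh <- function(spec, cl, ca, axial_mm = 3, gap_mm = 0.05,
                              ns = 13L, nt = 17L) {
  pos <- ca[1L]; extent <- ca[2L] * pi / 180; thick <- ca[3L]
  s_lo <- pos - axial_mm / 2; s_hi <- pos + axial_mm / 2
  svals <- seq(s_lo, s_hi, length.out = ns)
  th0 <- 0
  tvals <- seq(th0, th0 + extent, length.out = nt)
  inner <- matrix(0, ns * nt, 3L); outer_v <- inner
  for (i in seq_len(ns)) {
    ii <- which.min(abs(cl$arclength - svals[i]))
    r_in <- phantom_radius(spec, svals[i]) + gap_mm
    e1 <- cl$frames$normal[ii, ]; e2 <- cl$frames$binormal[ii, ]
    ori <- cl$points[ii, ]
    # taper the slab ends so the solid stays smooth
    tap <- sin(pi * (i - 1) / (ns - 1))^0.5
    r_out <- r_in + pmax(thick * tap, 0.05)
    for (j in seq_len(nt)) {
      d <- cos(tvals[j]) * e1 + sin(tvals[j]) * e2
      inner[(i - 1L) * nt + j, ] <- ori + r_in * d
      outer_v[(i - 1L) * nt + j, ] <- ori + r_out * d
    }
  }
  grid_slab_mesh(inner, outer_v, ns, nt)
}

# watertight slab between two (ns x nt) grids of matching topology
grid_slab_mesh <- function(inner, outer_v, ns, nt) {
  v <- rbind(inner, outer_v)
  off <- ns * nt
  id <- function(i, j, layer) (layer - 1L) * off + (i - 1L) * nt + j
  f <- list()
  quad <- function(a, b, cc, d) rbind(c(a, b, cc), c(a, cc, d))
  for (i in seq_len(ns - 1L)) {
    for (j in seq_len(nt - 1L)) {
      f[[length(f) + 1L]] <- quad(id(i, j, 1L), id(i + 1L, j, 1L),
                                  id(i + 1L, j + 1L, 1L), id(i, j + 1L, 1L))
      f[[length(f) + 1L]] <- quad(id(i, j, 2L), id(i, j + 1L, 2L),
                                  id(i + 1L, j + 1L, 2L), id(i + 1L, j, 2L))
    }
  }
  for (i in seq_len(ns - 1L)) {  # angular side walls
    f[[length(f) + 1L]] <- quad(id(i, 1L, 1L), id(i, 1L, 2L),
                                id(i + 1L, 1L, 2L), id(i + 1L, 1L, 1L))
    f[[length(f) + 1L]] <- quad(id(i, nt, 1L), id(i + 1L, nt, 1L),
                                id(i + 1L, nt, 2L), id(i, nt, 2L))
  }
  for (j in seq_len(nt - 1L)) {  # axial end walls
    f[[length(f) + 1L]] <- quad(id(1L, j, 1L), id(1L, j + 1L, 1L),
                                id(1L, j + 1L, 2L), id(1L, j, 2L))
    f[[length(f) + 1L]] <- quad(id(ns, j, 1L), id(ns, j, 2L),
                                id(ns, j + 1L, 2L), id(ns, j + 1L, 1L))
  }
  orient_mesh(surface_mesh(v, do.call(rbind, f)))
}

#' Analytic lumen contour of a phantom cross-section
#'
#' The noiseless, untwisted section at arc length `s_mm` in the local frame
#' (catheter at centerline): an area-preserving ellipse of equal-area radius
#' `phantom_radius(spec, s_mm)`.
#'
#' @param spec a [phantom_spec].
#' @param s_mm station along the vessel.
#' @param n number of contour points.
#' @return a [contour2d].
#' @export
phantom_section_contour <- function(spec, s_mm, n = 256L) {
  r <- phantom_radius(spec, s_mm)
  e <- spec$ellipticity
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour2d(cbind(r * sqrt(e) * cos(th), r / sqrt(e) * sin(th)))
}

#' Generate a smooth seeded twist profile
#'
#' Cumulative catheter twist over `n_frames` whose per-frame increments are
#' a smooth sinusoid bounded by `amplitude_deg`.
#'
#' @param n_frames number of frames.
#' @param amplitude_deg per-frame increment bound (degrees).
#' @param seed integer seed.
#' @return list with `cumulative_deg` and `increment_deg` (length
#'   `n_frames`; first increment 0).
#' @export
phantom_twist_profile <- function(n_frames, amplitude_deg, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  amp <- stats::runif(1, 0.4, 1) * amplitude_deg
  period <- stats::runif(1, 15, 40)
  phase <- stats::runif(1, 0, 2 * pi)
  inc <- c(0, amp * sin(2 * pi * seq_len(n_frames - 1L) / period + phase))
  list(cumulative_deg = cumsum(inc), increment_deg = inc)
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, globalenv())
}

#' Render a phantom pullback as annotated pseudo-OCT frames
#'
#' For each frame station the analytic lumen section (plus seeded radial
#' noise) is rotated by the injected twist profile, offset by the catheter
#' position and drawn as a closed border in the annotation colour over a
#' multiplicative-speckle background with a bright catheter ring — enough
#' texture to stress the colour thresholding without modelling OCT physics.
#'
#' @param phantom output of [build_phantom].
#' @param cal an [oct_calibration].
#' @param window length-2 arc-length range imaged (mm); default the central
#'   stretch covering all stenoses and branches.
#' @param image_px frame size (default 1024).
#' @param catheter_offset_mm in-frame catheter offset (x, y).
#' @param annotation_color border colour.
#' @param line_px border thickness in px.
#' @param frame_sink optional `function(frame, k)` consuming each rendered
#'   [annotated_frame] as it is produced (e.g. writing it to disk); when
#'   given, frames are not accumulated in memory and `frames` is empty.
#' @return list with `frames` (list of [annotated_frame]), `stations_mm`,
#'   `twist` (injected profile), `truth_contours` (per-frame noiseless
#'   [contour2d] in corrected frame coordinates), `window`.
#' @export
render_pullback <- function(phantom, cal = oct_calibration(),
                            window = NULL, image_px = 1024L,
                            catheter_offset_mm = c(0.25, 0.1),
                            annotation_color = c(0, 1, 0), line_px = 3L,
                            frame_sink = NULL) {
  spec <- phantom$truth$spec
  if (is.null(window)) {
    feat <- c(vapply(spec$stenoses, `[`, numeric(1), 1L),
              spec$side_branches |> vapply(`[`, numeric(1), 1L))
    if (length(feat) == 0L) feat <- spec$length_mm / 2
    window <- c(max(0, min(feat) - 5), min(spec$length_mm, max(feat) + 5))
  }
  spacing <- cal$frame_spacing_mm
  stations <- seq(window[1L], window[2L], by = spacing)
  n <- length(stations)
  fov_mm <- image_px / (2 * cal$px_per_mm)
  rmax <- max(phantom_radius(spec, stations)) * sqrt(spec$ellipticity)
  if (rmax + max(abs(catheter_offset_mm)) >= fov_mm) {
    stop(sprintf(
      "render_pullback: section radius %.2f mm exceeds the %.2f mm field of view",
      rmax, fov_mm), call. = FALSE)
  }
  tw <- phantom_twist_profile(n, spec$twist_amplitude_deg, spec$seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed + 1L)
  frames <- vector("list", n)
  truth_contours <- vector("list", n)
  for (k in seq_len(n)) {
    base <- phantom_section_contour(spec, stations[k])
    truth_contours[[k]] <- translate_contour(base, -catheter_offset_mm)
    noisy <- if (spec$noise_sd_mm > 0) {
      xy <- base$xy
      nn <- nrow(xy)
      rad <- sqrt(rowSums(xy^2))
      pert <- stats::rnorm(nn, sd = spec$noise_sd_mm)
      # correlate the noise along the border so it stays smooth
      pert <- stats::filter(c(pert[(nn - 4L):nn], pert, pert[1:5]),
                            rep(1 / 11, 11L))[5L + seq_len(nn)]
      contour2d(xy * (1 + pert / rad))
    } else base
    # catheter twist rotates the image about the catheter axis (the origin
    # of frame coordinates), after centring on the catheter
    view <- rotate_contour(translate_contour(noisy, -catheter_offset_mm),
                           tw$cumulative_deg[k])
    fr <- annotated_frame(
      render_frame_image(view, cal, image_px, annotation_color, line_px),
      frame_index = k - 1L, annotation_color = annotation_color)
    if (is.null(frame_sink)) frames[[k]] <- fr else frame_sink(fr, k)
  }
  list(frames = if (is.null(frame_sink)) frames else list(),
       stations_mm = stations, twist = tw,
       truth_contours = truth_contours, window = window)
}

# draw a contour (mm, catheter at origin) as a coloured border over speckle
render_frame_image <- function(contour, cal, image_px, color, line_px) {
  ctr <- (image_px + 1) / 2
  img <- array(0, c(image_px, image_px, 3L))
  speckle <- matrix(stats::runif(image_px * image_px, 0, 0.35),
                    image_px, image_px)
  # bright catheter ring around the image centre
  ring_r <- 0.45 * cal$px_per_mm
  band <- ceiling(ring_r + 3)
  rows <- round(ctr) + (-band:band)
  cols <- rows
  rr <- outer(rows - ctr, cols * 0 + 1)
  cc <- outer(rows * 0 + 1, cols - ctr)
  dd <- sqrt(rr^2 + cc^2)
  ring <- exp(-((dd - ring_r)^2) / 8) * 0.6
  speckle[rows, cols] <- pmin(1, speckle[rows, cols] + ring)
  for (ch in 1:3) img[, , ch] <- speckle
  # rasterise the border: dense samples along the polyline, thickened
  xy <- contour$xy
  n <- nrow(xy)
  seg <- rbind(xy, xy[1L, ])
  dens <- max(2000L, n * 8L)
  tpar <- seq(0, n, length.out = dens)
  i0 <- pmin(floor(tpar) + 1L, n)
  frac <- tpar - (i0 - 1L)
  px <- seg[i0, 1L] + frac * (seg[i0 + 1L, 1L] - seg[i0, 1L])
  py <- seg[i0, 2L] + frac * (seg[i0 + 1L, 2L] - seg[i0, 2L])
  col_px <- round(ctr + px * cal$px_per_mm)
  row_px <- round(ctr - py * cal$px_per_mm)
  half <- floor(line_px / 2)
  offs <- expand.grid(dr = -half:half, dc = -half:half)
  r <- rep(row_px, nrow(offs)) + rep(offs$dr, each = length(row_px))
  cpx <- rep(col_px, nrow(offs)) + rep(offs$dc, each = length(col_px))
  ok <- r >= 1 & r <= image_px & cpx >= 1 & cpx <= image_px
  lin <- (cpx[ok] - 1L) * image_px + r[ok]
  npix <- image_px * image_px
  img[lin] <- color[1L]
  img[lin + npix] <- color[2L]
  img[lin + 2 * npix] <- color[3L]
  img
}

#' CCTA-like point cloud of a phantom
#'
#' Emulates the resolution limit of CCTA: the lumen surface is sampled,
#' coordinates are quantised to the scanner resolution and radial noise of
#' half the resolution is added. Calcification meshes are dilated by their
#' blooming offset to emulate the CT blooming artifact.
#'
#' @param phantom output of [build_phantom].
#' @param resolution_mm CCTA voxel pitch (default 0.4 mm).
#' @param density surface samples per mm^2.
#' @return list with `cloud` (a [labeled_point_cloud]) and
#'   `bloomed_calcifications` (list of [calcification_model] with enlarged
#'   meshes and the matching correction offset).
#' @export
make_ccta_like_cloud <- function(phantom, resolution_mm = 0.4, density = 10) {
  stopifnot(resolution_mm > 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(phantom$truth$spec$seed + 2L)
  pc <- mesh_to_point_cloud(phantom$mesh, density = density)
  q <- round(pc$points / resolution_mm) * resolution_mm
  q <- q + pc$normals * stats::rnorm(nrow(q), sd = resolution_mm / 2)
  bloomed <- lapply(phantom$truth$calcifications, function(cm) {
    if (cm$bloom_offset_mm > 0) {
      calcification_model(offset_mesh(cm$mesh, cm$bloom_offset_mm,
                                      voxel_mm = 0.1),
                          bloom_offset_mm = cm$bloom_offset_mm)
    } else cm
  })
  list(cloud = labeled_point_cloud(q, "CCTA", normals = pc$normals),
       bloomed_calcifications = bloomed)
}

#' Ground-truth landmark for a phantom side branch
#'
#' Builds the [landmark_pair] a user would have annotated for a given side
#' branch: the OCT frame nearest the branch ostium with the carina point at
#' the lumen border in the branch direction, and CCTA projection points on
#' the main and side branch whose midpoint falls on the ostium.
#'
#' @param phantom output of [build_phantom].
#' @param render output of [render_pullback] (for stations and twist).
#' @param branch which side branch (index into the spec's list).
#' @param catheter_offset_mm offset used at render time.
#' @return a [landmark_pair].
#' @export
phantom_landmark <- function(phantom, render, branch = 1L,
                             catheter_offset_mm = c(0.25, 0.1)) {
  spec <- phantom$truth$spec
  cl <- phantom$truth$centerline
  br <- spec$side_branches[[branch]]
  bg <- branch_geometry(spec, cl, br)
  k <- which.min(abs(render$stations_mm - br[1L]))
  s_k <- render$stations_mm[k]
  i <- which.min(abs(cl$arclength - s_k))
  e1 <- cl$frames$normal[i, ]; e2 <- cl$frames$binormal[i, ]
  # branch direction in the section plane
  d2 <- c(sum(bg$direction * e1), sum(bg$direction * e2))
  d2 <- d2 / sqrt(sum(d2^2))
  r <- phantom_radius(spec, s_k)
  # carina point on the raw (twisted) frame: centre on the catheter, then
  # rotate about it, mirroring the renderer
  tw <- render$twist$cumulative_deg[k] * pi / 180
  R <- matrix(c(cos(tw), sin(tw), -sin(tw), cos(tw)), 2L, 2L)
  car <- as.numeric(R %*% (r * d2 - catheter_offset_mm))
  # the carina sits on the lumen border between the branches: place the
  # projection points so their midpoint lands there, at the carina level
  # (in-plane direction, since the branch takes off with a distal tilt)
  ost <- cl$points[i, ]
  dir_ip <- normalize3(d2[1L] * e1 + d2[2L] * e2)
  landmark_pair(oct_frame_index = k - 1L,
                oct_carina_point = car,
                ccta_main_point = ost,
                ccta_side_point = ost + 2 * r * dir_ip)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits everything the pipeline consumes: per-frame annotated TIFFs, the
#' centerline text file, the CCTA-like labeled point cloud (PLY),
#' calcification meshes (STL), a landmarks JSON and a ground-truth JSON.
#'
#' @param spec a [phantom_spec] (e.g. from [phantom_preset]).
#' @param out_dir output directory (created if missing).
#' @param cal an [oct_calibration].
#' @return invisible list of written paths plus the in-memory objects.
#' @export
write_phantom_dataset <- function(spec, out_dir, cal = oct_calibration()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- build_phantom(spec)
  frame_dir <- file.path(out_dir, "frames")
  dir.create(frame_dir, showWarnings = FALSE)
  rp <- render_pullback(ph, cal, frame_sink = function(fr, k) {
    tiff::writeTIFF(fr$image,
                    file.path(frame_dir, sprintf("frame_%04d.tif", k - 1L)))
  })
  cc <- make_ccta_like_cloud(ph)
  write_centerline(ph$truth$centerline, file.path(out_dir, "centerline.txt"))
  write_point_cloud(cc$cloud, file.path(out_dir, "ccta_cloud.ply"))
  calc_paths <- character(0)
  for (i in seq_along(cc$bloomed_calcifications)) {
    pth <- file.path(out_dir, sprintf("calc_%02d.stl", i))
    write_mesh(cc$bloomed_calcifications[[i]]$mesh, pth)
    calc_paths <- c(calc_paths, pth)
  }
  lm <- if (length(spec$side_branches)) {
    l <- phantom_landmark(ph, rp)
    write_landmarks(l, file.path(out_dir, "landmarks.json"))
    l
  } else NULL
  truth <- list(true_pct_AS = ph$truth$true_pct_AS,
                branch_positions_mm = ph$truth$branch_positions_mm,
                window_mm = rp$window,
                stations_mm = rp$stations_mm,
                twist_cumulative_deg = rp$twist$cumulative_deg,
                frame_spacing_mm = cal$frame_spacing_mm)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, phantom = ph, render = rp, ccta = cc,
                 landmark = lm, truth = truth))
}
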