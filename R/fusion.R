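#' Labeled 3D point cloud
#'
#' Point set tagged by source modality (`"OCT"` or `"CCTA"`), optionally
#' carrying per-point unit normals used by the surface reconstruction.
#'
#' @param points n x 3 numeric matrix in mm.
#' @param labels character vector (length n or 1) of source tags.
#' @param normals optional n x 3 matrix of unit normals.
#' @return object of class `labeled_point_cloud`.
#' @export
labeled_point_cloud <- function(points, labels = "CCTA", normals = NULL) {
  points <- as.matrix(points)
  if (nrow(points) > 0L && (ncol(points) != 3L || any(!is.finite(points)))) {
    stop("labeled_point_cloud: points must be finite n x 3", call. = FALSE)
  }
  labels <- rep_len(as.character(labels), nrow(points))
  if (!all(labels %in% c("OCT", "CCTA"))) {
    stop("labeled_point_cloud: labels must be 'OCT' or 'CCTA'", call. = FALSE)
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(nrow(normals) == nrow(points), ncol(normals) == 3L)
  }
  structure(list(points = unname(points), labels = labels, normals = normals),
            class = "labeled_point_cloud")
}

#' @export
print.labeled_point_cloud <- function(x, ...) {
  cat(sprintf("<labeled_point_cloud> %d points (OCT %d, CCTA %d)%s\n",
              nrow(x$points), sum(x$labels == "OCT"),
              sum(x$labels == "CCTA"),
              if (!is.null(x$normals)) ", with normals" else ""))
  invisible(x)
}

#' Fusion configuration
#'
#' @param overlap_radius_mm CCTA points closer than this to any OCT point
#'   are removed before fusion (default 0.35 mm).
#' @param wall_thickness_mm uniform vessel wall thickness (default 1 mm).
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(overlap_radius_mm = 0.35, wall_thickness_mm = 1) {
  if (overlap_radius_mm <= 0 || wall_thickness_mm <= 0) {
    stop("fusion_config: radii/thickness must be positive", call. = FALSE)
  }
  structure(list(overlap_radius_mm = overlap_radius_mm,
                 wall_thickness_mm = wall_thickness_mm),
            class = "fusion_config")
}

#' Sample a surface mesh into a labeled point cloud
#'
#' Returns the mesh vertices plus `round(density * total_area)` additional
#' points sampled uniformly on the surface (faces chosen with probability
#' proportional to area, barycentric placement within each face), labeled
#' CCTA. Normals follow the sampled faces (vertices get area-weighted vertex
#' normals).
#'
#' @param mesh a [surface_mesh].
#' @param density surface samples per mm^2 (default 10).
#' @param label source tag for the resulting points.
#' @return a [labeled_point_cloud] with normals.
#' @export
mesh_to_point_cloud <- function(mesh, density = 10, label = "CCTA") {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0L) {
    stop("mesh_to_point_cloud: empty mesh", call. = FALSE)
  }
  if (density <= 0) stop("mesh_to_point_cloud: density must be > 0",
                         call. = FALSE)
  areas <- face_areas(mesh)
  n_extra <- round(density * sum(areas))
  pts <- mesh$vertices
  nrm <- vertex_normals(mesh)
  if (n_extra > 0) {
    fi <- sample.int(nrow(mesh$faces), n_extra, replace = TRUE,
                     prob = areas)
    r1 <- sqrt(stats::runif(n_extra))
    r2 <- stats::runif(n_extra)
    a <- mesh$vertices[mesh$faces[fi, 1L], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2L], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3L], , drop = FALSE]
    samp <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
    pts <- rbind(pts, samp)
    nrm <- rbind(nrm, face_normals(mesh)[fi, , drop = FALSE])
  }
  labeled_point_cloud(pts, label, normals = nrm)
}

#' Remove CCTA points overlapping the OCT cloud
#'
#' k-d tree fixed-radius filter: CCTA points whose nearest OCT neighbour is
#' strictly closer than `overlap_radius_mm` are dropped; a point exactly at
#' the radius is kept. An empty OCT cloud returns the CCTA cloud unchanged
#' with a warning.
#'
#' @param ccta,oct [labeled_point_cloud]s.
#' @param cfg a [fusion_config].
#' @return filtered CCTA [labeled_point_cloud].
#' @export
remove_overlapping_points <- function(ccta, oct, cfg = fusion_config()) {
  stopifnot(inherits(ccta, "labeled_point_cloud"),
            inherits(oct, "labeled_point_cloud"))
  if (nrow(oct$points) == 0L) {
    warning("remove_overlapping_points: empty OCT cloud; nothing removed",
            call. = FALSE)
    return(ccta)
  }
  nn <- RANN::nn2(oct$points, ccta$points, k = 1L)
  keep <- nn$nn.dists[, 1L] >= cfg$overlap_radius_mm
  labeled_point_cloud(ccta$points[keep, , drop = FALSE],
                      ccta$labels[keep],
                      normals = if (!is.null(ccta$normals))
                        ccta$normals[keep, , drop = FALSE])
}

#' Region predicates for point selection
#'
#' Programmatic stand-ins for interactive point selection: spheres, axis
#' aligned boxes and tube segments around a centerline index range.
#'
#' @param center,radius sphere centre (mm) and radius (mm).
#' @return a region object usable with [select_points_region].
#' @export
region_sphere <- function(center, radius) {
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = radius), class = "cloud_region")
}

#' @rdname region_sphere
#' @param lo,hi opposite corners of the box (mm).
#' @export
region_box <- function(lo, hi) {
  structure(list(kind = "box", lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "cloud_region")
}

#' @rdname region_sphere
#' @param cl a [centerline].
#' @param index_range length-2 integer range of centerline indices.
#' @param tube_radius radius around the polyline segment (mm).
#' @export
region_tube <- function(cl, index_range, tube_radius) {
  stopifnot(inherits(cl, "centerline"))
  structure(list(kind = "tube", cl = cl,
                 index_range = as.integer(index_range),
                 radius = tube_radius), class = "cloud_region")
}

region_contains <- function(region, points) {
  switch(region$kind,
    sphere = sqrt(rowSums(sweep(points, 2L, region$center)^2)) <=
      region$radius,
    box = points[, 1L] >= region$lo[1L] & points[, 1L] <= region$hi[1L] &
      points[, 2L] >= region$lo[2L] & points[, 2L] <= region$hi[2L] &
      points[, 3L] >= region$lo[3L] & points[, 3L] <= region$hi[3L],
    tube = {
      ir <- region$index_range
      seg <- region$cl$points[ir[1L]:ir[2L], , drop = FALSE]
      dist_to_polyline(points, seg) <= region$radius
    },
    stop("unknown region kind", call. = FALSE))
}

# distance from points to a 3D polyline (min over segments)
dist_to_polyline <- function(points, poly) {
  n <- nrow(poly)
  if (n == 1L) {
    return(sqrt(rowSums(sweep(points, 2L, poly[1L, ])^2)))
  }
  dmin <- rep(Inf, nrow(points))
  for (i in seq_len(n - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    t <- pmin(1, pmax(0, (sweep(points, 2L, a) %*% ab) / sum(ab^2)))
    proj <- outer(as.numeric(t), ab) + rep(a, each = nrow(points))
    dmin <- pmin(dmin, sqrt(rowSums((points - proj)^2)))
  }
  dmin
}

#' Keep or drop cloud points by region predicates
#'
#' @param cloud a [labeled_point_cloud].
#' @param regions a single region or list of regions (from [region_sphere],
#'   [region_box], [region_tube]); applied in order.
#' @param keep `TRUE` keeps points inside the regions, `FALSE` drops them.
#' @return filtered [labeled_point_cloud]; removing every point is an error.
#' @export
select_points_region <- function(cloud, regions, keep = FALSE) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  if (inherits(regions, "cloud_region")) regions <- list(regions)
  sel <- rep(!keep, nrow(cloud$points))
  for (rg in regions) {
    inside <- region_contains(rg, cloud$points)
    sel <- if (keep) sel | inside else sel & !inside
  }
  if (!any(sel)) {
    stop("select_points_region: selection removed every point", call. = FALSE)
  }
  labeled_point_cloud(cloud$points[sel, , drop = FALSE], cloud$labels[sel],
                      normals = if (!is.null(cloud$normals))
                        cloud$normals[sel, , drop = FALSE])
}

#' Fuse the filtered CCTA cloud with a registered OCT stack
#'
#' Concatenates the CCTA points with all registered 3D contour points
#' (labeled OCT). OCT normals are the in-plane outward directions from each
#' contour centroid, which seeds the surface reconstruction.
#'
#' @param ccta_filtered a [labeled_point_cloud] (after overlap removal).
#' @param stack a registered stack from [register_pullback()].
#' @return fused [labeled_point_cloud].
#' @export
fuse_point_clouds <- function(ccta_filtered, stack) {
  stopifnot(inherits(ccta_filtered, "labeled_point_cloud"),
            inherits(stack, "registered_stack"))
  if (nrow(ccta_filtered$points) == 0L || length(stack$contours3d) == 0L) {
    stop("fuse_point_clouds: both inputs must be nonempty", call. = FALSE)
  }
  oct_pts <- do.call(rbind, lapply(stack$contours3d, `[[`, "points"))
  oct_nrm <- do.call(rbind, lapply(stack$contours3d, function(ct) {
    ctr <- colMeans(ct$points)
    v <- sweep(ct$points, 2L, ctr)
    # outward in-plane direction
    v <- v - outer(as.numeric(v %*% ct$normal), ct$normal)
    v / pmax(sqrt(rowSums(v^2)), .Machine$double.eps)
  }))
  ccta_nrm <- ccta_filtered$normals
  if (is.null(ccta_nrm)) ccta_nrm <- matrix(NA_real_,
                                            nrow(ccta_filtered$points), 3L)
  labeled_point_cloud(rbind(ccta_filtered$points, oct_pts),
                      c(ccta_filtered$labels,
                        rep("OCT", nrow(oct_pts))),
                      normals = rbind(ccta_nrm, oct_nrm))
}

#' Reconstruct a surface mesh from a fused point cloud
#'
#' Implicit reconstruction: a smooth signed distance is built from the
#' oriented points (normals estimated by local PCA when absent, oriented
#' using the centerline when given, else by spanning-tree propagation), its
#' zero level set is extracted with marching tetrahedra in a band around the
#' cloud, the largest component is kept, holes are fan-filled and the faces
#' oriented outward.
#'
#' @param cloud a [labeled_point_cloud] with at least 100 points.
#' @param voxel_mm marching grid spacing (mm).
#' @param cl optional [centerline] used to orient estimated normals.
#' @param k_sdf neighbours used by the signed-distance blend.
#' @return a watertight [surface_mesh] (an error is raised when the cleanup
#'   still leaves a non-manifold surface).
#' @export
reconstruct_surface <- function(cloud, voxel_mm = 0.15, cl = NULL,
                                k_sdf = 10L) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  if (nrow(cloud$points) < 100L) {
    stop("reconstruct_surface: need at least 100 points", call. = FALSE)
  }
  nrm <- cloud$normals
  if (is.null(nrm) || anyNA(nrm)) {
    est <- estimate_cloud_normals(cloud$points, centerline = cl)
    if (is.null(nrm)) nrm <- est else {
      bad <- !stats::complete.cases(nrm)
      nrm[bad, ] <- est[bad, , drop = FALSE]
    }
  }
  f <- oriented_cloud_sdf(cloud$points, nrm, k = k_sdf)
  mesh <- march_implicit(f, cloud$points, voxel_mm = voxel_mm)
  if (nrow(mesh$faces) == 0L) {
    stop("reconstruct_surface: no surface extracted", call. = FALSE)
  }
  mesh <- largest_component(mesh)
  mesh <- fill_holes(mesh)  # re-orients when fans were added
  if (!is_watertight(mesh)) {
    stop(sprintf(
      "reconstruct_surface: non-manifold output (%d boundary edges) after cleanup",
      nrow(boundary_edges(mesh))), call. = FALSE)
  }
  mesh
}

#' Thicken a lumen mesh into a walled solid
#'
#' Offsets the lumen surface outward by the wall thickness and returns a
#' two-shell solid (outer shell plus inward-facing lumen shell) bounding the
#' vessel wall. `method = "normals"` offsets along area-weighted vertex
#' normals; `method = "implicit"` re-extracts the offset surface from the
#' signed distance field, which also resolves self-intersections at
#' high-curvature stenoses.
#'
#' @param lumen_mesh watertight [surface_mesh] with outward normals.
#' @param cfg a [fusion_config] (wall thickness).
#' @param method offset strategy, `"normals"` (default) or `"implicit"`.
#' @param voxel_mm grid spacing for the implicit method.
#' @return a [surface_mesh] solid with two shells.
#' @export
add_wall <- function(lumen_mesh, cfg = fusion_config(),
                     method = c("normals", "implicit"), voxel_mm = 0.15) {
  stopifnot(inherits(lumen_mesh, "surface_mesh"))
  method <- match.arg(method)
  if (!is_watertight(lumen_mesh)) {
    stop("add_wall: lumen mesh must be watertight", call. = FALSE)
  }
  t <- cfg$wall_thickness_mm
  outer_mesh <- if (method == "normals") {
    m <- lumen_mesh
    m$vertices <- m$vertices + t * vertex_normals(lumen_mesh)
    m
  } else {
    vn <- vertex_normals(lumen_mesh)
    seeds <- lumen_mesh$vertices + t * vn
    f <- function(q) point_mesh_distance(q, lumen_mesh, signed = TRUE) - t
    m <- march_implicit(f, seeds, voxel_mm = voxel_mm)
    m <- fill_holes(largest_component(m))
    orient_mesh(m)
  }
  merge_meshes(outer_mesh, flip_faces(lumen_mesh))
}

#' Write / read a labeled point cloud
#'
#' PLY files carry a `source` vertex property (0 = CCTA, 1 = OCT); plain
#' text files hold `x y z label` per line.
#'
#' @param cloud a [labeled_point_cloud].
#' @param path output path (`.ply` or `.txt`/`.xyz`).
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  ext <- tolower(tools::file_ext(path))
  p <- cloud$points
  if (ext == "ply") {
    has_n <- !is.null(cloud$normals) && !anyNA(cloud$normals)
    header <- c("ply", "format ascii 1.0",
                "comment corofuse labeled point cloud",
                sprintf("element vertex %d", nrow(p)),
                "property float x", "property float y", "property float z",
                if (has_n) c("property float nx", "property float ny",
                             "property float nz"),
                "property uchar source",
                "end_header")
    body <- if (has_n) {
      sprintf("%.9g %.9g %.9g %.6g %.6g %.6g %d", p[, 1L], p[, 2L], p[, 3L],
              cloud$normals[, 1L], cloud$normals[, 2L], cloud$normals[, 3L],
              as.integer(cloud$labels == "OCT"))
    } else {
      sprintf("%.9g %.9g %.9g %d", p[, 1L], p[, 2L], p[, 3L],
              as.integer(cloud$labels == "OCT"))
    }
    writeLines(c(header, body), path)
  } else {
    writeLines(sprintf("%g %g %g %s", p[, 1L], p[, 2L], p[, 3L],
                       cloud$labels), path)
  }
  invisible(path)
}

#' @rdname write_point_cloud
#' @return `read_point_cloud` returns a [labeled_point_cloud].
#' @export
read_point_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    pl <- read_ply_raw(path)
    vt <- pl$vertex_table
    labels <- if ("source" %in% colnames(vt)) {
      ifelse(vt[, "source"] > 0, "OCT", "CCTA")
    } else "CCTA"
    nrm <- if (all(c("nx", "ny", "nz") %in% colnames(vt))) {
      vt[, c("nx", "ny", "nz")]
    } else NULL
    labeled_point_cloud(vt[, c("x", "y", "z")], labels, normals = nrm)
  } else {
    rows <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
    rows <- rows[lengths(rows) >= 3L]
    pts <- do.call(rbind, lapply(rows, function(r) as.numeric(r[1:3])))
    labels <- vapply(rows, function(r)
      if (length(r) >= 4L) r[4L] else "CCTA", character(1))
    labeled_point_cloud(pts, labels)
  }
}
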