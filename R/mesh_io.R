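#' Read a surface mesh from STL, PLY or OBJ
#'
#' Format is chosen by file extension (case-insensitive). STL may be ASCII or
#' binary; PLY must be ASCII; OBJ supports `v`/`f` records (polygonal faces
#' are fan-triangulated). STL files carry no connectivity, so identical
#' vertices are welded on read.
#'
#' @param path file path ending in `.stl`, `.ply` or `.obj`.
#' @return a [surface_mesh].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply_mesh(path),
         obj = read_obj(path),
         stop("read_mesh: unsupported extension '", ext, "'", call. = FALSE))
}

#' Write a surface mesh to STL, PLY or OBJ
#'
#' @param mesh a [surface_mesh].
#' @param path output path; extension selects the format.
#' @param binary for STL only: write the binary dialect (default ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (binary) write_stl_binary(mesh, path) else
           write_stl_ascii(mesh, path),
         ply = write_ply_mesh(mesh, path),
         obj = write_obj(mesh, path),
         stop("write_mesh: unsupported extension '", ext, "'", call. = FALSE))
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  # ASCII files start with "solid" and contain "facet" soon after
  txt_head <- rawToChar(head[head != as.raw(0)])
  if (grepl("^\\s*solid", txt_head) &&
      grepl("facet", paste(readLines(path, n = 20L, warn = FALSE),
                           collapse = " "))) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  weld_triangle_soup(verts)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", ntri * 50L)
  m <- matrix(rec, nrow = 50L)
  fl <- apply(m[1:48, , drop = FALSE], 2L, function(r)
    readBin(r, "numeric", 12L, size = 4L, endian = "little"))
  verts <- matrix(as.numeric(fl[4:12, ]), ncol = 3L, byrow = TRUE)
  weld_triangle_soup(verts)
}

weld_triangle_soup <- function(verts) {
  key <- apply(round(verts, 9L), 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  surface_mesh(verts[uk, , drop = FALSE], matrix(idx, ncol = 3L, byrow = TRUE))
}

write_stl_ascii <- function(mesh, path) {
  fn <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  vx <- function(col) sprintf("      vertex %.9g %.9g %.9g",
                              v[f[, col], 1L], v[f[, col], 2L],
                              v[f[, col], 3L])
  block <- rbind(sprintf("  facet normal %.9g %.9g %.9g",
                         fn[, 1L], fn[, 2L], fn[, 3L]),
                 "    outer loop", vx(1L), vx(2L), vx(3L),
                 "    endloop", "  endfacet")
  writeLines(c("solid corofuse", as.vector(block), "endsolid corofuse"),
             path)
}

write_stl_binary <- function(mesh, path) {
  fn <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  rec <- cbind(fn, v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
               v[f[, 3L], , drop = FALSE])
  fl <- writeBin(as.numeric(t(rec)), raw(), size = 4L, endian = "little")
  out <- matrix(as.raw(0L), 50L, nrow(f))
  out[1:48, ] <- matrix(fl, 48L, nrow(f))
  writeBin(as.vector(out), con)
}

read_ply_mesh <- function(path) {
  pl <- read_ply_raw(path)
  surface_mesh(pl$vertices, pl$faces)
}

# generic ASCII PLY reader returning vertices, faces and extra vertex props
read_ply_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("read_ply: missing end_header", call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  elems <- grep("^element ", header)
  counts <- list(); props <- list(); cur <- NULL
  for (h in header) {
    if (startsWith(h, "element ")) {
      parts <- strsplit(h, "\\s+")[[1L]]
      cur <- parts[2L]
      counts[[cur]] <- as.integer(parts[3L])
      props[[cur]] <- character(0)
    } else if (startsWith(h, "property ") && !is.null(cur)) {
      parts <- strsplit(h, "\\s+")[[1L]]
      props[[cur]] <- c(props[[cur]], parts[length(parts)])
    }
  }
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  nv <- counts[["vertex"]] %||% 0L
  nf <- counts[["face"]] %||% 0L
  vlines <- body[seq_len(nv)]
  vmat <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  colnames(vmat) <- props[["vertex"]][seq_len(ncol(vmat))]
  faces <- NULL
  if (nf > 0L) {
    flines <- body[nv + seq_len(nf)]
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                                   function(x) {
      x <- as.integer(x)
      if (x[1L] != 3L) stop("read_ply: only triangle faces supported",
                            call. = FALSE)
      x[2:4] + 1L
    }))
  }
  list(vertices = vmat[, c("x", "y", "z"), drop = FALSE],
       faces = faces, vertex_table = vmat)
}

write_ply_mesh <- function(mesh, path, vertex_quality = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  qline <- if (!is.null(vertex_quality)) "property float quality" else NULL
  header <- c("ply", "format ascii 1.0",
              "comment corofuse mesh",
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              qline,
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  vbody <- if (is.null(vertex_quality)) {
    sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L])
  } else {
    sprintf("%.9g %.9g %.9g %g", v[, 1L], v[, 2L], v[, 3L], vertex_quality)
  }
  fbody <- sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
  writeLines(c(header, vbody, fbody), path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- list()
  for (ln in fl) {
    idx <- strsplit(trimws(ln), "\\s+")[[1L]][-1L]
    idx <- as.integer(vapply(strsplit(idx, "/"), `[`, character(1), 1L))
    for (k in seq_len(length(idx) - 2L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
    }
  }
  surface_mesh(verts, do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L])), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- primitives -----------------------------------------------------------

#' Cylinder mesh
#'
#' Closed cylinder along the z axis from `z0` to `z0 + length`, with end
#' caps. Mainly used for tests and synthetic phantoms.
#'
#' @param radius radius in mm.
#' @param length axial length in mm.
#' @param z0 axial start coordinate.
#' @param n_theta circumferential resolution.
#' @param n_axial axial resolution (number of rings).
#' @param caps close the ends with triangle fans.
#' @return a watertight [surface_mesh] when `caps = TRUE`.
#' @export
mesh_cylinder <- function(radius, length, z0 = 0, n_theta = 64L,
                          n_axial = 32L, caps = TRUE) {
  z <- seq(z0, z0 + length, length.out = n_axial)
  cl <- centerline(cbind(0, 0, z))
  mesh_tube(cl, rep(radius, n_axial), n_theta = n_theta, caps = caps)
}

#' Sphere mesh (UV tessellation)
#'
#' @param radius radius in mm.
#' @param center length-3 centre.
#' @param n_theta longitudinal resolution.
#' @param n_phi latitudinal resolution.
#' @return a watertight [surface_mesh].
#' @export
mesh_sphere <- function(radius, center = c(0, 0, 0), n_theta = 48L,
                        n_phi = 24L) {
  phi <- seq(0, pi, length.out = n_phi + 1L)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  # interior rings
  verts <- list(center + c(0, 0, radius))
  for (i in 2:n_phi) {
    ring <- cbind(radius * sin(phi[i]) * cos(th),
                  radius * sin(phi[i]) * sin(th),
                  radius * cos(phi[i]))
    verts[[length(verts) + 1L]] <- sweep(ring, 2L, center, `+`)
  }
  verts[[length(verts) + 1L]] <- center + c(0, 0, -radius)
  v <- do.call(rbind, lapply(verts, rbind))
  npole <- 1L
  spole <- nrow(v)
  idx <- function(i, j) 1L + (i - 2L) * n_theta + ((j - 1L) %% n_theta) + 1L
  f <- list()
  for (j in 1:n_theta) {
    f[[length(f) + 1L]] <- c(npole, idx(2L, j), idx(2L, j + 1L))
  }
  if (n_phi > 2L) {
    for (i in 2:(n_phi - 1L)) {
      for (j in 1:n_theta) {
        a <- idx(i, j); b <- idx(i, j + 1L)
        cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
        f[[length(f) + 1L]] <- c(a, cc, b)
        f[[length(f) + 1L]] <- c(b, cc, d)
      }
    }
  }
  for (j in 1:n_theta) {
    f[[length(f) + 1L]] <- c(spole, idx(n_phi, j + 1L), idx(n_phi, j))
  }
  orient_mesh(surface_mesh(v, do.call(rbind, f)))
}

#' Loft a tube mesh along a centerline
#'
#' Sweeps elliptical cross-sections along the centerline using its
#' rotation-minimizing frames. `radii` gives the equal-area radius at each
#' centerline point; `ellipticity` stretches the section (area-preserving:
#' semi-axes `r*sqrt(e)` and `r/sqrt(e)`).
#'
#' @param cl a [centerline] with frames.
#' @param radii per-point radius in mm (recycled if length 1).
#' @param n_theta circumferential resolution.
#' @param ellipticity axis ratio (1 = circular).
#' @param caps close both ends with fans.
#' @param theta0 per-point rotation of the section in degrees (recycled).
#' @return a [surface_mesh], watertight when capped.
#' @export
mesh_tube <- function(cl, radii, n_theta = 64L, ellipticity = 1,
                      caps = TRUE, theta0 = 0) {
  stopifnot(inherits(cl, "centerline"))
  n <- nrow(cl$points)
  radii <- rep_len(radii, n)
  theta0 <- rep_len(theta0, n)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  a <- radii * sqrt(ellipticity)
  b <- radii / sqrt(ellipticity)
  verts <- vector("list", n)
  for (i in seq_len(n)) {
    rot <- theta0[i] * pi / 180
    u <- a[i] * cos(th)
    w <- b[i] * sin(th)
    ur <- u * cos(rot) - w * sin(rot)
    wr <- u * sin(rot) + w * cos(rot)
    verts[[i]] <- sweep(outer(ur, cl$frames$normal[i, ]) +
                          outer(wr, cl$frames$binormal[i, ]),
                        2L, cl$points[i, ], `+`)
  }
  v <- do.call(rbind, verts)
  f <- list()
  for (i in seq_len(n - 1L)) {
    o1 <- (i - 1L) * n_theta
    o2 <- i * n_theta
    j2 <- c(2:n_theta, 1L)
    f[[i]] <- rbind(cbind(o1 + 1:n_theta, o2 + 1:n_theta, o1 + j2),
                    cbind(o1 + j2, o2 + 1:n_theta, o2 + j2))
  }
  faces <- do.call(rbind, f)
  if (caps) {
    c1 <- colMeans(verts[[1L]])
    c2 <- colMeans(verts[[n]])
    v <- rbind(v, c1, c2)
    i1 <- nrow(v) - 1L; i2 <- nrow(v)
    j2 <- c(2:n_theta, 1L)
    faces <- rbind(faces,
                   cbind(i1, 1:n_theta, j2),
                   cbind(i2, (n - 1L) * n_theta + j2,
                         (n - 1L) * n_theta + 1:n_theta))
  }
  orient_mesh(surface_mesh(v, faces))
}
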