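# Implicit-surface machinery: point-to-mesh distances with pseudonormal
# signs, smooth signed distance from oriented point clouds, and a
# marching-tetrahedra mesher restricted to a band of active cells. This
# backs surface reconstruction, mesh offsetting and boolean union.

# closest points on triangles for (point, triangle) candidate pairs,
# vectorised over pairs (Ericson's region classification)
closest_point_on_triangles <- function(p, a, b, cc) {
  ab <- b - a; ac <- cc - a; ap <- p - a
  dot <- function(u, v) rowSums(u * v)
  d1 <- dot(ab, ap); d2 <- dot(ac, ap)
  out <- matrix(NA_real_, nrow(p), 3L)
  done <- logical(nrow(p))

  set <- function(mask, val) {
    m <- mask & !done
    out[m, ] <<- val[m, , drop = FALSE]
    done[m] <<- TRUE
  }

  set(d1 <= 0 & d2 <= 0, a)

  bp <- p - b
  d3 <- dot(ab, bp); d4 <- dot(ac, bp)
  set(d3 >= 0 & d4 <= d3, b)

  vc <- d1 * d4 - d3 * d2
  t_ab <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + t_ab * ab)

  cp <- p - cc
  d5 <- dot(ab, cp); d6 <- dot(ac, cp)
  set(d6 >= 0 & d5 <= d6, cc)

  vb <- d5 * d2 - d1 * d6
  t_ac <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + t_ac * ac)

  va <- d3 * d6 - d5 * d4
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + t_bc * (cc - b))

  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  set(rep(TRUE, nrow(p)), a + v * ab + w * ac)
  out
}

# per-mesh acceleration structures for nearest-triangle queries
mesh_query_index <- function(mesh) {
  nf <- nrow(mesh$faces)
  fcent <- (mesh$vertices[mesh$faces[, 1L], , drop = FALSE] +
              mesh$vertices[mesh$faces[, 2L], , drop = FALSE] +
              mesh$vertices[mesh$faces[, 3L], , drop = FALSE]) / 3
  list(fcent = fcent,
       vface = split(rep(seq_len(nf), 3L), as.integer(mesh$faces)))
}

# candidate faces per query point: k nearest face centroids plus the faces
# incident to the nearest mesh vertex (guards against large-face pruning)
candidate_pairs <- function(points, mesh, k, qi = mesh_query_index(mesh)) {
  nf <- nrow(mesh$faces)
  k <- min(k, nf)
  nnf <- RANN::nn2(qi$fcent, points, k = k)$nn.idx
  nnv <- RANN::nn2(mesh$vertices, points, k = 1L)$nn.idx[, 1L]
  extra <- qi$vface[as.character(nnv)]
  np <- nrow(points)
  pidx <- c(rep(seq_len(np), each = k), rep(seq_len(np), lengths(extra)))
  fidx <- c(as.integer(t(nnf)), unlist(extra, use.names = FALSE))
  keep <- !duplicated(pidx * (nf + 1) + fidx)
  list(p = pidx[keep], f = fidx[keep])
}

#' Distance from points to a mesh surface
#'
#' For each query point, the unsigned distance to the nearest point on any
#' triangle of the mesh (point-to-surface, not point-to-vertex). When
#' `signed = TRUE` the sign is taken from the normals of the face(s) realising
#' the minimum (angle-weighted pseudonormal convention): negative inside a
#' closed, outward-oriented mesh.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a [surface_mesh].
#' @param signed return signed distances.
#' @param k number of nearest face centroids searched per point.
#' @param chunk queries are processed in blocks of this size to bound the
#'   memory of the candidate-pair expansion.
#' @return numeric vector of distances (mm).
#' @export
point_mesh_distance <- function(points, mesh, signed = FALSE, k = 24L,
                                chunk = 60000L) {
  points <- as.matrix(points)
  if (nrow(mesh$faces) == 0L) stop("point_mesh_distance: empty mesh",
                                   call. = FALSE)
  np <- nrow(points)
  if (np > chunk) {
    qi <- mesh_query_index(mesh)
    fn <- if (signed) face_normals(mesh)
    starts <- seq(1L, np, by = chunk)
    return(unlist(lapply(starts, function(s) {
      pmd_block(points[s:min(np, s + chunk - 1L), , drop = FALSE],
                mesh, signed, k, qi, fn)
    }), use.names = FALSE))
  }
  pmd_block(points, mesh, signed, k, mesh_query_index(mesh),
            if (signed) face_normals(mesh))
}

pmd_block <- function(points, mesh, signed, k, qi, fn) {
  pr <- candidate_pairs(points, mesh, k, qi)
  a <- mesh$vertices[mesh$faces[pr$f, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[pr$f, 2L], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[pr$f, 3L], , drop = FALSE]
  p <- points[pr$p, , drop = FALSE]
  cp <- closest_point_on_triangles(p, a, b, cc)
  d2 <- rowSums((p - cp)^2)
  ord <- order(pr$p, d2)
  pp <- pr$p[ord]
  first <- !duplicated(pp)
  dmin <- sqrt(d2[ord][first])
  if (!signed) return(dmin)
  # sign: sum face-normal components over every candidate face that attains
  # the minimum (within tolerance) — the pseudonormal at edges and vertices
  dsort <- sqrt(d2[ord])
  dmin_of <- dmin[match(pp, pp[first])]
  near <- dsort <= dmin_of + 1e-9
  vec <- p[ord, , drop = FALSE] - cp[ord, , drop = FALSE]
  contrib <- rowSums(vec * fn[pr$f[ord], , drop = FALSE])
  s <- rowsum(contrib * near, pp)  # rows in ascending point order, like dmin
  sgn <- sign(as.numeric(s))
  sgn[sgn == 0] <- 1
  dmin * sgn
}

# smooth signed distance from an oriented point set (locally weighted plane
# distance, Hoppe-style)
oriented_cloud_sdf <- function(points, normals, k = 10L, h = NULL) {
  force(points); force(normals)
  function(q) {
    q <- as.matrix(q)
    kk <- min(k, nrow(points))
    nn <- RANN::nn2(points, q, k = kk)
    if (is.null(h)) h <- stats::median(nn$nn.dists[, min(2L, kk)]) * 2 + 1e-9
    w <- exp(-(nn$nn.dists^2) / (h^2))
    num <- matrix(0, nrow(q), kk)
    for (j in seq_len(kk)) {
      idx <- nn$nn.idx[, j]
      num[, j] <- rowSums((q - points[idx, , drop = FALSE]) *
                            normals[idx, , drop = FALSE])
    }
    rowSums(w * num) / pmax(rowSums(w), .Machine$double.eps)
  }
}

# estimate unit normals of a point cloud by local PCA; orientation from a
# centerline (outward) when given, else by propagation along a spanning tree
estimate_cloud_normals <- function(points, k = 12L, centerline = NULL) {
  n <- nrow(points)
  k <- min(k, n)
  nn <- RANN::nn2(points, points, k = k)$nn.idx
  nrm <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    nb <- points[nn[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    nrm[i, ] <- ev$vectors[, 3L]
  }
  if (!is.null(centerline)) {
    idx <- RANN::nn2(centerline$points, points, k = 1L)$nn.idx[, 1L]
    outward <- points - centerline$points[idx, , drop = FALSE]
    flip <- rowSums(nrm * outward) < 0
    nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  } else {
    nrm <- orient_normals_mst(points, nrm, nn)
  }
  nrm
}

# consistent normal orientation by minimum-spanning-tree propagation
orient_normals_mst <- function(points, nrm, nn) {
  n <- nrow(points)
  k <- ncol(nn)
  from <- rep(seq_len(n), k - 1L)
  to <- as.integer(nn[, -1L])
  w <- 1 - abs(rowSums(nrm[from, , drop = FALSE] * nrm[to, , drop = FALSE]))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w + 1e-9),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  mst <- igraph::mst(g)
  # root at the point with extreme z; make it point away from the centroid
  root <- which.max(points[, 3L])
  ctr <- colMeans(points)
  if (sum(nrm[root, ] * (points[root, ] - ctr)) < 0) nrm[root, ] <- -nrm[root, ]
  bfs <- igraph::bfs(mst, root = as.character(root), father = TRUE)
  ord <- as.integer(igraph::as_ids(bfs$order))
  father <- as.integer(igraph::as_ids(bfs$father))
  for (v in ord) {
    f <- father[match(v, as.integer(igraph::V(mst)$name))]
    if (is.na(f)) next
    if (sum(nrm[v, ] * nrm[f, ]) < 0) nrm[v, ] <- -nrm[v, ]
  }
  nrm
}

# deterministic on-surface points at roughly `spacing`: per-face barycentric
# lattices sized by the longest edge (used to seed the marching band)
surface_lattice_points <- function(mesh, spacing) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  emax <- pmax(sqrt(rowSums((a - b)^2)), sqrt(rowSums((b - cc)^2)),
               sqrt(rowSums((cc - a)^2)))
  kf <- pmin(pmax(1L, ceiling(emax / spacing)), 64L)
  out <- list(v)
  for (k in setdiff(sort(unique(kf)), 1L)) {
    rows <- which(kf == k)
    bary <- expand.grid(i = 0:k, j = 0:k)
    # interior and edge lattice nodes only; the corners are the vertices,
    # which are already included
    bary <- bary[bary$i + bary$j <= k &
                   !(bary$i %in% c(0L, k) & bary$j %in% c(0L, k)) &
                   !(bary$i == 0L & bary$j == k), , drop = FALSE]
    u <- bary$i / k; w <- bary$j / k
    for (m in seq_len(nrow(bary))) {
      out[[length(out) + 1L]] <- (1 - u[m] - w[m]) * a[rows, , drop = FALSE] +
        u[m] * b[rows, , drop = FALSE] + w[m] * cc[rows, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

# ---- marching tetrahedra --------------------------------------------------

# corner offsets, bit order (x, y, z)
.mt_corners <- cbind(x = c(0, 1, 0, 1, 0, 1, 0, 1),
                     y = c(0, 0, 1, 1, 0, 0, 1, 1),
                     z = c(0, 0, 0, 0, 1, 1, 1, 1))
# six-tetrahedra decomposition around the 0-7 diagonal; consistent across
# neighbouring cubes, which makes the extracted surface watertight
.mt_tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

#' Extract the zero surface of an implicit function (marching tetrahedra)
#'
#' Evaluates `f` on a voxel grid restricted to cells near `seed_points`
#' (which must lie close to the target surface) and triangulates the zero
#' level set with a six-tetrahedra-per-cube decomposition. The convention is
#' `f < 0` inside; output faces are oriented outward.
#'
#' @param f vectorised function taking an n x 3 matrix and returning n values.
#' @param seed_points points near the wanted surface (defines the active band).
#' @param voxel_mm grid spacing in mm.
#' @param band_cells half-width of the active band around seed cells, in cells.
#' @return a [surface_mesh] (not post-processed; see [reconstruct_surface]).
#' @export
march_implicit <- function(f, seed_points, voxel_mm = 0.15, band_cells = 2L) {
  seed_points <- as.matrix(seed_points)
  h <- voxel_mm
  lo <- apply(seed_points, 2L, min) - (band_cells + 2L) * h
  # irrational half-cell shift: keeps flat axis-aligned features (end caps,
  # symmetry planes) off the grid planes, where grazing zero sets would
  # produce sliver triangles
  base <- floor(lo / h) * h - h * (sqrt(2) - 1)
  ijk <- floor(sweep(seed_points, 2L, base) / h)
  offs <- as.matrix(expand.grid(dx = -band_cells:band_cells,
                                dy = -band_cells:band_cells,
                                dz = -band_cells:band_cells))
  span <- apply(ijk, 2L, max) + band_cells + 2L
  NX <- span[1L] + 2L; NY <- span[2L] + 2L
  enc <- function(m) m[, 1L] + NX * (m[, 2L] + NY * m[, 3L])
  dec <- function(g) {
    i <- g %% NX; g <- (g - i) / NX
    j <- g %% NY
    cbind(i, j, (g - j) / NY)
  }
  ijk <- ijk[!duplicated(enc(ijk)), , drop = FALSE]
  cells <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    cells <- unique(c(cells, enc(sweep(ijk, 2L, offs[r, ], `+`))))
  }
  cells <- cells[cells >= 0]
  cijk <- dec(cells)
  # global corner ids for the 8 corners of every cell
  corner_g <- matrix(0, length(cells), 8L)
  for (cbit in 1:8) {
    corner_g[, cbit] <- enc(sweep(cijk, 2L, .mt_corners[cbit, ], `+`))
  }
  gids <- sort(unique(as.numeric(corner_g)))
  gxyz <- sweep(dec(gids) * h, 2L, base, `+`)
  fv <- f(gxyz)
  fv[fv == 0] <- 1e-12  # avoid on-grid zeros producing degenerate triangles
  cidx <- matrix(match(as.numeric(corner_g), gids), ncol = 8L)
  fc <- matrix(fv[cidx], ncol = 8L)
  crossing <- rowSums(fc < 0) %in% 1:7
  if (!any(crossing)) {
    return(surface_mesh(matrix(numeric(0), 0L, 3L),
                        matrix(integer(0), 0L, 3L)))
  }
  cidx <- cidx[crossing, , drop = FALSE]

  # expand to tets
  tet_v <- do.call(rbind, lapply(seq_len(6L), function(t)
    cidx[, .mt_tets[t, ], drop = FALSE]))
  tf <- matrix(fv[tet_v], ncol = 4L)
  inside <- tf < 0
  nin <- rowSums(inside)
  tris <- list()
  edge_a <- integer(0); edge_b <- integer(0)
  tri_tet <- integer(0)
  add_tris <- function(rows, e1a, e1b, e2a, e2b, e3a, e3b) {
    # each e* argument: global corner ids of the crossing-edge endpoints
    n0 <- length(edge_a)
    edge_a <<- c(edge_a, e1a, e2a, e3a)
    edge_b <<- c(edge_b, e1b, e2b, e3b)
    tri_tet <<- c(tri_tet, rows)
    nt <- length(e1a)
    cbind(n0 + seq_len(nt), n0 + nt + seq_len(nt), n0 + 2L * nt + seq_len(nt))
  }
  pick <- function(rows, col) tet_v[cbind(rows, col)]

  # one vertex on one side: single triangle
  for (lone_in in c(TRUE, FALSE)) {
    rows <- which(if (lone_in) nin == 1L else nin == 3L)
    if (!length(rows)) next
    m <- if (lone_in) inside[rows, , drop = FALSE] else
      !inside[rows, , drop = FALSE]
    lonecol <- max.col(m + 0, ties.method = "first")
    others <- matrix(0L, length(rows), 3L)
    for (l in 1:4) {
      sel <- lonecol == l
      if (any(sel)) others[sel, ] <- matrix(setdiff(1:4, l), sum(sel), 3L,
                                            byrow = TRUE)
    }
    la <- pick(rows, lonecol)
    tris[[length(tris) + 1L]] <- add_tris(rows,
      la, pick(rows, others[, 1L]),
      la, pick(rows, others[, 2L]),
      la, pick(rows, others[, 3L]))
  }
  # two-two split: quad as two triangles
  rows <- which(nin == 2L)
  if (length(rows)) {
    mi <- inside[rows, , drop = FALSE]
    i1 <- pick(rows, max.col(mi + 0, ties.method = "first"))
    i2 <- pick(rows, max.col(mi + 0, ties.method = "last"))
    o1 <- pick(rows, max.col(1 - mi, ties.method = "first"))
    o2 <- pick(rows, max.col(1 - mi, ties.method = "last"))
    # quad order (i1,o1) (i1,o2) (i2,o2) (i2,o1)
    tris[[length(tris) + 1L]] <- add_tris(rows, i1, o1, i1, o2, i2, o2)
    tris[[length(tris) + 1L]] <- add_tris(rows, i1, o1, i2, o2, i2, o1)
  }
  if (!length(tris)) {
    return(surface_mesh(matrix(numeric(0), 0L, 3L),
                        matrix(integer(0), 0L, 3L)))
  }
  faces_e <- do.call(rbind, tris)

  # weld: unique crossing edges, one interpolated vertex each
  ekey <- pmin(edge_a, edge_b) * (length(gids) + 1) + pmax(edge_a, edge_b)
  uidx <- !duplicated(ekey)
  vid <- match(ekey, ekey[uidx])
  ea <- edge_a[uidx]; eb <- edge_b[uidx]
  f0 <- fv[ea]; f1 <- fv[eb]
  t <- f0 / (f0 - f1)
  vx <- gxyz[ea, , drop = FALSE] +
    t * (gxyz[eb, , drop = FALSE] - gxyz[ea, , drop = FALSE])
  faces <- matrix(vid[faces_e], ncol = 3L)
  tri_rows <- tri_tet
  # drop degenerate faces (repeated welded vertices)
  ok <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
    faces[, 1L] != faces[, 3L]
  faces <- faces[ok, , drop = FALSE]
  tri_rows <- tri_rows[ok]

  # orient each triangle toward increasing f: within its tet, f is treated
  # as linear, so the direction from the inside-corner centroid to the
  # outside-corner centroid crosses the surface transversally
  A <- vx[faces[, 1L], , drop = FALSE]
  B <- vx[faces[, 2L], , drop = FALSE]
  Cc <- vx[faces[, 3L], , drop = FALSE]
  nrmf <- cbind((B[, 2L] - A[, 2L]) * (Cc[, 3L] - A[, 3L]) -
                  (B[, 3L] - A[, 3L]) * (Cc[, 2L] - A[, 2L]),
                (B[, 3L] - A[, 3L]) * (Cc[, 1L] - A[, 1L]) -
                  (B[, 1L] - A[, 1L]) * (Cc[, 3L] - A[, 3L]),
                (B[, 1L] - A[, 1L]) * (Cc[, 2L] - A[, 2L]) -
                  (B[, 2L] - A[, 2L]) * (Cc[, 1L] - A[, 1L]))
  ins_t <- inside[tri_rows, , drop = FALSE]
  dirv <- matrix(0, nrow(faces), 3L)
  for (corner in 1:4) {
    cg <- tet_v[cbind(tri_rows, corner)]
    w <- ifelse(ins_t[, corner], -1 / pmax(rowSums(ins_t), 1L),
                1 / pmax(4L - rowSums(ins_t), 1L))
    dirv <- dirv + w * gxyz[cg, , drop = FALSE]
  }
  flip <- rowSums(nrmf * dirv) < 0
  faces[flip, ] <- faces[flip, c(1L, 3L, 2L), drop = FALSE]
  compact_mesh(surface_mesh(vx, faces))
}
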