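#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param drop_degenerate remove zero-area faces during construction.
#' @return object of class `surface_mesh` with fields `vertices`, `faces`.
#' @export
surface_mesh <- function(vertices, faces, drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L || !is.numeric(vertices)) {
    stop("surface_mesh: 'vertices' must be n x 3 numeric", call. = FALSE)
  }
  if (any(!is.finite(vertices))) {
    stop("surface_mesh: non-finite vertex coordinates", call. = FALSE)
  }
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("surface_mesh: face index out of range", call. = FALSE)
  }
  m <- structure(list(vertices = unname(vertices), faces = unname(faces)),
                 class = "surface_mesh")
  if (drop_degenerate && nrow(faces) > 0L) {
    a <- face_areas(m)
    if (any(a <= 0)) m$faces <- m$faces[a > 0, , drop = FALSE]
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.3f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Per-face areas of a mesh
#' @param mesh a [surface_mesh].
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(numeric(0))
  sqrt(rowSums(face_cross(mesh)^2)) / 2
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem volume; positive for a closed mesh with outward-facing
#' normals. For a two-shell wall solid (outer shell plus inward-facing inner
#' shell) this returns the material volume between the shells.
#'
#' @param mesh a [surface_mesh].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) +
        a[, 2L] * (b[, 3L] * cc[, 1L] - b[, 1L] * cc[, 3L]) +
        a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])) / 6
}

#' Unit face normals
#' @param mesh a [surface_mesh].
#' @return m x 3 matrix.
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
}

#' Area-weighted unit vertex normals
#' @param mesh a [surface_mesh].
#' @return n x 3 matrix (rows may be zero for unreferenced vertices).
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # magnitude = 2 * area, so this is area weighting
  n <- nrow(mesh$vertices)
  vn <- matrix(0, n, 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    vn[, 1L] <- vn[, 1L] + unname(tapply2(cr[, 1L], idx, n))
    vn[, 2L] <- vn[, 2L] + unname(tapply2(cr[, 2L], idx, n))
    vn[, 3L] <- vn[, 3L] + unname(tapply2(cr[, 3L], idx, n))
  }
  len <- sqrt(rowSums(vn^2))
  vn / pmax(len, .Machine$double.eps)
}

# fast grouped sum into a length-n vector
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Flip face orientation
#' @param mesh a [surface_mesh].
#' @return mesh with reversed winding.
#' @export
flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Concatenate meshes into one
#' @param ... [surface_mesh] objects.
#' @return combined [surface_mesh] (vertex indices re-based; shells are not
#'   stitched).
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1L]]) &&
      !inherits(ms[[1L]], "surface_mesh")) ms <- ms[[1L]]
  off <- 0L
  vs <- list(); fs <- list()
  for (m in ms) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Apply a rigid transform to a mesh
#' @param mesh a [surface_mesh].
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 offset (default zero).
#' @return transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2L, translation, `+`)
  mesh
}

# ---- plane sections -------------------------------------------------------

#' Cross-section plane
#' @param origin length-3 point on the plane (mm).
#' @param normal length-3 normal (normalised internally).
#' @return object of class `plane`.
#' @export
plane <- function(origin, normal) {
  structure(list(origin = as.numeric(origin),
                 normal = normalize3(as.numeric(normal))),
            class = "plane")
}

#' Deterministic in-plane orthonormal basis
#'
#' `e1` is the normalised projection of the global x-axis onto the plane
#' (falling back to the y-axis when the normal is parallel to x), and
#' `e2 = normal x e1`, giving a right-handed (e1, e2, normal) triad.
#'
#' @param p a [plane].
#' @return list with unit vectors `e1`, `e2`.
#' @export
plane_basis <- function(p) {
  e1 <- reference_inplane_axis(p$normal)
  e2 <- c(p$normal[2L] * e1[3L] - p$normal[3L] * e1[2L],
          p$normal[3L] * e1[1L] - p$normal[1L] * e1[3L],
          p$normal[1L] * e1[2L] - p$normal[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

#' Intersect a mesh with a plane
#'
#' Cuts the triangle mesh with the plane and chains the intersection segments
#' into closed polylines, returned as [contour2d] objects in the deterministic
#' [plane_basis] coordinates (origin at the plane origin). Open chains (from
#' boundaries or numerically non-closed regions) are discarded unless they
#' close within tolerance.
#'
#' @param mesh a [surface_mesh].
#' @param p a [plane].
#' @param min_points minimum points for a loop to be kept.
#' @return list of [contour2d] (possibly empty). Attribute `centroids3d`
#'   holds the 3D centroid of each returned loop.
#' @export
plane_mesh_section <- function(mesh, p, min_points = 3L) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(p, "plane"))
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(list())
  d <- as.numeric(sweep(v, 2L, p$origin) %*% p$normal)
  # nudge on-plane vertices so every crossing is a clean two-edge cut
  eps <- 1e-12 + 1e-9 * max(abs(d))
  d[abs(d) < eps] <- eps
  s <- matrix(d[f], ncol = 3L)
  pos <- s > 0
  npos <- rowSums(pos)
  cut <- which(npos == 1L | npos == 2L)
  if (length(cut) == 0L) return(list())

  seg_a <- matrix(0, length(cut), 3L)
  seg_b <- matrix(0, length(cut), 3L)
  key_a <- character(length(cut)); key_b <- character(length(cut))
  for (ii in seq_along(cut)) {
    fi <- f[cut[ii], ]
    di <- d[fi]
    odd <- if (sum(di > 0) == 1L) which(di > 0) else which(di <= 0)
    others <- setdiff(1:3, odd)
    p0 <- v[fi[odd], ]; d0 <- di[odd]
    out <- matrix(0, 2L, 3L); keys <- character(2L)
    for (jj in 1:2) {
      p1 <- v[fi[others[jj]], ]; d1 <- di[others[jj]]
      t <- d0 / (d0 - d1)
      out[jj, ] <- p0 + t * (p1 - p0)
      keys[jj] <- paste(sort(c(fi[odd], fi[others[jj]])), collapse = "-")
    }
    seg_a[ii, ] <- out[1L, ]; seg_b[ii, ] <- out[2L, ]
    key_a[ii] <- keys[1L]; key_b[ii] <- keys[2L]
  }

  # chain segments by shared mesh-edge keys
  loops <- chain_segments(key_a, key_b)
  basis <- plane_basis(p)
  res <- list(); cent <- list()
  for (lp in loops) {
    if (length(lp$edges) < min_points || !lp$closed) next
    # lp$edges is an ordered sequence of edge keys; take intersection points
    pts3 <- matrix(0, length(lp$edges), 3L)
    for (k in seq_along(lp$edges)) {
      hit <- match(lp$edges[k], key_a)
      pts3[k, ] <- if (!is.na(hit)) seg_a[hit, ] else
        seg_b[match(lp$edges[k], key_b), ]
    }
    u <- as.numeric(sweep(pts3, 2L, p$origin) %*% basis$e1)
    w <- as.numeric(sweep(pts3, 2L, p$origin) %*% basis$e2)
    ct <- tryCatch(contour2d(cbind(u, w)), error = function(e) NULL)
    if (!is.null(ct)) {
      res[[length(res) + 1L]] <- ct
      cent[[length(cent) + 1L]] <- colMeans(pts3)
    }
  }
  attr(res, "centroids3d") <- cent
  res
}

# chain segments given by (edge-key endpoint A, edge-key endpoint B) into
# closed loops of edge keys; each key appears in exactly two segments on a
# manifold cut
chain_segments <- function(key_a, key_b) {
  nseg <- length(key_a)
  keys <- unique(c(key_a, key_b))
  ka <- match(key_a, keys); kb <- match(key_b, keys)
  # adjacency: for each node (edge key), the segments touching it
  touch <- vector("list", length(keys))
  for (i in seq_len(nseg)) {
    touch[[ka[i]]] <- c(touch[[ka[i]]], i)
    touch[[kb[i]]] <- c(touch[[kb[i]]], i)
  }
  used <- logical(nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    node_seq <- c(ka[start], kb[start])
    closed <- FALSE
    repeat {
      tail_node <- node_seq[length(node_seq)]
      nxt <- touch[[tail_node]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) {
        closed <- tail_node == node_seq[1L]
        break
      }
      i <- nxt[1L]
      used[i] <- TRUE
      nn <- if (ka[i] == tail_node) kb[i] else ka[i]
      if (nn == node_seq[1L]) { closed <- TRUE; break }
      node_seq <- c(node_seq, nn)
    }
    loops[[length(loops) + 1L]] <-
      list(edges = keys[node_seq], closed = closed)
  }
  loops
}

# ---- connectivity, holes, components --------------------------------------

edge_key_mat <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

edge_keys_num <- function(e, n) pmin(e[, 1L], e[, 2L]) * (n + 1) +
  pmax(e[, 1L], e[, 2L])

#' Boundary edges of a mesh
#' @param mesh a [surface_mesh].
#' @return k x 2 matrix of vertex index pairs used by exactly one face.
#' @export
boundary_edges <- function(mesh) {
  e <- edge_key_mat(mesh$faces)
  key <- edge_keys_num(e, nrow(mesh$vertices))
  id <- match(key, unique(key))
  cnt <- tabulate(id)[id]
  e[cnt == 1L, , drop = FALSE]
}

#' Is the mesh watertight?
#'
#' True when every edge is shared by exactly two faces.
#' @param mesh a [surface_mesh].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  key <- sort(edge_keys_num(edge_key_mat(mesh$faces), nrow(mesh$vertices)))
  n <- length(key)
  if (n %% 2L != 0L) return(FALSE)
  odd <- key[seq(1L, n, by = 2L)]
  even <- key[seq(2L, n, by = 2L)]
  all(odd == even) && !any(odd[-1L] == even[-length(even)])
}

#' Fill boundary holes with centroid fans
#'
#' Finds boundary loops and triangulates each with a fan to the loop
#' centroid. Intended for the small end-cap and reconstruction holes of
#' tubular models, not for arbitrary topology repair.
#'
#' @param mesh a [surface_mesh].
#' @param max_loop maximum number of edges a hole may have to be filled.
#' @return mesh with holes filled.
#' @export
fill_holes <- function(mesh, max_loop = 2000L) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) return(mesh)
  # orient boundary edges as they appear in faces (so fans close consistently)
  loops <- boundary_loops(mesh, be)
  v <- mesh$vertices
  f <- mesh$faces
  nv0 <- nrow(v)
  # existing ordered half-edges: a fan triangle over boundary edge (a, b)
  # must traverse it in the opposite direction to the face that owns it
  he_key <- c(f[, 1L] * (nv0 + 1) + f[, 2L],
              f[, 2L] * (nv0 + 1) + f[, 3L],
              f[, 3L] * (nv0 + 1) + f[, 1L])
  for (lp in loops) {
    if (length(lp) < 3L || length(lp) > max_loop) next
    cpt <- colMeans(v[lp, , drop = FALSE])
    v <- rbind(v, cpt)
    ci <- nrow(v)
    aa <- lp; bb <- c(lp[-1L], lp[1L])
    fwd <- (aa * (nv0 + 1) + bb) %in% he_key
    fan <- cbind(ifelse(fwd, bb, aa), ifelse(fwd, aa, bb), ci)
    f <- rbind(f, fan)
  }
  out <- surface_mesh(v, f)
  if (mesh_volume(out) < 0) out <- flip_faces(out)
  out
}

# order boundary edges into vertex loops
boundary_loops <- function(mesh, be = boundary_edges(mesh)) {
  if (nrow(be) == 0L) return(list())
  nbr <- split(c(be[, 2L], be[, 1L]), c(be[, 1L], be[, 2L]))
  verts <- as.integer(names(nbr))
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (v0 in verts) {
    if (!is.null(visited[[as.character(v0)]])) next
    lp <- v0
    visited[[as.character(v0)]] <- TRUE
    prev <- -1L; cur <- v0
    repeat {
      nxts <- nbr[[as.character(cur)]]
      nxts <- nxts[nxts != prev]
      nxts <- nxts[vapply(nxts, function(x)
        is.null(visited[[as.character(x)]]), logical(1))]
      if (length(nxts) == 0L) break
      prev <- cur; cur <- nxts[1L]
      visited[[as.character(cur)]] <- TRUE
      lp <- c(lp, cur)
    }
    if (length(lp) >= 3L) loops[[length(loops) + 1L]] <- lp
  }
  loops
}

#' Keep the largest connected component of a mesh
#' @param mesh a [surface_mesh].
#' @return the component with the largest total face area.
#' @export
largest_component <- function(mesh) {
  comp <- mesh_components(mesh)
  if (max(comp) == 1L) return(mesh)
  areas <- face_areas(mesh)
  fcomp <- comp[mesh$faces[, 1L]]
  sums <- rowsum(areas, fcomp)
  best <- as.integer(rownames(sums))[which.max(sums)]
  compact_mesh(surface_mesh(mesh$vertices,
                            mesh$faces[fcomp == best, , drop = FALSE]))
}

# vertex component labels via the edge graph
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  e <- edge_key_mat(mesh$faces)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

# drop unreferenced vertices
compact_mesh <- function(mesh) {
  used <- sort(unique(as.integer(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[mesh$faces], ncol = 3L))
}

#' Orient mesh faces consistently outward
#'
#' Propagates a consistent winding across shared edges and flips the whole
#' mesh if its signed volume comes out negative, so closed meshes end up with
#' outward normals.
#'
#' @param mesh a [surface_mesh].
#' @return oriented mesh.
#' @export
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  nv <- nrow(mesh$vertices)
  # half-edges per face; adjacent faces share an undirected edge key
  he_from <- cbind(f[, 1L], f[, 2L], f[, 3L])
  he_to <- cbind(f[, 2L], f[, 3L], f[, 1L])
  ekey <- pmin(he_from, he_to) * (nv + 1) + pmax(he_from, he_to)
  face_of <- rep(seq_len(nf), 3L)
  ord <- order(as.vector(ekey))
  sk <- as.vector(ekey)[ord]; sf <- face_of[ord]
  same <- which(sk[-1L] == sk[-length(sk)])
  adj_a <- sf[same]; adj_b <- sf[same + 1L]
  # consistent orientation <=> the shared edge is traversed in opposite
  # directions by the two faces
  dir_of <- as.vector(he_from < he_to)[ord]
  agree <- dir_of[same] != dir_of[same + 1L]
  if (all(agree)) {  # already consistent: only the global sign can be off
    if (mesh_volume(mesh) < 0) mesh <- flip_faces(mesh)
    return(mesh)
  }
  g <- igraph::graph_from_edgelist(cbind(adj_a, adj_b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nf - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  flip <- logical(nf)
  pair_key <- pmin(adj_a, adj_b) * (nf + 1) + pmax(adj_a, adj_b)
  for (root in which(!duplicated(comp))) {
    bfs <- igraph::bfs(g, root = root, unreachable = FALSE, father = TRUE,
                       order = TRUE)
    vord <- as.integer(bfs$order)
    vord <- vord[!is.na(vord)]
    fa <- as.integer(bfs$father)
    vk <- pmin(vord, fa[vord]) * (nf + 1) + pmax(vord, fa[vord])
    ag <- agree[match(vk, pair_key)]
    for (ii in seq_along(vord)) {
      v <- vord[ii]
      if (is.na(fa[v])) next
      flip[v] <- if (isTRUE(ag[ii])) flip[fa[v]] else !flip[fa[v]]
    }
  }
  f[flip, ] <- f[flip, c(1L, 3L, 2L)]
  out <- mesh; out$faces <- f
  if (mesh_volume(out) < 0) out <- flip_faces(out)
  out
}
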