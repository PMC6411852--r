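# Surface extraction (marching tetrahedra on a Kuhn-subdivided grid),
# Taubin smoothing, mesh metrics, and generation of the conforming
# cube-minus-cell volumetric tetrahedral mesh used by the elasticity solver.

# The six Kuhn simplices of the unit cube, as corner offsets (dz, dx, dy).
# They tile space consistently (shared faces between neighboring cubes match),
# which makes both marching tetrahedra and the volume mesher watertight.
.kuhn_tets <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    corners <- matrix(0, 4, 3)
    for (i in 1:3) corners[i + 1, ] <- corners[i, ]
    for (i in 1:3) corners[(i + 1):4, p[i]] <- 1
    corners
  })
})

#' Binary voxel mask
#'
#' @param voxels logical 3D array (z, x, y).
#' @param pitch voxel pitch (um, length 3).
#' @param offset_um physical position of voxel (1,1,1)'s center (um).
#' @param time_index acquisition time index.
#' @return object of class `tfocm_mask`.
#' @export
binary_mask <- function(voxels, pitch, offset_um = c(0, 0, 0), time_index = 0L) {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3L)
  structure(list(voxels = voxels, pitch = pitch, offset_um = offset_um,
                 time_index = time_index),
            class = "tfocm_mask")
}

#' Extract an iso-surface triangle mesh by marching tetrahedra
#'
#' Each grid cube is split into the six Kuhn simplices; within each simplex
#' the iso-surface of the trilinear field is approximated by the linear
#' interpolant, yielding a closed, consistently oriented triangle mesh
#' (outward normals point toward decreasing field).
#'
#' @param field numeric 3D array.
#' @param iso iso-value.
#' @param pitch grid pitch (um, length 3).
#' @param origin physical position of grid node (1,1,1) (um).
#' @return a `tfocm_surface` (vertices n x 3 um, faces m x 3).
#' @export
marching_tetrahedra <- function(field, iso = 0.5, pitch = c(1, 1, 1),
                                origin = c(0, 0, 0)) {
  d <- dim(field)
  nzc <- d[1] - 1L; nxc <- d[2] - 1L; nyc <- d[3] - 1L
  if (min(nzc, nxc, nyc) < 1L) stop("field too small")
  # cube base node indices (0-based)
  base <- as.matrix(expand.grid(iz = 0:(nzc - 1L), ix = 0:(nxc - 1L),
                                iy = 0:(nyc - 1L)))
  lin <- function(izxy) (izxy[, 3]) * d[1] * d[2] + (izxy[, 2]) * d[1] +
    izxy[, 1] + 1
  verts_key <- numeric(0)
  tri_v1 <- tri_v2 <- tri_v3 <- numeric(0)   # vertex keys per triangle corner
  key_pos <- list()
  ng <- prod(d)
  edge_vertex <- function(na, nb, va, vb) {
    # na, nb: global node linear indices; returns key and position
    swap <- na > nb
    a <- ifelse(swap, nb, na); b <- ifelse(swap, na, nb)
    key <- (a - 1) * ng + b
    t <- (iso - va) / (vb - va)
    pa <- .node_xyz(na, d, pitch, origin)
    pb <- .node_xyz(nb, d, pitch, origin)
    list(key = key, pos = pa + (pb - pa) * t)
  }
  all_keys <- numeric(0); all_pos <- matrix(numeric(0), 0, 3)
  tris <- list(); ti <- 1L
  for (tet in .kuhn_tets) {
    # global node indices of the 4 tet corners for every cube
    nid <- sapply(1:4, function(i) lin(sweep(base, 2, tet[i, ], "+")))
    vals <- matrix(field[nid], ncol = 4)
    ins <- vals > iso
    cfg <- ins %*% c(8L, 4L, 2L, 1L)
    for (cf in setdiff(unique(as.vector(cfg)), c(0L, 15L))) {
      rows <- which(cfg == cf)
      if (!length(rows)) next
      inside <- which(bitwAnd(cf, c(8L, 4L, 2L, 1L)) > 0)
      outside <- setdiff(1:4, inside)
      emit <- function(pairs) {
        # pairs: list of 2-vectors (corner indices) defining edge vertices
        ev <- lapply(pairs, function(pr) {
          edge_vertex(nid[rows, pr[1]], nid[rows, pr[2]],
                      vals[rows, pr[1]], vals[rows, pr[2]])
        })
        ev
      }
      if (length(inside) == 1L) {
        A <- inside; oth <- outside
        ev <- emit(list(c(A, oth[1]), c(A, oth[2]), c(A, oth[3])))
        tris[[ti]] <- .orient_tris(ev[[1]], ev[[2]], ev[[3]],
                                   .corner_pos(nid[rows, A], d, pitch, origin),
                                   inward = TRUE)
        ti <- ti + 1L
      } else if (length(inside) == 3L) {
        A <- outside; oth <- inside
        ev <- emit(list(c(A, oth[1]), c(A, oth[2]), c(A, oth[3])))
        tris[[ti]] <- .orient_tris(ev[[1]], ev[[2]], ev[[3]],
                                   .corner_pos(nid[rows, A], d, pitch, origin),
                                   inward = FALSE)
        ti <- ti + 1L
      } else {
        A <- inside[1]; B <- inside[2]; C <- outside[1]; D <- outside[2]
        ev <- emit(list(c(A, C), c(A, D), c(B, D), c(B, C)))
        ref <- .corner_pos(nid[rows, A], d, pitch, origin)
        tris[[ti]] <- .orient_tris(ev[[1]], ev[[2]], ev[[3]], ref, inward = TRUE)
        ti <- ti + 1L
        tris[[ti]] <- .orient_tris(ev[[1]], ev[[3]], ev[[4]], ref, inward = TRUE)
        ti <- ti + 1L
      }
    }
  }
  if (!length(tris)) stop("no iso-surface found at iso = ", iso)
  K <- do.call(rbind, lapply(tris, `[[`, "keys"))
  P <- do.call(rbind, lapply(tris, `[[`, "pos"))
  uk <- unique(as.vector(K))
  vid <- matrix(match(as.vector(K), uk), nrow(K), 3)
  vpos <- matrix(0, length(uk), 3)
  for (corner in 1:3) {
    cols <- (3 * corner - 2):(3 * corner)
    vpos[vid[, corner], ] <- P[, cols]
  }
  # drop degenerate (zero-area) triangles from flat tet faces
  a <- vpos[vid[, 2], ] - vpos[vid[, 1], ]
  b <- vpos[vid[, 3], ] - vpos[vid[, 1], ]
  ar <- 0.5 * sqrt(rowSums(.cross3(a, b)^2))
  good <- ar > max(ar) * 1e-10 & vid[, 1] != vid[, 2] &
    vid[, 2] != vid[, 3] & vid[, 1] != vid[, 3]
  new_surface(vpos, vid[good, , drop = FALSE])
}

#' Construct a triangle surface mesh object
#'
#' @param vertices n x 3 matrix (um).
#' @param faces m x 3 integer matrix (1-based, counterclockwise seen from
#'   outside).
#' @return a `tfocm_surface`.
#' @export
new_surface <- function(vertices, faces) {
  used <- sort(unique(as.vector(faces)))
  if (length(used) < nrow(vertices)) {
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3)
  }
  structure(list(vertices = vertices, faces = faces), class = "tfocm_surface")
}

#' @export
print.tfocm_surface <- function(x, ...) {
  cat(sprintf("triangle surface mesh: %d vertices, %d faces, area %.1f um^2, volume %.1f um^3%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x), mesh_volume(x),
              if (mesh_is_closed(x)) ", watertight" else " (NOT closed)"))
  invisible(x)
}

.node_xyz <- function(nid, d, pitch, origin) {
  nid0 <- nid - 1
  iz <- nid0 %% d[1]
  ix <- (nid0 %/% d[1]) %% d[2]
  iy <- nid0 %/% (d[1] * d[2])
  cbind(iz * pitch[1] + origin[1], ix * pitch[2] + origin[2],
        iy * pitch[3] + origin[3])
}

.corner_pos <- function(nid, d, pitch, origin) .node_xyz(nid, d, pitch, origin)

.orient_tris <- function(e1, e2, e3, ref, inward) {
  # normals must point away from the inside region: away from `ref` when
  # ref is an inside corner (inward = TRUE), toward it when outside.
  n <- .cross3(e2$pos - e1$pos, e3$pos - e1$pos)
  dir <- e1$pos - ref
  s <- rowSums(n * dir)
  flip <- if (inward) s < 0 else s > 0
  k1 <- e1$key; k2 <- ifelse(flip, e3$key, e2$key); k3 <- ifelse(flip, e2$key, e3$key)
  p2 <- e2$pos; p3 <- e3$pos
  p2[flip, ] <- e3$pos[flip, ]; p3[flip, ] <- e2$pos[flip, ]
  list(keys = cbind(k1, k2, k3),
       pos = cbind(e1$pos, p2, p3))   # 9 columns: p1, p2, p3
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Surface mesh metrics
#'
#' `mesh_area` is the total triangle area; `mesh_volume` the signed enclosed
#' volume (positive for outward orientation); `mesh_is_closed` checks that
#' every edge is shared by exactly two faces.
#' @param mesh a `tfocm_surface`.
#' @return numeric scalar (or logical for `mesh_is_closed`).
#' @export
mesh_area <- function(mesh) sum(facet_areas(mesh))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(p1 * .cross3(p2, p3))) / 6
}

#' @rdname mesh_area
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Per-facet areas, outward normals and centroids of a surface mesh
#' @param mesh a `tfocm_surface`.
#' @return numeric vector / matrix.
#' @export
facet_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * sqrt(rowSums(.cross3(a, b)^2))
}

#' @rdname facet_areas
#' @export
facet_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- .cross3(a, b)
  n / sqrt(rowSums(n^2))
}

#' @rdname facet_areas
#' @export
facet_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Taubin (shrink-compensated Laplacian) smoothing of a surface mesh
#'
#' Alternates Laplacian steps with positive factor `lambda` and negative
#' factor `mu`; with the default pair the surface is smoothed with very
#' little volume shrinkage.
#'
#' @param mesh a `tfocm_surface`.
#' @param iters smoothing iterations (one iteration = one lambda + one mu
#'   step).
#' @param lambda,mu Taubin factors.
#' @return the smoothed `tfocm_surface`.
#' @export
taubin_smooth <- function(mesh, iters = 10L, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n),
                            repr = "C")
  A <- A > 0
  deg <- Matrix::rowSums(A)
  W <- A / deg
  for (it in seq_len(iters)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  out <- mesh
  out$vertices <- v
  out
}

#' Decimate a surface mesh by vertex clustering
#'
#' Vertices are clustered on a uniform grid whose cell size is chosen to
#' approach `target_faces`; faces collapsing to fewer than three distinct
#' clusters are dropped. Fast and robust, at the cost of some regularity;
#' intended for display and for reducing facet counts before inversion.
#'
#' @param mesh a `tfocm_surface`.
#' @param target_faces approximate face budget.
#' @return the decimated `tfocm_surface`.
#' @export
decimate_mesh <- function(mesh, target_faces) {
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  v <- mesh$vertices
  bb <- apply(v, 2, range)
  span <- pmax(bb[2, ] - bb[1, ], 1e-9)
  fallback <- NULL
  best_closed <- NULL
  for (jit in c(0, 0.37, 0.71)) for (ncell in rev(seq(4L, 80L, by = 2L))) {
    h <- max(span) / ncell
    cl <- floor(sweep(v, 2, bb[1, ] - jit * h) / h + 1e-9)
    key <- cl[, 1] * 1e10 + cl[, 2] * 1e5 + cl[, 3]
    uk <- unique(key)
    map <- match(key, uk)
    nf <- matrix(map[mesh$faces], ncol = 3)
    ok <- nf[, 1] != nf[, 2] & nf[, 2] != nf[, 3] & nf[, 1] != nf[, 3]
    nf <- nf[ok, , drop = FALSE]
    # cancel face pairs that collapsed onto the same vertex triple
    keyf <- paste(pmin(nf[, 1], pmin(nf[, 2], nf[, 3])),
                  nf[, 1] + nf[, 2] + nf[, 3],
                  pmax(nf[, 1], pmax(nf[, 2], nf[, 3])))
    tab <- table(keyf)
    nf <- nf[!(keyf %in% names(tab)[tab > 1L]), , drop = FALSE]
    if (nrow(nf) < 8L) next
    nv <- matrix(0, length(uk), 3)
    for (c3 in 1:3) nv[, c3] <- as.vector(tapply(v[, c3], map, mean))
    out <- new_surface(nv, nf)
    closed <- mesh_is_closed(out)
    if (closed && nrow(out$faces) <= target_faces) return(out)
    if (closed && (is.null(best_closed) ||
                   nrow(out$faces) < nrow(best_closed$faces)))
      best_closed <- out
    if (!closed && nrow(out$faces) <= target_faces && is.null(fallback))
      fallback <- out
  }
  # a somewhat larger closed mesh beats a smaller leaky one
  best_closed %||% fallback %||% mesh
}

#' Build a cell-surface triangle mesh from a binary mask
#'
#' Gaussian pre-smoothing of the (zero-padded) mask, marching-tetrahedra
#' iso-surface extraction at 0.5, Taubin smoothing, and optional decimation.
#' The result is closed, manifold and outward-oriented.
#'
#' @param mask a [binary_mask()].
#' @param smoothing_iters Taubin iterations.
#' @param target_faces optional decimation budget (NULL = keep all faces).
#' @param pre_sigma Gaussian pre-smoothing of the indicator (voxels).
#' @param min_voxels minimum mask size; smaller masks are rejected as
#'   degenerate.
#' @return a `tfocm_surface`.
#' @export
make_surface_mesh <- function(mask, smoothing_iters = 10L, target_faces = NULL,
                              pre_sigma = 1, min_voxels = 8L) {
  stopifnot(inherits(mask, "tfocm_mask"))
  nvox <- sum(mask$voxels)
  if (nvox < min_voxels)
    stop("mask has only ", nvox, " voxels; too small to mesh")
  pad <- 2L
  d <- dim(mask$voxels)
  f <- array(0, d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask$voxels)
  f <- gaussian_smooth3(f, pre_sigma)
  origin <- mask$offset_um - pad * mask$pitch
  surf <- marching_tetrahedra(f, iso = 0.5, pitch = mask$pitch, origin = origin)
  if (smoothing_iters > 0) surf <- taubin_smooth(surf, smoothing_iters)
  if (!is.null(target_faces)) {
    dec <- decimate_mesh(surf, target_faces)
    if (mesh_is_closed(dec)) surf <- dec
    else warning("decimation produced a non-watertight mesh; keeping the ",
                 "full-resolution surface (", nrow(surf$faces), " faces)")
  }
  if (!mesh_is_closed(surf))
    stop("surface mesh is not watertight (", nrow(surf$faces), " faces); ",
         "inspect the mask for single-voxel bridges")
  if (mesh_volume(surf) < 0) surf$faces <- surf$faces[, c(1, 3, 2)]
  surf
}

#' Point-in-mesh test by ray casting
#'
#' Casts a ray along +x (the fast axis) from each point and counts triangle
#' crossings; odd parity means inside. Points are jittered by a tiny amount
#' to avoid edge-grazing rays.
#'
#' @param points n x 3 matrix (z, x, y) in um.
#' @param mesh a closed `tfocm_surface`.
#' @return logical vector.
#' @export
point_in_mesh <- function(points, mesh) {
  points <- rbind(points)
  v <- mesh$vertices; f <- mesh$faces
  eps <- 1e-7 * max(apply(v, 2, function(c) diff(range(c))), 1)
  set.seed(42L)
  pj <- points + matrix(stats::runif(length(points), -eps, eps), nrow(points))
  cnt <- integer(nrow(points))
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  for (tr in seq_len(nrow(f))) {
    # triangle in (z, y) projection; ray along +x
    az <- p1[tr, 1]; ay <- p1[tr, 3]
    bz <- p2[tr, 1]; by <- p2[tr, 3]
    cz <- p3[tr, 1]; cy <- p3[tr, 3]
    den <- (by - cy) * (az - cz) + (cz - bz) * (ay - cy)
    if (abs(den) < 1e-14) next
    l1 <- ((by - cy) * (pj[, 1] - cz) + (cz - bz) * (pj[, 3] - cy)) / den
    l2 <- ((cy - ay) * (pj[, 1] - cz) + (az - cz) * (pj[, 3] - cy)) / den
    l3 <- 1 - l1 - l2
    hit <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(hit)) next
    xs <- l1[hit] * p1[tr, 2] + l2[hit] * p2[tr, 2] + l3[hit] * p3[tr, 2]
    fwd <- xs > pj[hit, 2]
    cnt[hit][fwd] <- cnt[hit][fwd] + 1L
  }
  cnt %% 2L == 1L
}

#' Voxelize a closed surface mesh onto a grid
#'
#' @param mesh a closed `tfocm_surface`.
#' @param dims grid dimensions (z, x, y).
#' @param pitch voxel pitch (um).
#' @param origin physical position of voxel (1,1,1) center (um).
#' @return a [binary_mask()].
#' @export
voxelize_mesh <- function(mesh, dims, pitch, origin = c(0, 0, 0)) {
  g <- as.matrix(expand.grid(iz = seq_len(dims[1]), ix = seq_len(dims[2]),
                             iy = seq_len(dims[3])))
  pts <- cbind((g[, 1] - 1) * pitch[1] + origin[1],
               (g[, 2] - 1) * pitch[2] + origin[2],
               (g[, 3] - 1) * pitch[3] + origin[3])
  inside <- point_in_mesh(pts, mesh)
  binary_mask(array(inside, dims), pitch, origin)
}

# Closest-point distance from points to a triangle soup (exact projection).
.point_surface_dist <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(points)
  best <- rep(Inf, n)
  proj <- points
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  for (tr in seq_len(nrow(f))) {
    dp <- sweep(points, 2, p1[tr, ])
    b1 <- dp %*% e1[tr, ]; b2 <- dp %*% e2[tr, ]
    den <- a11[tr] * a22[tr] - a12[tr]^2
    s <- (a22[tr] * b1 - a12[tr] * b2) / den
    t <- (a11[tr] * b2 - a12[tr] * b1) / den
    # clamp to the triangle (approximate but adequate: clamp then renormalize)
    s <- pmax(0, pmin(1, s)); t <- pmax(0, pmin(1, t))
    over <- s + t > 1
    if (any(over)) {
      sc <- s[over] + t[over]
      s[over] <- s[over] / sc; t[over] <- t[over] / sc
    }
    cp <- matrix(p1[tr, ], n, 3, byrow = TRUE) + s %*% t(e1[tr, ]) +
      t %*% t(e2[tr, ])
    d2 <- rowSums((points - cp)^2)
    upd <- d2 < best
    best[upd] <- d2[upd]
    proj[upd, ] <- cp[upd, , drop = FALSE]
  }
  list(dist = sqrt(best), proj = proj)
}

#' Generate a conforming tetrahedral mesh of the cube-minus-cell domain
#'
#' Builds a structured grid over the imaging box, splits it into Kuhn
#' tetrahedra, removes elements whose centroid lies inside the cell surface,
#' and snaps the nodes of the exposed internal boundary onto the cell
#' surface so that the labeled `cell_surface` facets approximate the true
#' surface (an inscribed triangulation). Boundary facets exactly partition
#' into `outer` (the box) and `cell` labels. Snaps that would invert an
#' element are relaxed until all element volumes are positive.
#'
#' @param surface a closed `tfocm_surface` strictly inside the box, or NULL
#'   for a plain cube mesh (only outer facets).
#' @param box length-3 box dimensions (um); the box spans `[0, box]` in each
#'   axis (z, x, y).
#' @param n length-3 (or scalar) grid cell counts per axis.
#' @param inside optional predicate `function(points) -> logical` overriding
#'   the ray-casting inside test (useful when an implicit phantom is known).
#' @return object of class `tfocm_mesh3d`: `nodes` (N x 3), `tets` (M x 4),
#'   `cell_facets` (F x 3 node triples, outward from the elastic domain,
#'   i.e. pointing into the cell), `cell_facet_areas`, `cell_facet_centroids`,
#'   `cell_facet_normals`, `outer_nodes` (indices on the box boundary),
#'   `h` (cell size), `box`, `quality` (min volume ratio).
#' @export
make_volume_mesh <- function(surface, box, n = 12L, inside = NULL,
                             min_quality = 0.005) {
  n <- rep(as.integer(n), length.out = 3L)
  h <- box / n
  dgrid <- n + 1L
  g <- as.matrix(expand.grid(iz = 0:n[1], ix = 0:n[2], iy = 0:n[3]))
  nodes <- cbind(g[, 1] * h[1], g[, 2] * h[2], g[, 3] * h[3])
  nlin <- function(izxy) izxy[, 3] * dgrid[1] * dgrid[2] +
    izxy[, 2] * dgrid[1] + izxy[, 1] + 1
  if (!is.null(surface)) {
    bb <- apply(surface$vertices, 2, range)
    if (any(bb[1, ] <= 0) || any(bb[2, ] >= box))
      stop("cell surface intersects or touches the box boundary")
    if (is.null(inside)) inside <- function(p) point_in_mesh(p, surface)
  }
  # element centroids; drop cells inside the cell body
  cbase <- as.matrix(expand.grid(iz = 0:(n[1] - 1L), ix = 0:(n[2] - 1L),
                                 iy = 0:(n[3] - 1L)))
  tets <- list()
  parent <- list()
  for (ti in seq_along(.kuhn_tets)) {
    tet <- .kuhn_tets[[ti]]
    nid <- sapply(1:4, function(i) nlin(sweep(cbase, 2, tet[i, ], "+")))
    tets[[ti]] <- nid
    parent[[ti]] <- cbase
  }
  tets <- do.call(rbind, tets)
  parent <- do.call(rbind, parent)
  tv <- .tet_volumes(nodes, tets)
  neg <- tv < 0
  if (any(neg)) tets[neg, 3:4] <- tets[neg, c(4, 3)]
  keep <- rep(TRUE, nrow(tets))
  if (!is.null(surface)) {
    # a tet is removed if any node or its centroid is inside the cell, so
    # the exposed boundary nodes all lie outside and snapping onto the
    # surface moves them inward into the cavity (no element squashing)
    pad <- 2 * max(h)
    near_pt <- function(p) {
      p[, 1] > bb[1, 1] - pad & p[, 1] < bb[2, 1] + pad &
        p[, 2] > bb[1, 2] - pad & p[, 2] < bb[2, 2] + pad &
        p[, 3] > bb[1, 3] - pad & p[, 3] < bb[2, 3] + pad
    }
    inside_cached <- rep(FALSE, nrow(nodes))
    nb <- near_pt(nodes)
    if (any(nb)) inside_cached[nb] <- inside(nodes[nb, , drop = FALSE])
    cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] +
              nodes[tets[, 4], ]) / 4
    cin <- rep(FALSE, nrow(cen))
    nbc <- near_pt(cen)
    if (any(nbc)) cin[nbc] <- inside(cen[nbc, , drop = FALSE])
    anyin <- inside_cached[tets[, 1]] | inside_cached[tets[, 2]] |
      inside_cached[tets[, 3]] | inside_cached[tets[, 4]]
    keep <- !(anyin | cin)
  }
  tets_k <- tets[keep, , drop = FALSE]
  parent_k <- parent[keep, , drop = FALSE]
  # boundary faces: those appearing exactly once among kept tets
  faces <- rbind(tets_k[, c(1, 2, 3)], tets_k[, c(1, 2, 4)],
                 tets_k[, c(1, 3, 4)], tets_k[, c(2, 3, 4)])
  opp <- c(tets_k[, 4], tets_k[, 3], tets_k[, 2], tets_k[, 1])
  fs <- t(apply(faces, 1, sort))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  tab <- table(key)
  bnd <- key %in% names(tab)[tab == 1L]
  bfaces <- faces[bnd, , drop = FALSE]
  bopp <- opp[bnd]
  # classify: a face is outer if all three nodes lie on a box plane
  onb <- function(idx) {
    p <- nodes[idx, , drop = FALSE]
    tol <- 1e-9 * max(box)
    (abs(p[, 1]) < tol | abs(p[, 1] - box[1]) < tol) |
      (abs(p[, 2]) < tol | abs(p[, 2] - box[2]) < tol) |
      (abs(p[, 3]) < tol | abs(p[, 3] - box[3]) < tol)
  }
  same_plane <- function(fidx) {
    p <- nodes[fidx, , drop = FALSE]
    tol <- 1e-9 * max(box)
    any(vapply(1:3, function(ax)
      (max(abs(p[, ax])) < tol) || (max(abs(p[, ax] - box[ax])) < tol),
      logical(1)))
  }
  is_outer <- vapply(seq_len(nrow(bfaces)), function(i)
    same_plane(bfaces[i, ]), logical(1))
  cfaces <- bfaces[!is_outer, , drop = FALSE]
  copp <- bopp[!is_outer]
  # snap internal-boundary nodes onto the surface
  quality <- 1
  if (!is.null(surface) && nrow(cfaces)) {
    snap_nodes <- sort(unique(as.vector(cfaces)))
    pd <- .point_surface_dist(nodes[snap_nodes, , drop = FALSE], surface)
    target <- pd$proj
    # tangential relaxation: average each snapped node with its boundary
    # neighbors and re-project, smoothing out staircase pleats
    sidx <- integer(nrow(nodes)); sidx[snap_nodes] <- seq_along(snap_nodes)
    fe <- rbind(cfaces[, 1:2], cfaces[, 2:3], cfaces[, c(3, 1)])
    fe <- cbind(sidx[fe[, 1]], sidx[fe[, 2]])
    fe <- rbind(fe, fe[, 2:1])
    W <- Matrix::sparseMatrix(i = fe[, 1], j = fe[, 2], x = 1,
                              dims = rep(length(snap_nodes), 2))
    W <- (W > 0) / pmax(Matrix::rowSums(W > 0), 1)
    for (it in 1:4) {
      avg <- as.matrix(W %*% target)
      target <- .point_surface_dist(avg, surface)$proj
    }
    orig <- nodes[snap_nodes, , drop = FALSE]
    alpha <- rep(1, length(snap_nodes))
    tv0 <- .tet_volumes(nodes, tets_k)
    ref_vol <- stats::median(abs(tv0))
    for (pass in 1:10) {
      nodes[snap_nodes, ] <- orig + alpha * (target - orig)
      tv <- .tet_volumes(nodes, tets_k)
      bad <- which(tv < min_quality * ref_vol)
      if (!length(bad)) break
      bad_nodes <- unique(as.vector(tets_k[bad, ]))
      shrink <- snap_nodes %in% bad_nodes
      if (!any(shrink)) break
      alpha[shrink] <- alpha[shrink] * 0.5
      if (pass == 10L) nodes[snap_nodes[shrink], ] <- orig[shrink, , drop = FALSE]
    }
    tv <- .tet_volumes(nodes, tets_k)
    if (any(tv <= 0)) stop("volume mesh has inverted elements after snapping")
    quality <- min(tv) / stats::median(tv)
  }
  # orient cell facets so normals point out of the domain (into the cell)
  if (nrow(cfaces)) {
    p1 <- nodes[cfaces[, 1], , drop = FALSE]
    nvec <- .cross3(nodes[cfaces[, 2], , drop = FALSE] - p1,
                    nodes[cfaces[, 3], , drop = FALSE] - p1)
    dir <- nodes[copp, , drop = FALSE] - p1
    flip <- rowSums(nvec * dir) > 0
    cfaces[flip, ] <- cfaces[flip, c(1, 3, 2), drop = FALSE]
  }
  csurf <- list(vertices = nodes, faces = cfaces)
  class(csurf) <- "tfocm_surface"
  ofaces <- bfaces[is_outer, , drop = FALSE]
  oopp <- bopp[is_outer]
  if (nrow(ofaces)) {
    p1 <- nodes[ofaces[, 1], , drop = FALSE]
    nvec <- .cross3(nodes[ofaces[, 2], , drop = FALSE] - p1,
                    nodes[ofaces[, 3], , drop = FALSE] - p1)
    dir <- nodes[oopp, , drop = FALSE] - p1
    flip <- rowSums(nvec * dir) > 0
    ofaces[flip, ] <- ofaces[flip, c(1, 3, 2), drop = FALSE]
  }
  outer_nodes <- which(onb(seq_len(nrow(nodes))))
  m <- structure(list(
    nodes = nodes, tets = tets_k, parent_cell = parent_k,
    grid_n = n, h = h, box = box,
    cell_facets = cfaces,
    cell_facet_areas = if (nrow(cfaces)) facet_areas(csurf) else numeric(0),
    cell_facet_centroids = if (nrow(cfaces)) facet_centroids(csurf) else
      matrix(0, 0, 3),
    cell_facet_normals = if (nrow(cfaces)) facet_normals(csurf) else
      matrix(0, 0, 3),
    outer_nodes = outer_nodes,
    outer_facets = ofaces,
    quality = quality), class = "tfocm_mesh3d")
  m
}

.tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  rowSums(a * .cross3(b, c3)) / 6
}

#' @export
print.tfocm_mesh3d <- function(x, ...) {
  cat(sprintf("tetrahedral mesh: %d nodes, %d tets, %d cell-surface facets (area %.1f um^2), quality %.3f\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$cell_facets),
              sum(x$cell_facet_areas), x$quality))
  invisible(x)
}
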