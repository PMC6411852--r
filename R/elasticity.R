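# Linear-elastic forward machinery: the analytic Kelvin point-force oracle
# and a linear-tetrahedron FEM for the cube-minus-cell domain. Internal
# units: lengths um, stresses Pa, forces Pa.um^2 (1e-3 nN).

#' Linear elastic material model
#'
#' Homogeneous, isotropic, time-invariant linear elasticity. The defaults
#' are those of a soft basement-membrane hydrogel: Young's modulus 90 Pa
#' (bulk rheology) and Poisson's ratio 0.45 (nearly incompressible).
#'
#' @param youngs_modulus E in Pa (> 0).
#' @param poisson_ratio nu in (-1, 0.5); the incompressible limit nu = 0.5
#'   is rejected (a pure displacement formulation locks there).
#' @return object of class `tfocm_elastic` with derived `shear_modulus`
#'   (mu = E / (2 (1 + nu))) and first Lame parameter `lame_lambda`.
#' @export
elastic_model <- function(youngs_modulus = 90, poisson_ratio = 0.45) {
  if (youngs_modulus <= 0) stop("youngs_modulus must be positive")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (-1, 0.5); 0.5 is unsupported by the ",
         "displacement formulation")
  structure(list(E = youngs_modulus, nu = poisson_ratio,
                 shear_modulus = youngs_modulus / (2 * (1 + poisson_ratio)),
                 lame_lambda = youngs_modulus * poisson_ratio /
                   ((1 + poisson_ratio) * (1 - 2 * poisson_ratio))),
            class = "tfocm_elastic")
}

#' Kelvin solution: displacement of a point force in an infinite medium
#'
#' `u_i = F_j / (16 pi mu (1 - nu) r) * ((3 - 4 nu) delta_ij + r_i r_j / r^2)`
#' with F the point force, mu the shear modulus and r the source-target
#' distance. On the force axis this collapses to `u = F / (4 pi mu r)`,
#' independent of nu. Serves as the analytic oracle for the FEM solver.
#'
#' @param force_nn length-3 force vector (nN).
#' @param source length-3 source point (um).
#' @param targets n x 3 (or length-3) target points (um).
#' @param model an [elastic_model()].
#' @return n x 3 matrix of displacements (um).
#' @export
kelvin_displacement <- function(force_nn, source, targets, model) {
  targets <- rbind(targets)
  Fv <- nn_to_pa_um2(force_nn)            # Pa.um^2
  d <- sweep(targets, 2, source)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("target coincides with the source point")
  mu <- model$shear_modulus
  nu <- model$nu
  pref <- 1 / (16 * pi * mu * (1 - nu) * r)
  rdotF <- as.vector(d %*% Fv) / r^2
  u <- pref * ((3 - 4 * nu) * matrix(Fv, nrow(targets), 3, byrow = TRUE) +
                 d * rdotF)
  u
}

# ---- FEM assembly --------------------------------------------------------

# Shape-function gradients and volumes for all tets, vectorized.
# Returns list(vol, grads): grads is a list of four n x 3 matrices.
.tet_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c3 <- nodes[tets[, 4], , drop = FALSE] - p1
  bxc <- .cross3(b, c3); cxa <- .cross3(c3, a); axb <- .cross3(a, b)
  det <- rowSums(a * bxc)                  # 6 V
  g2 <- bxc / det; g3 <- cxa / det; g4 <- axb / det
  g1 <- -(g2 + g3 + g4)
  list(vol = det / 6, grads = list(g1, g2, g3, g4))
}

#' Assemble the global stiffness matrix for linear tetrahedra
#'
#' The shear (mu) term is integrated per element. Near the incompressible
#' limit linear tetrahedra lock volumetrically, so by default the
#' dilatational (lambda) term uses mean dilatation over each parent grid
#' hexahedron (the six Kuhn tetrahedra share one averaged volumetric
#' strain), the standard B-bar remedy. Set `vol_averaging = FALSE` for the
#' fully conforming (but locking-prone) assembly.
#'
#' @param mesh a `tfocm_mesh3d`.
#' @param model an [elastic_model()].
#' @param vol_averaging average the volumetric strain over parent hexes.
#' @return sparse symmetric stiffness matrix (3N x 3N, dgCMatrix), dof
#'   ordering `(node - 1) * 3 + component`.
#' @export
fem_assemble <- function(mesh, model, vol_averaging = TRUE) {
  tg <- .tet_gradients(mesh$nodes, mesh$tets)
  V <- tg$vol
  if (any(V <= 0)) stop("mesh contains inverted elements")
  mu <- model$shear_modulus
  lam <- model$lame_lambda
  nn <- nrow(mesh$nodes)
  per_tet_lambda <- if (vol_averaging && !is.null(mesh$parent_cell)) 0 else lam
  ii <- jj <- xx <- vector("list", 16L * 9L)
  idx <- 1L
  for (A in 1:4) for (B in 1:4) {
    ga <- tg$grads[[A]]; gb <- tg$grads[[B]]
    gg <- rowSums(ga * gb)
    na <- mesh$tets[, A]; nb <- mesh$tets[, B]
    for (i in 1:3) for (j in 1:3) {
      kij <- V * (per_tet_lambda * ga[, i] * gb[, j] + mu * gb[, i] * ga[, j] +
                    (i == j) * mu * gg)
      ii[[idx]] <- (na - 1L) * 3L + i
      jj[[idx]] <- (nb - 1L) * 3L + j
      xx[[idx]] <- kij
      idx <- idx + 1L
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * nn, 3 * nn))
  if (per_tet_lambda == 0 && lam != 0) {
    hex <- mesh$parent_cell[, 1] + mesh$grid_n[1] *
      (mesh$parent_cell[, 2] + mesh$grid_n[2] * mesh$parent_cell[, 3])
    # per-tet divergence contributions: dof, hex, value = V * dN/dx
    dof <- val <- vector("list", 12L)
    k <- 1L
    for (A in 1:4) for (i in 1:3) {
      dof[[k]] <- (mesh$tets[, A] - 1L) * 3L + i
      val[[k]] <- V * tg$grads[[A]][, i]
      k <- k + 1L
    }
    dofv <- unlist(dof); valv <- unlist(val); hexv <- rep(hex, 12L)
    key <- paste(hexv, dofv)
    agg <- rowsum(valv, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    hexid <- vapply(parts, function(p) p[1], character(1))
    dofid <- as.integer(vapply(parts, function(p) p[2], character(1)))
    Vh <- rowsum(V, as.character(hex))
    vh_of <- as.vector(Vh)[match(hexid, rownames(Vh))]
    byhex <- split(seq_along(hexid), hexid)
    ii2 <- jj2 <- xx2 <- vector("list", length(byhex))
    for (h in seq_along(byhex)) {
      sel <- byhex[[h]]
      b <- agg[sel]
      dd <- dofid[sel]
      coef <- lam / vh_of[sel][1]
      op <- coef * (b %o% b)
      ii2[[h]] <- rep(dd, length(dd))
      jj2[[h]] <- rep(dd, each = length(dd))
      xx2[[h]] <- as.vector(op)
    }
    K <- K + Matrix::sparseMatrix(i = unlist(ii2), j = unlist(jj2),
                                  x = unlist(xx2), dims = c(3 * nn, 3 * nn))
  }
  Matrix::drop0((K + Matrix::t(K)) / 2)
}

#' Consistent nodal loads for piecewise-constant facet tractions
#'
#' Each facet's traction (Pa) times its area is split equally among its
#' three nodes (the consistent load for linear elements under constant
#' traction).
#'
#' @param mesh a `tfocm_mesh3d`.
#' @param facets f x 3 node-index matrix.
#' @param tractions f x 3 traction vectors (Pa) or a single length-3 vector.
#' @param areas optional facet areas (computed if missing).
#' @return load vector of length 3N (Pa.um^2).
#' @export
facet_loads <- function(mesh, facets, tractions, areas = NULL) {
  if (is.null(dim(tractions)))
    tractions <- matrix(tractions, nrow(facets), 3, byrow = TRUE)
  if (is.null(areas)) {
    fs <- list(vertices = mesh$nodes, faces = facets)
    class(fs) <- "tfocm_surface"
    areas <- facet_areas(fs)
  }
  f <- numeric(3 * nrow(mesh$nodes))
  w <- tractions * areas / 3
  for (cn in 1:3) for (cc in 1:3) {
    dof <- (facets[, cn] - 1L) * 3L + cc
    acc <- rowsum(w[, cc], dof)
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc
  }
  f
}

#' Solve the static linear-elastic problem
#'
#' Applies Dirichlet constraints by reduction and solves the SPD system with
#' a sparse Cholesky factorization (cached in the returned state and
#' reusable across right-hand sides).
#'
#' @param mesh a `tfocm_mesh3d`.
#' @param model an [elastic_model()].
#' @param loads length-3N load vector (Pa.um^2), e.g. from [facet_loads()].
#' @param dirichlet data.frame with columns `node`, `comp` (1-3), `value`
#'   (um); all listed dofs are prescribed.
#' @param state optional solver state from a previous call with the same
#'   mesh/model/constraints (reuses the factorization).
#' @return list with `u` (N x 3 nodal displacements, um), `state` (solver
#'   state), and `residual` (relative residual of the reduced system).
#' @export
fem_solve <- function(mesh, model, loads, dirichlet, state = NULL) {
  ndof <- 3L * nrow(mesh$nodes)
  if (is.null(state)) {
    K <- fem_assemble(mesh, model)
    # grid nodes inside the carved-out cavity belong to no element; pin them
    unused <- setdiff(seq_len(nrow(mesh$nodes)), unique(as.vector(mesh$tets)))
    if (length(unused)) {
      dirichlet <- rbind(dirichlet,
                         data.frame(node = rep(unused, 3L),
                                    comp = rep(1:3, each = length(unused)),
                                    value = 0))
    }
    fixed <- (dirichlet$node - 1L) * 3L + dirichlet$comp
    if (anyDuplicated(fixed)) {
      keep <- !duplicated(fixed)
      dirichlet <- dirichlet[keep, ]
      fixed <- fixed[keep]
    }
    free <- setdiff(seq_len(ndof), fixed)
    if (length(fixed) == 0L)
      stop("no Dirichlet constraints anywhere: system is singular for ",
           "unbalanced loads; fix the outer boundary or prescribe rollers")
    Kff <- K[free, free]
    Kfd <- K[free, fixed, drop = FALSE]
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
    state <- list(fac = fac, free = free, fixed = fixed,
                  xd = dirichlet$value, Kfd = Kfd, Kff = Kff)
  }
  rhs <- loads[state$free] - as.vector(state$Kfd %*% state$xd)
  uf <- as.vector(Matrix::solve(state$fac, rhs, system = "A"))
  res <- sqrt(sum((as.vector(state$Kff %*% uf) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.xmin)
  u <- numeric(ndof)
  u[state$free] <- uf
  u[state$fixed] <- state$xd
  list(u = matrix(u, ncol = 3, byrow = TRUE), state = state, residual = res)
}

#' Forward elasticity: surface traction to nodal displacement
#'
#' Applies a traction field on the labeled cell-surface facets and solves
#' with the chosen outer boundary condition.
#'
#' @param mesh a `tfocm_mesh3d` from [make_volume_mesh()].
#' @param traction a [traction_field()] (or NULL for zero traction).
#' @param model an [elastic_model()].
#' @param outer_bc `"fixed"` (zero displacement on the box, the default:
#'   far-field beads show essentially no motion), `"free"` is not supported
#'   without additional constraints, or a function `f(points) -> n x 3`
#'   prescribing displacements on the outer boundary (used for analytic
#'   benchmark boundary conditions).
#' @param state optional solver state to reuse.
#' @return list with `u` (N x 3, um), `state`, `residual`.
#' @export
fem_forward <- function(mesh, traction = NULL, model = elastic_model(),
                        outer_bc = "fixed", state = NULL) {
  loads <- numeric(3L * nrow(mesh$nodes))
  if (!is.null(traction)) {
    stopifnot(inherits(traction, "tfocm_traction"))
    loads <- facet_loads(mesh, mesh$cell_facets, traction$vectors,
                         mesh$cell_facet_areas)
  }
  if (is.null(state)) {
    onodes <- mesh$outer_nodes
    if (is.function(outer_bc)) {
      vals <- outer_bc(mesh$nodes[onodes, , drop = FALSE])
      dir <- data.frame(node = rep(onodes, 3L),
                        comp = rep(1:3, each = length(onodes)),
                        value = c(vals[, 1], vals[, 2], vals[, 3]))
    } else if (identical(outer_bc, "fixed")) {
      dir <- data.frame(node = rep(onodes, 3L),
                        comp = rep(1:3, each = length(onodes)),
                        value = 0)
    } else {
      stop("unsupported outer_bc; use \"fixed\" or a displacement function")
    }
    out <- fem_solve(mesh, model, loads, dir)
  } else {
    out <- fem_solve(mesh, model, loads, dirichlet = NULL, state = state)
  }
  out
}

#' Interpolate a nodal field at arbitrary points
#'
#' Locates the tetrahedron containing each point (via the structured parent
#' grid of the mesh) and evaluates the linear shape functions. Points inside
#' the cell cavity or outside the box get NA rows.
#'
#' @param u N x 3 nodal values.
#' @param mesh a `tfocm_mesh3d`.
#' @param points n x 3 query points (um).
#' @return list with `points`, `vectors` (n x 3, NA where not in the
#'   domain), and `inside` (logical).
#' @export
sample_displacement <- function(u, mesh, points) {
  points <- rbind(points)
  n <- nrow(points)
  out <- matrix(NA_real_, n, 3)
  # tets indexed by parent cell
  cellkey <- mesh$parent_cell[, 1] + mesh$grid_n[1] *
    (mesh$parent_cell[, 2] + mesh$grid_n[2] * mesh$parent_cell[, 3])
  ord <- order(cellkey)
  tet_by_cell <- split(ord, cellkey[ord])
  ci <- floor(sweep(points, 2, mesh$h, "/"))
  ci <- pmin(pmax(ci, 0), matrix(mesh$grid_n - 1L, n, 3, byrow = TRUE))
  for (p in seq_len(n)) {
    found <- FALSE
    # search own cell first, then neighbors (snapped boundaries move a bit)
    for (ring in 0:1) {
      offs <- as.matrix(expand.grid(-ring:ring, -ring:ring, -ring:ring))
      if (ring == 1) offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        cc <- ci[p, ] + offs[r, ]
        if (any(cc < 0) || any(cc >= mesh$grid_n)) next
        key <- as.character(cc[1] + mesh$grid_n[1] *
                              (cc[2] + mesh$grid_n[2] * cc[3]))
        tl <- tet_by_cell[[key]]
        if (is.null(tl)) next
        for (tt in tl) {
          lam <- .barycentric(mesh$nodes, mesh$tets[tt, ], points[p, ])
          if (all(lam >= -1e-9)) {
            out[p, ] <- lam %*% u[mesh$tets[tt, ], , drop = FALSE]
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) break
    }
  }
  list(points = points, vectors = out, inside = is.finite(out[, 1]))
}

.barycentric <- function(nodes, tet, p) {
  M <- t(nodes[tet[2:4], , drop = FALSE]) - nodes[tet[1], ]
  lam <- tryCatch(solve(M, p - nodes[tet[1], ]), error = function(e) rep(NA, 3))
  c(1 - sum(lam), lam)
}

# Mean displacement of each cell-surface facet (average of its 3 nodes).
facet_mean_displacement <- function(u, mesh) {
  (u[mesh$cell_facets[, 1], , drop = FALSE] +
     u[mesh$cell_facets[, 2], , drop = FALSE] +
     u[mesh$cell_facets[, 3], , drop = FALSE]) / 3
}
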