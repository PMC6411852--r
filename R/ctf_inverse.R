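# Tikhonov-regularized reconstruction of cell traction forces from bead
# displacements, with exact force/moment balance, L-curve selection of the
# regularization strength, and the dipole-matrix summary outputs.

#' Construct a traction field on the cell-surface facets of a mesh
#'
#' Tractions are piecewise constant per labeled cell-surface facet, in Pa,
#' in global (z, x, y) components. The stored facet normals point out of
#' the elastic domain, i.e. into the cell, so a uniformly contracting cell
#' (pulling the substrate toward itself) has `t = p * normal` with p > 0;
#' see [normal_traction()].
#'
#' @param mesh a `tfocm_mesh3d` with cell-surface facets.
#' @param vectors f x 3 matrix of traction vectors (Pa).
#' @return object of class `tfocm_traction`.
#' @export
traction_field <- function(mesh, vectors) {
  f <- nrow(mesh$cell_facets)
  if (is.null(dim(vectors))) vectors <- matrix(vectors, f, 3, byrow = TRUE)
  stopifnot(nrow(vectors) == f, all(is.finite(vectors)))
  structure(list(vectors = vectors,
                 areas = mesh$cell_facet_areas,
                 centroids = mesh$cell_facet_centroids,
                 normals = mesh$cell_facet_normals),
            class = "tfocm_traction")
}

#' @rdname traction_field
#' @param p uniform normal traction magnitude (Pa); positive = contraction
#'   (cell pulls the substrate inward).
#' @export
normal_traction <- function(mesh, p) {
  traction_field(mesh, p * mesh$cell_facet_normals)
}

#' Build the forward operator G mapping facet tractions to bead displacements
#'
#' Column (f, d) of G is the displacement response at all bead positions to
#' a unit (1 Pa) traction along axis d on facet f, computed by one FEM
#' factorization reused across all right-hand sides. Beads lying inside the
#' cell or outside the box are dropped with a warning.
#'
#' @param mesh a `tfocm_mesh3d`.
#' @param bead_points n x 3 bead positions (um).
#' @param model an [elastic_model()].
#' @param outer_bc passed to [fem_forward()] (default "fixed").
#' @return object of class `tfocm_inverse_problem`: `G` (3 n_beads x
#'   3 n_facets, um per Pa), `bead_points`, `bead_ok` (which input rows were
#'   kept), `mesh`, `model`, and the balance-constraint matrix `C`
#'   (6 x 3 n_facets: net force and net moment rows).
#' @export
build_forward_operator <- function(mesh, bead_points, model = elastic_model(),
                                   outer_bc = "fixed") {
  bead_points <- rbind(bead_points)
  if (nrow(bead_points) == 0L) stop("empty bead set")
  nf <- nrow(mesh$cell_facets)
  if (nf == 0L) stop("mesh has no cell-surface facets")
  # prime the factorization with a zero solve
  base <- fem_forward(mesh, NULL, model, outer_bc = outer_bc)
  state <- base$state
  # bead containment via a probe interpolation
  probe <- sample_displacement(base$u * 0, mesh, bead_points)
  ok <- probe$inside
  if (!all(ok))
    warning(sum(!ok), " bead(s) outside the elastic domain dropped")
  pts <- bead_points[ok, , drop = FALSE]
  nb <- nrow(pts)
  if (nb == 0L) stop("no beads inside the elastic domain")
  G <- matrix(0, 3L * nb, 3L * nf)
  for (f in seq_len(nf)) {
    for (dcomp in 1:3) {
      tv <- matrix(0, nf, 3)
      tv[f, dcomp] <- 1
      loads <- facet_loads(mesh, mesh$cell_facets, tv, mesh$cell_facet_areas)
      sol <- fem_solve(mesh, model, loads, dirichlet = NULL, state = state)
      s <- sample_displacement(sol$u, mesh, pts)
      G[, (f - 1L) * 3L + dcomp] <- as.vector(t(s$vectors))
    }
  }
  A <- mesh$cell_facet_areas
  X <- mesh$cell_facet_centroids
  C <- matrix(0, 6, 3 * nf)
  for (f in seq_len(nf)) {
    j <- (f - 1L) * 3L
    C[1, j + 1] <- A[f]; C[2, j + 2] <- A[f]; C[3, j + 3] <- A[f]
    # moment rows: x cross t (components in z, x, y order)
    C[4, j + 2] <- -X[f, 3] * A[f]; C[4, j + 3] <- X[f, 2] * A[f]
    C[5, j + 1] <- X[f, 3] * A[f]; C[5, j + 3] <- -X[f, 1] * A[f]
    C[6, j + 1] <- -X[f, 2] * A[f]; C[6, j + 2] <- X[f, 1] * A[f]
  }
  structure(list(G = G, bead_points = pts, bead_ok = ok, C = C,
                 mesh = mesh, model = model),
            class = "tfocm_inverse_problem")
}

#' @export
print.tfocm_inverse_problem <- function(x, ...) {
  cat(sprintf("inverse problem: %d beads x %d facets (G %d x %d)\n",
              nrow(x$bead_points), ncol(x$G) / 3, nrow(x$G), ncol(x$G)))
  invisible(x)
}

# Internal: SVD of the normalized operator restricted to the balance
# null space. Cached on the problem via attributes when reused.
.inverse_core <- function(problem, u_meas, t_char, u_char) {
  Gh <- problem$G * (t_char / u_char)
  qrC <- qr(t(problem$C))
  Q <- qr.Q(qrC, complete = TRUE)
  r <- qrC$rank
  Z <- Q[, (r + 1L):ncol(Q), drop = FALSE]    # null space of C
  GZ <- Gh %*% Z
  if (any(!is.finite(GZ))) stop("non-finite entries in the forward operator")
  sv <- tryCatch(svd(GZ), error = function(e) {
    # dgesdd occasionally fails to converge; the crossproduct eigenroute
    # is slower but dependable
    ee <- eigen(crossprod(GZ), symmetric = TRUE)
    d <- sqrt(pmax(ee$values, 0))
    keep <- d > max(d) * 1e-14
    v <- ee$vectors[, keep, drop = FALSE]
    u <- GZ %*% v %*% diag(1 / d[keep], sum(keep))
    list(d = d[keep], u = u, v = v)
  })
  # truncate numerical-rank noise: directions with singular values this far
  # below the largest are pure round-off and would fabricate a spurious
  # L-curve branch at tiny lambda
  keep <- sv$d > max(sv$d) * 1e-10
  sv$d <- sv$d[keep]
  sv$u <- sv$u[, keep, drop = FALSE]
  sv$v <- sv$v[, keep, drop = FALSE]
  list(Z = Z, sv = sv, uh = u_meas / u_char, t_char = t_char, u_char = u_char)
}

# Tikhonov solution in the null space for one lambda, from the core SVD.
.tikhonov_at <- function(core, lambda) {
  sv <- core$sv
  b <- crossprod(sv$u, core$uh)
  filt <- sv$d / (sv$d^2 + lambda^2)
  y <- sv$v %*% (filt * b)
  that <- core$Z %*% y
  # residual includes the component of uh outside the column space of GZ
  dfb <- sv$d * filt * b
  resid_h <- sqrt(max(0, sum(core$uh^2) - 2 * sum(b * dfb) + sum(dfb^2)))
  list(t_hat = as.vector(that), resid_h = resid_h,
       norm_h = sqrt(sum(that^2)))
}

#' Solve the regularized, balance-constrained inverse problem
#'
#' Minimizes `||G_hat t_hat - u_hat||^2 + lambda^2 ||t_hat||^2` over
#' tractions normalized by a characteristic traction (the Young's modulus)
#' and displacements normalized by a characteristic displacement, subject
#' to exact force and moment balance (enforced by projection onto the null
#' space of the balance constraints). Quasi-static cell motion makes the
#' balance categorical, not a soft penalty.
#'
#' @param problem a `tfocm_inverse_problem`.
#' @param u n x 3 matrix (or stacked length-3n vector) of measured bead
#'   displacements (um), rows matching `problem$bead_points`.
#' @param lambda regularization coefficient on the normalized operator;
#'   `"auto"` selects it with [select_lambda_lcurve()].
#' @param u_char characteristic displacement for normalization (um);
#'   default 1 (about one voxel).
#' @param lambda_grid grid used when `lambda = "auto"`.
#' @return object of class `tfocm_ctf`: `traction` (a [traction_field()]),
#'   `lambda`, `residual_norm` (um), `solution_norm` (Pa), `dipole`,
#'   `principal_axis`, `total_force_nn` (see [total_force()]), and balance
#'   diagnostics.
#' @export
solve_tikhonov <- function(problem, u, lambda = 1e-7, u_char = 1,
                           lambda_grid = 10^seq(-10, 0, length.out = 25)) {
  if (!is.null(dim(u))) u <- as.vector(t(u))
  stopifnot(length(u) == nrow(problem$G))
  t_char <- problem$model$E
  core <- .inverse_core(problem, u, t_char, u_char)
  if (identical(lambda, "auto"))
    lambda <- select_lambda_lcurve(problem, u, u_char = u_char,
                                   grid = lambda_grid, core = core)
  sol <- .tikhonov_at(core, lambda)
  tvec <- matrix(sol$t_hat * t_char, ncol = 3, byrow = TRUE)
  tf <- traction_field(problem$mesh, tvec)
  bal <- .balance_check(problem, sol$t_hat * t_char)
  tot <- total_force(tf)
  structure(list(traction = tf,
                 lambda = lambda,
                 residual_norm = sol$resid_h * u_char,
                 solution_norm = sol$norm_h * t_char,
                 dipole = tot$M,
                 principal_axis = tot$principal_axis,
                 total_force_nn = tot$total_force_nn,
                 balance = bal),
            class = "tfocm_ctf")
}

.balance_check <- function(problem, t_stacked) {
  viol <- as.vector(problem$C %*% t_stacked)
  A <- problem$mesh$cell_facet_areas
  tm <- matrix(t_stacked, ncol = 3, byrow = TRUE)
  scale <- sum(sqrt(rowSums(tm^2)) * A)
  list(force = viol[1:3], moment = viol[4:6],
       relative = max(abs(viol)) / max(scale, .Machine$double.xmin))
}

#' @export
print.tfocm_ctf <- function(x, ...) {
  cat(sprintf("CTF reconstruction: lambda %.3g, |F| %.3g nN along (%.2f, %.2f, %.2f)\n",
              x$lambda, x$total_force_nn, x$principal_axis[1],
              x$principal_axis[2], x$principal_axis[3]))
  cat(sprintf("  residual %.4g um, ||t|| %.4g Pa, balance %.2g (relative)\n",
              x$residual_norm, x$solution_norm, x$balance$relative))
  invisible(x)
}

#' Select the regularization coefficient by the L-curve method
#'
#' Evaluates (log residual norm, log solution norm) along a lambda grid and
#' returns the point of maximum curvature (the L-curve corner), evaluated
#' on a dense log-spaced refinement of the grid via the SVD. If the
#' curvature has no interior maximum (no corner), the recorded default of
#' 1e-7 on the normalized operator is returned with a warning.
#'
#' @param problem a `tfocm_inverse_problem`.
#' @param u measured displacements as in [solve_tikhonov()].
#' @param grid lambda grid; must have >= 10 points spanning >= 4 decades.
#' @param u_char characteristic displacement (um).
#' @param fallback value returned when no corner is found.
#' @param core internal (precomputed SVD core).
#' @return the selected lambda (scalar).
#' @export
select_lambda_lcurve <- function(problem, u, grid = 10^seq(-10, 0,
                                                           length.out = 25),
                                 u_char = 1, fallback = 1e-7, core = NULL) {
  if (length(grid) < 10L || diff(range(log10(grid))) < 4)
    stop("lambda grid must have >= 10 points spanning >= 4 decades")
  if (!is.null(dim(u))) u <- as.vector(t(u))
  if (is.null(core))
    core <- .inverse_core(problem, u, problem$model$E, u_char)
  dense <- 10^seq(min(log10(grid)), max(log10(grid)), length.out = 200L)
  rho <- eta <- numeric(length(dense))
  for (i in seq_along(dense)) {
    s <- .tikhonov_at(core, dense[i])
    rho[i] <- s$resid_h; eta[i] <- s$norm_h
  }
  lr <- log(pmax(rho, 1e-300)); le <- log(pmax(eta, 1e-300))
  x <- log(dense)
  d1r <- .cgrad(lr, x); d1e <- .cgrad(le, x)
  d2r <- .cgrad(d1r, x); d2e <- .cgrad(d1e, x)
  kappa <- (d1r * d2e - d2r * d1e) / (d1r^2 + d1e^2)^1.5
  kappa[!is.finite(kappa)] <- -Inf
  # ignore the flat stretches where the curve barely moves: curvature there
  # is numerical noise, not a corner
  speed <- sqrt(d1r^2 + d1e^2)
  kappa[speed < 0.05 * max(speed)] <- -Inf
  inner <- 5:(length(dense) - 4)
  best <- inner[which.max(kappa[inner])]
  if (!is.finite(kappa[best]) || kappa[best] <= 0) {
    warning("L-curve has no corner (monotone curvature); using fallback ",
            "lambda = ", fallback)
    return(fallback)
  }
  dense[best]
}

.cgrad <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  g
}

#' Dipole matrix, principal stress axis, and total force of a traction field
#'
#' The dipole (first-moment) matrix is
#' `M = sym(sum_f centroid_f (x) t_f A_f)` (Pa um^3). The principal stress
#' axis is the eigenvector of M with the largest absolute eigenvalue. The
#' total force is defined here as half the sum of absolute projected pulls,
#' `F = 0.5 * sum_f |t_f . p| A_f`, representing the equal-and-opposite
#' contraction along the principal axis; this concretization is this
#' package's own (stated in the methods vignette).
#'
#' @param traction a `tfocm_traction` (balanced).
#' @return list with `M` (3 x 3, Pa um^3), `principal_axis` (unit 3-vector),
#'   `total_force_nn` (nN, >= 0), and `degenerate` (TRUE when all
#'   eigenvalues coincide and the axis is arbitrary).
#' @export
total_force <- function(traction) {
  tA <- traction$vectors * traction$areas
  M <- crossprod(traction$centroids, tA)
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  imax <- which.max(abs(ev$values))
  p <- ev$values
  degenerate <- diff(range(abs(p))) <= 1e-9 * max(abs(p), 1e-300)
  axis <- ev$vectors[, imax]
  f_pa <- 0.5 * sum(abs(as.vector(traction$vectors %*% axis)) * traction$areas)
  list(M = M, principal_axis = axis,
       total_force_nn = pa_um2_to_nn(f_pa),
       degenerate = degenerate)
}

#' Summarize a reconstructed time course
#'
#' Collects the per-time total force and residual together with the
#' near-cell mean displacement from the tracking module, and (for multiple
#' cells) five-number box summaries.
#'
#' @param results list of `tfocm_ctf`, one per time point.
#' @param near per-time near-cell mean displacement table (the `near`
#'   element of [displacement_profile()]), or NULL.
#' @param t_minutes optional times (minutes).
#' @return data.frame with one row per time point: t_index, t_minutes,
#'   total_force_nn, residual_um, lambda, mean_u_near.
#' @export
summarize_timecourse <- function(results, near = NULL, t_minutes = NULL) {
  nt <- length(results)
  if (nt < 1L) stop("need at least one time point")
  if (is.null(t_minutes)) t_minutes <- 5 * (seq_len(nt) - 1)
  out <- data.frame(
    t_index = seq_len(nt) - 1L,
    t_minutes = t_minutes,
    total_force_nn = vapply(results, function(r) r$total_force_nn, numeric(1)),
    residual_um = vapply(results, function(r) r$residual_norm, numeric(1)),
    lambda = vapply(results, function(r) r$lambda, numeric(1)))
  if (!is.null(near)) {
    out$mean_u_near <- near$mean_u_near[match(out$t_index, near$t_index)]
  }
  out
}

#' Five-number (box plot) summary across cells per time point
#'
#' @param values_by_cell matrix (time x cells) of a per-time quantity.
#' @return data.frame with min, q1, median, q3, max per time row.
#' @export
box_summary <- function(values_by_cell) {
  qs <- t(apply(values_by_cell, 1, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  out <- as.data.frame(qs)
  names(out) <- c("min", "q1", "median", "q3", "max")
  out
}
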