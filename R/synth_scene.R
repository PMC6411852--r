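#' Cell phantom specification
#'
#' A speckle-producing cell body modeled as a union of ellipsoids, filled
#' with randomly phased point scatterers (fully developed circular-Gaussian
#' speckle interior). Used by [make_scene()].
#'
#' @param ellipsoids list of ellipsoids, each `list(center = c(z, x, y),
#'   semiaxes = c(az, ax, ay))` in um.
#' @param scatterer_density interior scatterer density (per um^3).
#' @param amplitude RMS amplitude of an interior scatterer, relative to a
#'   bead amplitude of 1.
#' @return object of class `tfocm_phantom`.
#' @export
cell_phantom <- function(ellipsoids, scatterer_density = 0.05, amplitude = 0.35) {
  stopifnot(length(ellipsoids) >= 1)
  for (e in ellipsoids) stopifnot(length(e$center) == 3L, length(e$semiaxes) == 3L,
                                  all(e$semiaxes > 0))
  structure(list(ellipsoids = ellipsoids,
                 scatterer_density = scatterer_density,
                 amplitude = amplitude),
            class = "tfocm_phantom")
}

#' Test whether points lie inside a phantom
#'
#' @param phantom a `tfocm_phantom` (or NULL, in which case all points are
#'   outside).
#' @param points n x 3 matrix of (z, x, y) positions in um.
#' @return logical vector of length n.
#' @export
phantom_inside <- function(phantom, points) {
  points <- rbind(points)
  if (is.null(phantom)) return(rep(FALSE, nrow(points)))
  inside <- rep(FALSE, nrow(points))
  for (e in phantom$ellipsoids) {
    d <- sweep(points, 2, e$center)
    d <- sweep(d, 2, e$semiaxes, "/")
    inside <- inside | rowSums(d^2) <= 1
  }
  inside
}

# Approximate volume of the phantom (Monte Carlo over the union so that
# overlapping ellipsoids are not double counted).
phantom_volume <- function(phantom, n_mc = 20000L, seed = 1L) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (e in phantom$ellipsoids) {
    lo <- pmin(lo, e$center - e$semiaxes)
    hi <- pmax(hi, e$center + e$semiaxes)
  }
  set.seed(seed)
  pts <- cbind(stats::runif(n_mc, lo[1], hi[1]),
               stats::runif(n_mc, lo[2], hi[2]),
               stats::runif(n_mc, lo[3], hi[3]))
  mean(phantom_inside(phantom, pts)) * prod(hi - lo)
}

#' Generate a ground-truth scene of beads and an optional cell phantom
#'
#' Draws `round(concentration * V_fov)` scattering beads uniformly at random
#' in the field of view (bead centers excluded from the phantom interior),
#' plus Poisson-distributed speckle scatterers inside the phantom. At the
#' standard concentration of 1.6e8 beads/mL the characteristic spacing
#' `concentration^(-1/3)` is about 18 um.
#'
#' @param geometry a [acquisition_geometry()].
#' @param bead_concentration beads per mL (1 mL = 1e12 um^3).
#' @param phantom optional [cell_phantom()].
#' @param seed integer RNG seed; the scene is reproducible from
#'   (seed, geometry).
#' @param coverslip_depth optional depth (um) of a planar reference reflector,
#'   used by coherence-gate estimation; NULL for none.
#' @param bead_diameter_um nominal bead diameter, used only for the sanity
#'   check that the mean spacing stays above two diameters.
#' @return object of class `tfocm_scene` with fields `bead_positions`
#'   (n x 3 um, axis order z, x, y), `bead_amplitudes`, `phantom`,
#'   `phantom_scatterers`, `coverslip_depth`, `spacing_um`, `rng_seed`.
#' @export
make_scene <- function(geometry, bead_concentration = 1.6e8, phantom = NULL,
                       seed = 1L, coverslip_depth = NULL,
                       bead_diameter_um = 1) {
  stopifnot(bead_concentration > 0)
  spacing <- (1e12 / bead_concentration)^(1 / 3)  # um
  if (spacing < 2 * bead_diameter_um)
    stop("bead concentration too high: mean spacing ", signif(spacing, 3),
         " um is below two bead diameters")
  vol_ml <- prod(geometry$fov_um) / 1e12
  n_beads <- round(bead_concentration * vol_ml)
  set.seed(seed)
  pos <- cbind(stats::runif(n_beads, 0, geometry$fov_um[1]),
               stats::runif(n_beads, 0, geometry$fov_um[2]),
               stats::runif(n_beads, 0, geometry$fov_um[3]))
  if (!is.null(phantom)) {
    bad <- phantom_inside(phantom, pos)
    guard <- 0L
    while (any(bad) && guard < 100L) {
      pos[bad, ] <- cbind(stats::runif(sum(bad), 0, geometry$fov_um[1]),
                          stats::runif(sum(bad), 0, geometry$fov_um[2]),
                          stats::runif(sum(bad), 0, geometry$fov_um[3]))
      bad <- phantom_inside(phantom, pos)
      guard <- guard + 1L
    }
  }
  amp <- stats::rlnorm(n_beads, 0, 0.1)
  ph_sc <- NULL
  if (!is.null(phantom)) {
    vol <- phantom_volume(phantom, seed = seed)
    n_sc <- stats::rpois(1, phantom$scatterer_density * vol)
    # rejection-sample interior points from the bounding box
    lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
    for (e in phantom$ellipsoids) {
      lo <- pmin(lo, e$center - e$semiaxes)
      hi <- pmax(hi, e$center + e$semiaxes)
    }
    got <- matrix(numeric(0), 0, 3)
    while (nrow(got) < n_sc) {
      cand <- cbind(stats::runif(2 * n_sc, lo[1], hi[1]),
                    stats::runif(2 * n_sc, lo[2], hi[2]),
                    stats::runif(2 * n_sc, lo[3], hi[3]))
      got <- rbind(got, cand[phantom_inside(phantom, cand), , drop = FALSE])
    }
    got <- got[seq_len(n_sc), , drop = FALSE]
    ph_sc <- list(positions = got,
                  amplitudes = rep(phantom$amplitude, n_sc),
                  phase_seed = seed + 101L)
  }
  structure(list(bead_positions = pos,
                 bead_amplitudes = amp,
                 phantom = phantom,
                 phantom_scatterers = ph_sc,
                 coverslip_depth = coverslip_depth,
                 spacing_um = spacing,
                 fov_um = geometry$fov_um,
                 displaced_outside_fov = logical(n_beads),
                 rng_seed = as.integer(seed)),
            class = "tfocm_scene")
}

#' @export
print.tfocm_scene <- function(x, ...) {
  cat(sprintf("OCM scene: %d beads (characteristic spacing %.1f um)%s%s\n",
              nrow(x$bead_positions), x$spacing_um,
              if (!is.null(x$phantom)) ", cell phantom" else "",
              if (!is.null(x$coverslip_depth))
                sprintf(", coverslip at z = %g um", x$coverslip_depth) else ""))
  invisible(x)
}

#' Deform a scene by pushing a traction field through the forward solver
#'
#' Solves the linear-elastic forward problem for `traction` on the cell
#' surface of `mesh`, samples the resulting displacement field at the bead
#' positions (and phantom scatterer positions), and returns the displaced
#' scene. This inverts the measurement chain to create ground truth for the
#' tracking and inverse stages.
#'
#' @param scene a `tfocm_scene`.
#' @param traction a traction field on `mesh` (see [traction_field()]).
#' @param model an [elastic_model()].
#' @param mesh a cube-minus-cell volumetric mesh ([make_volume_mesh()]).
#' @param fem optional pre-assembled solver state from [fem_forward()]
#'   (reused factorization).
#' @return a list with `scene` (deformed `tfocm_scene`), `displacement`
#'   (a function mapping n x 3 points to n x 3 displacements, um), and
#'   `nodal` (the nodal FEM solution).
#' @export
deform_scene <- function(scene, traction, model, mesh, fem = NULL) {
  sol <- fem_forward(mesh, traction, model, state = fem)
  disp_fun <- function(points) {
    s <- sample_displacement(sol$u, mesh, points)
    s$vectors
  }
  out <- scene
  u_beads <- disp_fun(scene$bead_positions)
  miss <- !is.finite(u_beads[, 1])
  u_beads[miss, ] <- 0   # beads inside the cell or outside the box: undisplaced
  out$bead_positions <- scene$bead_positions + u_beads
  fov <- scene$fov_um
  outside <- out$bead_positions[, 1] < 0 | out$bead_positions[, 1] > fov[1] |
    out$bead_positions[, 2] < 0 | out$bead_positions[, 2] > fov[2] |
    out$bead_positions[, 3] < 0 | out$bead_positions[, 3] > fov[3]
  out$displaced_outside_fov <- outside   # flagged, retained in ground truth
  if (!is.null(out$phantom_scatterers)) {
    u_sc <- disp_fun(out$phantom_scatterers$positions)
    u_sc[!is.finite(u_sc[, 1])] <- 0
    # interior points sit inside the cell (outside the elastic domain); advect
    # them with the surface field extended by nearest-facet displacement
    inside <- !is.finite(sample_displacement(sol$u, mesh,
                                             out$phantom_scatterers$positions)$vectors[, 1])
    if (any(inside)) {
      surf_u <- facet_mean_displacement(sol$u, mesh)
      nn <- nearest_row(mesh$cell_facet_centroids,
                        out$phantom_scatterers$positions[inside, , drop = FALSE])
      u_sc[inside, ] <- surf_u[nn, , drop = FALSE]
    }
    out$phantom_scatterers$positions <- out$phantom_scatterers$positions + u_sc
  }
  # record the deformation so phantom_inside-style ground truth can follow it
  out$applied_displacement <- disp_fun
  list(scene = out, displacement = disp_fun, nodal = sol$u, state = sol$state)
}

# index of nearest row of `ref` (m x 3) for each row of `pts` (n x 3)
nearest_row <- function(ref, pts) {
  n <- nrow(pts)
  out <- integer(n)
  for (i in seq_len(n)) {
    d <- sweep(ref, 2, pts[i, ])
    out[i] <- which.min(rowSums(d^2))
  }
  out
}
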