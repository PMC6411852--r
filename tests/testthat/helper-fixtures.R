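# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code from fixed seeds; no stored data.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# Clean small geometry: no artifacts, flat maps, focal mid-depth.
fx_clean_geometry <- function(nk = 128L, nxy = 48L, fov = c(160, 80, 80),
                              zf = 80) {
  acquisition_geometry(n_k_samples = nk, fov_um = c(fov[1], fov[2], fov[3]),
                       n_voxels = c(nk, nxy, nxy),
                       focal_plane = c(c = zf))
}

# A scene holding explicit bead positions (no randomness).
fx_fixed_scene <- function(positions, amplitudes = NULL, fov = c(160, 80, 80),
                           seed = 1L, coverslip = NULL) {
  positions <- rbind(positions)
  structure(list(bead_positions = positions,
                 bead_amplitudes = amplitudes %||% rep(1, nrow(positions)),
                 phantom = NULL, phantom_scatterers = NULL,
                 coverslip_depth = coverslip, spacing_um = 20,
                 fov_um = fov,
                 displaced_outside_fov = logical(nrow(positions)),
                 rng_seed = as.integer(seed)),
            class = "tfocm_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The standard synthetic scene for image-formation fidelity: beads spanning
# defocus up to ~210 um, with all instrument artifacts switched on.
fx_standard_scene <- function() fx("standard_scene", function() {
  g <- acquisition_geometry(
    n_k_samples = 192L, fov_um = c(240, 80, 80), n_voxels = c(192L, 48L, 48L),
    focal_plane = c(c = 20, x1y0 = 1.5, x0y1 = -1),
    coherence_gate = c(c = 0, x2y0 = 3, x0y2 = 2),
    carrier = c(0.3, -0.2), phase_jitter_std = 0.6, noise_floor_db = -45,
    falloff_db_per_mm = 5)
  set.seed(42)
  nb <- 36L
  z <- rep(seq(30, 225, length.out = 12), 3)
  xy <- matrix(stats::runif(2 * nb, 10, 70), ncol = 2)
  scene <- fx_fixed_scene(cbind(z, xy), fov = g$fov_um, coverslip = 8)
  raw <- simulate_spectra(scene, g, noise_seed = 7L)
  list(geometry = g, scene = scene, raw = raw)
})

# Fully corrected volume of the standard scene (all six steps).
fx_standard_volume <- function() fx("standard_volume", function() {
  std <- fx_standard_scene()
  vol <- reconstruct_volume(std$raw)
  vol <- remove_cg_curvature(vol)$volume
  vol <- register_focal_plane(vol, half_range = 10)
  vol <- phase_register(vol)$volume
  vol <- bulk_demodulate(vol)$volume
  apply_cao(vol)
})

# Expected bead positions of the standard scene in the registered frame.
# Focal-plane registration advances each A-scan by the *applied* map minus
# its mean, so ground truth must be transformed with that same applied map
# (a constant bias in the estimated focal depth only redefines the frame
# origin and cancels; it is not a geometric error).
fx_standard_truth <- function(vol) {
  std <- fx_standard_scene()
  g <- std$geometry
  pos <- std$scene$bead_positions
  map <- vol$maps$focal_plane
  p <- voxel_pitch(g)
  ix <- pmin(pmax(round(pos[, 2] / p[2]) + 1, 1), nrow(map))
  iy <- pmin(pmax(round(pos[, 3] / p[3]) + 1, 1), ncol(map))
  applied <- map[cbind(ix, iy)]
  ztrue <- pos[, 1] - (applied - mean(map))
  cbind(ztrue, pos[, 2], pos[, 3])
}

poly2d_eval_ <- function(coef, x, y) {
  out <- rep(0, length(x))
  for (nm in names(coef)) {
    if (nm %in% c("c", "x0y0")) { out <- out + coef[[nm]]; next }
    px <- as.integer(substr(nm, 2, 2)); py <- as.integer(substr(nm, 4, 4))
    out <- out + coef[[nm]] * x^px * y^py
  }
  out
}

# Contracting-sphere inverse fixture: mesh, operator, true traction and
# noiseless bead displacements.
fx_sphere_inverse <- function() fx("sphere_inverse", function() {
  set.seed(11)
  L <- 160; ctr <- c(80, 80, 80); a <- 20
  model <- elastic_model(90, 0.45)
  inside <- function(p) sqrt(rowSums(sweep(p, 2, ctr)^2)) <= a
  ng <- 33; pitch <- rep(L / (ng - 1), 3)
  gr <- as.matrix(expand.grid(iz = seq_len(ng), ix = seq_len(ng),
                              iy = seq_len(ng)))
  pts <- sweep(gr - 1, 2, pitch, "*")
  fld <- array(a - sqrt(rowSums(sweep(pts, 2, ctr)^2)), rep(ng, 3))
  surf <- marching_tetrahedra(fld, 0, pitch)
  mesh <- make_volume_mesh(surf, box = c(L, L, L), n = 14, inside = inside)
  beads <- matrix(0, 0, 3)
  while (nrow(beads) < 200) {
    cand <- matrix(stats::runif(600 * 3, 8, L - 8), ncol = 3)
    rr <- sqrt(rowSums(sweep(cand, 2, ctr)^2))
    beads <- rbind(beads, cand[rr > a + 6, , drop = FALSE])
  }
  beads <- beads[1:200, ]
  problem <- build_forward_operator(mesh, beads, model)
  p0 <- 5
  tr_true <- normal_traction(mesh, p0)
  u_true <- sample_displacement(fem_forward(mesh, tr_true, model)$u, mesh,
                                problem$bead_points)$vectors
  list(mesh = mesh, model = model, problem = problem, p0 = p0, a = a,
       ctr = ctr, tr_true = tr_true, u_true = u_true, surface = surf)
})

# Random tiny inverse problem (20 facets, 12 beads) for brute-force checks.
fx_toy_problem <- function() fx("toy_problem", function() {
  set.seed(5)
  nf <- 20L; nb <- 12L
  centroids <- matrix(stats::runif(3 * nf, 30, 70), ncol = 3)
  areas <- stats::runif(nf, 2, 6)
  normals <- matrix(stats::rnorm(3 * nf), ncol = 3)
  normals <- normals / sqrt(rowSums(normals^2))
  mesh <- list(cell_facets = matrix(seq_len(3 * nf), ncol = 3),
               cell_facet_areas = areas, cell_facet_centroids = centroids,
               cell_facet_normals = normals)
  class(mesh) <- "tfocm_mesh3d"
  model <- elastic_model(90, 0.45)
  G <- matrix(stats::rnorm(3 * nb * 3 * nf, sd = 1e-3), 3 * nb, 3 * nf)
  C <- matrix(0, 6, 3 * nf)
  for (f in seq_len(nf)) {
    j <- (f - 1L) * 3L; X <- centroids[f, ]; A <- areas[f]
    C[1, j + 1] <- A; C[2, j + 2] <- A; C[3, j + 3] <- A
    C[4, j + 2] <- -X[3] * A; C[4, j + 3] <- X[2] * A
    C[5, j + 1] <- X[3] * A; C[5, j + 3] <- -X[1] * A
    C[6, j + 1] <- -X[2] * A; C[6, j + 2] <- X[1] * A
  }
  problem <- structure(list(G = G, bead_points = matrix(0, nb, 3),
                            bead_ok = rep(TRUE, nb), C = C, mesh = mesh,
                            model = model),
                       class = "tfocm_inverse_problem")
  u <- stats::rnorm(3 * nb, sd = 0.05)
  list(problem = problem, u = u, nf = nf, nb = nb)
})

# One shared small-pipeline run (used by the end-to-end acceptance block).
fx_pipeline <- function() fx("pipeline", function() {
  run_pipeline(small_config(seed = 3L), verbose = FALSE)
})

# Per-bead transverse FWHM (um): find the local intensity peak near the
# expected position and measure the x profile through it over a window, so
# neighbors and wrap-around halos do not contaminate the width.
bead_fwhm <- function(vol, positions, halo = 4L, win = 9L) {
  p <- vol$voxel_pitch
  m <- abs(vol$field)
  d <- dim(m)
  vapply(seq_len(nrow(positions)), function(i) {
    iz0 <- round(positions[i, 1] / p[1]) + 1
    ix0 <- round(positions[i, 2] / p[2]) + 1
    iy0 <- round(positions[i, 3] / p[3]) + 1
    zr <- max(1, iz0 - halo):min(d[1], iz0 + halo)
    xr <- max(1, ix0 - halo):min(d[2], ix0 + halo)
    yr <- max(1, iy0 - halo):min(d[3], iy0 + halo)
    sub <- m[zr, xr, yr, drop = FALSE]
    pk <- arrayInd(which.max(sub), dim(sub))
    iz <- zr[pk[1]]; ix <- xr[pk[2]]; iy <- yr[pk[3]]
    # spline-upsampled profiles through the peak: sub-pixel FWHM without
    # tail sensitivity
    fw_axis <- function(prof, pitch) {
      n <- length(prof)
      if (n < 5) return(NA_real_)
      xx <- seq_len(n)
      dense <- stats::spline(xx, prof, n = 20L * n)
      profile_fwhm(dense$y) * (xx[2] - xx[1]) / 20 * pitch
    }
    xs <- max(1, ix - win):min(d[2], ix + win)
    ys <- max(1, iy - win):min(d[3], iy + win)
    fx_w <- fw_axis(m[iz, xs, iy], p[2])
    fy_w <- fw_axis(m[iz, ix, ys], p[3])
    mean(c(fx_w, fy_w), na.rm = TRUE)
  }, numeric(1))
}

# CAO sharpness pair: one bead in focus, one 200 um below, clean geometry.
fx_cao_pair <- function() fx("cao_pair", function() {
  g <- fx_clean_geometry(nk = 192L, nxy = 48L, fov = c(240, 80, 80), zf = 20)
  sc <- fx_fixed_scene(rbind(c(20, 40, 40), c(220, 40, 40)), fov = g$fov_um)
  vol <- reconstruct_volume(simulate_spectra(sc, g, include_noise = FALSE))
  p <- voxel_pitch(g)
  iz_f <- round(20 / p[1]) + 1
  iz_d <- round(220 / p[1]) + 1
  fw_focus <- profile_fwhm(abs(vol$field[iz_f, , 25])) * p[2]
  fw_blur <- profile_fwhm(abs(vol$field[iz_d, , 25])) * p[2]
  vc <- apply_cao(vol, focal_depth = 20, force = TRUE)
  fw_cao <- profile_fwhm(abs(vc$field[iz_d, , 25])) * p[2]
  list(fw_focus = fw_focus, fw_blur = fw_blur, fw_cao = fw_cao)
})

# Focal-plane tilt scene at higher NA: beads ~50 um above a tilted focal
# plane; with and without focal-plane registration before CAO.
fx_tilt_fwhm <- function() fx("tilt_fwhm", function() {
  # high NA (small Rayleigh range) so the tilt matters for sharpness, over a
  # wide transverse FOV so the registration's spectral shear stays small
  g <- acquisition_geometry(
    n_k_samples = 128L, fov_um = c(160, 192, 192),
    n_voxels = c(128L, 192L, 192L), transverse_resolution_um = 2.2,
    focal_plane = c(c = 40, x1y0 = 16))
  set.seed(31)
  nb <- 24L
  # beads on exact voxel centers: at ~1 px per FWHM the trilinear source
  # encoding otherwise modulates apparent width with sub-pixel position,
  # which would mask the focal-tilt effect this fixture isolates
  pos <- cbind(rep(60, nb), sample(8:184, nb), sample(8:184, nb))
  sc <- fx_fixed_scene(pos, fov = g$fov_um)
  raw <- simulate_spectra(sc, g, include_noise = FALSE)
  vol <- reconstruct_volume(raw)
  # without registration: refocus about the mean focal depth
  v_no <- apply_cao(vol, focal_depth = 40, force = TRUE)
  fw_no <- bead_fwhm(v_no, pos)
  # with registration (true map), then demodulation of the linear phase the
  # tilt shift introduces (the canonical step order), then CAO
  v_reg <- register_focal_plane(vol, map = g$focal_plane)
  v_reg <- bulk_demodulate(v_reg)$volume
  pos_reg <- pos
  xn <- 2 * pos[, 2] / g$fov_um[2] - 1
  pos_reg[, 1] <- pos[, 1] - (poly2d_eval_(g$focal_plane, xn, 0 * xn) -
                                v_reg$focal_depth)
  v_yes <- apply_cao(v_reg, force = TRUE)
  fw_yes <- bead_fwhm(v_yes, pos_reg)
  list(fw_no = fw_no, fw_yes = fw_yes)
})

# Shear slopes of the standard scene with and without bulk demodulation.
# Both chains register with the true focal map so the comparison isolates
# the demodulation step (the registration of a tilt adds its own linear
# carrier, which step 5 removes along with the instrument carrier).
fx_shear_slopes <- function() fx("shear_slopes", function() {
  std <- fx_standard_scene()
  g <- std$geometry
  chain <- function(with_demod) {
    v <- reconstruct_volume(std$raw)
    v <- remove_cg_curvature(v)$volume
    v <- register_focal_plane(v, map = g$focal_plane)
    v <- phase_register(v)$volume
    if (with_demod) v <- bulk_demodulate(v)$volume
    apply_cao(v, force = TRUE)
  }
  v_yes <- chain(TRUE)
  v_no <- chain(FALSE)
  truth <- fx_standard_truth(v_yes)
  p <- voxel_pitch(std$geometry)
  slope_of <- function(vol) {
    b <- localize_beads(vol, min_voxels = 4L)
    m <- match_beads(stats::setNames(as.data.frame(truth), c("z", "x", "y")),
                     b, k_neighbors = 6L, max_displacement = 12)
    dz <- truth[m[, "a"], 1] - vol$focal_depth
    lat <- (as.matrix(b[m[, "b"], "x"]) - truth[m[, "a"], 2]) / p[2]
    unname(stats::coef(stats::lm(lat ~ dz))[2])
  }
  list(with_demod = slope_of(v_yes), without_demod = slope_of(v_no))
})

# Geometric fidelity of the standard scene: bead centroid RMS (voxels).
fx_fidelity_rms <- function() fx("fidelity_rms", function() {
  vol <- fx_standard_volume()
  truth <- fx_standard_truth(vol)
  beads <- localize_beads(vol, min_voxels = 4L)
  m <- match_beads(stats::setNames(as.data.frame(truth), c("z", "x", "y")),
                   beads, k_neighbors = 6L, max_displacement = 10)
  p <- voxel_pitch(vol$geometry)
  errv <- sweep(as.matrix(beads[m[, "b"], c("z", "x", "y")]) -
                  truth[m[, "a"], ], 2, p, "/")
  # the absolute depth datum is set by the reference reflector and is
  # arbitrary to within the (unknowable) median gate offset; geometry is
  # relative, so align the global z datum before scoring
  errv[, 1] <- errv[, 1] - stats::median(errv[, 1])
  list(rms = sqrt(mean(rowSums(errv^2) / 3)), n = nrow(m),
       n_truth = nrow(truth))
})

# Speckle phantom: std projection, ground-truth region, segmentation.
fx_speckle_phantom <- function() fx("speckle_phantom", function() {
  g <- acquisition_geometry(n_k_samples = 96L, fov_um = c(120, 80, 80),
                            n_voxels = c(96L, 48L, 48L),
                            focal_plane = c(c = 60), noise_floor_db = -45)
  ph <- cell_phantom(list(list(center = c(60, 40, 40),
                               semiaxes = c(14, 17, 15))),
                     scatterer_density = 0.08, amplitude = 0.5)
  sc <- make_scene(g, 1.6e8, ph, seed = 6L)
  burst <- simulate_burst(sc, g, n_repeats = 8L, factor = 1L,
                          include_noise = TRUE)
  vols <- lapply(burst, function(b) reconstruct_volume(b, window = "hann"))
  sd_vol <- speckle_reduce(vols)
  p <- voxel_pitch(g)
  idx <- as.matrix(expand.grid(iz = seq_len(dim(sd_vol)[1]),
                               ix = seq_len(dim(sd_vol)[2]),
                               iy = seq_len(dim(sd_vol)[3])))
  pts <- sweep(idx - 1, 2, p, "*")
  inside <- array(phantom_inside(ph, pts), dim(sd_vol))
  contrast <- mean(sd_vol[inside]) / mean(sd_vol[!inside])
  mask <- segment_cell(sd_vol, pitch = p)
  list(sd_vol = sd_vol, inside = inside, mask = mask, contrast = contrast,
       dice = dice_coefficient(mask$voxels, inside), pitch = p)
})

# Point-load FEM against the Kelvin oracle: shell RMS relative error.
fx_kelvin_bench <- function() fx("kelvin_bench", function() {
  L <- 160; ctr <- c(80, 80, 80)
  model <- elastic_model(90, 0.45)
  m <- make_volume_mesh(NULL, box = c(L, L, L), n = 20)
  Fn <- c(5, 3, -2)
  kel <- function(x) kelvin_displacement(Fn, ctr, x, model)
  nid <- which.min(rowSums(sweep(m$nodes, 2, ctr)^2))
  loads <- numeric(3 * nrow(m$nodes))
  loads[(nid - 1) * 3 + 1:3] <- nn_to_pa_um2(Fn)
  sol <- fem_forward(m, NULL, model, outer_bc = kel)
  sol <- fem_solve(m, model, loads, dirichlet = NULL, state = sol$state)
  src <- m$nodes[nid, ]
  set.seed(2)
  dirn <- matrix(stats::rnorm(450), ncol = 3)
  dirn <- dirn / sqrt(rowSums(dirn^2))
  errs <- c()
  for (r in c(28, 34, 40)) {
    tgt <- sweep(dirn * r, 2, src, "+")
    su <- sample_displacement(sol$u, m, tgt)
    uex <- kel(tgt[su$inside, , drop = FALSE])
    errs <- c(errs, sqrt(rowSums((su$vectors[su$inside, ] - uex)^2)) /
                sqrt(rowSums(uex^2)))
  }
  list(rms = sqrt(mean(errs^2)), n = length(errs))
})
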