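# Synthetic scene and instrument forward model.

test_that("bead concentration arithmetic gives the expected spacings", {
  g <- fx_clean_geometry()
  # 1.6e8 beads/mL -> characteristic spacing ~18 um
  sc <- make_scene(g, 1.6e8, seed = 1L)
  expect_equal(sc$spacing_um, (1e12 / 1.6e8)^(1 / 3), tolerance = 1e-12)
  expect_lt(abs(sc$spacing_um - 18.42), 0.01)
  # bead count = round(concentration x FOV volume)
  expect_equal(nrow(sc$bead_positions),
               round(1.6e8 * prod(g$fov_um) / 1e12))
  # 1 bead/um^3 (= 1e12 per mL) -> spacing parameter 1 um
  expect_equal(make_scene(g, 1e12, seed = 1L,
                          bead_diameter_um = 0.4)$spacing_um, 1)
  # 1.0e8 beads/mL -> (1e12 / 1e8)^(1/3) = 21.54 um
  expect_equal(make_scene(g, 1e8, seed = 1L)$spacing_um, 1e4^(1 / 3))
  # empirical nearest-neighbor spacing is on the order of the parameter
  d2 <- as.matrix(dist(sc$bead_positions))
  diag(d2) <- Inf
  emp <- mean(apply(d2, 1, min))
  expect_gt(emp, 0.3 * sc$spacing_um)
  expect_lt(emp, 1.5 * sc$spacing_um)
})

test_that("unphysically dense bead suspensions are rejected", {
  g <- fx_clean_geometry()
  expect_error(make_scene(g, 1e12, bead_diameter_um = 1), "too high")
})

test_that("scenes are reproducible from their seed and beads avoid the phantom", {
  g <- fx_clean_geometry()
  ph <- cell_phantom(list(list(center = c(80, 40, 40),
                               semiaxes = c(15, 20, 18))))
  s1 <- make_scene(g, 1.6e8, ph, seed = 9L)
  s2 <- make_scene(g, 1.6e8, ph, seed = 9L)
  expect_identical(s1$bead_positions, s2$bead_positions)
  expect_false(any(phantom_inside(ph, s1$bead_positions)))
  expect_true(all(phantom_inside(ph, s1$phantom_scatterers$positions)))
})

test_that("spectra are linear in the scatterers and reproducible", {
  g <- fx_clean_geometry()
  s1 <- fx_fixed_scene(c(60, 30, 40), fov = g$fov_um)
  s2 <- fx_fixed_scene(c(100, 50, 45), fov = g$fov_um)
  s12 <- fx_fixed_scene(rbind(c(60, 30, 40), c(100, 50, 45)), fov = g$fov_um)
  f1 <- simulate_spectra(s1, g, include_noise = FALSE)$fringes
  f2 <- simulate_spectra(s2, g, include_noise = FALSE)$fringes
  f12 <- simulate_spectra(s12, g, include_noise = FALSE)$fringes
  expect_lt(max(abs(f12 - (f1 + f2))), 1e-12 * max(abs(f12)))
  fa <- simulate_spectra(s12, g, noise_seed = 4L)$fringes
  fb <- simulate_spectra(s12, g, noise_seed = 4L)$fringes
  expect_identical(fa, fb)
})

test_that("a clean scatterer reconstructs at its own voxel", {
  g <- fx_clean_geometry()
  pos <- c(55.3, 41.1, 38.7)
  raw <- simulate_spectra(fx_fixed_scene(pos, fov = g$fov_um), g,
                          include_noise = FALSE)
  vol <- reconstruct_volume(raw)
  pk <- arrayInd(which.max(abs(vol$field)), dim(vol$field))
  expect_true(all(abs((pk - 1) * voxel_pitch(g) - pos) <= voxel_pitch(g)))
})

test_that("aliasing beyond the axial FOV is rejected", {
  g <- fx_clean_geometry()
  expect_error(simulate_spectra(fx_fixed_scene(c(170, 40, 40),
                                               fov = c(180, 80, 80)), g),
               "aliasing")
})

test_that("burst repeats share beads but re-randomize intracellular speckle", {
  g <- fx_clean_geometry(nk = 96L, nxy = 32L, fov = c(120, 54, 54), zf = 60)
  ph <- cell_phantom(list(list(center = c(60, 27, 27),
                               semiaxes = c(12, 14, 13))),
                     scatterer_density = 0.08, amplitude = 0.5)
  sc <- make_scene(g, 1.6e8, ph, seed = 2L)
  expect_error(simulate_burst(sc, g, n_repeats = 1L), "n_repeats")
  burst <- simulate_burst(sc, g, n_repeats = 4L, factor = 2L,
                          include_noise = FALSE)
  expect_length(burst, 4L)
  # identical speckle seeds -> zero std projection
  same <- replicate(3, simulate_spectra(sc, burst[[1]]$geometry,
                                        include_noise = FALSE,
                                        phase_seed_offset = 1L),
                    simplify = FALSE)
  vols_same <- lapply(same, reconstruct_volume)
  expect_lt(max(speckle_reduce(vols_same)),
            1e-6 * max(abs(vols_same[[1]]$field)))
  # distinct speckle seeds -> fluctuation concentrated in the cell interior
  vols <- lapply(burst, reconstruct_volume)
  sd_vol <- speckle_reduce(vols)
  bg2 <- burst[[1]]$geometry
  p <- voxel_pitch(bg2)
  idx <- as.matrix(expand.grid(iz = seq_len(dim(sd_vol)[1]),
                               ix = seq_len(dim(sd_vol)[2]),
                               iy = seq_len(dim(sd_vol)[3])))
  pts <- cbind((idx[, 1] - 1) * p[1] + bg2$offset_um[1],
               (idx[, 2] - 1) * p[2] + bg2$offset_um[2],
               (idx[, 3] - 1) * p[3] + bg2$offset_um[3])
  inside <- phantom_inside(ph, pts)
  expect_gt(mean(sd_vol[inside]) / mean(sd_vol[!inside]), 5)
})

test_that("deform_scene is consistent, linear and flags escapes", {
  sph <- fx_sphere_inverse()
  g <- fx_clean_geometry(fov = c(160, 160, 160))
  set.seed(21)
  sc <- make_scene(g, 0.6e8, seed = 21L)
  # keep beads outside the cavity
  rr <- sqrt(rowSums(sweep(sc$bead_positions, 2, sph$ctr)^2))
  sc$bead_positions <- sc$bead_positions[rr > sph$a + 5, , drop = FALSE]
  sc$bead_amplitudes <- rep(1, nrow(sc$bead_positions))
  sc$displaced_outside_fov <- logical(nrow(sc$bead_positions))
  zero <- traction_field(sph$mesh, matrix(0, nrow(sph$mesh$cell_facets), 3))
  d0 <- deform_scene(sc, zero, sph$model, sph$mesh)
  expect_equal(d0$scene$bead_positions, sc$bead_positions, tolerance = 1e-12)
  dp <- deform_scene(sc, sph$tr_true, sph$model, sph$mesh)
  dm <- deform_scene(sc, traction_field(sph$mesh, -sph$tr_true$vectors),
                     sph$model, sph$mesh, fem = dp$state)
  up <- dp$scene$bead_positions - sc$bead_positions
  um <- dm$scene$bead_positions - sc$bead_positions
  expect_lt(max(abs(up + um)), 1e-8)
  # displacement read back equals bead motion
  u_rb <- dp$displacement(sc$bead_positions)
  expect_lt(max(abs(u_rb - up), na.rm = TRUE), 1e-6)
})

test_that("a contracting sphere produces a near 1/r^2 radial bead field", {
  sph <- fx_sphere_inverse()
  mu <- sph$model$shear_modulus
  pts <- sph$problem$bead_points
  rr <- sqrt(rowSums(sweep(pts, 2, sph$ctr)^2))
  sel <- rr > 28 & rr < 45
  umag <- sqrt(rowSums(sph$u_true[sel, ]^2))
  pred <- sph$p0 * sph$a^3 / (4 * mu * rr[sel]^2)
  # fixed outer boundary suppresses the far field; magnitude stays on scale
  expect_lt(median(abs(umag / pred - 1)), 0.6)
  fit <- stats::lm(log(umag) ~ log(rr[sel]))
  expect_lt(abs(stats::coef(fit)[2] + 2), 0.8)
  # displacements point inward (contraction)
  rad <- sweep(pts[sel, ], 2, sph$ctr) / rr[sel]
  expect_true(all(rowSums(sph$u_true[sel, ] * rad) < 0))
})
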