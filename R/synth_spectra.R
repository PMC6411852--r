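# Forward model of the spectral-domain OCM instrument.
#
# A scatterer at (z, x, y) with amplitude a contributes fringes
#   a * E(k) * exp(i 2 n k (z + dz_cg(x,y))) * T_delta(x - x_j, y - y_j)
# where E(k) is the Gaussian spectral envelope and T_delta is the transverse
# defocus response at defocus delta = z - z_f(x, y): the inverse transform of
# the Gaussian pupil P(q) times the angular-spectrum phase
# exp(i (kz(q) - 2 n k0) delta), evaluated at the central wavenumber k0.
# Because the defocus phase is evaluated at k0, the computational adaptive
# optics kernel (the conjugate phase) inverts it exactly; chromatic defocus
# is not modeled. Per-slow-line phase jitter, a bulk transverse carrier,
# depth fall-off and complex sensor noise are applied on top.

# Gather all scatterers of a scene into local (cropped) coordinates.
gather_scatterers <- function(scene, geometry, phase_seed_offset = 0L) {
  off <- geometry$offset_um %||% c(0, 0, 0)
  pos <- scene$bead_positions
  amp <- as.complex(scene$bead_amplitudes)
  if (!is.null(scene$phantom_scatterers)) {
    ps <- scene$phantom_scatterers
    set.seed(ps$phase_seed + phase_seed_offset)
    phases <- stats::runif(nrow(ps$positions), 0, 2 * pi)
    pos <- rbind(pos, ps$positions)
    amp <- c(amp, ps$amplitudes * exp(1i * phases))
  }
  pos <- sweep(pos, 2, off)
  fov <- geometry$fov_um
  nb <- nrow(scene$bead_positions)
  flagged <- c(scene$displaced_outside_fov %||% logical(nb),
               rep(FALSE, nrow(pos) - nb))
  too_deep <- (pos[, 1] < 0 | pos[, 1] >= fov[1]) & !flagged
  if (any(too_deep))
    stop("scatterer beyond the axial range supported by n_k_samples ",
         "(aliasing); deepen the FOV or remove it")
  keep <- pos[, 1] >= 0 & pos[, 1] < fov[1] &
    pos[, 2] >= 0 & pos[, 2] < fov[2] &
    pos[, 3] >= 0 & pos[, 3] < fov[3]
  pos <- pos[keep, , drop = FALSE]
  amp <- amp[keep]
  if (!is.null(scene$coverslip_depth)) {
    # planar reference reflector: one strong scatterer under every beam
    p <- voxel_pitch(geometry)
    nv <- geometry$n_voxels
    bx <- (seq_len(nv[2]) - 1) * p[2]
    by <- (seq_len(nv[3]) - 1) * p[3]
    grid <- as.matrix(expand.grid(x = bx, y = by))
    cs <- cbind(scene$coverslip_depth, grid)
    pos <- rbind(pos, cs)
    amp <- c(amp, rep(as.complex(3), nrow(cs)))
  }
  list(pos = pos, amp = amp, offset = off)
}

# Trilinear gridding weights: returns data.frame(iz, ix, iy, w) of up to 8
# corner contributions per point (1-based indices, clamped rows dropped).
.trilinear <- function(pos, nv, pitch) {
  f <- sweep(pos, 2, pitch, "/")          # voxel centers at index * pitch
  i0 <- floor(f)
  fr <- f - i0
  rows <- vector("list", 8L)
  r <- 1L
  for (dz in 0:1) for (dx in 0:1) for (dy in 0:1) {
    w <- (if (dz) fr[, 1] else 1 - fr[, 1]) *
      (if (dx) fr[, 2] else 1 - fr[, 2]) *
      (if (dy) fr[, 3] else 1 - fr[, 3])
    rows[[r]] <- cbind(i0[, 1] + dz + 1, i0[, 2] + dx + 1, i0[, 3] + dy + 1,
                       w, seq_len(nrow(pos)))
    r <- r + 1L
  }
  m <- do.call(rbind, rows)
  ok <- m[, 1] >= 1 & m[, 1] <= nv[1] & m[, 2] >= 1 & m[, 2] <= nv[2] &
    m[, 3] >= 1 & m[, 3] <= nv[3] & m[, 4] > 0
  m[ok, , drop = FALSE]
}

#' Simulate raw OCM fringe spectra for a scene
#'
#' Implements the instrument forward model described above on the uniform
#' wavenumber grid implied by the geometry.
#'
#' @param scene a [make_scene()] scene (possibly deformed).
#' @param geometry an [acquisition_geometry()]; may be a [burst_geometry()]
#'   crop of a larger frame.
#' @param include_noise logical; set FALSE for noise-free linearity tests.
#' @param noise_seed RNG seed for jitter and sensor noise (defaults to the
#'   scene seed).
#' @param phase_seed_offset integer added to the phantom speckle phase seed;
#'   burst repeats use it to re-randomize intracellular speckle.
#' @return object of class `tfocm_spectra`: `fringes` (complex array,
#'   k x fast x slow, physical k order), `k` (rad/um), `geometry`, and the
#'   applied per-line `jitter_phases`.
#' @export
simulate_spectra <- function(scene, geometry, include_noise = TRUE,
                             noise_seed = NULL, phase_seed_offset = 0L) {
  nv <- geometry$n_voxels
  p <- voxel_pitch(geometry)
  kg <- k_grid(geometry)
  n <- geometry$refractive_index
  sc <- gather_scatterers(scene, geometry, phase_seed_offset)

  psi <- array(0 + 0i, nv)
  if (nrow(sc$pos)) {
    # focal depth at each scatterer (maps live on the parent frame if cropped)
    parent_fov <- geometry$parent_fov_um %||% geometry$fov_um
    off <- sc$offset
    xn <- 2 * (sc$pos[, 2] + off[2]) / parent_fov[2] - 1
    yn <- 2 * (sc$pos[, 3] + off[3]) / parent_fov[3] - 1
    zf <- poly2d_eval(geometry$focal_plane, xn, yn)
    delta <- sc$pos[, 1] - zf
    bin <- as.integer(round(delta / p[1]))

    tri <- .trilinear(sc$pos, nv, p)
    tri_bin <- bin[tri[, 5]]
    tri_amp <- sc$amp[tri[, 5]] * tri[, 4]
    # phase-correct the axial split: the fringe carrier advances by
    # 2 n k0 dz between slices, so the two z-copies of a sub-voxel source
    # would otherwise interfere and bias the reconstructed envelope
    z_true <- sc$pos[tri[, 5], 1]
    z_slice <- (tri[, 1] - 1) * p[1]
    tri_amp <- tri_amp * exp(1i * 2 * n * kg$k0 * (z_true - z_slice))
    kzr <- kz_relative(geometry)
    P <- pupil(geometry)
    grp <- paste(tri_bin, tri[, 1])
    for (g in unique(grp)) {
      sel <- grp == g
      iz <- tri[sel, 1][1]
      b <- tri_bin[sel][1]
      lin <- (tri[sel, 3] - 1L) * nv[2] + tri[sel, 2]
      re <- rowsum(Re(tri_amp[sel]), lin)
      im <- rowsum(Im(tri_amp[sel]), lin)
      slice <- matrix(0 + 0i, nv[2], nv[3])
      slice[as.integer(rownames(re))] <- complex(real = re, imaginary = im)
      H <- P * exp(1i * kzr$kz_rel * (b * p[1]))
      psi[iz, , ] <- psi[iz, , ] + ifft2(fft2(slice) * H)
    }
  }
  # depth fall-off (amplitude, dB per mm)
  if (geometry$falloff_db_per_mm != 0) {
    z <- (seq_len(nv[1]) - 1) * p[1]
    att <- 10^(-abs(geometry$falloff_db_per_mm) * (z / 1000) / 20)
    psi <- psi * att
  }
  # z -> k transform: fringes(k) = E(k) sum_z psi_z exp(i 2 n k z)
  z <- (seq_len(nv[1]) - 1) * p[1]
  g <- psi * exp(1i * 2 * n * kg$k0 * z)
  dim(g) <- c(nv[1], nv[2] * nv[3])
  Fr <- stats::mvfft(g, inverse = TRUE)          # unnormalized sum with e^{+i}
  m <- seq_len(nv[1]) - 1 - floor(nv[1] / 2)     # physical k index offsets
  ord <- (m %% nv[1]) + 1
  Fr <- Fr[ord, , drop = FALSE]
  E <- spectral_envelope(geometry)
  if (geometry$dispersion_quadratic != 0) {
    u <- (kg$k - kg$k0) / (max(kg$k) - kg$k0)
    E <- E * exp(1i * geometry$dispersion_quadratic * u^2)
  }
  Fr <- Fr * E
  dim(Fr) <- nv

  # coherence gate curvature: extra path length per beam
  cg <- coherence_gate_map(geometry)
  if (any(cg != 0)) {
    for (ik in seq_len(nv[1])) {
      Fr[ik, , ] <- Fr[ik, , ] * exp(1i * 2 * n * kg$k[ik] * cg)
    }
  }
  seed <- noise_seed %||% (scene$rng_seed + 7919L)
  set.seed(seed)
  jit <- numeric(nv[3])
  if (geometry$phase_jitter_std > 0) {
    jit <- stats::rnorm(nv[3], 0, geometry$phase_jitter_std)
    Fr <- Fr * rep(exp(1i * jit), each = nv[1] * nv[2])
  }
  if (any(geometry$carrier != 0)) {
    nc <- norm_xy(geometry)
    ph <- outer(geometry$carrier[1] * nc$x, geometry$carrier[2] * nc$y, "+")
    Fr <- Fr * rep(exp(1i * ph), each = nv[1])
  }
  if (include_noise && is.finite(geometry$noise_floor_db)) {
    a_unit <- mean(pupil(geometry)) * mean(spectral_envelope(geometry))
    sig <- 10^(geometry$noise_floor_db / 20) * a_unit * sqrt(nv[1])
    nz <- complex(real = stats::rnorm(length(Fr), 0, sig / sqrt(2)),
                  imaginary = stats::rnorm(length(Fr), 0, sig / sqrt(2)))
    Fr <- Fr + nz
  }
  structure(list(fringes = Fr, k = kg$k, geometry = geometry,
                 jitter_phases = jit),
            class = "tfocm_spectra")
}

#' @export
print.tfocm_spectra <- function(x, ...) {
  cat(sprintf("raw OCM spectra: %s (k x fast x slow)\n",
              paste(dim(x$fringes), collapse = " x ")))
  invisible(x)
}

#' Simulate a burst of reduced-FOV acquisitions for speckle reduction
#'
#' Repeats share the beads and any static background but re-randomize the
#' phases of the cell-interior scatterers between repeats, emulating dynamic
#' intracellular speckle. The instrument burst design acquires eight such
#' repeats at a reduced transverse FOV around the cell.
#'
#' @param scene a `tfocm_scene` (should contain a phantom).
#' @param geometry the full-frame [acquisition_geometry()].
#' @param n_repeats number of repeats (>= 2; the standard burst uses 8).
#' @param factor transverse FOV reduction factor passed to [burst_geometry()].
#' @param center_um transverse center of the reduced FOV (defaults to the
#'   phantom centroid when a phantom is present).
#' @param include_noise logical.
#' @return list of `tfocm_spectra`, one per repeat.
#' @export
simulate_burst <- function(scene, geometry, n_repeats = 8L, factor = 2L,
                           center_um = NULL, include_noise = TRUE) {
  if (n_repeats < 2L)
    stop("n_repeats must be >= 2 (a standard-deviation projection of a ",
         "single repeat is undefined)")
  if (is.null(center_um) && !is.null(scene$phantom)) {
    ctr <- colMeans(do.call(rbind, lapply(scene$phantom$ellipsoids,
                                          function(e) rbind(e$center))))
    center_um <- ctr[2:3]
  }
  bg <- burst_geometry(geometry, factor = factor, center_um = center_um)
  bg$parent_fov_um <- geometry$fov_um
  lapply(seq_len(n_repeats), function(r) {
    simulate_spectra(scene, bg, include_noise = include_noise,
                     noise_seed = scene$rng_seed + 7919L * r,
                     phase_seed_offset = 13L * r)
  })
}
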