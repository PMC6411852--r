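#' Acquisition geometry of a spectral-domain OCM system
#'
#' Bundles the optical and scan parameters that define both the synthetic
#' forward model (how raw fringe spectra are generated from a scene) and the
#' reconstruction (how complex volumes are formed from spectra). Axis order
#' everywhere is (z, x, y) = (axial, fast scan, slow scan); physical
#' coordinates are voxel-center positions in micrometres, with voxel index
#' `i` (0-based) centered at `i * pitch`.
#'
#' Defaults emulate a Ti:Sapph spectral-domain OCM (800 nm center wavelength,
#' 160 nm bandwidth) on a reduced desk-scale grid of 256 spectral samples and
#' 96 x 96 beams over 320 x 160 x 160 um^3, which preserves the voxel pitch
#' of the full-scale instrument (1.25 um axial) while keeping volumes small.
#'
#' @param center_wavelength_nm center wavelength (nm).
#' @param bandwidth_nm FWHM of the Gaussian source spectrum (nm).
#' @param n_k_samples number of spectral (wavenumber) samples per A-scan.
#' @param fov_um length-3 field of view (z, x, y) in um.
#' @param n_voxels length-3 voxel counts (z, x, y); `n_voxels[1]` must equal
#'   `n_k_samples`.
#' @param refractive_index group/phase index of the medium (>= 1).
#' @param transverse_resolution_um FWHM of the in-focus transverse amplitude
#'   PSF (um); sets the width of the Gaussian pupil.
#' @param na numerical aperture at which the pupil is truncated.
#' @param focal_plane named coefficients of the focal-depth map z_f(x, y)
#'   (um), a 2D polynomial on coordinates normalized to \[-1, 1\]; the "c"
#'   entry is the nominal focal depth.
#' @param coherence_gate named coefficients of the coherence-gate offset map
#'   dz_cg(x, y) (um), same convention.
#' @param carrier length-2 bulk transverse phase carrier q (rad/um).
#' @param phase_jitter_std per-slow-scan-line phase jitter (rad).
#' @param noise_floor_db complex sensor noise floor relative to the image
#'   amplitude of a unit scatterer (dB; e.g. -90 means 90 dB below it).
#' @param falloff_db_per_mm sensitivity fall-off with depth (dB/mm).
#' @param dispersion_quadratic optional quadratic spectral phase (rad at the
#'   band edge); hook, default 0 (not simulated).
#' @return an object of class `tfocm_geometry`.
#' @export
acquisition_geometry <- function(center_wavelength_nm = 800,
                                 bandwidth_nm = 160,
                                 n_k_samples = 256L,
                                 fov_um = c(320, 160, 160),
                                 n_voxels = c(256L, 96L, 96L),
                                 refractive_index = 1.34,
                                 transverse_resolution_um = 3.4,
                                 na = 0.2,
                                 focal_plane = c(c = 160),
                                 coherence_gate = c(c = 0),
                                 carrier = c(0, 0),
                                 phase_jitter_std = 0,
                                 noise_floor_db = -Inf,
                                 falloff_db_per_mm = 0,
                                 dispersion_quadratic = 0) {
  stopifnot(length(fov_um) == 3L, length(n_voxels) == 3L)
  if (any(fov_um <= 0) || any(n_voxels <= 0))
    stop("fov_um and n_voxels must be strictly positive")
  if (bandwidth_nm >= center_wavelength_nm)
    stop("bandwidth must be smaller than the center wavelength")
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  if (n_voxels[1] != n_k_samples)
    stop("n_voxels[1] must equal n_k_samples (one z voxel per spectral sample)")
  if (length(carrier) != 2L) stop("carrier must be a length-2 vector (qx, qy)")
  g <- structure(list(
    center_wavelength_nm = center_wavelength_nm,
    bandwidth_nm = bandwidth_nm,
    n_k_samples = as.integer(n_k_samples),
    fov_um = as.numeric(fov_um),
    n_voxels = as.integer(n_voxels),
    refractive_index = refractive_index,
    transverse_resolution_um = transverse_resolution_um,
    na = na,
    focal_plane = focal_plane,
    coherence_gate = coherence_gate,
    carrier = as.numeric(carrier),
    phase_jitter_std = phase_jitter_std,
    noise_floor_db = noise_floor_db,
    falloff_db_per_mm = falloff_db_per_mm,
    dispersion_quadratic = dispersion_quadratic
  ), class = "tfocm_geometry")
  g
}

#' @export
print.tfocm_geometry <- function(x, ...) {
  cat("OCM acquisition geometry\n")
  cat(sprintf("  lambda0 %g nm, bandwidth %g nm, n = %g\n",
              x$center_wavelength_nm, x$bandwidth_nm, x$refractive_index))
  cat(sprintf("  FOV %s um, voxels %s (pitch %s um)\n",
              paste(x$fov_um, collapse = " x "),
              paste(x$n_voxels, collapse = " x "),
              paste(signif(voxel_pitch(x), 4), collapse = " x ")))
  cat(sprintf("  carrier (%g, %g) rad/um, jitter %g rad, noise %g dB\n",
              x$carrier[1], x$carrier[2], x$phase_jitter_std, x$noise_floor_db))
  invisible(x)
}

#' Voxel pitch of a geometry
#' @param geometry a `tfocm_geometry`.
#' @return length-3 numeric, um per voxel along (z, x, y).
#' @export
voxel_pitch <- function(geometry) geometry$fov_um / geometry$n_voxels

# Central vacuum wavenumber (rad/um) and the uniform k grid implied by the
# axial FOV: the fringe phase is exp(i 2 n k z), so resolving z in [0, Z)
# with n_k samples requires dk = pi / (n Z).
k_grid <- function(geometry) {
  k0 <- 2 * pi / (geometry$center_wavelength_nm * 1e-3)
  n <- geometry$refractive_index
  Z <- geometry$fov_um[1]
  dk <- pi / (n * Z)
  nk <- geometry$n_k_samples
  k <- k0 + (seq_len(nk) - 1 - floor(nk / 2)) * dk
  list(k = k, k0 = k0, dk = dk)
}

# Gaussian spectral envelope on the geometry's k grid (amplitude, peak 1).
spectral_envelope <- function(geometry) {
  kg <- k_grid(geometry)
  lam0 <- geometry$center_wavelength_nm * 1e-3
  dlam <- geometry$bandwidth_nm * 1e-3
  dk_fwhm <- 2 * pi * dlam / lam0^2
  sigma_k <- dk_fwhm / (2 * sqrt(2 * log(2)))
  exp(-(kg$k - kg$k0)^2 / (2 * sigma_k^2))
}

#' Theoretical axial amplitude-PSF FWHM for a Gaussian spectrum
#'
#' Closed form `2 ln2 / pi * lambda0^2 / (n * dlambda)` in micrometres; used
#' as an oracle for the reconstructed point-spread function.
#' @param geometry a `tfocm_geometry`.
#' @return FWHM in um.
#' @export
axial_psf_fwhm <- function(geometry) {
  lam0 <- geometry$center_wavelength_nm * 1e-3
  dlam <- geometry$bandwidth_nm * 1e-3
  2 * log(2) / pi * lam0^2 / (geometry$refractive_index * dlam)
}

# Transverse angular-frequency grids (rad/um) for the (x, y) FFT plane.
transverse_freq <- function(geometry) {
  p <- voxel_pitch(geometry)
  list(qx = fft_omega(geometry$n_voxels[2], p[2]),
       qy = fft_omega(geometry$n_voxels[3], p[3]))
}

# Gaussian pupil (amplitude) on the transverse frequency grid, truncated at
# the double-pass NA cutoff and at the grid Nyquist.
pupil <- function(geometry) {
  tf <- transverse_freq(geometry)
  q2 <- outer(tf$qx^2, tf$qy^2, "+")
  # amplitude PSF exp(-sigma_q^2 r^2 / 2) has FWHM 2 sqrt(2 ln 2) / sigma_q
  sigma_q <- 2 * sqrt(2 * log(2)) / geometry$transverse_resolution_um
  kg <- k_grid(geometry)
  q_na <- 2 * kg$k0 * geometry$na    # double-pass transverse support
  P <- exp(-q2 / (2 * sigma_q^2))
  P[q2 > q_na^2] <- 0
  P
}

# Double-pass axial spatial frequency k_z(qx, qy) at the central wavenumber,
# minus its on-axis value 2 n k0. This is the shared defocus kernel phase of
# the simulator and of computational adaptive optics: a scatterer at defocus
# dz carries transverse spectral phase exp(i kz_rel * dz).
kz_relative <- function(geometry) {
  kg <- k_grid(geometry)
  n <- geometry$refractive_index
  knk <- 2 * n * kg$k0
  tf <- transverse_freq(geometry)
  q2 <- outer(tf$qx^2, tf$qy^2, "+")
  rad <- knk^2 - q2
  kz <- sqrt(pmax(rad, 0))
  list(kz_rel = kz - knk, evanescent = rad < 0)
}

# Normalized transverse coordinates in [-1, 1] at beam centers.
norm_xy <- function(geometry) {
  nv <- geometry$n_voxels
  p <- voxel_pitch(geometry)
  x <- (seq_len(nv[2]) - 1) * p[2]
  y <- (seq_len(nv[3]) - 1) * p[3]
  list(xn = 2 * x / geometry$fov_um[2] - 1, yn = 2 * y / geometry$fov_um[3] - 1,
       x = x, y = y)
}

# Evaluate the focal-plane / coherence-gate maps (um) on the beam grid.
focal_plane_map <- function(geometry) {
  nc <- norm_xy(geometry)
  outer(nc$xn, nc$yn, function(x, y) poly2d_eval(geometry$focal_plane, x, y))
}

coherence_gate_map <- function(geometry) {
  nc <- norm_xy(geometry)
  outer(nc$xn, nc$yn, function(x, y) poly2d_eval(geometry$coherence_gate, x, y))
}

#' Reduced-FOV geometry for burst (speckle-reduction) acquisitions
#'
#' Returns a copy of `geometry` with the transverse FOV and beam counts
#' divided by `factor` (voxel pitch preserved), centered on `center_um`.
#' This mirrors the instrument's burst design, where repeated small volumes
#' are captured around the cell for speckle reduction.
#'
#' @param geometry a `tfocm_geometry`.
#' @param factor integer reduction factor (full-scale systems use 4; the
#'   desk-scale default FOV uses 2 so a whole cell still fits).
#' @param center_um length-2 transverse center (x, y) of the reduced FOV (um);
#'   default the FOV center. Stored in the result as `$offset_um`.
#' @return a `tfocm_geometry` with an `offset_um` field (z, x, y origin).
#' @export
burst_geometry <- function(geometry, factor = 2L, center_um = NULL) {
  g <- geometry
  nv <- g$n_voxels
  g$n_voxels[2:3] <- as.integer(nv[2:3] %/% factor)
  g$fov_um[2:3] <- g$fov_um[2:3] * g$n_voxels[2:3] / nv[2:3]
  if (is.null(center_um)) center_um <- geometry$fov_um[2:3] / 2
  orig <- center_um - g$fov_um[2:3] / 2
  # snap the crop origin to the parent voxel grid
  p <- voxel_pitch(geometry)[2:3]
  orig <- round(orig / p) * p
  g$offset_um <- c(0, orig)
  g
}
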