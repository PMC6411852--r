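# Computational image formation: raw fringe spectra -> geometrically
# faithful, uniformly focused complex volumes, in six steps:
#   (1) initial volume reconstruction     (reconstruct_volume)
#   (2) coherence gate curvature removal  (remove_cg_curvature)
#   (3) focal plane registration          (register_focal_plane)
#   (4) phase registration                (phase_register)
#   (5) bulk demodulation                 (bulk_demodulate)
#   (6) computational adaptive optics     (apply_cao)
# Steps 2-5 are phase-only (unitary) transforms of the complex field; step 6
# is a unitary transverse spatial-frequency filter. The point of the chain is
# not only sharpness but geometric fidelity: bead centroids after refocusing
# must land at their physical positions at all depths.

.cv_steps <- c("reconstruct", "cg_removal", "focal_registration",
               "phase_registration", "bulk_demodulation", "cao")

new_complex_volume <- function(field, geometry, corrections = "reconstruct",
                               focal_depth = NULL, maps = list()) {
  structure(list(field = field,
                 voxel_pitch = voxel_pitch(geometry),
                 geometry = geometry,
                 corrections_applied = corrections,
                 focal_depth = focal_depth,
                 maps = maps),
            class = "tfocm_volume")
}

#' @export
print.tfocm_volume <- function(x, ...) {
  cat(sprintf("complex OCM volume %s (z x fast x slow), pitch %s um\n",
              paste(dim(x$field), collapse = " x "),
              paste(signif(x$voxel_pitch, 4), collapse = " x ")))
  cat("  corrections:", paste(x$corrections_applied, collapse = " -> "), "\n")
  invisible(x)
}

#' Step 1: reconstruct a complex volume from raw spectra
#'
#' Per beam: background (mean-spectrum) subtraction, optional resampling to
#' the uniform wavenumber grid, optional spectral window, and an inverse
#' Fourier transform along k. The complex field is retained.
#'
#' @param raw a `tfocm_spectra` object. If `raw$k` is non-uniform the spectra
#'   are first linearly resampled onto the uniform grid implied by the
#'   geometry.
#' @param window `"none"` (default; the Gaussian source spectrum is already
#'   apodized) or `"hann"`.
#' @param dc_subtract subtract the mean spectrum across beams before
#'   transforming.
#' @return a `tfocm_volume`.
#' @export
reconstruct_volume <- function(raw, window = c("none", "hann"),
                               dc_subtract = TRUE) {
  window <- match.arg(window)
  if (any(!is.finite(raw$fringes))) stop("non-finite values in raw spectra")
  geometry <- raw$geometry
  nv <- geometry$n_voxels
  kg <- k_grid(geometry)
  Fr <- raw$fringes
  dim(Fr) <- c(nv[1], nv[2] * nv[3])
  # resample to the uniform grid if needed
  dk <- diff(raw$k)
  if (max(abs(dk - kg$dk)) > 1e-9 * kg$dk) {
    Fr <- .resample_k(Fr, raw$k, kg$k)
  }
  if (dc_subtract) Fr <- Fr - rowMeans(Fr)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nv[1]) - 1) / (nv[1] - 1))
    Fr <- Fr * w
  }
  # invert the z -> k map: physical order -> fft order -> forward FFT
  m <- seq_len(nv[1]) - 1 - floor(nv[1] / 2)
  ord <- (m %% nv[1]) + 1
  G <- Fr
  G[ord, ] <- Fr
  g <- stats::mvfft(G) / nv[1]
  z <- (seq_len(nv[1]) - 1) * voxel_pitch(geometry)[1]
  field <- g * exp(-1i * 2 * geometry$refractive_index * kg$k0 * z)
  dim(field) <- nv
  new_complex_volume(field, geometry)
}

# Linear resampling of spectra (rows = k) onto a target grid via a sparse
# interpolation matrix; columns are beams.
.resample_k <- function(Fr, k_src, k_dst) {
  n <- length(k_src)
  idx <- findInterval(k_dst, k_src, all.inside = TRUE)
  t <- (k_dst - k_src[idx]) / (k_src[idx + 1] - k_src[idx])
  t <- pmax(0, pmin(1, t))
  W <- Matrix::sparseMatrix(
    i = c(seq_along(k_dst), seq_along(k_dst)),
    j = c(idx, idx + 1L),
    x = c(1 - t, t),
    dims = c(length(k_dst), n))
  out <- as.matrix(W %*% Re(Fr)) + 1i * as.matrix(W %*% Im(Fr))
  out
}

# Sub-voxel axial advance of the complex field: f'(z) = f(z + s(x, y)).
# The shift is carried out in the spectral (wavenumber) domain by
# multiplying each A-scan's spectrum by exp(-i 2 n k s): the field's axial
# carrier 2 n k0 does not sit on a DFT bin of the sampled envelope, so an
# envelope-domain Fourier shift would leave a residual per-beam phase
# (a transverse chirp for curved maps) that corrupts later demodulation
# and refocusing. Doing the shift at the true wavenumbers is exact.
.axial_shift_vol <- function(vol, s) {
  d <- dim(vol$field)
  if (length(s) != 1 && !all(dim(s) == d[2:3])) stop("shift map shape mismatch")
  g <- vol$geometry
  kg <- k_grid(g)
  n <- g$refractive_index
  z <- (seq_len(d[1]) - 1) * vol$voxel_pitch[1]
  f <- vol$field
  dim(f) <- c(d[1], d[2] * d[3])
  gmat <- f * exp(1i * 2 * n * kg$k0 * z)      # undo the reconstruction phase
  G <- stats::mvfft(gmat, inverse = TRUE) / d[1]  # back to spectra (fft order)
  m <- seq_len(d[1]) - 1 - floor(d[1] / 2)
  ord <- (m %% d[1]) + 1
  k_fft <- numeric(d[1])
  k_fft[ord] <- kg$k                            # physical k per fft-order row
  if (length(s) == 1) {
    G <- G * exp(-1i * 2 * n * k_fft * s)
  } else {
    G <- G * exp(-1i * outer(2 * n * k_fft, as.vector(s)))
  }
  out <- stats::mvfft(G) * exp(-1i * 2 * n * kg$k0 * z)
  dim(out) <- d
  out
}

#' Step 2: estimate and remove coherence-gate curvature
#'
#' Locates a planar reference reflector (coverslip) per beam by axial peak
#' detection with sub-voxel parabolic interpolation, fits a low-order 2D
#' polynomial offset map dz_cg(x, y), and removes it by a sub-voxel axial
#' Fourier shift of each A-scan. Afterwards the reflector is flat to well
#' under a voxel.
#'
#' @param vol a `tfocm_volume`.
#' @param map optional explicit offset map: either an (x, y) matrix in um or
#'   named polynomial coefficients (normalized coordinates). When supplied,
#'   no reflector is needed.
#' @param fit_order polynomial order of the fitted map (<= 4).
#' @param min_prominence reflector detection threshold: the median-over-beams
#'   axial profile peak must exceed this multiple of its own median.
#' @return list with `volume` (corrected) and `map` (the removed offsets, um,
#'   as an (x, y) matrix).
#' @export
remove_cg_curvature <- function(vol, map = NULL, fit_order = 2,
                                min_prominence = 3) {
  g <- vol$geometry
  nv <- dim(vol$field)
  if (is.null(map)) {
    mag <- abs(vol$field)
    prof <- apply(mag, 1, stats::median)
    zr <- which.max(prof)
    if (prof[zr] < min_prominence * stats::median(prof))
      stop("no detectable reference reflector; supply an explicit coherence-",
           "gate map via `map=`")
    halo <- 10L
    lo <- max(2L, zr - halo); hi <- min(nv[1] - 1L, zr + halo)
    sub <- mag[lo:hi, , , drop = FALSE]
    pk <- apply(sub, c(2, 3), which.max)
    zpk <- matrix(0, nv[2], nv[3])
    for (ix in seq_len(nv[2])) for (iy in seq_len(nv[3])) {
      i <- pk[ix, iy]
      off <- parabolic_peak_offset(sub[, ix, iy], i)
      zpk[ix, iy] <- (lo + i - 2 + off) * vol$voxel_pitch[1]
    }
    nc <- norm_xy(g)
    xy <- expand.grid(xn = nc$xn, yn = nc$yn)
    cf <- poly2d_fit(xy$xn, xy$yn, as.vector(zpk), order = fit_order)
    fitted <- matrix(poly2d_eval(cf, xy$xn, xy$yn), nv[2], nv[3])
    map <- fitted - stats::median(fitted)
  } else if (!is.matrix(map)) {
    nc <- norm_xy(g)
    map <- outer(nc$xn, nc$yn, function(x, y) poly2d_eval(map, x, y))
  }
  out <- vol
  out$field <- .axial_shift_vol(vol, map)
  out$corrections_applied <- c(vol$corrections_applied, "cg_removal")
  out$maps$coherence_gate_offset <- map
  list(volume = out, map = map)
}

#' Estimate the focal-depth map z_f(x, y) from bead sharpness
#'
#' Splits the transverse plane into tiles, and for each tile maximizes a
#' normalized intensity-variance sharpness metric of the refocused tile over
#' trial focal depths (coarse grid plus parabolic refinement). A low-order
#' polynomial is then fitted through the tile estimates, weighted by tile
#' signal energy.
#'
#' @param vol a `tfocm_volume` (steps 1-2 applied).
#' @param z_nominal center of the focal-depth search (um); defaults to the
#'   geometry's nominal focal depth.
#' @param half_range half-width of the search (um).
#' @param tiles length-2 tile grid, default 4 x 4.
#' @param n_trial number of coarse trial depths.
#' @param fit_order polynomial order of the fitted map.
#' @return named coefficients of the fitted map (normalized coordinates),
#'   with the per-tile estimates attached as attributes.
#' @export
estimate_focal_plane <- function(vol, z_nominal = NULL, half_range = 12,
                                 tiles = c(4L, 4L), n_trial = 9L,
                                 fit_order = 1) {
  g <- vol$geometry
  nv <- dim(vol$field)
  if (is.null(z_nominal)) {
    nomc <- g$focal_plane[["c"]]
    z_nominal <- if (is.null(nomc)) g$fov_um[1] / 2 else nomc
  }
  trials <- seq(z_nominal - half_range, z_nominal + half_range,
                length.out = n_trial)
  xb <- floor(seq(0, nv[2], length.out = tiles[1] + 1))
  yb <- floor(seq(0, nv[3], length.out = tiles[2] + 1))
  est <- wt <- xn <- yn <- numeric(0)
  for (i in seq_len(tiles[1])) for (j in seq_len(tiles[2])) {
    xi <- (xb[i] + 1):xb[i + 1]; yi <- (yb[j] + 1):yb[j + 1]
    tile <- vol$field[, xi, yi, drop = FALSE]
    sharp <- vapply(trials, function(zf) .tile_sharpness(tile, vol, zf),
                    numeric(1))
    b <- which.max(sharp)
    off <- parabolic_peak_offset(sharp, b)
    est <- c(est, trials[b] + off * diff(trials[1:2]))
    wt <- c(wt, sum(abs(tile)^2))
    xn <- c(xn, 2 * mean(xi - 1) / (nv[2] - 1) - 1)
    yn <- c(yn, 2 * mean(yi - 1) / (nv[3] - 1) - 1)
  }
  cf <- poly2d_fit(xn, yn, est, order = fit_order, w = wt)
  attr(cf, "tile_estimates") <- data.frame(xn = xn, yn = yn, zf = est, w = wt)
  cf
}

# Sharpness of a refocused tile: normalized intensity variance, summed over
# the most informative z slices. Slices are ranked by energy times initial
# intensity contrast, which keeps bead-bearing slices and rejects bright but
# featureless planes (the coverslip reflector would otherwise dominate the
# energy ranking while carrying no sharpness information).
.tile_sharpness <- function(tile, vol, zf, n_slices = 24L) {
  d <- dim(tile)
  en <- apply(abs(tile)^2, 1, sum)
  nvar <- apply(abs(tile)^2, 1, function(I) {
    m <- mean(I); if (m <= 0) 0 else stats::var(as.vector(I)) / m^2
  })
  keep <- order(en * nvar, decreasing = TRUE)[seq_len(min(n_slices, d[1]))]
  p <- vol$voxel_pitch
  qx <- fft_omega(d[2], p[2]); qy <- fft_omega(d[3], p[3])
  kg <- k_grid(vol$geometry)
  knk <- 2 * vol$geometry$refractive_index * kg$k0
  kz_rel <- sqrt(pmax(knk^2 - outer(qx^2, qy^2, "+"), 0)) - knk
  s <- 0
  for (iz in keep) {
    z <- (iz - 1) * p[1]
    sl <- ifft2(fft2(tile[iz, , ]) * exp(-1i * kz_rel * (z - zf)))
    I <- abs(sl)^2
    m <- mean(I)
    if (m > 0) s <- s + stats::var(as.vector(I)) / m^2
  }
  s
}

#' Step 3: focal plane registration
#'
#' Axially resamples the data (sub-voxel Fourier shifts) so that the focal
#' depth is transversely invariant, allowing a single transversely invariant
#' refocusing kernel to apply across the whole FOV.
#'
#' @param vol a `tfocm_volume`.
#' @param map focal-depth map: named polynomial coefficients or an (x, y)
#'   matrix in um. If NULL it is estimated with [estimate_focal_plane()].
#' @param ... passed to [estimate_focal_plane()].
#' @return the registered `tfocm_volume`, with `focal_depth` set to the
#'   (scalar) registered focal depth.
#' @export
register_focal_plane <- function(vol, map = NULL, ...) {
  g <- vol$geometry
  nv <- dim(vol$field)
  if (is.null(map)) map <- estimate_focal_plane(vol, ...)
  if (!is.matrix(map)) {
    nc <- norm_xy(g)
    mapm <- outer(nc$xn, nc$yn, function(x, y) poly2d_eval(map, x, y))
  } else mapm <- map
  p <- vol$voxel_pitch
  gx <- max(abs(diff(mapm)))
  gy <- max(abs(diff(t(mapm))))
  if (max(gx / p[1], gy / p[1]) > 1)
    stop("focal-depth map steeper than one axial voxel per transverse voxel; ",
         "not physical")
  zf_ref <- mean(mapm)
  out <- vol
  out$field <- .axial_shift_vol(vol, mapm - zf_ref)
  out$focal_depth <- zf_ref
  out$maps$focal_plane <- mapm
  out$corrections_applied <- c(vol$corrections_applied, "focal_registration")
  out
}

#' Step 4: phase registration
#'
#' Estimates one phase per slow-scan line (the axis most susceptible to
#' interferometric phase fluctuation) as the phase of the complex inner
#' product between the line and a jitter-suppressed reference (the running
#' mean across slow lines), iterated a few times, and conjugates it away.
#'
#' @param vol a `tfocm_volume`.
#' @param n_iter refinement iterations.
#' @param min_correlation if the mean normalized correlation against the
#'   reference falls below this, lines are considered decorrelated and the
#'   volume is returned uncorrected with a warning.
#' @return list with `volume` and `phases` (rad, per slow line, zero-mean).
#' @export
phase_register <- function(vol, n_iter = 3L, min_correlation = 0.05) {
  d <- dim(vol$field)
  M <- vol$field
  dim(M) <- c(d[1] * d[2], d[3])
  # two starting points: zero phase, and the dominant line-to-line ramp
  # (the slow-axis component of a bulk carrier can null the naive mean
  # reference, while on ramp-free data the ramp seed is itself noise);
  # the iteration that aligns the lines better wins
  inc <- Arg(colSums(Conj(M[, -d[3], drop = FALSE]) * M[, -1, drop = FALSE]))
  ramp <- Arg(mean(exp(1i * inc)))
  iterate <- function(phi) {
    for (it in seq_len(n_iter)) {
      R <- rowMeans(M * rep(exp(-1i * phi), each = d[1] * d[2]))
      ip <- colSums(Conj(R) * M)
      phi <- Arg(ip)
    }
    list(phi = phi, energy = sum(abs(ip)))
  }
  cand <- list(iterate(numeric(d[3])),
               iterate(ramp * (seq_len(d[3]) - 1)))
  best <- which.max(vapply(cand, `[[`, numeric(1), "energy"))
  phi <- cand[[best]]$phi
  R <- rowMeans(M * rep(exp(-1i * phi), each = d[1] * d[2]))
  corr <- abs(colSums(Conj(R) * M)) /
    (sqrt(colSums(abs(M)^2)) * sqrt(sum(abs(R)^2)) + .Machine$double.eps)
  if (mean(corr) < min_correlation) {
    warning("slow-scan lines are decorrelated; phase registration skipped")
    return(list(volume = vol, phases = rep(0, d[3])))
  }
  phi <- phi - mean(phi)
  # split-half validation: a free phase per line can always overfit the
  # reference, so phases estimated from half the pixels must also improve
  # the alignment of the other half before any correction is applied
  ridx <- seq_len(nrow(M))
  hA <- ridx[ridx %% 2L == 1L]
  hB <- ridx[ridx %% 2L == 0L]
  phiA <- numeric(d[3])
  for (it in seq_len(n_iter)) {
    RA <- rowMeans(M[hA, , drop = FALSE] *
                     rep(exp(-1i * phiA), each = length(hA)))
    phiA <- Arg(colSums(Conj(RA) * M[hA, , drop = FALSE]))
  }
  ebase <- sum(abs(colSums(Conj(rowMeans(M[hB, , drop = FALSE])) *
                             M[hB, , drop = FALSE])))
  MB <- M[hB, , drop = FALSE] * rep(exp(-1i * phiA), each = length(hB))
  eval_ <- sum(abs(colSums(Conj(rowMeans(MB)) * MB)))
  if (eval_ < (1 + 0.02) * ebase) {
    out <- vol
    out$maps$per_line_phase <- rep(0, d[3])
    out$corrections_applied <- c(vol$corrections_applied, "phase_registration")
    return(list(volume = out, phases = rep(0, d[3])))
  }
  out <- vol
  F2 <- M * rep(exp(-1i * phi), each = d[1] * d[2])
  dim(F2) <- d
  out$field <- F2
  out$maps$per_line_phase <- phi
  out$corrections_applied <- c(vol$corrections_applied, "phase_registration")
  list(volume = out, phases = phi)
}

#' Step 5: bulk demodulation
#'
#' Estimates the dominant transverse phase carrier q as the peak of the
#' depth-averaged transverse spatial-frequency magnitude (quadratically
#' interpolated to sub-bin precision) and multiplies the field by
#' exp(-i q . (x, y)). An uncorrected carrier shears computationally
#' refocused volumes: beads acquire a lateral offset growing linearly with
#' defocus and flipping sign across the focal plane.
#'
#' @param vol a `tfocm_volume`.
#' @param z_stride evaluate the average spectrum on every `z_stride`-th slice.
#' @return list with `volume` and `carrier` (estimated q, rad/um).
#' @export
bulk_demodulate <- function(vol, z_stride = 2L) {
  d <- dim(vol$field)
  S <- matrix(0, d[2], d[3])
  for (iz in seq(1L, d[1], by = z_stride)) {
    S <- S + abs(fft2(vol$field[iz, , ]))^2
  }
  pk <- arrayInd(which.max(S), dim(S))
  # sub-bin refinement along each axis on the log spectrum
  wrap <- function(i, n) ((i - 1) %% n) + 1
  sx <- log(S[wrap(pk[1] + (-1:1), d[2]), pk[2]] + .Machine$double.xmin)
  sy <- log(S[pk[1], wrap(pk[2] + (-1:1), d[3])] + .Machine$double.xmin)
  ox <- parabolic_peak_offset(sx, 2L)
  oy <- parabolic_peak_offset(sy, 2L)
  p <- vol$voxel_pitch
  dqx <- 2 * pi / (d[2] * p[2]); dqy <- 2 * pi / (d[3] * p[3])
  mx <- pk[1] - 1; if (mx >= d[2] / 2) mx <- mx - d[2]
  my <- pk[2] - 1; if (my >= d[3] / 2) my <- my - d[3]
  q <- c((mx + ox) * dqx, (my + oy) * dqy)
  # flag ambiguity: a comparable secondary peak far from the chosen one
  S2 <- S; S2[wrap(pk[1] + (-2:2), d[2]), wrap(pk[2] + (-2:2), d[3])] <- 0
  if (max(S2) > 0.85 * S[pk[1], pk[2]])
    message("bulk_demodulate: multiple comparable spectral peaks; ",
            "using the strongest")
  nc <- norm_xy(vol$geometry)
  ph <- outer(q[1] * nc$x, q[2] * nc$y, "+")
  out <- vol
  out$field <- vol$field * rep(exp(-1i * ph), each = d[1])
  # sub-bin refinement: the parabolic peak is only good to a fraction of a
  # bin, and the residual carrier shears refocused beads in proportion to
  # defocus. The phase gradient of the brightest plane (the reflector, when
  # present) measures the residual directly.
  en <- apply(abs(out$field)^2, 1, sum)
  izb <- which.max(en)
  cs <- out$field[izb, , ]
  Ib <- abs(cs)^2
  flatness <- stats::var(as.vector(Ib)) / max(mean(Ib)^2, 1e-300)
  dq <- c(Arg(sum(Conj(cs[-nrow(cs), ]) * cs[-1, ])) / p[2],
          Arg(sum(Conj(cs[, -ncol(cs)]) * cs[, -1])) / p[3])
  # only a laterally uniform (reflector-like) plane gives an unbiased
  # phase-gradient reading; speckle or bead planes would corrupt it
  if (flatness < 0.5 && all(is.finite(dq)) &&
      all(abs(dq) < 0.6 * c(dqx, dqy))) {
    q <- q + dq
    ph2 <- outer(dq[1] * nc$x, dq[2] * nc$y, "+")
    out$field <- out$field * rep(exp(-1i * ph2), each = d[1])
  }
  out$maps$carrier_estimate <- q
  out$corrections_applied <- c(vol$corrections_applied, "bulk_demodulation")
  list(volume = out, carrier = q)
}

#' Step 6: computational adaptive optics (defocus correction)
#'
#' For each depth z, applies the transversely invariant defocus-conjugate
#' kernel exp(-i (z - z_f) (k_z(q) - 2 n k0)) with
#' k_z = sqrt((2 n k0)^2 - qx^2 - qy^2) in the transverse spatial-frequency
#' domain (evanescent region zeroed). Restores focal-plane transverse
#' resolution throughout the volume.
#'
#' @param vol a `tfocm_volume` whose `focal_depth` is set (by
#'   [register_focal_plane()]) or supplied via `focal_depth`.
#' @param focal_depth scalar focal depth (um) to use if the volume has none.
#' @param sign kernel sign convention; `+1` (default) is the sign that
#'   sharpens a below-focus bead under this package's forward model. Both
#'   signs are exposed for real-data dialects.
#' @param force apply even if steps 2-5 have not all been run (needed only
#'   for controlled experiments; the chain order matters on real data).
#' @return the refocused `tfocm_volume`.
#' @export
apply_cao <- function(vol, focal_depth = NULL, sign = 1, force = FALSE) {
  need <- c("cg_removal", "focal_registration", "phase_registration",
            "bulk_demodulation")
  if (!force && !all(need %in% vol$corrections_applied))
    stop("apply_cao: steps 2-5 (", paste(setdiff(need, vol$corrections_applied),
                                         collapse = ", "),
         ") have not been applied; run them first or use force = TRUE")
  zf <- vol$focal_depth %||% focal_depth
  if (is.null(zf)) stop("apply_cao: focal depth unknown; register the focal ",
                        "plane or pass focal_depth")
  d <- dim(vol$field)
  kzr <- kz_relative(vol$geometry)
  p <- vol$voxel_pitch
  out <- vol
  for (iz in seq_len(d[1])) {
    z <- (iz - 1) * p[1]
    H <- exp(-1i * sign * kzr$kz_rel * (z - zf))
    H[kzr$evanescent] <- 0
    out$field[iz, , ] <- ifft2(fft2(vol$field[iz, , ]) * H)
  }
  out$focal_depth <- zf
  out$corrections_applied <- c(vol$corrections_applied, "cao")
  out
}

#' Run image-formation steps 1-6 in order
#'
#' Convenience driver used by the pipeline: reconstruct, then apply the
#' requested correction steps in canonical order.
#'
#' @param raw `tfocm_spectra`.
#' @param steps character vector of step names among
#'   `c("cg_removal", "focal_registration", "phase_registration",
#'   "bulk_demodulation", "cao")`, applied in canonical order.
#' @param cg_map,focal_map optional explicit maps (see the step functions).
#' @param focal_search passed to [estimate_focal_plane()] as `half_range`.
#' @return a `tfocm_volume`.
#' @export
form_image <- function(raw, steps = c("cg_removal", "focal_registration",
                                      "phase_registration",
                                      "bulk_demodulation", "cao"),
                       cg_map = NULL, focal_map = NULL, focal_search = 12) {
  vol <- reconstruct_volume(raw)
  if ("cg_removal" %in% steps)
    vol <- remove_cg_curvature(vol, map = cg_map)$volume
  if ("focal_registration" %in% steps)
    vol <- register_focal_plane(vol, map = focal_map,
                                half_range = focal_search)
  if ("phase_registration" %in% steps)
    vol <- phase_register(vol)$volume
  if ("bulk_demodulation" %in% steps)
    vol <- bulk_demodulate(vol)$volume
  if ("cao" %in% steps)
    vol <- apply_cao(vol, force = TRUE)
  vol
}
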