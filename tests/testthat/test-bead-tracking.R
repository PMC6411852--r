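# Bead localization, matching, track assembly and displacement summaries.

test_that("size filters remove too-small and above-quantile objects", {
  # toy binary volume with components of 10, 30, 40 and 5000 voxels
  vol <- array(0, c(40, 40, 40))
  put_blob <- function(vol, z0, n) {
    k <- ceiling(n^(1 / 3))
    block <- array(seq_len(k^3) <= n, c(k, k, k))
    vol[z0:(z0 + k - 1), 5:(4 + k), 5:(4 + k)][block] <- 1
    vol
  }
  vol <- put_blob(vol, 2, 10)
  vol <- put_blob(vol, 12, 30)
  vol <- put_blob(vol, 22, 40)
  vol[30:39, 20:39, 20:29][] <- 1  # 2000-voxel slab: the "cell body"
  vol[1:10, 25:39, 5:14][] <- 1    # and a 1500-voxel aggregate
  beads <- localize_beads(vol, min_voxels = 16L, max_size_quantile = 0.5,
                          threshold = 0.5, normalize_depth = FALSE,
                          pitch = c(1, 1, 1))
  # 10 < 16 dropped; the two large slabs are above the median size of
  # {30, 40, 2000, 1500}; the 30- and 40-voxel objects remain
  expect_equal(nrow(beads), 2L)
  expect_setequal(beads$n_voxels, c(30L, 40L))
})

test_that("empty volumes yield empty bead sets with a warning", {
  expect_warning(b <- localize_beads(array(0, c(8, 8, 8)), pitch = c(1, 1, 1)),
                 "no beads")
  expect_equal(nrow(b), 0L)
})

test_that("localization is accurate and translation-equivariant", {
  # a faint noise floor keeps the background statistics well-posed for the
  # contrast-split threshold; the beads remain essentially noiseless
  # axial sampling fine enough that the point-spread function spans ~3
  # slices, as on the full-scale instrument
  g <- acquisition_geometry(n_k_samples = 256L, fov_um = c(160, 80, 80),
                            n_voxels = c(256L, 48L, 48L),
                            focal_plane = c(c = 80), noise_floor_db = -60)
  set.seed(4)
  pos <- cbind(stats::runif(25, 30, 130), stats::runif(25, 8, 72),
               stats::runif(25, 8, 72))
  raw <- simulate_spectra(fx_fixed_scene(pos, fov = g$fov_um), g,
                          include_noise = TRUE, noise_seed = 10L)
  vol <- reconstruct_volume(raw, window = "hann")
  vol <- apply_cao(vol, focal_depth = 80, force = TRUE)  # localize refocused
  beads <- localize_beads(vol, min_voxels = 4L)
  expect_gte(nrow(beads), 23L)
  m <- match_beads(stats::setNames(as.data.frame(pos), c("z", "x", "y")),
                   beads, k_neighbors = 5L, max_displacement = 5)
  errv <- sweep(as.matrix(beads[m[, "b"], c("z", "x", "y")]) -
                  pos[m[, "a"], ], 2, voxel_pitch(g), "/")
  expect_lt(sqrt(mean(rowSums(errv^2) / 3)), 0.1)
  # integer-voxel shift of the volume shifts every centroid by that amount
  sh <- c(3L, 2L, -4L)
  mag <- abs(vol$field)
  d <- dim(mag)
  shifted <- array(0, d)
  shifted[(1 + sh[1]):d[1], (1 + sh[2]):d[2], 1:(d[3] + sh[3])] <-
    mag[1:(d[1] - sh[1]), 1:(d[2] - sh[2]), (1 - sh[3]):d[3]]
  thr_raw <- 0.3 * max(mag)
  b2 <- localize_beads(shifted, min_voxels = 4L, pitch = voxel_pitch(g),
                       threshold = thr_raw, normalize_depth = FALSE)
  b1 <- localize_beads(mag, min_voxels = 4L, pitch = voxel_pitch(g),
                       threshold = thr_raw, normalize_depth = FALSE)
  keep1 <- b1$z < (d[1] - sh[1] - 3) * voxel_pitch(g)[1] &
    b1$x < (d[2] - sh[2] - 3) * voxel_pitch(g)[2] &
    b1$y > (3 - sh[3]) * voxel_pitch(g)[3]
  mm <- match_beads(b1[keep1, ], b2, k_neighbors = 5L,
                    max_displacement = 15)
  dd <- as.matrix(b2[mm[, "b"], c("z", "x", "y")]) -
    as.matrix(b1[keep1, ][mm[, "a"], c("z", "x", "y")])
  expect_lt(max(abs(sweep(dd, 2, sh * voxel_pitch(g)))), 1e-9)
})

# Synthetic bead clouds with a smooth displacement field.
.synth_cloud <- function(n = 300, seed = 1, spacing_scale = 18) {
  set.seed(seed)
  L <- spacing_scale * n^(1 / 3)
  pos <- matrix(stats::runif(3 * n, 0, L), ncol = 3)
  list(pos = pos, L = L)
}

.smooth_field <- function(pos, L, umax = 8) {
  ctr <- rep(L / 2, 3)
  d <- sweep(pos, 2, ctr)
  r <- sqrt(rowSums(d^2)) + 1e-9
  mag <- umax * exp(-(r / (L / 3))^2)
  -d / r * mag   # smooth contraction toward the center
}

test_that("matching survives smooth deformation with bead churn", {
  cl <- .synth_cloud(300, seed = 7)
  u <- .smooth_field(cl$pos, cl$L, umax = 8)
  set.seed(8)
  gone <- sample.int(300, 15)              # 5% disappear
  new <- matrix(stats::runif(45, 0, cl$L), ncol = 3)  # 5% appear
  a <- stats::setNames(as.data.frame(cl$pos), c("z", "x", "y"))
  bpos <- rbind(cl$pos[-gone, ] + u[-gone, ], new)
  perm <- sample.int(nrow(bpos))
  b <- stats::setNames(as.data.frame(bpos[perm, ]), c("z", "x", "y"))
  truth <- rep(NA_integer_, 300)
  truth[setdiff(1:300, gone)] <- match(seq_len(285), perm)
  m <- match_beads(a, b)
  got <- rep(NA_integer_, 300)
  got[m[, "a"]] <- m[, "b"]
  persisting <- setdiff(1:300, gone)
  correct <- mean(got[persisting] == truth[persisting], na.rm = TRUE)
  matched <- mean(!is.na(got[persisting]))
  expect_gte(correct * matched, 0.99)
})

test_that("matching handles rigid translations larger than the spacing", {
  cl <- .synth_cloud(150, seed = 9)
  shift <- c(25, 0, 0)
  a <- stats::setNames(as.data.frame(cl$pos), c("z", "x", "y"))
  b <- stats::setNames(as.data.frame(sweep(cl$pos, 2, -shift)), c("z", "x", "y"))
  m <- match_beads(a, b, max_displacement = 40)
  expect_equal(nrow(m), 150L)
  expect_true(all(m[, "a"] == m[, "b"]))
  # identity matching on identical sets
  mi <- match_beads(a, a)
  expect_true(all(mi[, "a"] == mi[, "b"]))
  expect_equal(nrow(mi), 150L)
  # mutual-best stage is symmetric
  ms <- match_beads(a, b, max_displacement = 40)
  mr <- match_beads(b, a, max_displacement = 40)
  sa <- ms[attr(ms, "stage") == "mutual", , drop = FALSE]
  sb <- mr[attr(mr, "stage") == "mutual", , drop = FALSE]
  expect_setequal(paste(sa[, 1], sa[, 2]), paste(sb[, 2], sb[, 1]))
})

test_that("tracks subtract rigid drift and preserve the local field", {
  cl <- .synth_cloud(350, seed = 10, spacing_scale = 18)
  u_local <- .smooth_field(cl$pos, cl$L, umax = 5)
  drift <- c(1, -2, 0.5)
  sets <- list(
    stats::setNames(as.data.frame(cl$pos + u_local +
                                    matrix(drift, 350, 3, byrow = TRUE)),
                    c("z", "x", "y")),
    stats::setNames(as.data.frame(cl$pos + 0.5 * u_local), c("z", "x", "y")),
    stats::setNames(as.data.frame(cl$pos), c("z", "x", "y")))
  tr <- build_tracks(sets, far_field_radius = 0.35 * cl$L,
                     cell_centroid = rep(cl$L / 2, 3))
  t0 <- tr[tr$t_index == 0 & !is.na(tr$uz), ]
  ref <- tr[tr$t_index == 2, ]
  idx <- match(t0$bead_id, ref$bead_id)
  # drift must be gone and the local field preserved
  nn <- apply(as.matrix(ref[idx, c("z", "x", "y")]), 1,
              function(p) which.min(colSums((t(cl$pos) - p)^2)))
  err <- as.matrix(t0[, c("uz", "ux", "uy")]) - u_local[nn, ]
  est_drift <- attr(tr, "drift")[1, ]
  far <- sqrt(rowSums(sweep(cl$pos[nn, ], 2, rep(cl$L / 2, 3))^2)) >
    0.35 * cl$L
  expect_lt(max(abs(est_drift - drift)), 0.1)
  expect_lt(sqrt(mean(rowSums(err^2) / 3)), 0.15)
  # reference displacements are exactly zero
  expect_true(all(tr$uz[tr$t_index == 2] == 0))
  # static scene: all displacements zero after correction
  sets0 <- list(sets[[3]], sets[[3]], sets[[3]])
  tr0 <- build_tracks(sets0, far_field_radius = 0.35 * cl$L,
                      cell_centroid = rep(cl$L / 2, 3))
  expect_lt(max(abs(tr0[, c("uz", "ux", "uy")]), na.rm = TRUE), 1e-9)
  # drift correction is idempotent: re-estimated drift on corrected tracks
  # is zero
  expect_lt(max(abs(attr(tr0, "drift"))), 1e-9)
})

test_that("displacement profiles fall off like the Kelvin field", {
  model <- elastic_model(90, 0.45)
  set.seed(12)
  n <- 3000
  pos <- matrix(stats::runif(3 * n, -150, 150), ncol = 3)
  keep <- sqrt(rowSums(pos^2)) > 20
  pos <- pos[keep, ]
  u <- kelvin_displacement(c(10, 0, 0), c(0, 0, 0), pos, model)
  tr <- data.frame(bead_id = seq_len(nrow(pos)), t_index = 0L, t_minutes = 0,
                   z = pos[, 1], x = pos[, 2], y = pos[, 3],
                   uz = u[, 1], ux = u[, 2], uy = u[, 3], confidence = 1)
  tr2 <- tr; tr2$t_index <- 1L; tr2[, c("uz", "ux", "uy")] <- 0
  tracks <- rbind(tr, tr2)
  class(tracks) <- c("tfocm_tracks", "data.frame")
  pr <- displacement_profile(tracks, cell_centroid = c(0, 0, 0),
                             bin_width = 10, near_radius = 50)
  p0 <- pr$profile[pr$profile$t_index == 0 & pr$profile$r_mid >= 30 &
                     pr$profile$r_mid <= 120 & pr$profile$n > 10, ]
  # mean |u| in a Kelvin field decays as 1/r
  pred <- p0$mean_u[1] * p0$r_mid[1] / p0$r_mid
  expect_lt(max(abs(p0$mean_u / pred - 1)), 0.15)
  # all-zero displacements give all-zero bins
  pz <- pr$profile[pr$profile$t_index == 1, ]
  expect_true(all(pz$mean_u[pz$n > 0] == 0))
  expect_true(all(is.na(pz$mean_u[pz$n == 0])))
})
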