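# Bead localization, feature-vector matching across time, track assembly
# with rigid-drift correction, and displacement summaries.

#' Localize scattering beads in a refocused volume
#'
#' Depth-normalizes image intensity, binarizes with a single global
#' threshold (a background/bead-peak contrast split by default), labels
#' 26-connected components, removes objects smaller than `min_voxels` and
#' objects larger than the `max_size_quantile` quantile of the remaining
#' sizes (cell bodies, aggregates, debris), and returns intensity-weighted
#' centroids in micrometres.
#'
#' @param vol a `tfocm_volume`, or a non-negative 3D intensity array (then
#'   `pitch` must be given).
#' @param min_voxels minimum object size in voxels (default 16).
#' @param max_size_quantile upper size quantile cut among surviving objects
#'   (default 0.99); objects strictly larger than it are dropped.
#' @param threshold numeric global threshold on the normalized intensity;
#'   NULL or "contrast" for the default contrast-split level (geometric
#'   midpoint between the background median and the bead-peak quantile), or
#'   "otsu" for a single Otsu split of the log-intensity histogram.
#' @param normalize_depth logical; divide each z slice by a smoothed
#'   per-slice brightness scale (compensates sensitivity fall-off).
#' @param pitch voxel pitch (um, length 3) when `vol` is a bare array.
#' @return a `tfocm_beads` data.frame with columns z, x, y (um), intensity,
#'   n_voxels.
#' @export
localize_beads <- function(vol, min_voxels = 16L, max_size_quantile = 0.99,
                           threshold = NULL, normalize_depth = TRUE,
                           pitch = NULL) {
  if (inherits(vol, "tfocm_volume")) {
    mag <- abs(vol$field)
    pitch <- vol$voxel_pitch
  } else {
    mag <- vol
    if (is.null(pitch)) stop("pitch required for a bare array")
  }
  d <- dim(mag)
  if (normalize_depth) {
    s <- apply(mag, 1, stats::quantile, probs = 0.999, names = FALSE)
    # the scale must vary only on the slow (fall-off) scale: slice-to-slice
    # fluctuations of the quantile would distort each bead's own axial
    # profile and bias its depth centroid
    s <- pmax(s, .Machine$double.xmin)
    if (d[1] >= 8L) {
      sm <- stats::lowess(seq_len(d[1]), log(s), f = 0.4)$y
      s <- exp(sm)
    }
    # floor the scale so sparse or noise-free slices are not amplified into
    # fake structure
    s <- pmax(s, 0.02 * max(s), .Machine$double.xmin)
    mag <- mag / s
  }
  if (is.null(threshold) || identical(threshold, "contrast")) {
    v <- mag[mag > 0]
    if (length(v) == 0L) {
      warning("empty volume; no beads found")
      return(.empty_beads())
    }
    # contrast split: beads occupy a vanishing fraction of the volume, so
    # histogram methods tend to land inside the background mode; the
    # geometric midpoint between the background level (median) and the
    # bead-peak level (extreme quantile) separates the classes stably
    threshold <- sqrt(stats::median(v) *
                        stats::quantile(v, 0.9997, names = FALSE))
  } else if (identical(threshold, "otsu")) {
    v <- mag[mag > 0]
    if (length(v) == 0L) {
      warning("empty volume; no beads found")
      return(.empty_beads())
    }
    threshold <- 10^otsu_threshold(log10(v + max(v) * 1e-6))
  }
  fg <- mag > threshold
  if (!any(fg)) {
    warning("no voxels above threshold; no beads found")
    return(.empty_beads())
  }
  lab <- label_components3(fg, connectivity = 26L)
  sizes <- lab$sizes
  keep <- which(sizes >= min_voxels)
  if (length(keep)) {
    cut <- stats::quantile(sizes[keep], max_size_quantile, names = FALSE)
    keep <- keep[sizes[keep] <= cut]
  }
  if (!length(keep)) {
    warning("no components passed the size filters; no beads found")
    return(.empty_beads())
  }
  idx <- which(fg)
  comp <- lab$labels[idx]
  sel <- comp %in% keep
  idx <- idx[sel]; comp <- comp[sel]
  posv <- arrayInd(idx, d)
  w <- mag[idx] - threshold          # background-subtracted weights: less
  wsum <- rowsum(w, comp)            # threshold-boundary centroid bias
  cz <- rowsum(w * (posv[, 1] - 1) * pitch[1], comp) / wsum
  cx <- rowsum(w * (posv[, 2] - 1) * pitch[2], comp) / wsum
  cy <- rowsum(w * (posv[, 3] - 1) * pitch[3], comp) / wsum
  inten <- rowsum(mag[idx], comp)
  out <- data.frame(z = as.vector(cz), x = as.vector(cx), y = as.vector(cy),
                    intensity = as.vector(inten),
                    n_voxels = as.vector(table(comp)[as.character(sort(unique(comp)))]))
  out <- out[order(-out$intensity), ]
  rownames(out) <- NULL
  class(out) <- c("tfocm_beads", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

.empty_beads <- function() {
  out <- data.frame(z = numeric(0), x = numeric(0), y = numeric(0),
                    intensity = numeric(0), n_voxels = integer(0))
  class(out) <- c("tfocm_beads", "data.frame")
  out
}

#' Match beads between two time points by conserved neighbor offsets
#'
#' Each bead is characterized by the offset vectors to its k nearest
#' neighbors. Candidate pairs (within `max_displacement`) are scored by how
#' many neighbor offsets are conserved to within `tol`; mutual-best pairs
#' are accepted first, and remaining beads are then matched iteratively by
#' consistency with the displacements of already-accepted neighbors. The
#' underlying assumption is that the substrate deforms smoothly on scales
#' longer than the bead spacing, so relative offsets are nearly conserved
#' even under large rigid motion.
#'
#' @param a,b `tfocm_beads` (or data.frames with z, x, y columns).
#' @param k_neighbors neighbors per feature vector (default 10; reduced with
#'   a warning if a set is too small).
#' @param tol offset conservation tolerance (um); default a quarter of the
#'   mean nearest-neighbor spacing of `a`.
#' @param max_displacement candidate search radius (um); default twice the
#'   mean spacing.
#' @param min_score minimum conserved-offset count for a mutual-best match.
#' @return integer matrix with columns `a`, `b` (row indices of matched
#'   pairs) and attribute `stage` ("mutual" or "relaxed").
#' @export
match_beads <- function(a, b, k_neighbors = 10L, tol = NULL,
                        max_displacement = NULL, min_score = 3L) {
  A <- as.matrix(a[, c("z", "x", "y")])
  B <- as.matrix(b[, c("z", "x", "y")])
  na <- nrow(A); nb <- nrow(B)
  if (na == 0L || nb == 0L) stop("match_beads: empty bead set")
  k <- k_neighbors
  if (k >= min(na, nb)) {
    k <- max(1L, min(na, nb) - 1L)
    warning("k_neighbors reduced to ", k, " (small bead set)")
  }
  spacing <- .mean_nn_spacing(A)
  if (is.null(tol)) tol <- 0.25 * spacing
  if (is.null(max_displacement)) max_displacement <- 2 * spacing
  offA <- .knn_offsets(A, k)
  offB <- .knn_offsets(B, k)
  # candidate pairs within max_displacement
  D2 <- .cross_dist2(A, B)
  cand <- which(D2 <= max_displacement^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(.match_result(integer(0), integer(0)))
  score <- numeric(nrow(cand))
  tol2 <- tol^2
  for (r in seq_len(nrow(cand))) {
    oa <- offA[[cand[r, 1]]]
    ob <- offB[[cand[r, 2]]]
    d2 <- .cross_dist2(oa, ob)
    score[r] <- sum(apply(d2, 1, min) <= tol2)
  }
  # mutual-best acceptance
  sA <- rep(-1, na); bestA <- integer(na)
  sB <- rep(-1, nb); bestB <- integer(nb)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (score[r] > sA[i] ||
        (score[r] == sA[i] && bestA[i] > 0 && D2[i, j] < D2[i, bestA[i]])) {
      sA[i] <- score[r]; bestA[i] <- j
    }
    if (score[r] > sB[j] ||
        (score[r] == sB[j] && bestB[j] > 0 && D2[i, j] < D2[bestB[j], j])) {
      sB[j] <- score[r]; bestB[j] <- i
    }
  }
  mi <- which(bestA > 0 & sA >= min_score)
  mi <- mi[bestB[bestA[mi]] == mi]
  ma <- mi; mb <- bestA[mi]
  stage <- rep("mutual", length(ma))
  # relaxation: match leftovers by consistency with accepted neighbor motion
  for (pass in 1:5) {
    um <- setdiff(seq_len(na), ma)
    ub <- setdiff(seq_len(nb), mb)
    if (!length(um) || !length(ub) || !length(ma)) break
    added <- FALSE
    accA <- A[ma, , drop = FALSE]
    disp <- B[mb, , drop = FALSE] - accA
    for (i in um) {
      if (!length(ub)) break
      dn <- .cross_dist2(A[i, , drop = FALSE], accA)
      nb_id <- order(dn)[seq_len(min(4L, length(ma)))]
      pred <- colMeans(disp[nb_id, , drop = FALSE])
      tgt <- A[i, ] + pred
      dj <- .cross_dist2(rbind(tgt), B[ub, , drop = FALSE])
      jb <- which.min(dj)
      if (dj[jb] <= (2 * tol)^2) {
        ma <- c(ma, i); mb <- c(mb, ub[jb]); stage <- c(stage, "relaxed")
        added <- TRUE
        accA <- A[ma, , drop = FALSE]
        disp <- B[mb, , drop = FALSE] - accA
        ub <- setdiff(ub, ub[jb])
      }
    }
    if (!added) break
  }
  .match_result(ma, mb, stage)
}

.match_result <- function(a, b, stage = character(length(a))) {
  m <- cbind(a = a, b = b)
  attr(m, "stage") <- stage
  m
}

.mean_nn_spacing <- function(P) {
  n <- nrow(P)
  if (n < 2) return(Inf)
  idx <- if (n > 300L) sample.int(n, 300L) else seq_len(n)
  d2 <- .cross_dist2(P[idx, , drop = FALSE], P)
  d2[cbind(seq_along(idx), idx)] <- Inf
  mean(sqrt(apply(d2, 1, min)))
}

.knn_offsets <- function(P, k) {
  d2 <- .cross_dist2(P, P)
  diag(d2) <- Inf
  lapply(seq_len(nrow(P)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    sweep(P[nb, , drop = FALSE], 2, P[i, ])
  })
}

.cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

#' Assemble bead tracks over time and compute reference-state displacements
#'
#' Chains pairwise matches between consecutive time points (closing gaps of
#' at most one missing time point) through to the final time point, which is
#' the relaxed reference state. Displacements are `u(t) = pos(t) -
#' pos(t_max)`, so `u(t_max) = 0` exactly. Rigid drift at each time point is
#' estimated as the componentwise median displacement of beads farther than
#' `far_field_radius` from the cell centroid, and subtracted from all
#' displacements at that time.
#'
#' @param sets list of `tfocm_beads`, one per time point (chronological).
#' @param far_field_radius drift-estimation radius (um, default 150).
#' @param cell_centroid either a length-3 vector, an n_t x 3 matrix, or NULL
#'   (FOV center of mass of beads).
#' @param t_minutes optional acquisition times (minutes).
#' @param drift_correct logical.
#' @param ... passed to [match_beads()].
#' @return a `tfocm_tracks` data.frame with columns bead_id, t_index,
#'   t_minutes, z, x, y, uz, ux, uy, confidence; attribute `drift` holds the
#'   per-time rigid drift removed.
#' @export
build_tracks <- function(sets, far_field_radius = 150, cell_centroid = NULL,
                         t_minutes = NULL, drift_correct = TRUE, ...) {
  nt <- length(sets)
  if (nt < 2L) stop("need at least two time points")
  if (is.null(t_minutes)) t_minutes <- 5 * (seq_len(nt) - 1)
  if (is.null(cell_centroid)) {
    cell_centroid <- colMeans(as.matrix(sets[[nt]][, c("z", "x", "y")]))
  }
  if (is.null(dim(cell_centroid)))
    cell_centroid <- matrix(cell_centroid, nt, 3, byrow = TRUE)
  # forward links t -> t+1
  links <- vector("list", nt - 1L)
  for (t in seq_len(nt - 1L)) links[[t]] <- match_beads(sets[[t]], sets[[t + 1L]], ...)
  # chain each bead of each start time to t_max; gap-close over one miss
  n_final <- nrow(sets[[nt]])
  pos <- array(NA_real_, c(n_final, nt, 3))
  pos[, nt, ] <- as.matrix(sets[[nt]][, c("z", "x", "y")])
  # map from (t, row) to final id, built backwards
  id_at <- vector("list", nt)
  id_at[[nt]] <- seq_len(n_final)
  for (t in (nt - 1L):1L) {
    id_at[[t]] <- rep(NA_integer_, nrow(sets[[t]]))
    m <- links[[t]]
    nxt <- id_at[[t + 1L]]
    ok <- !is.na(nxt[m[, "b"]])
    id_at[[t]][m[ok, "a"]] <- nxt[m[ok, "b"]]
    # gap closing: beads unmatched at t but matchable to t+2
    if (t + 2L <= nt) {
      miss <- which(is.na(id_at[[t]]))
      if (length(miss) >= 1L) {
        m2 <- tryCatch(match_beads(sets[[t]], sets[[t + 2L]], ...),
                       error = function(e) NULL)
        if (!is.null(m2)) {
          nxt2 <- id_at[[t + 2L]]
          for (r in seq_len(nrow(m2))) {
            i <- m2[r, "a"]; j <- m2[r, "b"]
            if (i %in% miss && !is.na(nxt2[j]) &&
                !(nxt2[j] %in% id_at[[t]])) id_at[[t]][i] <- nxt2[j]
          }
        }
      }
    }
    P <- as.matrix(sets[[t]][, c("z", "x", "y")])
    got <- which(!is.na(id_at[[t]]))
    pos[id_at[[t]][got], t, ] <- P[got, , drop = FALSE]
  }
  u <- array(NA_real_, c(n_final, nt, 3))
  for (t in seq_len(nt)) u[, t, ] <- pos[, t, ] - pos[, nt, ]
  drift <- matrix(0, nt, 3)
  if (drift_correct) {
    for (t in seq_len(nt)) {
      ref <- pos[, nt, ]
      dctr <- sqrt(rowSums(sweep(ref, 2, cell_centroid[t, ])^2))
      far <- which(dctr > far_field_radius & !is.na(u[, t, 1]))
      if (length(far) < 10L) {
        message("time ", t, ": fewer than 10 far-field beads; drift ",
                "correction skipped")
        next
      }
      drift[t, ] <- apply(u[far, t, , drop = FALSE], 3, stats::median)
      u[, t, ] <- sweep(u[, t, ], 2, drift[t, ])
    }
    # the reference state defines zero displacement by construction
    u[, nt, ] <- 0
  }
  # neighbor-consistency rejection: the substrate deforms smoothly on
  # scales longer than the bead spacing, so a bead whose displacement
  # deviates strongly from its neighbors' median is a mismatch or a
  # corrupted localization, not motion
  ref <- pos[, nt, ]
  for (t in seq_len(nt - 1L)) {
    have <- which(!is.na(u[, t, 1]))
    if (length(have) < 8L) next
    P <- ref[have, , drop = FALSE]
    d2 <- .cross_dist2(P, P)
    diag(d2) <- Inf
    k <- min(6L, length(have) - 1L)
    dev <- numeric(length(have))
    medu <- matrix(0, length(have), 3)
    for (i in seq_along(have)) {
      nb <- order(d2[i, ])[seq_len(k)]
      medu[i, ] <- apply(u[have[nb], t, , drop = FALSE], 3, stats::median)
      dev[i] <- sqrt(sum((u[have[i], t, ] - medu[i, ])^2))
    }
    cut <- max(0.5, 5 * stats::median(dev))
    bad <- have[dev > cut]
    if (length(bad)) u[bad, t, ] <- NA_real_
  }
  rows <- do.call(rbind, lapply(seq_len(nt), function(t) {
    data.frame(bead_id = seq_len(n_final), t_index = t - 1L,
               t_minutes = t_minutes[t],
               z = pos[, t, 1], x = pos[, t, 2], y = pos[, t, 3],
               uz = u[, t, 1], ux = u[, t, 2], uy = u[, t, 3],
               confidence = as.numeric(!is.na(pos[, t, 1])))
  }))
  rows <- rows[!is.na(rows$z), ]
  rownames(rows) <- NULL
  class(rows) <- c("tfocm_tracks", "data.frame")
  attr(rows, "drift") <- drift
  attr(rows, "cell_centroid") <- cell_centroid
  rows
}

#' Displacement magnitude versus distance from the cell, over time
#'
#' Bins mean displacement magnitude |u| by distance from the cell centroid
#' for each time point, and reports the scalar near-cell mean (beads within
#' `near_radius` of the centroid).
#'
#' @param tracks a `tfocm_tracks`.
#' @param cell_centroid length-3 vector or n_t x 3 matrix (um); defaults to
#'   the centroid stored on the tracks.
#' @param bin_width distance bin width (um).
#' @param near_radius near-cell radius (um, default 50).
#' @return list with `profile` (data.frame t_index, r_mid, mean_u, n; empty
#'   bins reported as NA, not zero) and `near` (data.frame t_index,
#'   t_minutes, mean_u_near, n).
#' @export
displacement_profile <- function(tracks, cell_centroid = NULL, bin_width = 10,
                                 near_radius = 50) {
  if (nrow(tracks) == 0L) stop("empty track table")
  if (is.null(cell_centroid)) cell_centroid <- attr(tracks, "cell_centroid")
  ts <- sort(unique(tracks$t_index))
  if (is.null(dim(cell_centroid)))
    cell_centroid <- matrix(cell_centroid, length(ts), 3, byrow = TRUE)
  prof <- list(); near <- list()
  for (i in seq_along(ts)) {
    tt <- tracks[tracks$t_index == ts[i] & !is.na(tracks$uz), ]
    r <- sqrt((tt$z - cell_centroid[i, 1])^2 + (tt$x - cell_centroid[i, 2])^2 +
                (tt$y - cell_centroid[i, 3])^2)
    um <- sqrt(tt$uz^2 + tt$ux^2 + tt$uy^2)
    br <- seq(0, max(r, bin_width) + bin_width, by = bin_width)
    bi <- findInterval(r, br, rightmost.closed = TRUE)
    mu <- tapply(um, factor(bi, levels = seq_len(length(br) - 1)), mean)
    nn <- tapply(um, factor(bi, levels = seq_len(length(br) - 1)), length)
    prof[[i]] <- data.frame(t_index = ts[i],
                            r_mid = br[-length(br)] + bin_width / 2,
                            mean_u = as.vector(mu),
                            n = ifelse(is.na(as.vector(nn)), 0L, as.vector(nn)))
    sel <- r <= near_radius
    near[[i]] <- data.frame(t_index = ts[i], t_minutes = tt$t_minutes[1] %||% NA,
                            mean_u_near = if (any(sel)) mean(um[sel]) else NA_real_,
                            n = sum(sel))
  }
  list(profile = do.call(rbind, prof), near = do.call(rbind, near))
}
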