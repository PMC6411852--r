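# Cell-geometry extraction: speckle reduction across burst repeats,
# K-means segmentation of the speckle-fluctuation volume, and mask cleanup.
# Meshing of the resulting masks lives in mesh.R.

#' Speckle reduction by voxelwise standard deviation across a burst
#'
#' Computes the standard deviation of the magnitude across co-registered
#' repeat volumes, voxel by voxel. Regions of dynamic intracellular speckle
#' are emphasized while static background scattering (beads, gel) is
#' suppressed, which is what makes automated cell segmentation feasible.
#' Cellular structures whose speckle is static over the burst (e.g. quiet
#' fine protrusions) are suppressed too - a known failure mode.
#'
#' @param burst list of >= 2 `tfocm_volume` (or 3D arrays) with identical
#'   dimensions.
#' @return a real 3D array of voxelwise standard deviations.
#' @export
speckle_reduce <- function(burst) {
  if (length(burst) < 2L)
    stop("need at least 2 repeat volumes for a standard-deviation projection")
  mags <- lapply(burst, function(v) {
    if (inherits(v, "tfocm_volume")) abs(v$field) else abs(v)
  })
  d <- dim(mags[[1]])
  for (m in mags) if (!identical(dim(m), d)) stop("burst volume shape mismatch")
  n <- length(mags)
  s1 <- Reduce(`+`, mags)
  s2 <- Reduce(`+`, lapply(mags, function(m) m * m))
  v <- (s2 - s1^2 / n) / (n - 1)
  v[v < 0] <- 0
  sqrt(v)
}

#' Segment the cell body from a speckle-reduced volume by K-means
#'
#' Features are the log of the Gaussian-smoothed standard-deviation volume
#' (log features make the clustering invariant to global intensity
#' scaling). Voxels are clustered with K-means; the cluster with the
#' highest mean is taken as cell, then the largest connected component is
#' kept, holes are filled, and a morphological closing (radius 1) is
#' applied.
#'
#' @param std_vol non-negative 3D array from [speckle_reduce()].
#' @param n_clusters number of K-means clusters (default 2: cell versus
#'   background).
#' @param smooth_sigma Gaussian smoothing of the feature volume (voxels).
#' @param pitch voxel pitch (um, length 3) recorded on the mask.
#' @param offset_um physical position of voxel (1,1,1) (um).
#' @param erode_radius voxels of final erosion compensating the outward
#'   point-spread smear of the speckle region (default 1).
#' @param min_separation minimum separation of the top two cluster centers,
#'   in units of the pooled within-cluster spread, below which the volume
#'   is declared cell-free (warning + empty mask).
#' @param time_index stored on the returned mask.
#' @return a [binary_mask()].
#' @export
segment_cell <- function(std_vol, n_clusters = 2L, smooth_sigma = 1,
                         pitch = c(1, 1, 1), offset_um = c(0, 0, 0),
                         min_separation = 2, erode_radius = 1L,
                         time_index = 0L) {
  if (any(std_vol < 0)) stop("std_vol must be non-negative")
  d <- dim(std_vol)
  eps <- max(std_vol) * 1e-6 + .Machine$double.xmin
  feat <- log(gaussian_smooth3(std_vol, smooth_sigma) + eps)
  set.seed(7L)  # k-means initialization; fixed for reproducibility
  km <- stats::kmeans(as.vector(feat), centers = n_clusters, nstart = 3L,
                      iter.max = 50L)
  ord <- order(km$centers)
  top <- ord[n_clusters]
  # separation check: distance of the top center from the next, relative to
  # the pooled within-cluster standard deviation
  wss <- sqrt(km$tot.withinss / length(feat))
  sep <- (km$centers[top] - km$centers[ord[n_clusters - 1L]]) / max(wss, 1e-12)
  frac <- km$size[top] / length(feat)
  if (sep < min_separation || frac > 0.25) {
    warning("no clear cell cluster (separation ", signif(sep, 3),
            ", top-cluster fraction ", signif(frac, 3),
            "); returning an empty mask")
    return(binary_mask(array(FALSE, d), pitch, offset_um, time_index))
  }
  mask <- array(km$cluster == top, d)
  lab <- label_components3(mask, connectivity = 26L)
  if (length(lab$sizes)) {
    biggest <- which.max(lab$sizes)
    mask <- lab$labels == biggest
  }
  mask <- fill_holes3(mask)
  mask <- morph_close3(mask)
  # the point-spread function smears the speckle region outward by about a
  # voxel; erode to compensate so the mask tracks the true boundary
  for (i in seq_len(erode_radius)) mask <- morph_erode3(mask)
  mask <- fill_holes3(mask)
  # warn if the cell is not isolated within the FOV
  for (ax in 1:3) {
    f1 <- switch(ax, mask[1, , ], mask[, 1, ], mask[, , 1])
    f2 <- switch(ax, mask[d[1], , ], mask[, d[2], ], mask[, , d[3]])
    if (mean(f1) > 0.5 || mean(f2) > 0.5) {
      warning("segmented cell touches more than half of a FOV face; the ",
              "cell may not be isolated in the field of view")
      break
    }
  }
  binary_mask(mask, pitch, offset_um, time_index)
}

# Fill interior holes: background voxels not 6-connected to the border
# become foreground.
fill_holes3 <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- label_components3(bg, connectivity = 6L)
  if (!length(lab$sizes)) return(mask)
  # labels touching any border face are true background
  border_labels <- unique(c(lab$labels[1, , ], lab$labels[d[1], , ],
                            lab$labels[, 1, ], lab$labels[, d[2], ],
                            lab$labels[, , 1], lab$labels[, , d[3]]))
  border_labels <- setdiff(border_labels, 0L)
  hole <- bg & !(lab$labels %in% border_labels)
  mask | hole
}

# Morphological closing with a 6-neighborhood structuring element.
morph_close3 <- function(mask) {
  morph_erode3(morph_dilate3(mask))
}

morph_dilate3 <- function(mask) {
  out <- mask
  d <- dim(mask)
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

morph_erode3 <- function(mask) !morph_dilate3(!mask)

#' Dice coefficient between two binary masks
#'
#' @param a,b logical arrays (or `tfocm_mask`) of identical dimensions.
#' @return numeric in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "tfocm_mask")) a <- a$voxels
  if (inherits(b, "tfocm_mask")) b <- b$voxels
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / max(sum(a) + sum(b), 1L)
}
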