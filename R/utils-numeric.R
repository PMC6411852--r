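# Small numeric helpers shared across modules.

#' Convert a force from Pa.um^2 to nN
#'
#' Internally the solvers work in micrometres and pascals, so integrated
#' surface forces come out in Pa.um^2. One Pa.um^2 equals 1e-3 nN; this
#' conversion is centralized here so the constant exists in exactly one place.
#'
#' @param x numeric, force(s) in Pa.um^2.
#' @return numeric, force(s) in nN.
#' @export
pa_um2_to_nn <- function(x) x * 1e-3

#' @rdname pa_um2_to_nn
#' @export
nn_to_pa_um2 <- function(x) x * 1e3

# Evaluate a 2D polynomial with named coefficients on normalized coordinates.
# `coef` is a named numeric vector; names are of the form "x2y1" meaning
# x^2 * y^1 (powers 0..4). "c" (or "x0y0") is the constant term. x and y are
# expected already normalized to [-1, 1] across the field of view.
poly2d_eval <- function(coef, x, y) {
  if (length(coef) == 0L) return(rep(0, length(x)))
  out <- rep(0, length(x))
  nm <- names(coef)
  if (is.null(nm)) stop("poly2d coefficients must be named, e.g. c(c = 0, x1y0 = 2)")
  for (i in seq_along(coef)) {
    if (nm[i] %in% c("c", "x0y0")) {
      out <- out + coef[i]
    } else {
      m <- regmatches(nm[i], regexec("^x([0-9])y([0-9])$", nm[i]))[[1]]
      if (length(m) != 3L) stop("bad poly2d coefficient name: ", nm[i])
      px <- as.integer(m[2]); py <- as.integer(m[3])
      out <- out + coef[i] * x^px * y^py
    }
  }
  out
}

# Fit a 2D polynomial of total order <= `order` to z(x, y) (normalized coords).
# Returns a named coefficient vector in the poly2d_eval convention.
poly2d_fit <- function(x, y, z, order = 2, w = NULL) {
  stopifnot(order >= 0, order <= 4)
  terms <- list()
  for (px in 0:order) for (py in 0:(order - px)) {
    nm <- if (px == 0 && py == 0) "c" else sprintf("x%dy%d", px, py)
    terms[[nm]] <- x^px * y^py
  }
  X <- do.call(cbind, terms)
  fit <- if (is.null(w)) stats::lm.fit(X, z) else stats::lm.wfit(X, z, w)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  names(cf) <- names(terms)
  cf
}

# Parabolic (three-point) interpolation of a peak location. v is a numeric
# vector, i the integer argmax; returns fractional offset in [-0.5, 0.5].
parabolic_peak_offset <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  a <- v[i - 1L]; b <- v[i]; c <- v[i + 1L]
  den <- a - 2 * b + c
  if (den == 0) return(0)
  off <- 0.5 * (a - c) / den
  max(-0.5, min(0.5, off))
}

# Full width at half maximum of a sampled 1D profile, with linear
# interpolation of the half-maximum crossings. Returns width in samples.
profile_fwhm <- function(v) {
  i <- which.max(v)
  h <- v[i] / 2
  # walk left
  l <- i
  while (l > 1L && v[l - 1L] >= h) l <- l - 1L
  left <- if (l == 1L) 1 else (l - (v[l] - h) / (v[l] - v[l - 1L]))
  r <- i
  n <- length(v)
  while (r < n && v[r + 1L] >= h) r <- r + 1L
  right <- if (r == n) n else (r + (v[r] - h) / (v[r] - v[r + 1L]))
  right - left
}

# Otsu threshold on a numeric vector (maximizes between-class variance).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# 2D FFT of a matrix (unnormalized), and its inverse (normalized).
fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# FFT frequency grid in angular units (rad per unit length), fftshift order.
fft_omega <- function(n, pitch) {
  idx <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  2 * pi * idx / (n * pitch)
}

# Separable Gaussian smoothing of a 3D array (replicate-padded edges).
gaussian_smooth3 <- function(a, sigma = 1) {
  if (all(sigma <= 0)) return(a)
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    a <- .convolve_axis(a, k, ax)
  }
  a
}

# Convolve 3D array along one axis with kernel k (odd length), replicate edges.
.convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(k) - 1L) %/% 2L
  # replicate-pad rows
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(dp[1], r), , drop = FALSE])
  out <- stats::filter(mp, k, method = "convolution", sides = 2)
  out <- out[(r + 1L):(r + dp[1]), , drop = FALSE]
  res <- array(out, dp)
  aperm(res, order(perm))
}

# Connected components of TRUE voxels in a logical 3D array.
# Returns a list with `labels` (integer array, 0 = background) and `sizes`.
# connectivity: 26 (default) or 6.
label_components3 <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(list(labels = labels, sizes = integer(0)))
  pos <- arrayInd(idx, d)
  # map from linear voxel index to 1..n foreground id
  id_of <- integer(prod(d))
  id_of[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dz = -1:1, dx = -1:1, dy = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  # only need half the offsets (undirected edges)
  keep <- offs[, 1] * 100 + offs[, 2] * 10 + offs[, 3] > 0
  offs <- offs[keep, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    np <- pos + matrix(offs[i, ], nrow(pos), 3, byrow = TRUE)
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    lin <- (np[ok, 3] - 1L) * d[1] * d[2] + (np[ok, 2] - 1L) * d[1] + np[ok, 1]
    nb <- id_of[lin]
    src <- which(ok)[nb > 0L]
    if (length(src)) edges[[i]] <- cbind(src, nb[nb > 0L])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
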