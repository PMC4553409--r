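#' Voxelwise features: ALFF, fALFF and ReHo
#'
#' Univariate maps of local resting-state activity. ALFF sums spectral
#' amplitude in the low-frequency band (0.01-0.08 Hz), fALFF is the fraction
#' of total spectral amplitude falling in that band, and ReHo is Kendall's
#' coefficient of concordance between a voxel's time course and its 26
#' neighbours. The processing order is: linear detrend; ALFF/fALFF on
#' smoothed, unfiltered data; ReHo on unsmoothed, bandpassed data, with the
#' resulting map smoothed afterwards. Each map is standardized by its
#' subject-specific in-mask global mean.
#'
#' @name voxel_features
NULL

as_ts_matrix <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L)

#' Remove the ordinary-least-squares linear trend
#'
#' @param x numeric vector, or matrix with one time series per column.
#' @return Residuals of the regression on `[1, t]`, same shape as `x`;
#'   orthogonal to both the intercept and the time index. A constant series
#'   becomes all zeros.
#' @export
linear_detrend <- function(x) {
  m <- as_ts_matrix(x)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 timepoints to detrend")
  tt <- seq_len(n) - (n + 1) / 2          # centered time, orthogonal to intercept
  slope <- crossprod(tt, m) / sum(tt^2)   # 1 x V
  out <- m - matrix(colMeans(m), n, ncol(m), byrow = TRUE) - outer(tt, drop(slope))
  if (is.matrix(x)) out else drop(out)
}

#' Ideal frequency-domain bandpass filter
#'
#' Zeroes every Fourier coefficient whose bin frequency lies outside
#' `[low, high]` and returns the inverse transform. Bin k of a length-T
#' series sampled every `tr` seconds has frequency `min(k, T-k) / (T tr)`.
#'
#' @param x numeric vector or matrix (series in columns).
#' @param tr sampling interval, seconds.
#' @param low,high band edges in Hz; requires `0 <= low < high < 1/(2 tr)`.
#' @return Filtered series, same shape as `x`.
#' @export
bandpass_filter <- function(x, tr, low = 0.01, high = 0.08) {
  nyq <- 1 / (2 * tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq)
    stop(sprintf("high (%g Hz) must be below the Nyquist frequency %g Hz", high, nyq))
  m <- as_ts_matrix(x)
  n <- nrow(m)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)
  keep <- f >= low & f <= high
  co <- stats::mvfft(m)
  co[!keep, ] <- 0
  out <- Re(stats::mvfft(co, inverse = TRUE)) / n
  if (is.matrix(x)) out else drop(out)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g / sum(g)
}

# Banded smoothing matrix for one axis: row i holds the truncated kernel
# renormalized over the voxels actually inside the volume.
smoothing_band_matrix <- function(n, sigma) {
  g <- gaussian_kernel_1d(sigma)
  r <- (length(g) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- g[j - i + r + 1L]
    B[i, j] <- w / sum(w)
  }
  B
}

apply_along_axis1 <- function(arr, B) {
  d <- dim(arr)
  array(B %*% matrix(arr, nrow = d[1]), d)
}

#' Separable Gaussian smoothing of a 3D or 4D image
#'
#' Kernel sigma per axis is `fwhm / (2 sqrt(2 log 2))` converted to voxel
#' units; the kernel is truncated at 3 sigma and renormalized at volume (and,
#' when a mask is given, mask) boundaries, so a constant image is returned
#' unchanged. `fwhm = 0` is the identity.
#'
#' @param x 3D array, or 4D array smoothed volume-by-volume.
#' @param fwhm full-width at half-maximum, mm.
#' @param voxel_size voxel edge length(s) in mm (scalar or length 3).
#' @param mask optional 3D logical mask; smoothing is then confined to the
#'   mask (out-of-mask voxels neither contribute nor receive signal).
#' @return Smoothed array, same shape as `x`.
#' @export
gaussian_smooth <- function(x, fwhm = 4, voxel_size = 1, mask = NULL) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(x)
  nd <- length(dim(x))
  stopifnot(nd %in% c(3L, 4L))
  vs <- rep_len(voxel_size, 3L)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vs
  d <- dim(x)
  d3 <- d[1:3]
  Bs <- lapply(1:3, function(a) smoothing_band_matrix(d3[a], sigma[a]))

  # smooth the whole (possibly 4D) array along each spatial axis at once
  smooth_spatial <- function(v) {
    nda <- length(dim(v))
    for (a in 1:3) {
      perm <- c(a, setdiff(seq_len(nda), a))
      v <- aperm(v, perm)
      v <- apply_along_axis1(v, Bs[[a]])
      v <- aperm(v, order(perm))
    }
    v
  }
  if (is.null(mask)) return(smooth_spatial(x))
  mm <- smooth_spatial(array(as.numeric(mask), d3))
  mvec <- as.vector(mask)
  scale_vec <- ifelse(mvec, 1 / as.vector(mm), 0)
  masked <- x * as.vector(mask)   # mask recycles over the 4th dimension
  out <- smooth_spatial(masked) * scale_vec
  array(out, d)
}

# Per-voxel spectral amplitudes: Mod of the DFT at positive-frequency bins
# k = 1..floor(T/2) (DC excluded), for in-mask voxel time courses.
spectral_amplitudes <- function(bold) {
  tp <- dim(bold$data)[4]
  vox <- which(as.vector(bold$mask))
  m <- t(matrix(bold$data, ncol = tp)[vox, , drop = FALSE])  # T x V
  amp <- Mod(stats::mvfft(m))
  k <- seq_len(tp %/% 2)
  list(amp = amp[k + 1L, , drop = FALSE], freq = k / (tp * bold$tr), vox = vox)
}

map_from_voxels <- function(values, vox, dims) {
  out <- array(0, dims)
  out[vox] <- values
  out
}

#' Amplitude of low-frequency fluctuation
#'
#' Per voxel, the sum of DFT amplitudes (square root of per-bin periodogram
#' power) over bins whose frequency falls in `band`, DC excluded. Input
#' should be detrended and smoothed but not bandpass filtered.
#'
#' @param bold a [bold_image].
#' @param band low/high frequency bounds, Hz.
#' @return 3D map, zero outside the mask (unstandardized).
#' @export
compute_alff <- function(bold, band = c(0.01, 0.08)) {
  stopifnot(inherits(bold, "bold_image"))
  if (dim(bold$data)[4] < 16) stop("need at least 16 timepoints for spectral features")
  sp <- spectral_amplitudes(bold)
  in_band <- sp$freq >= band[1] & sp$freq <= band[2]
  map_from_voxels(colSums(sp$amp[in_band, , drop = FALSE]), sp$vox, dim(bold$mask))
}

#' Fractional ALFF
#'
#' Ratio of the in-band amplitude sum to the amplitude sum over the entire
#' detectable frequency range (DC excluded); lies in \[0, 1\], with 0/0
#' defined as 0.
#'
#' @inheritParams compute_alff
#' @return 3D map in \[0, 1\], zero outside the mask.
#' @export
compute_falff <- function(bold, band = c(0.01, 0.08)) {
  stopifnot(inherits(bold, "bold_image"))
  if (dim(bold$data)[4] < 16) stop("need at least 16 timepoints for spectral features")
  sp <- spectral_amplitudes(bold)
  in_band <- sp$freq >= band[1] & sp$freq <= band[2]
  num <- colSums(sp$amp[in_band, , drop = FALSE])
  den <- colSums(sp$amp)
  v <- ifelse(den > 0, num / den, 0)
  map_from_voxels(v, sp$vox, dim(bold$mask))
}

neighbourhood_offsets <- function(n) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  switch(as.character(n),
         "27" = g,
         "19" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "7"  = g[rowSums(abs(g)) <= 1, , drop = FALSE],
         stop("neighbourhood must be 7, 19 or 27"))
}

#' Regional homogeneity (Kendall's W over a voxel neighbourhood)
#'
#' For each in-mask voxel, ranks the time courses of the K <= 27 in-mask
#' voxels of its 3x3x3 neighbourhood and computes Kendall's coefficient of
#' concordance
#' `W = 12 * sum_t (R_t - K(T+1)/2)^2 / (K^2 (T^3 - T))`,
#' where `R_t` is the across-voxel rank sum at timepoint t. Ties get average
#' ranks; no tie-correction term is applied. Neighbourhoods are truncated at
#' mask and volume edges (K adapts); voxels with fewer than 2 usable
#' neighbours get 0. Input should be detrended and bandpassed but unsmoothed;
#' the map itself may be smoothed afterwards via `smooth_fwhm`.
#'
#' @param bold a [bold_image].
#' @param neighbourhood 27 (faces+edges+corners), 19 or 7.
#' @param smooth_fwhm if positive, Gaussian-smooth the W map within the mask.
#' @param voxel_size voxel size in mm, for `smooth_fwhm`.
#' @return 3D map in (0, 1\] inside the mask (unstandardized).
#' @export
compute_reho <- function(bold, neighbourhood = 27, smooth_fwhm = 0, voxel_size = 1) {
  stopifnot(inherits(bold, "bold_image"))
  d <- dim(bold$data)
  tp <- d[4]
  mask <- bold$mask
  flat <- matrix(bold$data, ncol = tp)
  vox <- which(as.vector(mask))
  ranks <- matrix(0, nrow(flat), tp)
  ranks[vox, ] <- t(apply(flat[vox, , drop = FALSE], 1, rank))

  # accumulate rank sums and neighbour counts with precomputed linear-index
  # shifts (ranks are zero outside the mask, so out-of-mask neighbours add
  # nothing)
  offs <- neighbourhood_offsets(neighbourhood)
  ranks <- ranks * as.numeric(as.vector(mask))
  mask_num <- as.numeric(as.vector(mask))
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  rsum <- matrix(0, nrow(ranks), tp)
  kcount <- numeric(nrow(ranks))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    sx <- ix + o[1]; sy <- iy + o[2]; sz <- iz + o[3]
    valid <- which(sx >= 1 & sx <= nx & sy >= 1 & sy <= ny & sz >= 1 & sz <= nz)
    src <- (sz[valid] - 1L) * nx * ny + (sy[valid] - 1L) * nx + sx[valid]
    rsum[valid, ] <- rsum[valid, ] + ranks[src, ]
    kcount[valid] <- kcount[valid] + mask_num[src]
  }

  rbar <- kcount * (tp + 1) / 2
  ss <- rowSums((rsum - rbar)^2)
  denom <- kcount^2 * (tp^3 - tp)
  w_flat <- numeric(nrow(ranks))
  usable <- as.vector(mask) & kcount >= 2
  w_flat[usable] <- 12 * ss[usable] / denom[usable]
  w <- array(w_flat, d[1:3])
  if (smooth_fwhm > 0)
    w <- gaussian_smooth(w, fwhm = smooth_fwhm, voxel_size = voxel_size, mask = mask)
  w
}

#' Standardize a map by its in-mask global mean
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array.
#' @return `map / mean(map[mask])`, zero outside the mask; the in-mask mean of
#'   the result is 1.
#' @export
standardize_global_mean <- function(map, mask) {
  m <- mean(map[mask])
  if (!is.finite(m) || abs(m) < .Machine$double.eps)
    stop("global mean is zero (or not finite); cannot standardize")
  out <- array(0, dim(map))
  out[mask] <- map[mask] / m
  out
}

#' Compute all three standardized voxelwise feature maps for one subject
#'
#' Runs the fixed processing order: linear detrend; Gaussian smoothing then
#' ALFF/fALFF on unfiltered data; bandpass then ReHo on unsmoothed data with
#' the W map smoothed afterwards; global-mean standardization of each map.
#'
#' @param bold a [bold_image] (raw simulated or preprocessed data).
#' @param band analysis band, Hz.
#' @param fwhm smoothing FWHM, mm.
#' @param voxel_size voxel size, mm.
#' @param smooth_before_spectral smooth the detrended data before ALFF/fALFF
#'   (the default); set FALSE to run the spectral features on unsmoothed data.
#' @return list of class `voxel_feature_maps`: standardized `alff`, `falff`,
#'   `reho` 3D maps plus the `mask`.
#' @export
voxel_feature_maps <- function(bold, band = c(0.01, 0.08), fwhm = 4,
                               voxel_size = 1, smooth_before_spectral = TRUE) {
  stopifnot(inherits(bold, "bold_image"))
  d <- dim(bold$data)
  tp <- d[4]
  flat <- matrix(bold$data, ncol = tp)
  vox <- which(as.vector(bold$mask))
  flat[vox, ] <- t(linear_detrend(t(flat[vox, , drop = FALSE])))
  detrended <- array(flat, d)

  spec_input <- if (smooth_before_spectral)
    gaussian_smooth(detrended, fwhm = fwhm, voxel_size = voxel_size, mask = bold$mask)
  else detrended
  spec_bold <- bold_image(spec_input, bold$mask, bold$tr)
  alff <- compute_alff(spec_bold, band)
  falff <- compute_falff(spec_bold, band)

  bp <- flat
  bp[vox, ] <- t(bandpass_filter(t(flat[vox, , drop = FALSE]), tr = bold$tr,
                                 low = band[1], high = band[2]))
  reho <- compute_reho(bold_image(array(bp, d), bold$mask, bold$tr),
                       smooth_fwhm = fwhm, voxel_size = voxel_size)

  structure(list(
    alff = standardize_global_mean(alff, bold$mask),
    falff = standardize_global_mean(falff, bold$mask),
    reho = standardize_global_mean(reho, bold$mask),
    mask = bold$mask
  ), class = "voxel_feature_maps")
}
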