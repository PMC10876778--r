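#' Kendall's coefficient of concordance (W)
#'
#' Agreement between K time series regarded as K judges ranking the n time
#' points. With within-series ranks (average ranks on ties) and rank sums
#' `R_i` over the K series at time point i,
#' `W = 12 * S / (K^2 * (n^3 - n))` where `S = sum_i (R_i - mean(R))^2`.
#' No tie-correction term is applied to the denominator (ties have measure
#' zero in floating-point data). A constant series makes W undefined; the
#' function then returns 0 with attribute `"degenerate" = TRUE`.
#'
#' @param x numeric matrix with K rows (series) and n columns (time points),
#'   K >= 2, n >= 2.
#' @return W in `[0, 1]`.
#' @export
kendalls_w <- function(x) {
  x <- as.matrix(x)
  k <- nrow(x)
  n <- ncol(x)
  if (k < 2L || n < 2L) stop("need at least 2 series and 2 time points")
  rng <- apply(x, 1, function(s) max(s) - min(s))
  if (any(rng == 0))
    return(structure(0, degenerate = TRUE))
  ranks <- t(apply(x, 1, rank))
  ri <- colSums(ranks)
  s <- sum((ri - k * (n + 1) / 2)^2)
  w <- 12 * s / (k^2 * (n^3 - n))
  unname(w)
}

# add `src` shifted by (dx, dy, dz) into `acc`, zero beyond the boundary;
# works for 3D arrays and 4D arrays (shift applies to the first three dims)
shift_add <- function(acc, src, dx, dy, dz) {
  d <- dim(acc)
  xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
  ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
  zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
  if (length(d) == 3L) {
    acc[xs, ys, zs] <- acc[xs, ys, zs] +
      src[xs + dx, ys + dy, zs + dz]
  } else {
    acc[xs, ys, zs, ] <- acc[xs, ys, zs, , drop = FALSE] +
      src[xs + dx, ys + dy, zs + dz, , drop = FALSE]
  }
  acc
}

#' Regional homogeneity map (voxel-wise Kendall's W over a 27-voxel cube)
#'
#' Each in-mask voxel gets the concordance of its own time series with those
#' of its in-mask neighbours in the surrounding 3x3x3 cube (up to 26
#' neighbours). Voxels whose cube is clipped by the mask or the volume edge
#' use only the available neighbours (K < 27), so the map's support equals
#' the mask. Input should be nuisance-regressed, bandpass-filtered data.
#'
#' @param vol a preprocessed [ts_volume()].
#' @param mask logical/0-1 3D array; must contain at least one voxel.
#' @return an `activity_map` (metric `"reho"`) with values in `[0, 1]`;
#'   attribute `"n_degenerate"` counts voxels whose neighbourhood contained a
#'   constant series (assigned W = 0).
#' @export
reho_map <- function(vol, mask) {
  stopifnot(inherits(vol, "ts_volume"))
  d <- dim(vol$data)
  mask <- array(as.logical(mask), dim = d[1:3])
  if (!any(mask)) stop("empty mask")
  nt <- d[4]
  nvox <- prod(d[1:3])
  y <- matrix(vol$data, nrow = nvox, ncol = nt)
  idx <- which(mask)
  ranks <- matrix(0, nrow = nvox, ncol = nt)
  sub <- y[idx, , drop = FALSE]
  const <- (apply(sub, 1, max) - apply(sub, 1, min)) == 0
  ranks[idx, ] <- t(apply(sub, 1, rank))
  rk <- array(ranks, dim = d)
  m <- array(0, dim = d[1:3]); m[mask] <- 1
  cflag <- array(0, dim = d[1:3]); cflag[idx[const]] <- 1

  rsum <- array(0, dim = d)
  kcnt <- array(0, dim = d[1:3])
  ccnt <- array(0, dim = d[1:3])
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    rsum <- shift_add(rsum, rk, dx, dy, dz)
    kcnt <- shift_add(kcnt, m, dx, dy, dz)
    ccnt <- shift_add(ccnt, cflag, dx, dy, dz)
  }
  rs <- matrix(rsum, nrow = nvox, ncol = nt)[idx, , drop = FALSE]
  kk <- kcnt[idx]
  s <- rowSums((rs - kk * (nt + 1) / 2)^2)
  w <- 12 * s / (kk^2 * (nt^3 - nt))
  degen <- ccnt[idx] > 0
  w[degen] <- 0
  out <- array(0, dim = d[1:3])
  out[idx] <- w
  res <- activity_map(out, vol$affine, metric = "reho", mask = mask)
  attr(res, "n_degenerate") <- sum(degen)
  res
}

# single-sided DFT amplitudes per voxel row: a_k = 2 |X_k| / n for
# k = 1 .. floor(n/2) (DC excluded); a pure unit-amplitude tone at an exact
# bin centre then has amplitude 1 in its bin
one_sided_amplitudes <- function(y) {
  n <- ncol(y)
  half <- floor(n / 2)
  yf <- stats::mvfft(t(y))
  2 * Mod(t(yf[2:(half + 1), , drop = FALSE])) / n
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel: the mean single-sided spectral amplitude (the square root of
#' the periodogram ordinate, normalized as `2 |X_k| / n` so a unit tone at a
#' bin centre has amplitude 1) over DFT bins whose frequency lies inside the
#' band, DC excluded. Input should be nuisance-regressed but NOT
#' bandpass-filtered data, otherwise the band ratio in fALFF degenerates.
#'
#' @param vol a [ts_volume()] (detrended, not bandpassed).
#' @param mask logical/0-1 3D array.
#' @param low_hz,high_hz band edges in Hz (defaults 0.01 and 0.1, inclusive).
#' @return an `activity_map` (metric `"alff"`), nonnegative in-mask.
#' @export
alff_map <- function(vol, mask, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(vol, "ts_volume"))
  d <- dim(vol$data)
  mask <- array(as.logical(mask), dim = d[1:3])
  if (!any(mask)) stop("empty mask")
  nt <- d[4]
  if (high_hz > 1 / (2 * vol$tr_seconds))
    stop("band exceeds the Nyquist frequency")
  band <- in_band_bins(nt, vol$tr_seconds, low_hz, high_hz)
  if (length(band) < 2L)
    stop("fewer than 2 DFT bins fall in the band; use a longer time series")
  idx <- which(mask)
  y <- matrix(vol$data, nrow = prod(d[1:3]), ncol = nt)[idx, , drop = FALSE]
  amp <- one_sided_amplitudes(y)
  vals <- rowMeans(amp[, band - 1, drop = FALSE])  # bin 2 is column 1
  out <- array(0, dim = d[1:3])
  out[idx] <- vals
  activity_map(out, vol$affine, metric = "alff", mask = mask)
}

#' Fractional ALFF (fALFF)
#'
#' Per voxel: the sum of single-sided spectral amplitudes inside the band
#' divided by the sum over the entire non-DC spectrum up to Nyquist; lies in
#' `[0, 1]`. Constant voxels (zero total amplitude) get 0 and are counted in
#' attribute `"n_degenerate"`.
#'
#' @inheritParams alff_map
#' @return an `activity_map` (metric `"falff"`).
#' @export
falff_map <- function(vol, mask, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(vol, "ts_volume"))
  d <- dim(vol$data)
  mask <- array(as.logical(mask), dim = d[1:3])
  if (!any(mask)) stop("empty mask")
  nt <- d[4]
  if (high_hz > 1 / (2 * vol$tr_seconds))
    stop("band exceeds the Nyquist frequency")
  band <- in_band_bins(nt, vol$tr_seconds, low_hz, high_hz)
  if (length(band) < 2L)
    stop("fewer than 2 DFT bins fall in the band; use a longer time series")
  idx <- which(mask)
  y <- matrix(vol$data, nrow = prod(d[1:3]), ncol = nt)[idx, , drop = FALSE]
  const <- (apply(y, 1, max) - apply(y, 1, min)) == 0
  amp <- one_sided_amplitudes(y)
  total <- rowSums(amp)
  inband <- rowSums(amp[, band - 1, drop = FALSE])
  vals <- ifelse(!const & total > 0, inband / total, 0)
  out <- array(0, dim = d[1:3])
  out[idx] <- vals
  res <- activity_map(out, vol$affine, metric = "falff", mask = mask)
  attr(res, "n_degenerate") <- sum(const | total == 0)
  res
}

#' Standardize a map by its global (in-mask) mean
#'
#' Divides every voxel by the mean over in-mask voxels, so the standardized
#' map has in-mask mean exactly 1 (the "m" variants: mReHo, mALFF, mfALFF).
#'
#' @param map an [activity_map()].
#' @param mask logical/0-1 3D array (defaults to the map's own mask).
#' @return an `activity_map` with metric prefixed by `"m"`.
#' @export
normalize_by_global_mean <- function(map, mask = NULL) {
  stopifnot(inherits(map, "activity_map"))
  if (is.null(mask)) mask <- map$mask
  if (is.null(mask)) stop("no mask available")
  mask <- array(as.logical(mask), dim = dim(map$data))
  gm <- mean(map$data[mask])
  if (!is.finite(gm) || gm <= 0)
    stop("in-mask global mean must be positive")
  out <- map$data / gm
  out[!mask] <- 0
  activity_map(out, map$affine, metric = paste0("m", map$metric), mask = mask)
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w / sum(w)
}

#' Spatial Gaussian smoothing of a 3D map
#'
#' Separable convolution with a Gaussian of the given full width at half
#' maximum; `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis in mm, converted
#' to voxels using the voxel sizes read from the affine. Zero padding at the
#' volume edge; the kernel is normalized so interior signal mass is conserved.
#'
#' @param map an [activity_map()].
#' @param fwhm_mm kernel FWHM in mm (default 6; 0 returns the map unchanged).
#' @return a smoothed `activity_map`.
#' @export
gaussian_smooth <- function(map, fwhm_mm = 6) {
  stopifnot(inherits(map, "activity_map"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be nonnegative")
  if (fwhm_mm == 0) return(map)
  voxmm <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  x <- map$data
  d <- dim(x)
  for (axis in 1:3) {
    w <- gaussian_kernel_1d(sigma_mm / voxmm[axis])
    r <- (length(w) - 1L) / 2L
    acc <- array(0, dim = d)
    for (j in -r:r) {
      shift <- c(0L, 0L, 0L)
      shift[axis] <- j
      wj <- w[j + r + 1L]
      xs <- max(1, 1 - shift[1]):min(d[1], d[1] - shift[1])
      ys <- max(1, 1 - shift[2]):min(d[2], d[2] - shift[2])
      zs <- max(1, 1 - shift[3]):min(d[3], d[3] - shift[3])
      acc[xs, ys, zs] <- acc[xs, ys, zs] +
        wj * x[xs + shift[1], ys + shift[2], zs + shift[3]]
    }
    x <- acc
  }
  activity_map(x, map$affine, metric = map$metric, mask = map$mask)
}

#' Standardized, smoothed local-activity map for one preprocessed subject
#'
#' Convenience wrapper: metric map -> global-mean standardization -> Gaussian
#' smoothing, the order used for group comparison. ReHo is computed on
#' bandpassed data; ALFF/fALFF must be given non-bandpassed data.
#'
#' @param vol preprocessed [ts_volume()] (see [preprocess_bold()]).
#' @param mask gray-matter mask.
#' @param metric one of `"reho"`, `"alff"`, `"falff"`.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param low_hz,high_hz spectral band for ALFF/fALFF.
#' @return a smoothed, standardized `activity_map`.
#' @export
local_activity_map <- function(vol, mask, metric = c("reho", "alff", "falff"),
                               fwhm_mm = 6, low_hz = 0.01, high_hz = 0.1) {
  metric <- match.arg(metric)
  m <- switch(metric,
              reho = reho_map(vol, mask),
              alff = alff_map(vol, mask, low_hz, high_hz),
              falff = falff_map(vol, mask, low_hz, high_hz))
  gaussian_smooth(normalize_by_global_mean(m, mask), fwhm_mm)
}
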