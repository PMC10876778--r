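#' Discard initial volumes of a 4D acquisition
#'
#' Scanner equilibration volumes at the start of a resting-state run are
#' conventionally dropped before any further processing.
#'
#' @param vol a [ts_volume()].
#' @param n number of leading volumes to remove (default 10).
#' @return a `ts_volume` with `t - n` volumes and unchanged geometry.
#' @export
discard_initial_volumes <- function(vol, n = 10) {
  stopifnot(inherits(vol, "ts_volume"))
  nt <- dim(vol$data)[4]
  if (n < 0) stop("`n` must be nonnegative")
  if (n >= nt)
    stop(sprintf("cannot discard %d volumes from a %d-volume series", n, nt))
  if (n == 0) return(vol)
  ts_volume(vol$data[, , , (n + 1):nt, drop = FALSE], vol$affine,
            vol$tr_seconds)
}

#' Frame-wise displacement (Power's definition)
#'
#' FD(i) = sum of absolute volume-to-volume changes of the three translations
#' (mm) plus `rotation_radius_mm` times the absolute changes of the three
#' rotations (rad), i.e. rotations are converted to arc length on a sphere of
#' the given radius. FD of the first volume is 0.
#'
#' @param motion numeric matrix with one row per volume and 6 columns:
#'   3 translations (mm) then 3 rotations (rad).
#' @param rotation_radius_mm sphere radius for the rotation term (default 50).
#' @return numeric vector of FD values (mm), one per volume.
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 volumes")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Friston 24-parameter motion design
#'
#' The 6 rigid-body parameters, their one-volume-lagged copies (first row
#' zero-padded), and the squares of both sets: 24 columns in total.
#'
#' @inheritParams compute_fd
#' @return numeric matrix (volumes x 24) with descriptive column names.
#' @export
build_friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 volumes")
  lagged <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lagged, motion^2, lagged^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lag_sq"))
  out
}

#' Spike indicator regressors from an FD series
#'
#' One indicator column per volume whose FD strictly exceeds the threshold;
#' spike volumes are absorbed by regression rather than deleted, so the
#' temporal structure of the series is preserved.
#'
#' @param fd numeric FD series (mm).
#' @param threshold spike threshold in mm (default 0.5, strict `>`).
#' @return numeric matrix (volumes x n_spikes); 0 columns when no spikes.
#' @export
build_spike_regressors <- function(fd, threshold = 0.5) {
  spikes <- which(fd > threshold)
  out <- matrix(0, nrow = length(fd), ncol = length(spikes))
  if (length(spikes))
    out[cbind(spikes, seq_along(spikes))] <- 1
  colnames(out) <- if (length(spikes)) paste0("spike_", spikes) else character()
  out
}

#' Assemble a nuisance design matrix
#'
#' Combines intercept, linear drift, Friston-24 motion block, FD spike
#' indicators and mean white-matter / CSF signals into one labelled design.
#' The linear drift column doubles as the detrending step, so nuisance removal
#' and detrending happen in a single regression pass.
#'
#' @param n_volumes number of rows.
#' @param motion optional motion matrix (volumes x 6).
#' @param fd optional FD series for spike indicators.
#' @param wm optional mean white-matter signal (length `n_volumes`).
#' @param csf optional mean CSF signal.
#' @param spike_threshold FD spike threshold in mm.
#' @return numeric design matrix with intercept, drift and requested blocks.
#' @export
build_nuisance_design <- function(n_volumes, motion = NULL, fd = NULL,
                                  wm = NULL, csf = NULL,
                                  spike_threshold = 0.5) {
  design <- cbind(intercept = rep(1, n_volumes),
                  drift = seq_len(n_volumes) - (n_volumes + 1) / 2)
  if (!is.null(motion)) design <- cbind(design, build_friston24(motion))
  if (!is.null(fd)) design <- cbind(design,
                                    build_spike_regressors(fd, spike_threshold))
  if (!is.null(wm)) design <- cbind(design, wm = as.numeric(wm))
  if (!is.null(csf)) design <- cbind(design, csf = as.numeric(csf))
  design
}

#' Regress a nuisance design out of every voxel time series
#'
#' Ordinary least squares per voxel; the returned volume holds the residuals,
#' which are orthogonal to the design columns. Linearly dependent design
#' columns are dropped with a warning.
#'
#' @param vol a [ts_volume()].
#' @param design numeric matrix (volumes x regressors) including an intercept.
#' @return a `ts_volume` of residuals.
#' @export
regress_nuisance <- function(vol, design) {
  stopifnot(inherits(vol, "ts_volume"))
  design <- as.matrix(design)
  nt <- dim(vol$data)[4]
  if (nrow(design) != nt)
    stop("design rows must equal the number of volumes")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- qrd$pivot[(qrd$rank + 1):ncol(design)]
    lab <- colnames(design)[drop]
    warning(sprintf("dropping %d linearly dependent design column(s): %s",
                    length(drop),
                    paste(if (is.null(lab)) drop else lab, collapse = ", ")))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  y <- matrix(vol$data, nrow = prod(dim(vol$data)[1:3]), ncol = nt)
  resid <- t(qr.resid(qrd, t(y)))
  ts_volume(array(resid, dim = dim(vol$data)), vol$affine, vol$tr_seconds)
}

in_band_bins <- function(n, tr, low_hz, high_hz) {
  # indices (1-based, DC = 1) of one-sided DFT bins with low <= f <= high
  freqs <- (seq_len(n) - 1) / (n * tr)
  half <- floor(n / 2)
  which(freqs >= low_hz & freqs <= high_hz & seq_len(n) - 1 <= half &
          seq_len(n) - 1 >= 1)
}

#' Temporal bandpass filter (Fourier-domain masking)
#'
#' Keeps DFT bins whose frequency lies in `[low_hz, high_hz]` (inclusive) and
#' zeroes all others including DC, applied identically to every voxel.
#' Hard-masked filtering is idempotent and exactly characterizable: tones at
#' retained bin centres pass unchanged, tones outside are removed.
#'
#' @param vol a [ts_volume()].
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.1).
#' @return a filtered `ts_volume`.
#' @export
bandpass <- function(vol, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(vol, "ts_volume"))
  nt <- dim(vol$data)[4]
  nyquist <- 1 / (2 * vol$tr_seconds)
  if (low_hz < 0 || high_hz <= low_hz)
    stop("need 0 <= low_hz < high_hz")
  if (high_hz > nyquist)
    stop(sprintf("high_hz = %g exceeds the Nyquist frequency %g Hz",
                 high_hz, nyquist))
  freqs <- (seq_len(nt) - 1) / (nt * vol$tr_seconds)
  # symmetric mask: a bin at f and its alias at 1/tr - f are kept together
  fold <- pmin(freqs, 1 / vol$tr_seconds - freqs)
  keep <- fold >= low_hz & fold <= high_hz
  y <- matrix(vol$data, nrow = prod(dim(vol$data)[1:3]), ncol = nt)
  yf <- t(stats::mvfft(t(y)))
  yf[, !keep] <- 0
  out <- Re(t(stats::mvfft(t(yf), inverse = TRUE))) / nt
  ts_volume(array(out, dim = dim(vol$data)), vol$affine, vol$tr_seconds)
}

#' Standard preprocessing chain for one subject
#'
#' Discard initial volumes, regress nuisance covariates (intercept, linear
#' drift, Friston-24, FD spikes, mean WM and CSF signals), then bandpass.
#'
#' @param vol raw [ts_volume()].
#' @param motion motion matrix (volumes x 6) matching the raw volume.
#' @param wm_mask,csf_mask optional 3D masks used to extract mean tissue
#'   signals after volume discard.
#' @param n_discard leading volumes to drop.
#' @param low_hz,high_hz passband (set `bandpass_filter = FALSE` to skip, as
#'   required before fALFF/ALFF spectral estimation).
#' @param bandpass_filter apply the bandpass step (default `TRUE`).
#' @param spike_threshold FD threshold in mm for spike regressors.
#' @return a preprocessed `ts_volume` with the FD series (post-discard) in
#'   attribute `"fd"`.
#' @export
preprocess_bold <- function(vol, motion, wm_mask = NULL, csf_mask = NULL,
                            n_discard = 10, low_hz = 0.01, high_hz = 0.1,
                            bandpass_filter = TRUE, spike_threshold = 0.5) {
  stopifnot(inherits(vol, "ts_volume"))
  motion <- as.matrix(motion)
  if (nrow(motion) != dim(vol$data)[4])
    stop("motion rows must equal the number of volumes")
  vol <- discard_initial_volumes(vol, n_discard)
  motion <- motion[(n_discard + 1):nrow(motion), , drop = FALSE]
  fd <- compute_fd(motion)
  mean_in_mask <- function(v, mask) {
    idx <- which(as.logical(mask))
    y <- matrix(v$data, nrow = prod(dim(v$data)[1:3]))
    colMeans(y[idx, , drop = FALSE])
  }
  wm <- if (!is.null(wm_mask)) mean_in_mask(vol, wm_mask)
  csf <- if (!is.null(csf_mask)) mean_in_mask(vol, csf_mask)
  design <- build_nuisance_design(dim(vol$data)[4], motion = motion, fd = fd,
                                  wm = wm, csf = csf,
                                  spike_threshold = spike_threshold)
  vol <- regress_nuisance(vol, design)
  if (bandpass_filter) vol <- bandpass(vol, low_hz, high_hz)
  attr(vol, "fd") <- fd
  vol
}
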