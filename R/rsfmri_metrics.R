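# Voxel-level rsfMRI metrics: fALFF, LCOR, GCOR, with the nuisance
# regression / detrending / bandpass steps that precede them, and parcel
# averaging. fALFF is computed from nuisance-regressed, detrended but NOT
# bandpassed data (its denominator is the full spectrum); the correlation
# metrics are computed from fully bandpassed data.

#' Construct a voxel time-series object
#'
#' @param bold a 4D array (x, y, z, time) or a voxels x timepoints matrix.
#' @param tr repetition time in seconds.
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @param mask optional logical vector (one per voxel); default all in-mask.
#' @param coords optional voxels x 3 matrix of mm coordinates; derived from
#'   the grid when `bold` is 4D.
#' @return A `voxel_ts` object with fields `values` (voxels x timepoints),
#'   `mask`, `tr`, `dims`, `voxel_size`, `coords`.
#' @export
voxel_timeseries <- function(bold, tr, voxel_size = c(3, 3, 3), mask = NULL,
                             coords = NULL) {
  if (tr <= 0) stop_input("tr must be > 0")
  if (is.array(bold) && length(dim(bold)) == 4L) {
    dims <- dim(bold)[1:3]
    values <- matrix(bold, nrow = prod(dims), ncol = dim(bold)[4])
    coords <- (arrayInd(seq_len(prod(dims)), dims) - 1) *
      matrix(voxel_size, prod(dims), 3, byrow = TRUE)
  } else if (is.matrix(bold)) {
    dims <- c(nrow(bold), 1L, 1L)
    values <- bold
    if (is.null(coords)) {
      coords <- cbind((seq_len(nrow(bold)) - 1) * voxel_size[1], 0, 0)
    }
  } else {
    stop_input("bold must be a 4D array or a voxels x timepoints matrix")
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(values))
  if (!any(mask)) stop_input("mask is empty")
  structure(list(values = values, mask = mask, tr = tr, dims = dims,
                 voxel_size = voxel_size, coords = coords),
            class = "voxel_ts")
}

new_voxel_map <- function(values, metric, ts) {
  structure(list(values = values, metric = metric, dims = ts$dims,
                 voxel_size = ts$voxel_size, mask = ts$mask),
            class = "voxel_map")
}

#' Regress confounds out of every voxel time series
#'
#' Replaces each voxel's series by its ordinary-least-squares residuals
#' against an intercept plus all confound columns (the 24 motion-derived
#' regressors and the two tissue signals). Residuals are orthogonal to every
#' confound. A rank-deficient confound matrix triggers a warning and a
#' pseudo-inverse fit.
#'
#' @param ts a `voxel_ts` object.
#' @param confounds data.frame or matrix with one row per timepoint.
#' @return The `voxel_ts` with residualized values.
#' @export
nuisance_regress <- function(ts, confounds) {
  stopifnot(inherits(ts, "voxel_ts"))
  X <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(X) != ncol(ts$values)) {
    stop_input("confounds have %d rows but the series has %d timepoints",
               nrow(X), ncol(ts$values))
  }
  if (anyNA(X)) stop_input("confounds contain missing values")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("confound matrix is rank-deficient; using pseudo-inverse fit")
    sv <- svd(X)
    keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    pinv <- sv$v[, keep, drop = FALSE] %*%
      diag(1 / sv$d[keep], sum(keep)) %*% t(sv$u[, keep, drop = FALSE])
    ts$values <- ts$values - t(X %*% (pinv %*% t(ts$values)))
  } else {
    ts$values <- t(qr.resid(qrX, t(ts$values)))
  }
  ts
}

#' Linear detrend and FFT bandpass filter
#'
#' Removes a per-voxel linear trend, then keeps only DFT bins whose
#' frequencies fall inside `[low_hz, high_hz]` (zero-phase ideal filter).
#'
#' @param ts a `voxel_ts` object.
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below Nyquist.
#' @param detrend_only if `TRUE`, skip the bandpass.
#' @return The filtered `voxel_ts`.
#' @export
detrend_bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08,
                             detrend_only = FALSE) {
  stopifnot(inherits(ts, "voxel_ts"))
  T_ <- ncol(ts$values)
  nyq <- 1 / (2 * ts$tr)
  if (!detrend_only && high_hz >= nyq) {
    stop_input("band edge %.3f Hz is at or above Nyquist (%.3f Hz)", high_hz, nyq)
  }
  tt <- seq_len(T_)
  X <- cbind(1, tt)
  ts$values <- t(qr.resid(qr(X), t(ts$values)))
  if (detrend_only) return(ts)
  freqs <- (seq_len(T_) - 1) / (T_ * ts$tr)
  freqs <- pmin(freqs, 1 / ts$tr - freqs)  # two-sided spectrum
  keep <- freqs >= low_hz & freqs <= high_hz
  ft <- t(stats::mvfft(t(ts$values)))
  ft[, !keep] <- 0
  ts$values <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / T_
  ts
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' Per voxel, the ratio of summed periodogram amplitudes (square roots of
#' power) within the low-frequency band to the summed amplitude over the
#' whole positive spectrum. The spectrum is estimated from the demeaned,
#' Hann-tapered series; the taper confines spectral leakage to neighboring
#' frequency bins, without which narrow-band signals whose frequency falls
#' between bins would leak a substantial amplitude fraction across the whole
#' spectrum and bias the ratio downward. The input must be
#' nuisance-regressed and detrended but not bandpassed, since the
#' denominator needs the full spectrum. Values lie in `[0, 1]`; all-zero
#' series get value 0 with a warning.
#'
#' @param ts a `voxel_ts` (nuisance-regressed, detrended, not bandpassed).
#' @param band numeric band edges in Hz.
#' @return A `voxel_map` with metric `"fALFF"`.
#' @export
compute_falff <- function(ts, band = c(0.01, 0.08)) {
  stopifnot(inherits(ts, "voxel_ts"))
  T_ <- ncol(ts$values)
  x <- ts$values - rowMeans(ts$values)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(T_) - 1) / (T_ - 1))
  x <- sweep(x, 2L, taper, "*")
  ft <- t(stats::mvfft(t(x)))
  k <- seq_len(floor(T_ / 2))
  amp <- Mod(ft[, k + 1L, drop = FALSE]) / sqrt(T_)
  freq <- k / (T_ * ts$tr)
  in_band <- freq >= band[1] & freq <= band[2]
  tot <- rowSums(amp)
  val <- rep(NA_real_, nrow(x))
  zero <- tot <= 0
  if (any(zero & ts$mask)) warning("all-zero series: fALFF set to 0")
  val[!zero] <- rowSums(amp[, in_band, drop = FALSE])[!zero] / tot[!zero]
  val[zero] <- 0
  val[!ts$mask] <- NA_real_
  new_voxel_map(val, "fALFF", ts)
}

drop_zero_variance <- function(ts) {
  v <- apply(ts$values, 1L, stats::var)
  zero <- ts$mask & (is.na(v) | v <= 0)
  if (any(zero)) {
    warning(sprintf("%d zero-variance voxel(s) excluded from mask", sum(zero)))
    ts$mask[zero] <- FALSE
  }
  ts
}

#' Local correlation (LCOR)
#'
#' Per voxel, the Gaussian-kernel-weighted average of Pearson correlations
#' between that voxel's series and every other in-mask voxel's series, with
#' spatial weights from inter-voxel distance (kernel width given as FWHM in
#' mm), self excluded, weights normalized to sum 1.
#'
#' @param ts a bandpassed `voxel_ts`.
#' @param fwhm_mm kernel full width at half maximum in mm. The default of
#'   25 mm follows common toolbox practice.
#' @return A `voxel_map` with metric `"LCOR"`.
#' @export
compute_lcor <- function(ts, fwhm_mm = 25) {
  stopifnot(inherits(ts, "voxel_ts"))
  ts <- drop_zero_variance(ts)
  idx <- which(ts$mask)
  if (length(idx) < 2L) stop_input("LCOR needs at least 2 in-mask voxels")
  Z <- standardize_rows(ts$values[idx, , drop = FALSE])
  R <- Z %*% t(Z) / (ncol(Z) - 1L)
  xy <- ts$coords[idx, , drop = FALSE]
  d2 <- outer(rowSums(xy^2), rowSums(xy^2), "+") - 2 * xy %*% t(xy)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  W <- exp(-pmax(d2, 0) / (2 * sigma^2))
  diag(W) <- 0
  val <- rep(NA_real_, nrow(ts$values))
  val[idx] <- rowSums(W * R) / rowSums(W)
  new_voxel_map(val, "LCOR", ts)
}

#' Global correlation (GCOR)
#'
#' Per voxel, the signed mean Pearson correlation between that voxel's series
#' and every other in-mask voxel's series (self excluded). Computed through a
#' standardized-series matrix product, which is algebraically identical to
#' the direct pairwise mean.
#'
#' @param ts a bandpassed `voxel_ts`.
#' @return A `voxel_map` with metric `"GCOR"`.
#' @export
compute_gcor <- function(ts) {
  stopifnot(inherits(ts, "voxel_ts"))
  ts <- drop_zero_variance(ts)
  idx <- which(ts$mask)
  V <- length(idx)
  if (V < 2L) stop_input("GCOR needs at least 2 in-mask voxels")
  Z <- standardize_rows(ts$values[idx, , drop = FALSE])
  s <- colSums(Z)
  tot <- as.vector(Z %*% s) / (ncol(Z) - 1L)   # row i: sum_j r_ij incl. self
  val <- rep(NA_real_, nrow(ts$values))
  val[idx] <- (tot - 1) / (V - 1L)
  new_voxel_map(val, "GCOR", ts)
}

#' Average a voxel map into parcels
#'
#' @param vmap a `voxel_map` or a plain numeric vector of voxel values.
#' @param labels integer parcellation (array or vector, same voxel count),
#'   ids `1..P`, 0 = outside parcellation.
#' @param n_parcels number of parcels; defaults to `max(labels)`.
#' @return Named numeric vector of parcel means with attribute `missing`
#'   marking parcels with no in-mask voxels (value `NA`) and attribute
#'   `metric`.
#' @export
parcellate <- function(vmap, labels, n_parcels = NULL) {
  if (inherits(vmap, "voxel_map")) {
    values <- vmap$values
    metric <- vmap$metric
    mask <- vmap$mask
  } else {
    values <- as.vector(vmap)
    metric <- NA_character_
    mask <- rep(TRUE, length(values))
  }
  labels <- as.integer(labels)
  if (length(labels) != length(values)) {
    stop_input("parcellation has %d voxels but the map has %d",
               length(labels), length(values))
  }
  use <- mask & !is.na(values) & labels > 0L
  if (!any(use)) stop_input("no overlap between mask and parcellation labels")
  P <- n_parcels %||% max(labels)
  sums <- tapply(values[use], factor(labels[use], levels = seq_len(P)), mean)
  out <- as.numeric(sums)
  names(out) <- sprintf("parcel_%03d", seq_len(P))
  attr(out, "missing") <- is.na(out)
  attr(out, "metric") <- metric
  out
}
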