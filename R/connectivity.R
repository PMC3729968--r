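# Band-limited phase extraction and phase-lag-index connectivity.
#
# All filtering is zero-phase spectral masking: each epoch is transformed with
# the FFT, bins outside the passband are zeroed, and the signal is transformed
# back. This is exactly zero-phase, idempotent, and numerically safe at the
# delta band's very small normalized edge frequencies.

fft_band_mask <- function(n, band, fs) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  as.numeric(f >= band$lo & f <= band$hi)
}

check_epoch_length <- function(n, band, fs) {
  # spectral masking has an effective impulse response ~ 1/lo seconds; demand
  # epochs at least 3x that so edge transients can be trimmed away
  need <- 3 * fs / band$lo
  if (n < need) {
    stop(sprintf(
      "epoch of %d samples too short for band %s (need >= %.0f samples = 3x impulse response)",
      n, band$name, need))
  }
  invisible(TRUE)
}

#' Zero-phase band-pass filter
#'
#' Filters each epoch (column) with a zero-phase spectral mask retaining
#' frequencies in `[lo, hi]`.
#'
#' @param x numeric vector (one epoch) or matrix (samples x epochs).
#' @param band band name or `c(lo, hi)` in Hz (see [as_band()]).
#' @param fs sampling frequency in Hz.
#' @return filtered signal with the same shape as `x`.
#' @export
bandpass <- function(x, band, fs) {
  band <- as_band(band)
  if (band$hi >= fs / 2) {
    stop("band '", band$name, "' exceeds the Nyquist frequency ", fs / 2, " Hz")
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  check_epoch_length(nrow(xm), band, fs)
  mask <- fft_band_mask(nrow(xm), band, fs)
  y <- Re(stats::mvfft(stats::mvfft(xm) * mask, inverse = TRUE)) / nrow(xm)
  if (vec) drop(y) else y
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the phase of the analytic (Hilbert) signal per epoch, wrapped to
#' (-pi, pi]. Input should be band-limited (see [bandpass()]).
#'
#' @param x numeric vector (one epoch) or matrix (samples x epochs).
#' @return phases, same shape as `x`.
#' @export
instantaneous_phase <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  if (any(apply(xm, 2, function(col) all(col == 0)))) {
    stop("instantaneous phase undefined for an all-zero epoch")
  }
  n <- nrow(xm)
  h <- analytic_weights(n)
  a <- stats::mvfft(stats::mvfft(xm) * h, inverse = TRUE) / n
  ph <- Arg(a)
  ph[ph == -pi] <- pi  # Arg may return -pi; the contract is (-pi, pi]
  if (vec) drop(ph) else ph
}

analytic_weights <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

# Band-limited analytic phase in a single pass: equivalent to
# instantaneous_phase(bandpass(x)) because both are spectral masks.
band_phase <- function(xm, band, fs) {
  n <- nrow(xm)
  check_epoch_length(n, band, fs)
  mask <- fft_band_mask(n, band, fs) * analytic_weights(n)
  a <- stats::mvfft(stats::mvfft(xm) * mask, inverse = TRUE) / n
  Arg(a)
}

# Band-limited analytic phases for several bands, sharing one forward FFT.
band_phase_multi <- function(xm, bands, fs) {
  n <- nrow(xm)
  X <- stats::mvfft(xm)
  h <- analytic_weights(n)
  out <- lapply(bands, function(band) {
    check_epoch_length(n, band, fs)
    mask <- fft_band_mask(n, band, fs) * h
    Arg(stats::mvfft(X * mask, inverse = TRUE) / n)
  })
  names(out) <- vapply(bands, function(b) b$name, character(1))
  out
}

# Samples retained for PLI after trimming filter/Hilbert edge effects:
# 1/(2*lo) seconds at each epoch end.
edge_retain_idx <- function(n, band, fs, edge_trim = TRUE) {
  if (!edge_trim) return(seq_len(n))
  k <- ceiling(fs / (2 * band$lo))
  if (2 * k >= n) stop("edge trim would discard the whole epoch")
  (k + 1):(n - k)
}

#' Phase lag index of two phase series
#'
#' The PLI is the absolute value of the time-averaged sign of the wrapped
#' instantaneous phase difference: 0 for a symmetric phase-difference
#' distribution (including strictly zero lag), 1 for a consistent non-zero
#' lag. With several epochs the PLI is computed per epoch and averaged.
#'
#' @param phase_x,phase_y phases in radians; vectors (one epoch) or matrices
#'   (samples x epochs) of equal shape.
#' @return scalar PLI in `[0, 1]`.
#' @export
pli <- function(phase_x, phase_y) {
  px <- if (is.null(dim(phase_x))) matrix(phase_x, ncol = 1) else phase_x
  py <- if (is.null(dim(phase_y))) matrix(phase_y, ncol = 1) else phase_y
  if (!all(dim(px) == dim(py))) {
    stop("phase series have mismatched lengths/epoch counts")
  }
  d <- wrap_phase(px - py)
  mean(abs(colMeans(sign(d))))
}

#' PLI adjacency matrix across ROIs
#'
#' Band-filters each ROI series, extracts analytic phases, trims epoch edges,
#' computes the per-epoch PLI for every unordered ROI pair and averages over
#' the first `n_epochs` epochs.
#'
#' @param roi_series numeric array (samples x epochs x n_roi), e.g. the
#'   `series` element of [select_roi_voxel()] output or of a simulated cohort
#'   subject; dimnames on the third margin are used as ROI labels.
#' @param band band name or `c(lo, hi)` Hz.
#' @param fs sampling frequency in Hz.
#' @param n_epochs number of epochs averaged (default 5, the first epochs).
#' @param edge_trim drop 1/(2*lo) s at both epoch ends before the PLI sample
#'   set (default TRUE).
#' @param labels optional ROI labels (defaults to array dimnames).
#' @param subject_id optional subject identifier carried in the result.
#' @return an object of class `adjacency_matrix`: list with `values`
#'   (n_roi x n_roi symmetric, zero diagonal, entries in `[0,1]`), `band`,
#'   `subject_id`, `n_epochs`.
#' @export
adjacency <- function(roi_series, band, fs, n_epochs = 5, edge_trim = TRUE,
                      labels = NULL, subject_id = NA_character_) {
  band <- as_band(band)
  stopifnot(length(dim(roi_series)) == 3)
  n_roi <- dim(roi_series)[3]
  if (n_roi < 2) stop("adjacency needs at least 2 ROIs")
  avail <- dim(roi_series)[2]
  if (avail < n_epochs) {
    stop("recording has ", avail, " epochs; ", n_epochs, " required")
  }
  labels <- labels %||% dimnames(roi_series)[[3]] %||%
    sprintf("roi_%03d", seq_len(n_roi))
  n <- dim(roi_series)[1]
  keep <- edge_retain_idx(n, band, fs, edge_trim)
  acc <- matrix(0, n_roi, n_roi)
  for (e in seq_len(n_epochs)) {
    ph <- band_phase(roi_series[, e, , drop = TRUE], band, fs)
    acc <- acc + .pli_matrix_cpp(ph[keep, , drop = FALSE])
  }
  vals <- acc / n_epochs
  dimnames(vals) <- list(labels, labels)
  structure(
    list(values = vals, band = band, subject_id = subject_id,
         n_epochs = n_epochs),
    class = "adjacency_matrix")
}

adj_values <- function(A) {
  if (inherits(A, "adjacency_matrix")) A$values else as.matrix(A)
}

#' Node strength (weighted degree)
#'
#' Mean PLI of each ROI with all other ROIs, i.e. the mean of the off-diagonal
#' row entries of the adjacency matrix.
#'
#' @param A an `adjacency_matrix` or a plain symmetric matrix.
#' @return named numeric vector, one value per ROI.
#' @export
node_strength <- function(A) {
  v <- adj_values(A)
  n <- nrow(v)
  if (n < 2) stop("node strength needs at least 2 ROIs")
  (rowSums(v) - diag(v)) / (n - 1)
}

#' Whole-brain mean PLI
#'
#' Mean of the per-ROI node strengths; identical to the mean over all
#' unordered ROI pairs.
#'
#' @inheritParams node_strength
#' @return scalar mean PLI.
#' @export
whole_brain_mean <- function(A) {
  mean(node_strength(A))
}

#' Mean PLI within a resting-state network
#'
#' Averages the adjacency entries over the N(N-1)/2 unordered pairs of ROIs
#' belonging to the network.
#'
#' @inheritParams node_strength
#' @param rsn character vector of member ROI labels.
#' @return scalar mean within-network PLI.
#' @export
rsn_mean_pli <- function(A, rsn) {
  v <- adj_values(A)
  labels <- rownames(v)
  if (is.null(labels)) stop("adjacency matrix has no ROI labels")
  unknown <- setdiff(rsn, labels)
  if (length(unknown) > 0) {
    stop("RSN references unknown ROI label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(rsn) < 2) stop("RSN has fewer than 2 ROIs: no within-network connections")
  idx <- match(rsn, labels)
  sub <- v[idx, idx, drop = FALSE]
  n <- length(idx)
  sum(sub[upper.tri(sub)]) / (n * (n - 1) / 2)
}

#' Phase-scrambled surrogate
#'
#' Randomizes the Fourier phases of each epoch while preserving the amplitude
#' spectrum, destroying any cross-signal phase coupling. Used to build
#' permutation null distributions for the PLI.
#'
#' @param x numeric vector (one epoch) or matrix (samples x epochs).
#' @return surrogate of the same shape.
#' @export
phase_scramble <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  out <- apply(xm, 2, function(col) {
    X <- stats::fft(col)
    half <- seq(2, ceiling(n / 2))
    phi <- stats::runif(length(half), -pi, pi)
    X[half] <- Mod(X[half]) * exp(1i * phi)
    X[n - half + 2] <- Conj(X[half])
    Re(stats::fft(X, inverse = TRUE)) / n
  })
  if (vec) drop(out) else out
}
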