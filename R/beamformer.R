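# Spherical-head forward model and scalar (SAM-type) beamformer.
#
# The head is a homogeneous conducting sphere: the external magnetic field of
# a current dipole then has the closed-form solution of Sarvas (1987), and a
# radially oriented dipole is magnetically silent. Sensors are magnetometers
# characterized by a position and a normal; the lead field is the field
# component along each sensor normal.

MU0_OVER_4PI <- 1e-7  # T m / A

#' Magnetometer lead field of a dipole in a homogeneous sphere
#'
#' Evaluates the Sarvas closed-form magnetic field of a current dipole inside
#' a homogeneous conducting sphere, projected onto each magnetometer normal.
#'
#' @param voxel dipole position, 3-vector in meters (head coordinates).
#' @param moment dipole moment, 3-vector in ampere-meters.
#' @param sensors a `sensor_array` (see [generate_geometry()]).
#' @param head a `head_model` with `sphere_center` and `sphere_radius`.
#' @return list of class `lead_field` with `gain` (length n_channels, tesla
#'   per unit moment as supplied), `voxel`, `moment`.
#' @export
leadfield_sphere <- function(voxel, moment, sensors, head) {
  stopifnot(length(voxel) == 3, length(moment) == 3)
  r0 <- as.numeric(voxel) - head$sphere_center
  nr0 <- vnorm(r0)
  if (nr0 < 1e-9) stop("dipole at the sphere center is magnetically silent/undefined")
  if (nr0 >= head$sphere_radius) {
    stop("dipole lies on or outside the head sphere (|r0| = ", signif(nr0, 4),
         " m, radius = ", head$sphere_radius, " m)")
  }
  q <- as.numeric(moment)
  qxr0 <- cross3(q, r0)
  pos <- sweep(as.matrix(sensors$position), 2, head$sphere_center)
  ori <- as.matrix(sensors$orientation)
  gain <- vapply(seq_len(nrow(pos)), function(i) {
    r <- pos[i, ]
    nr <- vnorm(r)
    a <- r - r0
    na <- vnorm(a)
    if (na < 1e-12) stop("sensor coincides with the dipole")
    adotr <- sum(a * r)
    FF <- na * (nr * na + nr^2 - sum(r0 * r))
    gradF <- (na^2 / nr + adotr / na + 2 * na + 2 * nr) * r -
      (na + 2 * nr + adotr / na) * r0
    B <- MU0_OVER_4PI / FF^2 * (FF * qxr0 - sum(qxr0 * r) * gradF)
    sum(B * ori[i, ])
  }, numeric(1))
  structure(list(gain = gain, voxel = as.numeric(voxel), moment = q),
            class = "lead_field")
}

# Orthonormal tangential basis at a voxel (radial direction excluded: in a
# sphere the radial dipole component is silent).
tangential_basis <- function(voxel, head) {
  u <- as.numeric(voxel) - head$sphere_center
  nu <- vnorm(u)
  if (nu < 1e-9) stop("tangential basis undefined at the sphere center")
  u <- u / nu
  e <- diag(3)[, which.min(abs(u))]
  t1 <- cross3(u, e); t1 <- t1 / vnorm(t1)
  t2 <- cross3(u, t1)
  cbind(t1, t2)
}

# n_channels x 2 tangential lead-field matrix at a voxel.
leadfield_pair <- function(voxel, sensors, head) {
  Tb <- tangential_basis(voxel, head)
  cbind(leadfield_sphere(voxel, Tb[, 1], sensors, head)$gain,
        leadfield_sphere(voxel, Tb[, 2], sensors, head)$gain)
}

#' Broadband data covariance of an epoched recording
#'
#' Band-pass filters every epoch (default 0.5-48 Hz, the broadband window used
#' for beamformer weights), concatenates epochs, and computes the channel
#' covariance with the 1/n normalization (so duplicating epochs leaves the
#' estimate unchanged).
#'
#' @param recording an `epoched_recording` (array channels x samples x epochs
#'   plus `fs`), see [project_to_sensors()].
#' @param band broadband filter edges, default `c(0.5, 48)` Hz.
#' @return n_channels x n_channels symmetric covariance matrix.
#' @export
compute_covariance <- function(recording, band = c(0.5, 48)) {
  band <- as_band(band)
  dat <- recording$data
  stopifnot(length(dim(dat)) == 3)
  n_ch <- dim(dat)[1]; n_s <- dim(dat)[2]; n_ep <- dim(dat)[3]
  if (n_ep < 2) stop("covariance needs at least 2 epochs")
  X <- matrix(0, n_ch, n_s * n_ep)
  for (e in seq_len(n_ep)) {
    X[, ((e - 1) * n_s + 1):(e * n_s)] <- t(bandpass(t(dat[, , e]), band, recording$fs))
  }
  if (ncol(X) < n_ch) {
    warning("fewer samples than channels: covariance is rank deficient, regularization mandatory")
  }
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / ncol(X)
  (C + t(C)) / 2
}

#' Scalar beamformer weights with optimized tangential orientation
#'
#' For each voxel, chooses the dipole orientation in the tangential plane that
#' maximizes beamformer pseudo-power (the minimum-eigenvalue direction of the
#' 2x2 projected matrix `t(L) C^-1 L`), then forms the unit-gain minimum
#' variance weights `w = C^-1 l / (t(l) C^-1 l)`.
#'
#' @param voxels matrix (n_voxels x 3) of dipole positions in meters.
#' @param sensors a `sensor_array`.
#' @param head a `head_model`.
#' @param covariance channel covariance (see [compute_covariance()]).
#' @param reg_fraction diagonal-loading factor: the regularized covariance is
#'   `C + reg_fraction * mean(diag(C)) * I` (default 0.05).
#' @return object of class `beamformer_model`: list with `weights`
#'   (n_voxels x n_channels), `orientations` (n_voxels x 3 unit vectors),
#'   `leadfields` (n_voxels x n_channels, at the chosen orientation),
#'   `covariance`, `reg_fraction`, `channel_id`.
#' @export
compute_weights <- function(voxels, sensors, head, covariance, reg_fraction = 0.05) {
  voxels <- as.matrix(voxels)
  stopifnot(ncol(voxels) == 3, reg_fraction >= 0)
  n_ch <- nrow(sensors$position)
  stopifnot(all(dim(covariance) == c(n_ch, n_ch)))
  Creg <- covariance + reg_fraction * mean(diag(covariance)) * diag(n_ch)
  Ci <- tryCatch(chol2inv(chol(Creg)), error = function(e) {
    stop("regularized covariance is singular; increase reg_fraction (currently ",
         reg_fraction, ")")
  })
  W <- matrix(0, nrow(voxels), n_ch)
  L <- matrix(0, nrow(voxels), n_ch)
  O <- matrix(0, nrow(voxels), 3)
  for (v in seq_len(nrow(voxels))) {
    Tb <- tangential_basis(voxels[v, ], head)
    Lv <- leadfield_pair(voxels[v, ], sensors, head)
    A <- crossprod(Lv, Ci %*% Lv)
    A <- (A + t(A)) / 2
    eg <- eigen(A, symmetric = TRUE)
    u <- eg$vectors[, 2]  # smallest eigenvalue -> maximal pseudo-power
    if (u[which.max(abs(u))] < 0) u <- -u  # deterministic sign
    l <- drop(Lv %*% u)
    Cil <- drop(Ci %*% l)
    denom <- sum(l * Cil)
    if (!is.finite(denom) || denom <= 0) {
      stop("degenerate lead field at voxel ", v, " (reg_fraction = ", reg_fraction, ")")
    }
    W[v, ] <- Cil / denom
    L[v, ] <- l
    O[v, ] <- drop(Tb %*% u)
  }
  structure(
    list(weights = W, orientations = O, leadfields = L,
         covariance = covariance, reg_fraction = reg_fraction,
         channel_id = sensors$channel_id, voxels = voxels),
    class = "beamformer_model")
}

#' Project sensor data through beamformer weights
#'
#' @param recording an `epoched_recording`.
#' @param model a `beamformer_model` from [compute_weights()].
#' @return array (samples x epochs x n_voxels) of reconstructed voxel series.
#' @export
reconstruct_voxels <- function(recording, model) {
  dat <- recording$data
  if (dim(dat)[1] != ncol(model$weights)) {
    stop("channel count mismatch between recording and beamformer model")
  }
  if (!is.null(recording$channel_id) && !is.null(model$channel_id) &&
      !identical(recording$channel_id, model$channel_id)) {
    stop("channel ordering of recording does not match beamformer model")
  }
  n_s <- dim(dat)[2]; n_ep <- dim(dat)[3]; n_v <- nrow(model$weights)
  out <- array(0, dim = c(n_s, n_ep, n_v))
  for (e in seq_len(n_ep)) {
    out[, e, ] <- t(model$weights %*% dat[, , e])
  }
  out
}

#' Select one representative voxel per ROI by maximum band power
#'
#' Band-pass filters every member voxel's series and keeps, per ROI, the voxel
#' with the largest power (variance of the band-passed series summed over
#' epochs). Ties break toward the lowest voxel index.
#'
#' @param voxel_series array (samples x epochs x n_voxels) from
#'   [reconstruct_voxels()].
#' @param atlas an `roi_atlas` (see [generate_geometry()]) whose `roi_index`
#'   maps voxels to ROI labels.
#' @param band band name or `c(lo, hi)` Hz.
#' @param fs sampling frequency in Hz.
#' @return list of class `roi_series`: `series` (samples x epochs x n_roi,
#'   band-passed), `labels`, `selected_voxel` (index into the atlas voxel
#'   list per ROI), `band`, `fs`.
#' @export
select_roi_voxel <- function(voxel_series, atlas, band, fs) {
  band <- as_band(band)
  labels <- atlas$labels
  n_s <- dim(voxel_series)[1]; n_ep <- dim(voxel_series)[2]
  sel <- integer(length(labels))
  out <- array(0, dim = c(n_s, n_ep, length(labels)),
               dimnames = list(NULL, NULL, labels))
  for (k in seq_along(labels)) {
    vox <- which(atlas$roi_index == k)
    if (length(vox) == 0) stop("ROI '", labels[k], "' has no voxels")
    pow <- vapply(vox, function(v) {
      bp <- bandpass(voxel_series[, , v, drop = TRUE], band, fs)
      bp <- if (is.null(dim(bp))) matrix(bp, ncol = 1) else bp
      sum(apply(bp, 2, stats::var))
    }, numeric(1))
    best <- vox[which.max(pow)]  # which.max takes the first maximum: lowest index
    sel[k] <- best
    bp <- bandpass(voxel_series[, , best, drop = TRUE], band, fs)
    out[, , k] <- bp
  }
  structure(list(series = out, labels = labels, selected_voxel = sel,
                 band = band, fs = fs),
            class = "roi_series")
}
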