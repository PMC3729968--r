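# Source-level simulation: phase-coupled narrowband oscillators with a
# controlled, non-zero phase lag between designated ROI pairs, on top of a
# 1/f broadband background. The coupling model is chosen so that the phase
# lag index has a computable ground truth: for a coupled pair the
# instantaneous phase difference is lag_delta plus von Mises jitter with
# concentration jitter_kappa, so PLI = |E sign(sin(lag_delta + eps))| can be
# evaluated by brute-force Monte Carlo.

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the circular uniform,
#' `kappa = Inf` the point mass at `mu`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0, may be `Inf`).
#' @return angles wrapped to (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap_phase(stats::runif(n, -pi, pi)))
  if (is.infinite(kappa)) return(rep(wrap_phase(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[(got + 1):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      got <- got + k
    }
  }
  wrap_phase(out + mu)
}

#' Brute-force PLI of a von Mises lagged coupling
#'
#' Monte-Carlo oracle for the expected PLI of a pair whose phase difference is
#' `lag_delta` plus von Mises jitter of concentration `kappa`:
#' `|mean(sign(wrap(lag_delta + eps)))|` over `n` independent draws.
#'
#' @param lag_delta phase lag in radians.
#' @param kappa von Mises concentration.
#' @param n number of Monte-Carlo draws (default 1e6).
#' @return list with `pli` and its Monte-Carlo standard error `se`.
#' @export
pli_vonmises_oracle <- function(lag_delta, kappa, n = 1e6) {
  s <- sign(wrap_phase(lag_delta + rvonmises(n, 0, kappa)))
  m <- mean(s)
  list(pli = abs(m), se = stats::sd(s) / sqrt(n))
}

#' Specify band-limited phase coupling between ROI pairs
#'
#' @param band band name or `c(lo, hi)` Hz.
#' @param roi_pairs 2-column character matrix (or list of length-2 vectors) of
#'   unordered ROI label pairs to couple.
#' @param lag_delta consistent phase lag in radians, in (-pi, pi], default
#'   pi/2 (where the PLI is most sensitive).
#' @param jitter_kappa von Mises concentration of the phase-difference jitter
#'   (>= 0; `Inf` = noiseless constant lag).
#' @param amplitude_snr power of each band oscillation relative to the in-band
#'   1/f background power (default 5).
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(band, roi_pairs, lag_delta = pi / 2,
                          jitter_kappa = 2, amplitude_snr = 5) {
  band <- as_band(band)
  if (is.list(roi_pairs)) roi_pairs <- do.call(rbind, roi_pairs)
  roi_pairs <- as.matrix(roi_pairs)
  stopifnot(ncol(roi_pairs) == 2, jitter_kappa >= 0, amplitude_snr > 0,
            lag_delta > -pi, lag_delta <= pi)
  structure(list(band = band, roi_pairs = roi_pairs, lag_delta = lag_delta,
                 jitter_kappa = jitter_kappa, amplitude_snr = amplitude_snr),
            class = "coupling_spec")
}

# 1/f (power ~ 1/f) background noise, unit variance, one epoch per column.
# Random-phase spectral synthesis; the variance is fixed by Parseval, so the
# normalization is deterministic.
one_over_f_noise <- function(n, n_cols, fs, f_min = 0.5) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  amp <- ifelse(f >= f_min, 1 / sqrt(f), 0)
  half <- seq(2, ceiling(n / 2))
  X <- matrix(0i, n, n_cols)
  phi <- matrix(stats::runif(length(half) * n_cols, -pi, pi), length(half))
  X[half, ] <- amp[half] * exp(1i * phi)
  X[n - half + 2, ] <- Conj(X[half, ])
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  x / sqrt(2 * sum(amp[half]^2) / n^2)
}

# Random-phase narrowband analytic carrier, one epoch per column: in-band
# spectral bins get unit amplitude and uniform random phase. Re() has unit
# RMS (Parseval); the instantaneous phase is smooth with decorrelation time
# ~ 1/bandwidth.
carrier_analytic <- function(n, n_cols, band, fs) {
  check_epoch_length(n, band, fs)
  mask <- fft_band_mask(n, band, fs) * analytic_weights(n)
  nz <- which(mask > 0)
  X <- matrix(0i, n, n_cols)
  phi <- matrix(stats::runif(length(nz) * n_cols, -pi, pi), length(nz))
  X[nz, ] <- mask[nz] * exp(1i * phi)
  a <- stats::mvfft(X, inverse = TRUE) / n
  a / sqrt(sum(mask[nz]^2) / (2 * n^2))
}

# Instantaneous phase of a fresh narrowband carrier (one epoch per column).
carrier_phase <- function(n, n_cols, band, fs) {
  Arg(carrier_analytic(n, n_cols, band, fs))
}

# Piecewise-constant von Mises jitter: iid draws held for ~one band coherence
# time, so the jitter is in-band (survives filtering) while keeping an exact
# von Mises marginal.
held_vonmises <- function(n, n_cols, kappa, band, fs) {
  hold <- max(1L, as.integer(round(fs / (band$hi - band$lo))))
  n_knots <- ceiling(n / hold)
  draws <- matrix(rvonmises(n_knots * n_cols, 0, kappa), n_knots, n_cols)
  idx <- rep(seq_len(n_knots), each = hold)[seq_len(n)]
  draws[idx, , drop = FALSE]
}

#' Simulate coupled narrowband ROI source activity
#'
#' Each ROI receives a unit-variance 1/f background plus, for every band named
#' in `coupling`, a narrowband oscillation. ROIs joined by coupling pairs
#' share a carrier phase: along each pair the second ROI's phase equals the
#' first's minus `lag_delta` plus held von Mises jitter (see
#' [coupling_spec()]); ROIs not involved in any pair receive independent
#' carriers. The coupling pairs of one band (pooled over all specs of that
#' band) must form a forest (no cycles); specs of the same band may carry
#' different lags and jitter concentrations for their edges.
#'
#' @param atlas an `roi_atlas` (only `labels` is used).
#' @param coupling list of `coupling_spec` objects (possibly empty).
#' @param n_epochs number of epochs (default 5).
#' @param epoch_samples samples per epoch (default 4096, >= 256).
#' @param fs sampling frequency (default 625 Hz; must exceed twice the highest
#'   band edge).
#' @param seed integer seed.
#' @param keep_phases store the imposed ground-truth phase arrays per coupled
#'   band (default TRUE; cohort-scale simulations switch this off to save
#'   memory and time).
#' @return list of class `source_sim`: `series` (samples x epochs x n_roi),
#'   `phases` (named list per coupled band: imposed phase arrays of the same
#'   shape; empty when `keep_phases = FALSE`), `labels`, `fs`, `coupling`.
#' @export
simulate_sources <- function(atlas, coupling = list(), n_epochs = 5,
                             epoch_samples = 4096, fs = 625, seed = 1,
                             keep_phases = TRUE) {
  stopifnot(epoch_samples >= 256, n_epochs >= 1)
  if (inherits(coupling, "coupling_spec")) coupling <- list(coupling)
  for (cs in coupling) {
    if (cs$band$hi >= fs / 2) {
      stop("band '", cs$band$name, "' exceeds the Nyquist frequency")
    }
    unknown <- setdiff(as.vector(cs$roi_pairs), atlas$labels)
    if (length(unknown) > 0) {
      stop("coupling references unknown ROI label(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  labels <- atlas$labels
  n_roi <- length(labels)
  n <- epoch_samples
  with_seed(seed, {
    series <- array(one_over_f_noise(n, n_epochs * n_roi, fs),
                    dim = c(n, n_epochs, n_roi),
                    dimnames = list(NULL, NULL, labels))
    phases <- list()
    band_names <- unique(vapply(coupling, function(cs) cs$band$name, character(1)))
    for (bn in band_names) {
      specs <- coupling[vapply(coupling, function(cs) cs$band$name == bn, logical(1))]
      band <- specs[[1]]$band
      # per-edge coupling parameters, pooled over all specs of this band
      edges <- do.call(rbind, lapply(specs, function(cs) {
        p <- t(apply(cs$roi_pairs, 1, sort))
        data.frame(a = p[, 1], b = p[, 2], lag = cs$lag_delta,
                   kappa = cs$jitter_kappa, stringsAsFactors = FALSE)
      }))
      edges <- edges[!duplicated(edges[, c("a", "b")]), , drop = FALSE]
      members <- unique(c(edges$a, edges$b))

      # in-band background RMS sets the oscillation amplitude via the SNR
      snr_amp <- max(vapply(specs, function(cs) cs$amplitude_snr, numeric(1)))
      f_axis_pow <- sum(1 / pmax(seq(0.5, fs / 2, by = fs / n), 0.5))
      in_band <- sum(1 / seq(max(band$lo, 0.5), band$hi, by = fs / n))
      bg_band_var <- in_band / f_axis_pow  # fraction of unit background variance
      amp <- sqrt(2 * snr_amp * bg_band_var)

      ph_store <- if (keep_phases) {
        array(NA_real_, dim = c(n, n_epochs, n_roi),
              dimnames = list(NULL, NULL, labels))
      }
      phi_map <- list()  # phases of coupled nodes during traversal
      adj <- lapply(members, function(m) {
        hits <- which(edges$a == m | edges$b == m)
        lapply(hits, function(h) {
          nb <- if (edges$a[h] == m) edges$b[h] else edges$a[h]
          list(nb = nb,
               lag = if (edges$a[h] == m) edges$lag[h] else -edges$lag[h],
               kappa = edges$kappa[h])
        })
      })
      names(adj) <- members
      assigned <- character(0)
      n_components <- 0L
      for (root in members) {
        if (root %in% assigned) next
        n_components <- n_components + 1L
        phi_map[[root]] <- matrix(carrier_phase(n, n_epochs, band, fs),
                                  n, n_epochs)
        assigned <- c(assigned, root)
        queue <- root
        while (length(queue) > 0) {
          cur <- queue[1]; queue <- queue[-1]
          for (ed in adj[[cur]]) {
            if (ed$nb %in% assigned) next
            jit <- held_vonmises(n, n_epochs, ed$kappa, band, fs)
            # edge (cur -> nb): nb lags cur by ed$lag
            phi_map[[ed$nb]] <- wrap_phase(phi_map[[cur]] - ed$lag + jit)
            assigned <- c(assigned, ed$nb)
            queue <- c(queue, ed$nb)
          }
        }
      }
      if (nrow(edges) != length(members) - n_components) {
        stop("coupling pairs for band '", band$name,
             "' contain a cycle; pairs must form a forest")
      }
      # coupled members: constant-amplitude phase-coupled oscillation,
      # band-limited with the same brick-wall mask the measurement path
      # applies (the jitter steps would otherwise put coupling-bearing
      # sidebands into neighboring bands)
      member_idx <- match(members, labels)
      osc <- matrix(0, n, n_epochs * length(members))
      for (j in seq_along(members)) {
        osc[, ((j - 1) * n_epochs + 1):(j * n_epochs)] <- cos(phi_map[[members[j]]])
        if (keep_phases) ph_store[, , member_idx[j]] <- phi_map[[members[j]]]
      }
      bmask <- fft_band_mask(n, band, fs)
      osc <- Re(stats::mvfft(stats::mvfft(osc) * bmask, inverse = TRUE)) / n
      series[, , member_idx] <- series[, , member_idx] +
        array(amp * osc, dim = c(n, n_epochs, length(members)))
      # uncoupled ROIs: independent narrowband carriers (already exactly
      # band-limited; Re(a) has unit RMS, cos has RMS 1/sqrt(2))
      uncoupled <- setdiff(seq_len(n_roi), member_idx)
      if (length(uncoupled) > 0) {
        a <- carrier_analytic(n, n_epochs * length(uncoupled), band, fs)
        series[, , uncoupled] <- series[, , uncoupled] +
          array((amp / sqrt(2)) * Re(a), dim = c(n, n_epochs, length(uncoupled)))
        if (keep_phases) {
          ph_store[, , uncoupled] <- array(Arg(a),
                                           dim = c(n, n_epochs, length(uncoupled)))
        }
      }
      if (keep_phases) phases[[band$name]] <- ph_store
    }
    structure(list(series = series, phases = phases, labels = labels,
                   fs = fs, coupling = coupling),
              class = "source_sim")
  })
}

#' Project ROI source activity to the sensor array
#'
#' Places one tangentially oriented dipole at each ROI centroid voxel,
#' multiplies the source series by the spherical-head lead fields, and adds
#' white Gaussian sensor noise scaled to the requested SNR.
#'
#' @param sources a `source_sim` from [simulate_sources()].
#' @param atlas,sensors,head geometry from [generate_geometry()].
#' @param snr ratio of mean sensor-level signal power to sensor noise power
#'   (`Inf` = noiseless; must be > 0).
#' @param seed integer seed for the sensor noise.
#' @param dipole_moment dipole strength in ampere-meters (default 1e-8).
#' @return object of class `epoched_recording`: list with `data` (array
#'   channels x samples x epochs), `fs`, `channel_id`.
#' @export
project_to_sensors <- function(sources, atlas, sensors, head, snr = 5,
                               seed = 1, dipole_moment = 1e-8) {
  if (snr <= 0) stop("snr must be > 0 (use Inf for a noiseless projection)")
  n_roi <- length(atlas$labels)
  stopifnot(identical(sources$labels, atlas$labels))
  G <- vapply(seq_len(n_roi), function(k) {
    vx <- atlas$voxels[atlas$centroid_index[k], ]
    Tb <- tangential_basis(vx, head)
    leadfield_sphere(vx, Tb[, 1] * dipole_moment, sensors, head)$gain
  }, numeric(nrow(sensors$position)))
  n_s <- dim(sources$series)[1]; n_ep <- dim(sources$series)[2]
  dat <- array(0, dim = c(nrow(sensors$position), n_s, n_ep))
  for (e in seq_len(n_ep)) {
    dat[, , e] <- G %*% t(sources$series[, e, ])
  }
  if (is.finite(snr)) {
    sig_pow <- mean(dat^2)
    noise_sd <- sqrt(sig_pow / snr)
    dat <- dat + with_seed(seed, array(stats::rnorm(length(dat), sd = noise_sd),
                                       dim = dim(dat)))
  }
  structure(list(data = dat, fs = sources$fs, channel_id = sensors$channel_id),
            class = "epoched_recording")
}
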