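test_that("radial dipoles are magnetically silent in the sphere", {
  g <- small_geometry()
  for (k in 1:2) {
    v <- g$atlas$voxels[g$atlas$centroid_index[k], ]
    radial <- v / sqrt(sum(v^2))
    Tb <- megconn:::tangential_basis(v, g$head)
    gr <- leadfield_sphere(v, radial, g$sensors, g$head)$gain
    gt <- leadfield_sphere(v, Tb[, 1], g$sensors, g$head)$gain
    expect_lt(sqrt(sum(gr^2)), 1e-12 * sqrt(sum(gt^2)))
  }
})

test_that("the lead field is linear in the dipole moment", {
  g <- small_geometry()
  v <- g$atlas$voxels[1, ]
  Tb <- megconn:::tangential_basis(v, g$head)
  l1 <- leadfield_sphere(v, Tb[, 1], g$sensors, g$head)$gain
  l2 <- leadfield_sphere(v, 2 * Tb[, 1], g$sensors, g$head)$gain
  expect_equal(l2, 2 * l1)
  l12 <- leadfield_sphere(v, Tb[, 1] + Tb[, 2], g$sensors, g$head)$gain
  expect_equal(l12, l1 + leadfield_sphere(v, Tb[, 2], g$sensors, g$head)$gain,
               tolerance = 1e-12)
})

test_that("lead field matches the gradient of the magnetic scalar potential", {
  skip_if_not_installed("pracma")
  g <- small_geometry()
  vx <- c(0.02, 0.01, 0.03)
  Q <- c(0, 1e-8, 0)
  lf <- leadfield_sphere(vx, Q, g$sensors, g$head)
  # independent route: outside the sphere B = -mu0 * grad(U) with
  # U(r) = -(1/4pi) (Q x r0 . r) / F(r); evaluated by Richardson-extrapolated
  # numerical differentiation
  qxr0 <- c(Q[2] * vx[3] - Q[3] * vx[2],
            Q[3] * vx[1] - Q[1] * vx[3],
            Q[1] * vx[2] - Q[2] * vx[1])
  U <- function(r) {
    a <- r - vx
    na <- sqrt(sum(a^2)); nr <- sqrt(sum(r^2))
    FF <- na * (nr * na + nr^2 - sum(vx * r))
    -sum(qxr0 * r) / (4 * pi * FF)
  }
  scale <- max(abs(lf$gain))
  for (i in c(1, 5, 12, 20)) {
    r <- g$sensors$position[i, ]
    B <- -4 * pi * 1e-7 * pracma::grad(U, r)
    expect_lt(abs(sum(B * g$sensors$orientation[i, ]) - lf$gain[i]) / scale,
              1e-8)
  }
})

test_that("dipoles at the center or outside the sphere are rejected", {
  g <- small_geometry()
  expect_error(leadfield_sphere(c(0, 0, 0), c(0, 1, 0), g$sensors, g$head),
               "center")
  expect_error(leadfield_sphere(c(0, 0, 0.2), c(0, 1, 0), g$sensors, g$head),
               "outside")
})

test_that("covariance of filtered white noise is proportional to identity", {
  withr::with_seed(3, {
    fs <- 625; n <- 4096; n_ep <- 2; n_ch <- 12; sigma <- 1.5
    dat <- array(rnorm(n_ch * n * n_ep, sd = sigma), c(n_ch, n, n_ep))
    rec <- structure(list(data = dat, fs = fs), class = "epoched_recording")
    band <- c(1, 300)
    C <- compute_covariance(rec, band = band)
    frac <- mean(megconn:::fft_band_mask(n, as_band(band), fs))
    expect_equal(diag(C), rep(sigma^2 * frac, n_ch), tolerance = 0.05)
    off <- C[upper.tri(C)]
    expect_lt(max(abs(off)), 0.05 * mean(diag(C)))
  })
})

test_that("covariance is symmetric, rank-1 for one source, pooling-invariant", {
  fix <- single_source_recording()
  C <- compute_covariance(fix$recording)
  expect_lt(max(abs(C - t(C))), 1e-12)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(abs(ev[2]) / ev[1], 1e-10)

  rec2 <- fix$recording
  rec2$data <- array(c(rec2$data, rec2$data),
                     dim = dim(rec2$data) * c(1, 1, 2))
  expect_equal(compute_covariance(rec2), C, tolerance = 1e-12)
})

test_that("identity covariance gives the closed-form weights l / (l'l)", {
  g <- small_geometry()
  n_ch <- nrow(g$sensors$position)
  m <- compute_weights(g$atlas$voxels[1, , drop = FALSE], g$sensors, g$head,
                       diag(n_ch), reg_fraction = 0)
  l <- m$leadfields[1, ]
  expect_equal(m$weights[1, ], l / sum(l^2), tolerance = 1e-10)
})

test_that("weights satisfy unit gain and survive rank-deficient covariance", {
  fix <- single_source_recording()
  g <- fix$geometry
  C <- compute_covariance(fix$recording)  # rank 1
  m <- compute_weights(g$atlas$voxels, g$sensors, g$head, C, reg_fraction = 0.05)
  gains <- rowSums(m$weights * m$leadfields)
  expect_equal(gains, rep(1, nrow(g$atlas$voxels)), tolerance = 1e-8)
  expect_true(all(is.finite(m$weights)))
  expect_error(compute_weights(g$atlas$voxels, g$sensors, g$head,
                               matrix(0, 24, 24), reg_fraction = 0),
               "reg_fraction")
})

test_that("a noiseless single source is reconstructed essentially exactly", {
  fix <- single_source_recording()
  g <- fix$geometry
  C <- compute_covariance(fix$recording)
  m <- compute_weights(g$atlas$voxels, g$sensors, g$head, C, reg_fraction = 0.05)
  vox <- reconstruct_voxels(fix$recording, m)
  cc <- cor(as.vector(vox[, , fix$voxel_index]), as.vector(fix$source))
  expect_gte(abs(cc), 0.999)
})

test_that("zero sensor data projects to zero and channel mismatch errors", {
  fix <- single_source_recording()
  g <- fix$geometry
  C <- compute_covariance(fix$recording)
  m <- compute_weights(g$atlas$voxels, g$sensors, g$head, C)
  rec0 <- fix$recording
  rec0$data[] <- 0
  expect_true(all(reconstruct_voxels(rec0, m) == 0))
  rec_bad <- fix$recording
  rec_bad$data <- rec_bad$data[1:10, , ]
  expect_error(reconstruct_voxels(rec_bad, m), "channel")
})

test_that("two well-separated sources reconstruct onto their own voxels", {
  g <- small_geometry()
  sim <- simulate_sources(
    g$atlas,
    list(coupling_spec("alpha2", rbind(g$atlas$labels[c(1, 3)]),
                       jitter_kappa = 0)),  # kappa 0: independent phases
    n_epochs = 3, epoch_samples = 4096, seed = 12)
  rec <- project_to_sensors(sim, g$atlas, g$sensors, g$head, snr = Inf)
  C <- compute_covariance(rec)
  m <- compute_weights(g$atlas$voxels, g$sensors, g$head, C, reg_fraction = 0.05)
  vox <- reconstruct_voxels(rec, m)
  for (k in c(1, 3)) {
    ci <- g$atlas$centroid_index[k]
    own <- abs(cor(as.vector(vox[, , ci]), as.vector(sim$series[, , k])))
    other <- abs(cor(as.vector(vox[, , ci]),
                     as.vector(sim$series[, , setdiff(c(1, 3), k)])))
    expect_gt(own, other)
  }
})

test_that("voxel selection takes the maximum-band-power voxel, ties to lowest", {
  g <- small_geometry()
  fs <- 625; n <- 4096; n_ep <- 2
  t <- (0:(n - 1)) / fs
  n_vox <- nrow(g$atlas$voxels)
  vox_series <- array(rnorm(n * n_ep * n_vox, sd = 1e-3), c(n, n_ep, n_vox))
  # ROI 1 has voxels 1,2: give voxel 2 the stronger alpha2 signal
  vox_series[, , 1] <- vox_series[, , 1] + 1.0 * sin(2 * pi * 11 * t)
  vox_series[, , 2] <- vox_series[, , 2] + 2.0 * sin(2 * pi * 11 * t)
  # ROI 2 (voxels 3,4): voxel 3 stronger in alpha2, voxel 4 stronger in theta
  vox_series[, , 3] <- vox_series[, , 3] + 1.5 * sin(2 * pi * 11 * t)
  vox_series[, , 4] <- vox_series[, , 4] + 1.5 * sin(2 * pi * 6 * t)
  sel_a2 <- select_roi_voxel(vox_series, g$atlas, "alpha2", fs)
  expect_equal(sel_a2$selected_voxel[1:2], c(2, 3))
  sel_th <- select_roi_voxel(vox_series, g$atlas, "theta", fs)
  expect_equal(sel_th$selected_voxel[2], 4)  # selection differs across bands
  expect_equal(dim(sel_a2$series), c(n, n_ep, 4))
})
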